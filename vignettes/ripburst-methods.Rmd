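---
title: "Detecting burst-like TE expansions under RIP-like hypermutation"
author: "ripburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting burst-like TE expansions under RIP-like hypermutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Many fungal genomes police repetitive DNA with a hypermutation defense of the
repeat-induced point mutation (RIP) type: C-to-T transitions concentrated in
a specific sequence context. In *Microbotryum* and relatives the preferred
context is the trinucleotide TpCpG (reverse complement CpGpA), whose mutated
forms are TpTpG and CpApA. ripburst analyses an intragenomic *population* of
transposable-element (TE) copies — a few hundred sequenced insertions of one
*Gypsy*-like family, labelled by strain and chromosome of origin — and asks
three questions:

1. Did the family expand in a **burst** (a temporally compressed episode that
   leaves a clade of near-identical copies), and which copies belong to it?
2. How much **RIP-like mutation load** does each copy carry relative to the
   common ancestor of the extant copies?
3. Does that load **limit proliferation** — are heavily mutated copies less
   fit, in the sense of sitting in sparsely branching parts of the tree?

## The pipeline

`rip_burst()` runs the stages in fixed order; every stage is also an exported
function.

**Sampling filters.** Clones shorter than 700 bp are discarded
(`filter_by_length()`); within each (strain, chromosome) sample, exact
duplicate sequences are collapsed to one representative
(`dedupe_within_chromosome()`), because identical clones from a single
chromosome may be re-amplifications of one locus, while identical sequences
on *different* chromosomes are genuinely distinct insertions. Deduplication
uses exact string equality only; near-duplicates are never collapsed. The
length filter runs before deduplication (the order is configurable and the
result differs only when a short clone shadows a longer duplicate).

**Hypermutation-site masking.** Because RIP converts many sites in parallel,
target-site columns carry convergent, tree-distorting signal. Before tree
building, every occurrence of the four motif forms (TCG, CGA, TTG, CAA) in
*any* row — located on the degapped row and mapped back to alignment columns,
so gap placement cannot hide a site — is removed (`build_site_mask()`,
`apply_mask()`). Masking is a single pass: deleting columns can create new
motif junctions, but those junctions are sequence artefacts, not mutable
sites, so iterating the mask would discard real signal.

**Tree building.** The default builder is neighbor joining on
Jukes–Cantor (JC69) distances computed from the masked alignment
(`jc69_dist_matrix()`, `nj_tree()`), with negative branch-length estimates
clamped to zero and saturated pairs (p ≥ 0.75) capped at 5 substitutions/site
(configurable). An externally built tree in newick format is accepted in
place of the internal builder (`tree =`); all downstream stages are agnostic
to tree provenance. Trees are rooted by placing the root at the midpoint of
the branch leading to a supplied outgroup copy (`root_with_outgroup()`).

**Ancestral reconstruction.** The "common ancestor of extant copies" is the
reconstructed sequence at the ingroup MRCA after outgroup rooting, computed
by marginal maximum likelihood under JC69 with uniform base frequencies
(`ancestral_reconstruct()`): Felsenstein pruning up the tree, back-messages
down, per-site posteriors at every internal node. Reconstruction runs on the
*unmasked* alignment — the masked columns are exactly the target sites whose
ancestral state the RIP scoring needs — while the tree (topology and branch
lengths) comes from the masked alignment and is not re-estimated. Gaps and
`N` are missing data; exact posterior ties break alphabetically (A < C < G <
T) for determinism; branch lengths are floored at 1e-8 before computing
transition matrices, because exact zeros (common in NJ estimates) would turn
state conflicts into all-zero posterior columns.

**RIP scoring.** For every occurrence of an unmutated motif in the degapped
ancestor, the copy is called mutated only if it carries the mutated motif
*exactly* — the transition at the mutable position with both flanking
context positions conserved (`count_rip_mutations()`). A mutated flank makes
the site's RIP status ambiguous, so it is uncallable rather than counted;
gaps and `N` likewise. Overlapping TCG/CGA occurrences count as separate
sites. This is deliberately an observer's definition: a background
substitution that happens to produce the mutated motif is scored as RIP,
because no sequence-level analysis can tell the mechanisms apart.

**Burst detection.** The expanded clade is defined operationally
(`find_expanded_clade()`): among internal nodes whose leaf set is
single-strain (optional for single-strain data), has at least `min_size = 10`
leaves, and has mean pairwise identity at least `min_identity = 0.985`, take
the one with the most leaves (ties: higher identity, then first in
postorder). The 98.5% default sits just below the identity peak that a
recent burst produces; both thresholds are configurable. Note a structural
property of this rule: because the qualifying statistic is a *mean*, the
largest qualifying clade tends to include the burst plus however many of its
closest relatives the identity budget tolerates; with a tight clade of n
copies at identity c, roughly n(c − min_identity)/(2(c − x)) outsiders at
cross-identity x can be swept in before disqualification.

**Fitness inference.** The local branching index (LBI) of a node is the
total surrounding branch length exponentially discounted by path distance at
a memory timescale tau: along a branch of length b a message m propagates as
tau(1 − e^(−b/tau)) + e^(−b/tau) m, and two passes give every node's index
exactly (`compute_lbi()`). High LBI marks lineages at the base of, or
inside, rapidly branching regions — a proxy for replicative fitness. Leaves
are ranked by descending LBI (rank 0 = fittest; exact ties break by leaf id)
and cut into quartiles at ranks ⌈n/4⌉, ⌈n/2⌉, ⌈3n/4⌉
(`rank_and_quartile()`). The outgroup is removed before LBI computation.
Spearman's rank correlation between per-copy RIP load and fitness rank (so
positive means more mutations in less-fit copies), per-quartile summaries
and all pairwise quartile Mann–Whitney tests come from
`correlate_rip_fitness()`.

**tau.** No tau is canonical for this family. The default is 0.05 × the
mean root-to-tip path length: in simulation calibration this short memory
both recovered the selection signal best and kept the neutral-case
correlation closest to zero, because it reads fitness off local branching
density rather than deep clade structure. `tau_sweep()` recomputes the
correlation over a grid of tau values so the stability of the conclusion
can be inspected rather than assumed.

**Distribution comparisons.** Identity-to-ancestor and pairwise-identity
distributions are contrasted between strains with the two-sample
Kolmogorov–Smirnov test (asymptotic) and the two-sided Mann–Whitney U test
(normal approximation with tie correction) via `compare_distributions()`.
p-values are reported singly, as is conventional for one or two planned
contrasts; no multiple-testing correction is applied, and
`stats::p.adjust()` is available when many contrasts are run.

## The simulator

`simulate_strain()` / `simulate_pair()` provide a forward-time Gillespie
birth process with full ground truth; every test input in the package comes
from it or from hand-built fixtures.

A copy carrying k RIP-mutated target sites transposes at rate
lambda0 · s^k; retrotransposition is copy-and-paste (no excision, no death
by default). Processing events mutate each currently intact target motif
independently with probability `f_rip`, and occur by two routes: at birth
with probability `p_rip` (duplication-triggered), and on every resident
copy at rate `rip_rate` per unit time, modelling hypermutation of repeats
during recurrent sexual cycles. The time-based route matters structurally:
with sampling at a single present time, every root-to-leaf path spans the
same duration, so only selection and the distribution of exposure can
differentiate leaves. A young burst clade has had almost no time-based
exposure while old lineages carry the accumulated load — which is what
makes the expanded clade RIP-poor relative to the rest of the genome, and
what lets a neutral (s = 1) run show no correlation between load and tree
position. Background substitutions accrue on every lineage as a Poisson
process (rate mu per site), at uniform sites with uniform alternative
bases; they may convert target sites, and such sites are scored by sequence
state like any other.

From `burst_time` on, one lineage — a copy of the least-mutated class,
uniform among ties — and its descendants transpose at `burst_factor` times
the base rate. Restricting the burst to a single founder lineage makes the
expansion a clade, and drawing the founder from the fittest class encodes
the conditioning implicit in analysing an *observed* massive expansion.
The family is seeded with `n_init = 5` identical resident copies (a TE
family enters a genome as an established cluster; a single seed could be
sterilised by one unlucky early processing event). The truth record
includes the genealogy (ultrametric in time), the founder, the true MRCA of
the extant copies (the founder lineage's state at the first birth — the
quantity the analysis reconstructs), and per-copy birth times, RIP-event
counts (total and since the MRCA), background-mutation counts and burst
membership.

**Default conditions.** L = 938 nt with 35 seeded TCG/CGA sites, 250 copies
sampled across 12 chromosomes, lambda0 = 1 (the time unit is one
transposition waiting time), s = 0.5, p_rip = 0.3, f_rip = 0.05,
rip_rate = 0.3, mu = 0.015, burst_factor 50 at burst_time 2.5 in the burst
strain of a pair, strain founders diverged for 2 time units, outgroup at
0.12 expected substitutions/site. These were calibrated once so that
simulated populations show the structure of field-scale data — a per-copy
RIP load of ~1.5 ± 1.8 with 50–80% of copies carrying at least one mutated
site, background identity to the ancestor in the low-90s%, a burst clade
containing 70–90% of the retained sample at ~99% mean pairwise identity,
and clear between-strain test rejections — while null (no-burst) runs
produce no qualifying clade. Raising mu separates recent null clades from
the 98.5% identity threshold; raising p_rip keeps the burst clade's own
identity near 99% so the clade rule does not overshoot.

**Numerical details.** The Gillespie waiting time is drawn from the summed
rates, held fixed between events; background and time-based processing are
applied along each interval. Waiting times longer than 25/lambda0 are
consumed in bounded chunks (exact, by memorylessness of the exponential),
which keeps Poisson draws finite even if RIP load collapses every rate, and
a step cap turns a truly stalled population into an informative error.
All randomness flows from one seeded stream; identical seed and parameters
give byte-identical outputs.

## What passing tests do and do not show

The simulator emulates the statistical structure the analysis assumes:
clock-like background divergence, context-dependent hypermutation with a
per-site fitness penalty, one clade born in a short window. It does not
emulate alignment error or indels (sequences stay positionally homologous,
so `rip_burst()` requires pre-aligned input and the masking/scoring
coordinate mapping is exercised by constructed gapped fixtures rather than
by the simulator), PCR/sequencing error, ectopic recombination, copy loss,
rate heterogeneity across sites, or base-compositional bias. Recovery of
the burst clade and of the selection signal on simulated data therefore
shows the method chain is correct and well-calibrated under its own
assumptions, not that real data meet those assumptions.

Two further simulator-specific caveats. First, with the inflated background
rate needed for clade/background separation at desk scale, roughly a third
of paired runs plant a background transition at a target middle on the
shared burst-founder path; the whole clade then scores one spurious RIP
mutation, which is realistic observer behaviour but blurs the inside/outside
contrast in those runs. Second, in burst runs the expanded clade dominates
the retained sample (~85%), so the rank correlation between RIP load and
fitness is strongest in non-burst populations, where load varies across the
whole tree; the correlation tests use that configuration.

## Problem sizes

Simulation-based tests run at the default population size (250 copies per
strain, ~500-tip combined trees) for the burst-detection and sieve checks,
100 copies for reconstruction accuracy, and 30–120 copies for unit and
determinism checks — sizes chosen to keep the full suite comfortably
reproducible on a laptop while preserving the statistical structure the
checks rely on.

## Known limitations

- The site mask is the union of motif occurrences over *all* rows, so it
  grows with sample size and divergence; at the simulator's inflated
  background rate a combined two-strain sample can mask the majority of
  columns, leaving the combined tree with less signal than the per-strain
  trees. On real data, background rates are far lower relative to the
  hypermutation signal and the mask stays modest.
- NJ trees on near-clonal expansions are star-like; diverged loner lineages
  occasionally nest inside the burst subtree and can fragment the clade
  call (observed in ~5–10% of calibration replicates). An externally built
  maximum-likelihood tree, supplied via `tree =`, is the remedy the
  interface anticipates.
- The JC69 model (uniform rates and frequencies) backs both distances and
  reconstruction; for strongly biased compositions a richer model would be
  needed, which is out of scope.
- Identity-based clade calling reports the sample fraction of the clade,
  not genomic copy number.
- The composite dinucleotide RIP indices used for *Neurospora*-style RIP
  are not implemented; the motif set is configurable instead
  (`rip_motifs("CA", "TA")`).
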