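# ripburst

Intragenomic analysis of transposable-element (TE) populations in genomes
with a RIP-like hypermutation defense.

Fungal genome defenses of the repeat-induced point mutation (RIP) type
hypermutate repetitive DNA — in *Microbotryum* and relatives, C→T
transitions in the trinucleotide context TpCpG (reverse complement CpGpA,
mutated forms TpTpG/CpApA). Given a few hundred sequenced copies of one TE
family, labelled by strain and chromosome of origin, `ripburst` asks whether
the family expanded in a recent **burst** (a clade of near-identical
copies), how much **RIP-like mutation load** each copy carries relative to
the reconstructed common ancestor of the extant copies, and whether that
load **limits proliferation** — i.e. whether heavily mutated copies have
low tree-shape fitness. It is aimed at molecular evolutionists studying
mobile-element dynamics and genome defense.

## The methods in brief

- **Sampling filters**: drop clones `< 700` bp; collapse exact duplicate
  sequences within each (strain, chromosome) sample — identical sequences
  on *different* chromosomes are distinct insertions and are kept.
- **Masking**: every occurrence of TCG/CGA/TTG/CAA in any row (found on
  degapped rows, mapped to alignment columns) is removed before tree
  building, because convergent hypermutation distorts phylogeny.
- **Tree**: neighbor joining on Jukes–Cantor distances,
  `d = -(3/4) log(1 - (4/3) p)`, from the masked alignment (or an external
  newick tree); rooted at the midpoint of the outgroup branch.
- **Ancestor**: marginal maximum-likelihood reconstruction (JC69,
  Felsenstein pruning + back-messages, per-site posteriors) of the ingroup
  MRCA, on the unmasked alignment.
- **RIP score**: per copy, ancestral target sites whose mutated motif
  appears exactly (transition at the mutable position, flanks conserved);
  ambiguous sites are uncallable, not counted.
- **Burst clade**: largest single-strain clade with ≥ 10 leaves and mean
  pairwise identity ≥ 98.5% (thresholds configurable).
- **Fitness**: local branching index (LBI) — total branch length
  exponentially discounted by path distance at timescale τ, computed by
  exact two-pass message passing (`m' = τ(1-e^{-b/τ}) + e^{-b/τ} m`);
  leaves ranked (0 = fittest) and quartiled; Spearman correlation of RIP
  load against rank, plus quartile-wise Mann–Whitney tests.
- **Simulator**: forward-time Gillespie birth process with copy-and-paste
  transposition at rate `λ0·s^k` (k = RIP-mutated sites carried),
  duplication-triggered and time-based RIP processing, background
  substitutions, and a one-lineage burst — with full ground truth
  (genealogy, true MRCA, per-copy event counts, burst membership).

## Worked example

Simulate a two-strain study — strain V with a factor-50 burst in one
founder lineage, strain S without — and run the full analysis:

```r
library(ripburst)

params <- sim_params(burst_factor = 50, seed = 7)
sim <- simulate_pair(params)
fit <- rip_burst(sim$copies, outgroup = sim$outgroup)
fit
```

```
TE expansion / RIP / fitness analysis
  copies: 501 read, 501 after length filter, 453 after dedupe (+1 outgroup counted)
  alignment width 938; 871 hypermutation-site columns masked for tree building
  V: n=202  RIP-mutated copies 44%  RIP load 0.89 +/- 1.28  rho(RIP, rank)=0.14
  S: n=250  RIP-mutated copies 65%  RIP load 1.60 +/- 1.70  rho(RIP, rank)=0.20
Expanded clade: 152 copies (75.2% of the V sample), mean pairwise identity 99.5%
  RIP load median inside/outside clade: 0 / 1 (Mann-Whitney p = 0.0082)
  V vs S: KS(identity to ancestor) D=0.747 p=0; MW(pairwise identity) p=0
```

Reading this: 48 identical within-chromosome clones were collapsed; the
burst shows up as a clade of 152 near-identical copies covering three
quarters of the V sample; copies inside the expanded clade carry fewer
RIP-like mutations than the rest of the genome (median 0 vs 1); and the
two strains' diversity distributions differ sharply. The per-strain
fitness analysis:

```r
fit$per_strain$S$correlation
```

```
RIP load vs fitness rank: Spearman rho = 0.199 (p = 0.00156, n = 250)
Per-quartile RIP-like mutation counts (quartile 1 = highest fitness):
 quartile  n median_rip mean_rip
        1 63          1 1.285714
        2 62          1 1.419355
        3 63          1 1.555556
        4 62          2 2.129032
```

A positive rho means more RIP-like mutations in less-fit copies: the
hypermutation defense acts as a selective sieve on proliferation. Use
`plot(fit)` for the diagnostic histograms, `summary(fit)` for a structured
summary, `write_rip_burst(fit, "out/")` for TSV/JSON/newick reports, and
`tau_sweep()` to check the correlation's sensitivity to the LBI timescale.
Real data enter through `read_te_fasta()` (pre-aligned FASTA with
`id|strain|chromosome` headers, or a metadata TSV) and, optionally,
`tree =` for an externally built phylogeny. A thin command-line front end
lives at `inst/cli/ripburst.R` (`run`, `sim` and `lbi` subcommands).

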