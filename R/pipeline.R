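#' Run the full TE expansion / RIP / fitness analysis
#'
#' Orchestrates the whole intragenomic analysis on a set of aligned TE copy
#' sequences: length filtering, within-chromosome deduplication, masking of
#' hypermutation target sites, per-strain tree building (internal
#' neighbor-joining on JC69 distances over the masked alignment, or an
#' externally built tree), outgroup rooting, marginal-ML ancestral
#' reconstruction on the unmasked alignment, per-copy RIP scoring against
#' the reconstructed ingroup-MRCA sequence, diversity summaries with
#' between-strain tests, expanded-clade detection on the combined tree, and
#' LBI-based fitness inference correlated with RIP load.
#'
#' @param copies TE copy data frame (from [read_te_fasta()] or a simulator),
#'   or a path to a FASTA file with `id|strain|chromosome` headers.
#'   Sequences must be pre-aligned (equal lengths); copies of the strain
#'   named by `outgroup_strain` are used only for rooting.
#' @param outgroup Id of the outgroup copy. Defaults to the single copy of
#'   strain `"outgroup"` if present.
#' @param tree Optional externally built tree (`phylo`, or path to a newick
#'   file) covering all retained copies; bypasses the internal NJ builder.
#' @param min_length Minimum ungapped copy length (see [filter_by_length()]).
#' @param dedupe Collapse identical sequences within a chromosome sample
#'   (see [dedupe_within_chromosome()]).
#' @param motifs Hypermutation motif set ([rip_motifs()]).
#' @param min_identity,min_size Expanded-clade thresholds
#'   (see [find_expanded_clade()]).
#' @param tau LBI memory timescale; `NULL` for the per-tree default
#'   (see [compute_lbi()]).
#' @param max_distance JC69 saturation cap (substitutions/site).
#' @return An object of class `rip_burst`; see [print.rip_burst()],
#'   [summary.rip_burst()], [plot.rip_burst()] and [write_rip_burst()].
#'   Components: `counts` (copies surviving each stage), `mask` (masked
#'   alignment columns), `strains`, `per_strain` (per-strain tree, ancestral
#'   reconstruction, RIP profile, diversity, fitness scores and RIP-fitness
#'   correlation), `combined` (combined tree, expanded-clade call, RIP load
#'   inside vs outside the clade), `tests` (between-strain distribution
#'   tests), `params`.
#' @export
rip_burst <- function(copies, outgroup = NULL, tree = NULL,
                      min_length = 700, dedupe = TRUE, motifs = rip_motifs(),
                      min_identity = 0.985, min_size = 10, tau = NULL,
                      max_distance = 5) {
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))

  if (is.character(copies) && length(copies) == 1L)
    copies <- stage("read", read_te_fasta(copies))
  stage("read", stopifnot(is.data.frame(copies),
                          all(c("id", "strain", "chromosome", "sequence") %in% names(copies))))
  counts <- c(input = nrow(copies))

  copies <- stage("length_filter", filter_by_length(copies, min_length))
  counts["after_length_filter"] <- nrow(copies)
  if (dedupe) copies <- stage("dedupe", dedupe_within_chromosome(copies))
  counts["after_dedupe"] <- nrow(copies)

  if (is.null(outgroup)) {
    og_rows <- which(copies$strain == "outgroup")
    if (length(og_rows) != 1L)
      stop("stage 'outgroup': supply `outgroup=` (no unique copy of strain 'outgroup')")
    outgroup <- copies$id[og_rows]
  }
  if (!outgroup %in% copies$id)
    stop("stage 'outgroup': outgroup id '", outgroup, "' not among retained copies")

  aln <- stage("alignment", as_alignment(setNames(copies$sequence, copies$id)))
  strain_of <- setNames(copies$strain, copies$id)
  ingroup_ids <- copies$id[copies$id != outgroup]
  strains <- unique(strain_of[ingroup_ids])

  mask <- stage("mask", build_site_mask(aln, motifs))
  aln_masked <- stage("mask", apply_mask(aln, mask))

  if (!is.null(tree)) {
    if (is.character(tree)) tree <- stage("tree", read_newick(tree))
    stage("tree", stopifnot(all(copies$id %in% tree$tip.label)))
    tree <- stage("tree", ape::keep.tip(tree, copies$id))
  }

  id_all <- stage("identity", identity_matrix(aln[ingroup_ids]))

  per_strain <- list()
  for (s in strains) {
    ids <- ingroup_ids[strain_of[ingroup_ids] == s]
    if (length(ids) < 3L)
      stop("stage 'tree': strain '", s, "' has ", length(ids),
           " ingroup copies; at least 3 are required")
    sub <- c(ids, outgroup)
    tr <- if (is.null(tree)) {
      d <- stage("tree", jc69_dist_matrix(aln_masked[sub], max_distance))
      stage("tree", nj_tree(d))
    } else stage("tree", ape::keep.tip(tree, sub))
    tr <- stage("root", root_with_outgroup(tr, outgroup))
    recon <- stage("ancestor", ancestral_reconstruct(tr, aln[sub]))
    anc_seq <- mrca_sequence(recon)
    rip <- stage("rip_profile",
                 rip_profile(c(aln[ids], ancestor = anc_seq), "ancestor", motifs))
    div <- stage("diversity",
                 diversity_summary(aln[ids], anc_seq, strain_of[ids],
                                   id_matrix = id_all[ids, ids, drop = FALSE]))
    ingroup_tree <- stage("fitness", ape::drop.tip(tr, outgroup))
    lbi <- stage("fitness", compute_lbi(ingroup_tree, tau))
    scores <- stage("fitness",
                    rank_and_quartile(lbi[ingroup_tree$tip.label]))
    corr <- stage("fitness", correlate_rip_fitness(rip, scores))
    per_strain[[s]] <- list(ids = ids, tree = tr, recon = recon,
                            ancestor = anc_seq, rip = rip,
                            diversity = div[[s]], lbi = lbi, scores = scores,
                            correlation = corr)
  }

  combined_tree <- if (length(strains) > 1L) {
    if (is.null(tree)) {
      d <- stage("tree", jc69_dist_matrix(aln_masked, max_distance))
      stage("root", root_with_outgroup(stage("tree", nj_tree(d)), outgroup))
    } else stage("root", root_with_outgroup(tree, outgroup))
  } else per_strain[[strains[1L]]]$tree

  clade <- stage("expansion",
                 find_expanded_clade(combined_tree, aln[ingroup_ids],
                                     strain_of, min_identity, min_size,
                                     require_single_strain = length(strains) > 1L,
                                     id_matrix = id_all))
  clade_rip <- NULL
  if (!is.null(clade) && !is.na(clade$strain)) {
    prof <- per_strain[[clade$strain]]$rip
    inside <- prof$n_rip_mutations[prof$copy_id %in% clade$leaf_ids]
    outside <- prof$n_rip_mutations[!prof$copy_id %in% clade$leaf_ids]
    clade_rip <- list(
      median_inside = stats::median(inside),
      median_outside = if (length(outside)) stats::median(outside) else NA_real_,
      test = if (length(outside))
        stage("expansion", compare_distributions(inside, outside, "mannwhitney"))
      else NULL)
  }

  tests <- NULL
  if (length(strains) > 1L) {
    pairs <- utils::combn(strains, 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1L, i]; b <- pairs[2L, i]
      ks <- compare_distributions(
        per_strain[[a]]$diversity$identity_to_ancestor,
        per_strain[[b]]$diversity$identity_to_ancestor, "ks")
      mw <- compare_distributions(
        per_strain[[a]]$diversity$pairwise_identities,
        per_strain[[b]]$diversity$pairwise_identities, "mannwhitney")
      data.frame(strain_a = a, strain_b = b,
                 ks_identity_to_ancestor_D = ks$statistic,
                 ks_identity_to_ancestor_p = ks$p_value,
                 mw_pairwise_identity_U = mw$statistic,
                 mw_pairwise_identity_p = mw$p_value,
                 stringsAsFactors = FALSE)
    }))
  }

  structure(list(copies = copies, counts = counts, outgroup = outgroup,
                 mask = mask, width = aln_width(aln), strains = strains,
                 per_strain = per_strain,
                 combined = list(tree = combined_tree, clade = clade,
                                 clade_rip = clade_rip),
                 tests = tests,
                 params = list(min_length = min_length, dedupe = dedupe,
                               motifs = motifs, min_identity = min_identity,
                               min_size = min_size, tau = tau,
                               max_distance = max_distance,
                               external_tree = !is.null(tree))),
            class = "rip_burst")
}
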