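#' Per-strain sequence diversity summary
#'
#' For each strain, computes the identity of every copy to the (reconstructed)
#' ancestral sequence and the identity of every unordered pair of copies.
#' A burst-like expansion shows up as a sharp mode in the identity-to-ancestor
#' distribution and a peak of near-identical pairs.
#'
#' @param aln Named character vector of equal-width gapped sequences (copies
#'   only; the ancestor is passed separately).
#' @param ancestor Ancestral sequence aligned to `aln` (same width).
#' @param strain_of Named character vector mapping every row id of `aln` to
#'   its strain.
#' @param id_matrix Optional precomputed [identity_matrix()] of `aln`.
#' @return An object of class `diversity_summary`: a list with one element
#'   per strain, each holding `identity_to_ancestor` (named vector, one per
#'   copy) and `pairwise_identities` (vector of length n(n-1)/2).
#' @export
diversity_summary <- function(aln, ancestor, strain_of, id_matrix = NULL) {
  aln <- as_alignment(aln)
  if (nchar(ancestor) != aln_width(aln))
    stop("ancestor width does not match alignment")
  miss <- setdiff(names(aln), names(strain_of))
  if (length(miss)) stop("no strain label for: ", paste(miss, collapse = ", "))
  if (is.null(id_matrix)) id_matrix <- identity_matrix(aln)
  to_anc <- vapply(aln, pairwise_identity, 0, b = ancestor)
  per_strain <- lapply(split(names(aln), strain_of[names(aln)]), function(ids) {
    sub <- id_matrix[ids, ids, drop = FALSE]
    list(identity_to_ancestor = to_anc[ids],
         pairwise_identities = sub[upper.tri(sub)])
  })
  structure(per_strain, class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat("Sequence diversity summary\n")
  for (s in names(x)) {
    a <- x[[s]]$identity_to_ancestor
    p <- x[[s]]$pairwise_identities
    cat(sprintf("  %s: n=%d  identity to ancestor %.3f (median %.3f)  pairwise %.3f\n",
                s, length(a), mean(a), stats::median(a), mean(p)))
  }
  invisible(x)
}

#' Two-sample distribution comparison
#'
#' Two-sample Kolmogorov-Smirnov test (supremum of ECDF difference,
#' asymptotic p-value) or two-sided Mann-Whitney U test (normal approximation
#' with tie correction), as used to contrast diversity distributions between
#' strains.
#'
#' @param x,y Non-empty numeric vectors.
#' @param test `"ks"` or `"mannwhitney"`.
#' @return A list with `statistic`, `p_value` and `test`.
#' @examples
#' compare_distributions(c(1, 2, 3), c(4, 5, 6), "mannwhitney")  # U = 0
#' @export
compare_distributions <- function(x, y, test = c("ks", "mannwhitney")) {
  test <- match.arg(test)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (test == "ks") {
    res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    list(statistic = unname(res$statistic), p_value = res$p.value, test = "ks")
  } else {
    res <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    list(statistic = unname(res$statistic), p_value = res$p.value,
         test = "mannwhitney")
  }
}

#' Find the expanded clade of near-identical elements
#'
#' Operational definition of a burst clade: among all internal nodes of the
#' rooted tree whose leaf set (i) is single-strain (optional), (ii) has at
#' least `min_size` leaves, and (iii) has mean pairwise sequence identity of
#' at least `min_identity`, return the one with the most leaves. Ties go to
#' the higher mean identity, then to the first qualifying node in postorder.
#'
#' @param tree Rooted `phylo` tree of the TE copies (outgroup, if present as
#'   `tree$outgroup`, is ignored automatically).
#' @param aln Named character vector covering all leaves considered.
#' @param strain_of Named character vector mapping leaf ids to strains.
#' @param min_identity Minimum mean pairwise identity (default 0.985, the
#'   neighbourhood of the identity peak typical of a recent burst).
#' @param min_size Minimum clade size (default 10).
#' @param require_single_strain If `TRUE` (default) only strain-pure clades
#'   qualify; disable for single-strain data sets.
#' @param id_matrix Optional precomputed [identity_matrix()] of `aln`.
#' @return `NULL` if no clade qualifies, else a list of class `clade_call`:
#'   `leaf_ids`, `mean_pairwise_identity`, `fraction_of_strain_sample`
#'   (clade size over the number of sampled copies of that strain), `strain`
#'   and `node` (internal node number).
#' @export
find_expanded_clade <- function(tree, aln, strain_of, min_identity = 0.985,
                                min_size = 10, require_single_strain = TRUE,
                                id_matrix = NULL) {
  aln <- as_alignment(aln)
  drop <- if (!is.null(tree$outgroup)) tree$outgroup else character(0)
  leaves <- setdiff(tree$tip.label, drop)
  if (!all(leaves %in% names(aln)))
    stop("leaves missing from alignment: ",
         paste(setdiff(leaves, names(aln)), collapse = ", "))
  if (is.null(id_matrix)) id_matrix <- identity_matrix(aln[leaves])
  ntip <- ape::Ntip(tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  nn <- ntip + tr$Nnode
  leaf_sets <- vector("list", nn)
  wsum <- vector("list", nn)      # column sums of id_matrix over the leaf set
  idx <- match(tr$tip.label, rownames(id_matrix))
  for (i in seq_len(ntip)) {
    if (is.na(idx[i])) next       # outgroup: excluded from candidate sets
    leaf_sets[[i]] <- idx[i]
    wsum[[i]] <- id_matrix[idx[i], ]
  }
  best <- NULL
  # postorder over internal nodes (order of first appearance as edge parent)
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; child <- edge[e, 2L]
    if (is.null(leaf_sets[[child]]) && child <= ntip) next
    if (is.null(leaf_sets[[child]])) next
    leaf_sets[[par]] <- c(leaf_sets[[par]], leaf_sets[[child]])
    wsum[[par]] <- if (is.null(wsum[[par]])) wsum[[child]] else wsum[[par]] + wsum[[child]]
  }
  internal_postorder <- unique(edge[, 1L])
  n_by_strain <- table(strain_of[leaves])
  for (node in internal_postorder) {
    set <- leaf_sets[[node]]
    m <- length(set)
    if (m < min_size) next
    ids <- rownames(id_matrix)[set]
    strains <- unique(strain_of[ids])
    if (require_single_strain && length(strains) != 1L) next
    mean_id <- (sum(wsum[[node]][set]) - m) / (m * (m - 1))
    if (is.nan(mean_id) || mean_id < min_identity) next
    better <- is.null(best) || m > length(best$leaf_ids) ||
      (m == length(best$leaf_ids) && mean_id > best$mean_pairwise_identity)
    if (better) {
      frac <- if (length(strains) == 1L) m / as.integer(n_by_strain[[strains]])
              else m / length(leaves)
      best <- structure(list(leaf_ids = ids, mean_pairwise_identity = mean_id,
                             fraction_of_strain_sample = frac,
                             strain = if (length(strains) == 1L) strains else NA_character_,
                             node = node),
                        class = "clade_call")
    }
  }
  best
}

#' @export
print.clade_call <- function(x, ...) {
  cat(sprintf("Expanded clade: %d copies (%.1f%% of the %s sample), mean pairwise identity %.1f%%\n",
              length(x$leaf_ids), 100 * x$fraction_of_strain_sample,
              if (is.na(x$strain)) "combined" else x$strain,
              100 * x$mean_pairwise_identity))
  invisible(x)
}
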