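#' Pairwise sequence identity between two aligned rows
#'
#' Identity is the fraction of matching columns among columns where both
#' rows carry an unambiguous base (`A`, `C`, `G` or `T`); gaps and `N` are
#' excluded from the comparison.
#'
#' @param a,b Gapped sequences of equal length.
#' @return A value in \[0, 1\], or `NaN` if no column is comparable.
#' @examples
#' pairwise_identity("ACGT", "ACGA")  # 0.75
#' pairwise_identity("AC-T", "ACGT")  # 1.0 (3 comparable columns)
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences have unequal lengths")
  x <- strsplit(toupper(a), "")[[1L]]
  y <- strsplit(toupper(b), "")[[1L]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NaN)
  sum(x[ok] == y[ok]) / sum(ok)
}

#' All-against-all identity matrix of an alignment
#'
#' Vectorised computation of [pairwise_identity()] for every pair of rows.
#'
#' @param aln Named character vector of equal-width gapped sequences.
#' @return An n x n symmetric matrix of identities with unit diagonal;
#'   entries are `NaN` where a pair shares no comparable column.
#' @export
identity_matrix <- function(aln) {
  m <- aln_char_matrix(aln)
  n <- nrow(m)
  match_cnt <- matrix(0, n, n)
  valid <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    ind <- (m == b) * 1
    match_cnt <- match_cnt + tcrossprod(ind)
  }
  v <- (m == "A" | m == "C" | m == "G" | m == "T") * 1
  valid <- tcrossprod(v)
  out <- match_cnt / valid
  diag(out) <- ifelse(diag(valid) > 0, 1, NaN)
  dimnames(out) <- list(rownames(m), rownames(m))
  out
}

#' Jukes-Cantor (JC69) distance between two aligned rows
#'
#' `d = -(3/4) log(1 - (4/3) p)` where `p` is the proportion of mismatching
#' comparable columns. Saturated pairs (`p >= 0.75`, where the formula
#' diverges) are capped at `max_distance`.
#'
#' @param a,b Gapped sequences of equal length.
#' @param max_distance Cap (substitutions/site) for saturated pairs.
#' @return Distance in expected substitutions per site.
#' @export
jc69_distance <- function(a, b, max_distance = 5) {
  id <- pairwise_identity(a, b)
  if (is.nan(id)) stop("no comparable columns between sequences")
  jc69_from_p(1 - id, max_distance)
}

jc69_from_p <- function(p, max_distance = 5) {
  d <- ifelse(p >= 0.75, max_distance, -0.75 * log(pmax(1 - 4 * p / 3, .Machine$double.xmin)))
  pmin(pmax(d, 0), max_distance)
}

#' JC69 distance matrix of an alignment
#'
#' @param aln Named character vector of equal-width gapped sequences.
#' @param max_distance Cap for saturated pairs (substitutions/site).
#' @return An n x n symmetric distance matrix (zero diagonal).
#' @export
jc69_dist_matrix <- function(aln, max_distance = 5) {
  id <- identity_matrix(aln)
  if (anyNA(id) || any(is.nan(id)))
    stop("some sequence pair has no comparable columns")
  d <- jc69_from_p(1 - id, max_distance)
  diag(d) <- 0
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}); negative branch-length
#' estimates, which NJ can produce on non-additive matrices, are clamped
#' to zero. The result is an unrooted topology stored with an arbitrary
#' basal trichotomy; root it with [root_with_outgroup()].
#'
#' @param d Symmetric distance matrix with zero diagonal and row/col names,
#'   or a `dist` object.
#' @return An \pkg{ape} `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) stop("distance matrix must have row names")
  tr <- ape::nj(as.dist(d))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Root a tree with an outgroup
#'
#' Places the root at the midpoint of the branch leading to the outgroup
#' leaf. The returned tree carries `$ingroup_mrca`, the node number of the
#' most recent common ancestor of all non-outgroup leaves, and `$outgroup`,
#' the outgroup label.
#'
#' @param tree A `phylo` tree (rooted or unrooted).
#' @param outgroup Label of the outgroup leaf.
#' @return A rooted `phylo` tree with elements `ingroup_mrca` and `outgroup`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup leaf '", outgroup, "' not in tree")
  tr <- ape::root(ape::unroot(tree), outgroup = outgroup, resolve.root = TRUE)
  root <- ape::Ntip(tr) + 1L
  re <- which(tr$edge[, 1L] == root)
  if (length(re) != 2L) stop("rooting failed to produce a binary root")
  total <- sum(tr$edge.length[re])
  tr$edge.length[re] <- total / 2
  og_tip <- match(outgroup, tr$tip.label)
  kids <- tr$edge[re, 2L]
  if (!og_tip %in% kids)
    stop("outgroup is not attached at the root after rooting")
  tr$ingroup_mrca <- kids[kids != og_tip]
  tr$outgroup <- outgroup
  tr
}

#' Read / write trees in newick format
#'
#' Thin wrappers around \pkg{ape}'s newick I/O adding support for
#' single-quoted labels (which may contain spaces and punctuation),
#' defaulting absent branch lengths to 0, and validating that leaf names
#' are unique.
#'
#' @param x A file path or a newick string.
#' @return For `read_newick`, a `phylo` tree.
#' @export
read_newick <- function(x) {
  text <- if (length(x) == 1L && !grepl("[(;]", x) && file.exists(x))
    paste(readLines(x, warn = FALSE), collapse = "") else paste(x, collapse = "")
  quoted <- regmatches(text, gregexpr("'[^']*'", text))[[1L]]
  restore <- character(0)
  if (length(quoted)) {
    ph <- sprintf("RIPBURSTQL%dX", seq_along(quoted))
    restore <- setNames(substr(quoted, 2L, nchar(quoted) - 1L), ph)
    for (i in seq_along(quoted)) text <- sub(quoted[i], ph[i], text, fixed = TRUE)
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("invalid newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("invalid newick: could not parse tree text")
  fix <- function(lab) {
    hit <- match(lab, names(restore))
    ifelse(is.na(hit), lab, unname(restore[hit]))
  }
  tr$tip.label <- fix(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- fix(tr$node.label)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf names in newick: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr
}

#' @rdname read_newick
#' @param tree A `phylo` tree.
#' @param path Optional output file; if `NULL` the newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  needs_quote <- function(lab) grepl("[^A-Za-z0-9_.|/-]", lab)
  placeholder <- function(labs, off) sprintf("RIPBURSTQL%dX", off + seq_along(labs))
  tipq <- which(needs_quote(tree$tip.label))
  nodq <- if (is.null(tree$node.label)) integer(0) else which(needs_quote(tree$node.label))
  orig_tip <- tree$tip.label[tipq]; orig_nod <- tree$node.label[nodq]
  tree$tip.label[tipq] <- placeholder(orig_tip, 0L)
  if (length(nodq)) tree$node.label[nodq] <- placeholder(orig_nod, length(tipq))
  txt <- ape::write.tree(tree, digits = 10)
  ph <- c(tree$tip.label[tipq], if (length(nodq)) tree$node.label[nodq])
  orig <- c(orig_tip, orig_nod)
  for (i in seq_along(ph))
    txt <- sub(ph[i], paste0("'", orig[i], "'"), txt, fixed = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
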