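# JC69 transition probability matrix for branch length d (subs/site)
jc69_pmat <- function(d) {
  e <- exp(-4 * d / 3)
  same <- 0.25 + 0.75 * e
  diff <- 0.25 - 0.25 * e
  m <- matrix(diff, 4L, 4L)
  diag(m) <- same
  m
}

BASES <- c("A", "C", "G", "T")

# 4 x L conditional likelihood matrix for one leaf row; gaps/N are missing
leaf_likelihood <- function(row) {
  ch <- strsplit(row, "")[[1L]]
  L <- length(ch)
  m <- matrix(1, 4L, L)
  for (b in seq_along(BASES)) {
    hit <- ch == BASES[b]
    m[, hit] <- 0
    m[b, hit] <- 1
  }
  m
}

#' Marginal maximum-likelihood ancestral sequence reconstruction
#'
#' Reconstructs ancestral states at every internal node of a rooted tree
#' under the JC69 substitution model with uniform base frequencies, sites
#' independent, by two-pass (Felsenstein pruning + back-message) belief
#' propagation. Gaps and `N` in the alignment are treated as missing data
#' (partial likelihood 1 for all states). At each site the state with the
#' highest marginal posterior is reported; exact ties are broken
#' alphabetically (A < C < G < T) for determinism. Branch lengths are used
#' as given (no re-estimation).
#'
#' @param tree A rooted `phylo` tree (e.g. from [root_with_outgroup()]);
#'   every tip label must be a row of `aln`.
#' @param aln Named character vector of equal-width gapped sequences. The
#'   unmasked alignment should be used here: reconstruction must cover the
#'   hypermutation target sites that were excluded from tree building.
#' @return An object of class `ancestral_recon`: a list with
#'   \describe{
#'     \item{sequences}{named character vector of reconstructed sequences,
#'       one per internal node, named `node<N>` by node number;}
#'     \item{posterior}{list of 4 x width matrices of per-site posteriors
#'       (rows A,C,G,T), one per internal node;}
#'     \item{mrca}{node number of the ingroup MRCA if the tree carries one
#'       (see [root_with_outgroup()]), else the root;}
#'     \item{tree}{the input tree.}
#'   }
#' @seealso [mrca_sequence()]
#' @export
ancestral_reconstruct <- function(tree, aln) {
  aln <- as_alignment(aln)
  if (!all(tree$tip.label %in% names(aln)))
    stop("leaves missing from alignment: ",
         paste(setdiff(tree$tip.label, names(aln)), collapse = ", "))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  root <- ntip + 1L
  L <- aln_width(aln)
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  # floor branch lengths: exact zeros (common in NJ estimates) make P the
  # identity, whose hard zeros annihilate whole posterior columns when
  # zero-length paths carry conflicting states
  elen <- pmax(tr$edge.length, 1e-8)
  P <- lapply(elen, jc69_pmat)

  up <- vector("list", ntip + nnode)      # conditional likelihoods
  for (i in seq_len(ntip)) up[[i]] <- leaf_likelihood(aln[[tr$tip.label[i]]])
  umsg <- vector("list", nrow(edge))      # P %*% up[child], per edge
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; child <- edge[e, 2L]
    umsg[[e]] <- P[[e]] %*% up[[child]]
    up[[par]] <- if (is.null(up[[par]])) umsg[[e]] else up[[par]] * umsg[[e]]
    # rescale per site to avoid underflow on deep trees (scalars cancel in marginals)
    sc <- pmax(apply(up[[par]], 2L, max), .Machine$double.xmin)
    up[[par]] <- sweep(up[[par]], 2L, sc, "/")
  }

  down <- vector("list", ntip + nnode)    # messages from the rest of the tree
  down[[root]] <- matrix(0.25, 4L, L)
  for (e in rev(seq_len(nrow(edge)))) {   # preorder
    par <- edge[e, 1L]; child <- edge[e, 2L]
    sibs <- which(edge[, 1L] == par & edge[, 2L] != child)
    m <- down[[par]]
    for (s in sibs) m <- m * umsg[[s]]
    d <- crossprod(P[[e]], m)             # t(P) %*% m
    sc <- pmax(apply(d, 2L, max), .Machine$double.xmin)
    down[[child]] <- sweep(d, 2L, sc, "/")
  }

  internal <- root:(ntip + nnode)
  sequences <- character(nnode)
  posterior <- vector("list", nnode)
  for (j in seq_along(internal)) {
    node <- internal[j]
    marg <- up[[node]] * down[[node]]
    tot <- colSums(marg)
    marg <- sweep(marg, 2L, pmax(tot, .Machine$double.xmin), "/")
    best <- apply(marg, 2L, which.max)    # ties -> lowest index = alphabetical
    sequences[j] <- paste(BASES[best], collapse = "")
    posterior[[j]] <- marg
  }
  names(sequences) <- names(posterior) <- paste0("node", internal)
  structure(list(sequences = sequences, posterior = posterior,
                 mrca = if (!is.null(tree$ingroup_mrca)) tree$ingroup_mrca else root,
                 tree = tree),
            class = "ancestral_recon")
}

#' Reconstructed sequence at the ingroup MRCA
#'
#' @param recon An `ancestral_recon` object.
#' @param node Node number (default: the ingroup MRCA recorded at
#'   reconstruction time).
#' @return The reconstructed sequence string.
#' @export
mrca_sequence <- function(recon, node = recon$mrca) {
  stopifnot(inherits(recon, "ancestral_recon"))
  key <- paste0("node", node)
  if (!key %in% names(recon$sequences)) stop("no reconstruction for node ", node)
  recon$sequences[[key]]
}

#' @export
print.ancestral_recon <- function(x, ...) {
  cat("Ancestral reconstruction (JC69, marginal ML)\n")
  cat("  internal nodes:", length(x$sequences), "\n")
  cat("  ingroup MRCA  : node", x$mrca, "\n")
  post <- x$posterior[[paste0("node", x$mrca)]]
  cat(sprintf("  mean max-posterior at MRCA: %.4f\n", mean(apply(post, 2L, max))))
  invisible(x)
}
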