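# Shared helpers and independent oracles for the test suite.

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1L]]), collapse = ""), ""))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Random rooted tree with positive branch lengths (deterministic under a seed)
random_tree <- function(n, min_bl = 0.01, max_bl = 0.3) {
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

# Independent LBI oracle: discretise every branch into short segments and sum
# exp(-d(node, segment midpoint)/tau) * delta over all segments, using path
# distances from ape::dist.nodes. Shares nothing with the message-passing
# implementation.
lbi_oracle <- function(tree, tau, nseg = 400) {
  D <- ape::dist.nodes(tree)
  nn <- ape::Ntip(tree) + tree$Nnode
  out <- numeric(nn)
  for (i in seq_len(nn)) {
    tot <- 0
    for (e in seq_len(nrow(tree$edge))) {
      b <- tree$edge.length[e]
      if (b <= 0) next
      dnear <- min(D[i, tree$edge[e, 1L]], D[i, tree$edge[e, 2L]])
      delta <- b / nseg
      mids <- (seq_len(nseg) - 0.5) * delta
      tot <- tot + sum(exp(-(dnear + mids) / tau)) * delta
    }
    out[i] <- tot
  }
  names(out) <- c(tree$tip.label, paste0("node", (ape::Ntip(tree) + 1L):nn))
  out
}

# Ultrametric check in time units with tolerance
is_ultrametric <- function(tree, tol = 1e-8) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  diff(range(d)) < tol
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# A tiny deterministic simulated data set used by several files
small_sim <- function(seed = 11, n_max = 60, ...) {
  p <- sim_params(n_max = n_max, seed = seed, ...)
  simulate_strain(p, strain = "A", outgroup_divergence = 0.12)
}
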