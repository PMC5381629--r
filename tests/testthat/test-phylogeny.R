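test_that("pairwise identity counts matches over comparable columns only", {
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  expect_equal(pairwise_identity("AC-T", "ACGT"), 1.0)
  expect_equal(pairwise_identity("ACNT", "ACGT"), 1.0)
  s <- random_seq(50)
  expect_equal(pairwise_identity(s, s), 1.0)
  expect_true(is.nan(pairwise_identity("----", "AAAA")))
  expect_error(pairwise_identity("AC", "ACG"), "unequal")
})

test_that("identity matrix agrees with the scalar computation", {
  set.seed(3)
  aln <- setNames(replicate(6, random_seq(60)), letters[1:6])
  substr(aln[2], 5, 9) <- "-----"
  M <- identity_matrix(aln)
  for (i in 1:6) for (j in 1:6)
    expect_equal(M[i, j], pairwise_identity(aln[[i]], aln[[j]]))
})

test_that("JC69 distance follows the closed form and saturates at the cap", {
  s <- random_seq(100)
  expect_equal(jc69_distance(s, s), 0)
  # p = 0.3 by construction: change 30 of 100 sites
  x <- strrep("A", 100)
  y <- paste0(strrep("C", 30), strrep("A", 70))
  expect_equal(jc69_distance(x, y), -0.75 * log(1 - 0.4))
  # p = 0.75 saturates
  z <- paste0(strrep("C", 75), strrep("A", 25))
  expect_equal(jc69_distance(x, z), 5)
  expect_equal(jc69_distance(x, z, max_distance = 2), 2)
  expect_error(jc69_distance("----", "AAAA"), "comparable")
})

test_that("JC69 matrix agrees with ape::dist.dna", {
  set.seed(8)
  aln <- setNames(replicate(5, random_seq(300)), letters[1:5])
  # introduce moderate divergence from a common template
  base <- random_seq(300)
  aln <- vapply(1:5, function(i) {
    ch <- strsplit(base, "")[[1]]
    idx <- sample(300, 30)
    ch[idx] <- sample(c("A", "C", "G", "T"), 30, TRUE)
    paste(ch, collapse = "")
  }, "")
  names(aln) <- letters[1:5]
  d_mine <- jc69_dist_matrix(aln)
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(aln), ""), identity)))
  d_ape <- as.matrix(ape::dist.dna(bin, model = "JC69"))
  expect_equal(unname(d_mine), unname(d_ape), tolerance = 1e-10)
})

test_that("NJ recovers additive trees exactly", {
  # 4-taxon tree with known branch lengths; its cophenetic matrix is additive
  true4 <- read_newick("((A:0.12,B:0.07):0.05,(C:0.11,D:0.23):0.03);")
  D4 <- ape::cophenetic.phylo(true4)
  nj4 <- nj_tree(D4)
  expect_equal(ape::dist.topo(ape::unroot(true4), ape::unroot(nj4)), structure(0L, class = NULL),
               ignore_attr = TRUE)
  expect_lt(max(abs(ape::cophenetic.phylo(nj4)[rownames(D4), rownames(D4)] - D4)), 1e-9)

  true5 <- read_newick("(((A:0.04,B:0.09):0.06,C:0.2):0.02,(D:0.15,E:0.05):0.08);")
  D5 <- ape::cophenetic.phylo(true5)
  nj5 <- nj_tree(D5)
  expect_equal(ape::dist.topo(ape::unroot(true5), ape::unroot(nj5)), structure(0L, class = NULL),
               ignore_attr = TRUE)
  expect_lt(max(abs(ape::cophenetic.phylo(nj5)[rownames(D5), rownames(D5)] - D5)), 1e-9)
})

test_that("3-taxon NJ matches the closed-form star resolution", {
  D <- matrix(c(0, 0.3, 0.4,
                0.3, 0, 0.5,
                0.4, 0.5, 0), 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  # closed form: x_a = (dab + dac - dbc)/2, etc.
  expected <- c(a = 0.1, b = 0.2, c = 0.3)
  got <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])], tr$tip.label)
  expect_equal(got[names(expected)], expected)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ joins the correct cherries first on a pair-of-cherries matrix", {
  labs <- c("a", "b", "c", "d")
  D <- matrix(c(0, 0.2, 1, 1,
                0.2, 0, 1, 1,
                1, 1, 0, 0.2,
                1, 1, 0.2, 0), 4, 4, dimnames = list(labs, labs))
  tr <- ape::unroot(nj_tree(D))
  # a-b and c-d must be sisters
  mrca_ab <- ape::getMRCA(tr, c("a", "b"))
  expect_setequal(ape::extract.clade(ape::root(tr, "c", resolve.root = TRUE),
                                     mrca_ab)$tip.label, c("a", "b"))
})

test_that("negative NJ branch estimates are clamped to zero", {
  set.seed(10)
  # non-additive noisy matrix often yields negative NJ branches in raw form
  for (i in 1:5) {
    n <- 6
    M <- matrix(runif(n * n, 0.01, 0.5), n, n)
    D <- (M + t(M)) / 2; diag(D) <- 0
    dimnames(D) <- list(letters[1:n], letters[1:n])
    expect_true(all(nj_tree(D)$edge.length >= 0))
  }
})

test_that("outgroup rooting places the root mid-outgroup-branch", {
  tr <- read_newick("(A:0.1,B:0.2,OUT:0.6);")
  r <- root_with_outgroup(tr, "OUT")
  expect_true(ape::is.rooted(r))
  root <- ape::Ntip(r) + 1L
  re <- which(r$edge[, 1] == root)
  expect_equal(sort(r$edge.length[re]), c(0.3, 0.3))
  # ingroup MRCA subtends exactly A and B
  desc <- ape::extract.clade(r, r$ingroup_mrca)$tip.label
  expect_setequal(desc, c("A", "B"))
  expect_error(root_with_outgroup(tr, "nope"), "not in tree")
})

test_that("re-rooting with the same outgroup is idempotent on topology", {
  set.seed(12)
  tr <- random_tree(8)
  r1 <- root_with_outgroup(tr, "t1")
  r2 <- root_with_outgroup(r1, "t1")
  expect_equal(suppressWarnings(ape::dist.topo(r1, r2)), structure(0L),
               ignore_attr = TRUE)
  # rooting does not change the unrooted topology
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(r1)),
               structure(0L), ignore_attr = TRUE)
})

test_that("newick round-trips preserve topology, names and lengths", {
  tr <- read_newick("(A:1,(B:2,C:3):4);")
  expect_equal(ape::Ntip(tr) + tr$Nnode, 5L)
  rt <- read_newick(write_newick(tr))
  expect_equal(rt$tip.label, tr$tip.label)
  expect_equal(rt$edge.length, tr$edge.length)
  expect_equal(rt$edge, tr$edge)
  # absent branch lengths default to zero
  expect_equal(read_newick("(A,B);")$edge.length, c(0, 0))
  # quoted labels with spaces survive a round trip
  q <- read_newick("('taxon one':1,'taxon two':2);")
  expect_setequal(q$tip.label, c("taxon one", "taxon two"))
  q2 <- read_newick(write_newick(q))
  expect_setequal(q2$tip.label, c("taxon one", "taxon two"))
  # files work too
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, tf)
  expect_equal(read_newick(tf)$tip.label, tr$tip.label)
  expect_error(read_newick("(A:1,(B:2;"), "invalid newick")
  expect_error(read_newick("(A:1,A:2);"), "duplicate")
})

test_that("ancestral reconstruction is exact on unanimous sites", {
  aln <- setNames(rep("ACGTACGT", 4), c("t1", "t2", "t3", "t4"))
  tr <- read_newick("((t1:0.1,t2:0.1):0.1,(t3:0.1,t4:0.1):0.1);")
  rec <- ancestral_reconstruct(tr, aln)
  for (s in rec$sequences) expect_equal(s, "ACGTACGT")
  # posterior of the reconstructed state is the max everywhere
  post <- rec$posterior[[1]]
  expect_true(all(apply(post, 2, max) > 0.25))
})

test_that("a two-leaf tie splits the posterior equally and resolves to A", {
  tr <- read_newick("(a:0.2,b:0.2);")
  rec <- ancestral_reconstruct(tr, c(a = "A", b = "C"))
  post <- rec$posterior[["node3"]]
  expect_equal(post[1, 1], post[2, 1])        # P(A) == P(C)
  expect_gt(post[1, 1], post[3, 1])           # both beat G and T
  expect_equal(rec$sequences[["node3"]], "A") # alphabetical tie-break
})

test_that("site posteriors sum to one at every internal node", {
  sim <- small_sim(seed = 31, n_max = 25)
  aln <- setNames(sim$copies$sequence, sim$copies$id)
  mask <- build_site_mask(aln)
  tr <- root_with_outgroup(nj_tree(jc69_dist_matrix(apply_mask(aln, mask))),
                           "OUT_001")
  rec <- ancestral_reconstruct(tr, aln)
  for (p in rec$posterior) expect_equal(colSums(p), rep(1, ncol(p)))
})

test_that("gaps and N act as missing data in reconstruction", {
  tr <- read_newick("((t1:0.05,t2:0.05):0.05,(t3:0.05,t4:0.05):0.05);")
  aln <- c(t1 = "A-", t2 = "AN", t3 = "AA", t4 = "-A")
  rec <- ancestral_reconstruct(tr, aln)
  expect_equal(unname(rec$sequences[1]), "AA")
  expect_error(ancestral_reconstruct(tr, aln[1:3]), "missing from alignment")
})

test_that("reconstruction agrees with phangorn's marginal ML on a small case", {
  set.seed(14)
  tr <- random_tree(8)
  dat <- phangorn::simSeq(tr, l = 300, rate = 0.5)
  aln <- toupper(apply(as.character(dat), 1, paste, collapse = ""))
  rec <- ancestral_reconstruct(tr, aln)
  fit <- phangorn::pml(tr, dat)
  anc <- phangorn::ancestral.pml(fit, type = "marginal")
  root <- ape::Ntip(tr) + 1L
  marg <- anc[[paste0("Node", root - ape::Ntip(tr))]]     # root marginals
  best <- apply(marg[attr(anc, "index"), , drop = FALSE], 1, which.max)
  ref <- toupper(attr(anc, "levels"))[best]
  mine <- strsplit(rec$sequences[[paste0("node", root)]], "")[[1]]
  expect_gt(mean(ref == mine), 0.97)
})

test_that("root recovery improves as divergence decreases", {
  recover <- function(seed, m) {
    sim <- small_sim(seed = seed, n_max = 40, mu = m)
    aln <- setNames(sim$copies$sequence, sim$copies$id)
    tr <- root_with_outgroup(nj_tree(jc69_dist_matrix(apply_mask(aln, build_site_mask(aln)))),
                             "OUT_001")
    rec <- ancestral_reconstruct(tr, aln)
    mean(strsplit(mrca_sequence(rec), "")[[1]] ==
           strsplit(sim$truth$mrca_sequence, "")[[1]])
  }
  low <- mean(vapply(17:19, recover, 0, m = 2e-3))
  high <- mean(vapply(17:19, recover, 0, m = 8e-2))
  expect_gte(low, high)
  expect_gt(low, 0.95)
})
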