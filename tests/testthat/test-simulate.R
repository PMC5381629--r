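test_that("generated ancestors carry exactly the requested target sites", {
  a <- generate_ancestor(938, 35, seed = 1)
  hits <- scan_motifs(a, rip_motifs())
  expect_equal(nrow(hits), 35L)
  expect_equal(hits$pos, attr(a, "target_pos"))
  # no mutated forms anywhere
  expect_equal(nrow(scan_motifs(a, c("TTG", "CAA"))), 0L)
  # motif-free when no targets requested
  a0 <- generate_ancestor(500, 0, seed = 2)
  expect_equal(nrow(scan_motifs(a0, c("TCG", "CGA", "TTG", "CAA"))), 0L)
  # deterministic under a seed
  expect_equal(generate_ancestor(938, 35, seed = 3),
               generate_ancestor(938, 35, seed = 3))
  expect_error(generate_ancestor(10, 35), "infeasible")
})

test_that("identical seeds give byte-identical simulations", {
  p <- sim_params(n_max = 40, seed = 99)
  s1 <- simulate_strain(p, strain = "V", outgroup_divergence = 0.12)
  s2 <- simulate_strain(p, strain = "V", outgroup_divergence = 0.12)
  expect_identical(s1$copies, s2$copies)
  expect_identical(s1$truth$table, s2$truth$table)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  pp <- sim_params(n_max = 30, burst_factor = 20, seed = 123)
  write_te_fasta(simulate_pair(pp)$copies, f1)
  write_te_fasta(simulate_pair(pp)$copies, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("degenerate limits produce clonal copies on a Yule genealogy", {
  p <- sim_params(s = 1, p_rip = 0, rip_rate = 0, mu = 0, burst_factor = 1,
                  n_max = 30, seed = 7)
  sim <- simulate_strain(p)
  expect_equal(unique(sim$copies$sequence), sim$truth$ancestor,
               ignore_attr = TRUE)
  expect_equal(ape::Ntip(sim$truth$tree), 30L)
  expect_equal(sim$truth$table$n_rip_events, rep(0L, 30))
})

test_that("the truth genealogy is ultrametric in time with matching leaves", {
  sim <- small_sim(seed = 51, n_max = 45)
  tr <- sim$truth$tree
  expect_true(is_ultrametric(tr, tol = 1e-6))
  expect_setequal(tr$tip.label, sim$truth$table$id)
  # leaf depths equal final_time minus the first birth (root of the genealogy)
  first_birth <- sort(sim$truth$table$birth_time)[2]
  d <- ape::node.depth.edgelength(tr)[seq_len(ape::Ntip(tr))]
  expect_equal(unique(round(d + first_birth, 6)),
               round(sim$truth$final_time, 6))
})

test_that("without background mutation, sequence differences are exactly RIP truth", {
  sim <- small_sim(seed = 52, n_max = 35, mu = 0)
  aln <- setNames(sim$copies$sequence, sim$copies$id)
  tab <- sim$truth$table
  mrca <- strsplit(sim$truth$mrca_sequence, "")[[1]]
  for (i in seq_len(nrow(tab))) {
    diffs <- sum(strsplit(aln[[tab$id[i]]], "")[[1]] != mrca)
    expect_equal(diffs, tab$n_rip_events_since_mrca[i])
  }
})

test_that("the RIP fitness penalty acts as a selective sieve", {
  load_at <- function(s, seeds) sapply(seeds, function(sd) {
    p <- sim_params(s = s, n_max = 120, seed = sd)
    mean(simulate_strain(p)$truth$table$n_rip_events)
  })
  with_sieve <- load_at(0.5, 1:6)
  without <- load_at(1, 1:6)
  expect_lt(mean(with_sieve), mean(without))
})

test_that("burst membership forms a clade dominating the final sample", {
  p <- sim_params(burst_factor = 50, n_max = 150, seed = 53)
  sim <- simulate_strain(p)
  tab <- sim$truth$table
  expect_gt(mean(tab$in_burst), 0.5)
  # burst members are exactly the leaves of one genealogy clade
  tr <- sim$truth$tree
  burst_ids <- tab$id[tab$in_burst]
  mrca <- ape::getMRCA(tr, burst_ids)
  expect_setequal(ape::extract.clade(tr, mrca)$tip.label, burst_ids)
  # all burst members are born at/after the burst time (founder included)
  expect_true(all(tab$birth_time[match(setdiff(burst_ids, burst_ids[1]), tab$id)] >= 0))
})

test_that("a strain pair shares an ancestor and carries one outgroup copy", {
  p <- sim_params(n_max = 25, burst_factor = 10, seed = 54)
  sim <- simulate_pair(p)
  expect_setequal(unique(sim$copies$strain), c("V", "S", "outgroup"))
  expect_equal(sum(sim$copies$strain == "outgroup"), 1L)
  expect_equal(nchar(sim$truth$ancestor), p$L)
  # founders differ from the ancestor by background divergence only
  for (f in sim$truth$founders)
    expect_gt(pairwise_identity(f, sim$truth$ancestor), 0.95)
  # outgroup is far more diverged than either strain founder
  og <- sim$copies$sequence[sim$copies$strain == "outgroup"]
  expect_lt(pairwise_identity(og, sim$truth$ancestor), 0.95)
})

test_that("runaway growth in time-limited runs is stopped with advice", {
  p <- sim_params(n_init = 19500, n_max = Inf, t_end = 1e5, mu = 0, p_rip = 0,
                  rip_rate = 0, s = 1, seed = 55)
  expect_error(simulate_strain(p), "runaway")
})
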