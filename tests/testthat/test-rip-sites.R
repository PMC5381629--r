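test_that("the default motif set is strand-symmetric transition pairs", {
  m <- rip_motifs()
  expect_setequal(m$unmutated, c("TCG", "CGA"))
  expect_setequal(m$mutated, c("TTG", "CAA"))
  expect_equal(unname(revcomp("TCG")), "CGA")
  expect_equal(unname(revcomp("TTG")), "CAA")
  # custom dinucleotide context is accepted; non-transition pairs are not
  expect_silent(rip_motifs("CA", "TA"))
  expect_error(rip_motifs("TCG", "TAG"), "transition")
  expect_error(rip_motifs("TCG", "TAA"), "exactly one")
  expect_error(rip_motifs(c("TCG", "CA"), c("TTG", "TA")), "same length")
})

test_that("motif scanning reports every overlapping hit in order", {
  hits <- scan_motifs("AATCGAA", c("TCG", "CGA"))
  expect_equal(hits$pos, c(3L, 4L))          # overlapping TCG and CGA
  expect_equal(hits$motif, c("TCG", "CGA"))
  expect_equal(nrow(scan_motifs("AATCGAA", character(0))), 0L)
  expect_equal(nrow(scan_motifs("AATCNAA", c("TCG", "CGA"))), 0L)  # N never matches
  expect_equal(scan_motifs("AANCGAA", c("TCG", "CGA"))$pos, 4L)    # N-free window still hits
  expect_equal(nrow(scan_motifs("TC", c("TCG"))), 0L)              # too short
})

test_that("the published primer sequences contain no hypermutation targets", {
  fwd <- "AAAGTCCCCACGGCGTTAT"
  rev <- "GTTGAGAAACTGGGGTTAGCTGT"
  expect_equal(nrow(scan_motifs(fwd, rip_motifs())), 0L)
  expect_equal(nrow(scan_motifs(rev, rip_motifs())), 0L)
})

test_that("scanning is strand-symmetric for a reverse-complement-closed set", {
  set.seed(42)
  for (i in 1:20) {
    s <- random_seq(200)
    n_fwd <- nrow(scan_motifs(s, c("TCG", "CGA")))
    n_rev <- nrow(scan_motifs(unname(revcomp(s)), c("TCG", "CGA")))
    expect_equal(n_fwd, n_rev)
  }
})

test_that("site masks cover all motif columns, mapped through gaps", {
  expect_equal(build_site_mask(c(r1 = "AATCGAA")), c(3L, 4L, 5L, 6L))
  # gap inside the row: hits found on the degapped sequence, columns mapped back
  expect_equal(build_site_mask(c(r1 = "A-ATCGAA")), c(4L, 5L, 6L, 7L))
  expect_equal(build_site_mask(c(r1 = "AAAATTTT")), integer(0))
  # union over rows, invariant to row order
  aln <- c(a = "AATCGAA", b = "TTGAAAA", c = "AAAAAAA")
  expect_equal(build_site_mask(aln), build_site_mask(rev(aln)))
  expect_equal(build_site_mask(aln), c(1L, 2L, 3L, 4L, 5L, 6L))  # TTG at 1-3 too
})

test_that("mask application deletes columns and validates indices", {
  aln <- c(r1 = "AATCGAA")
  expect_equal(apply_mask(aln, c(3, 4, 5, 6)), c(r1 = "AAA"))
  expect_equal(apply_mask(aln, integer(0)), c(r1 = "AATCGAA"))
  expect_equal(unname(nchar(apply_mask(aln, 1:7))), 0L)
  expect_error(apply_mask(aln, 8), "out of range")
})

test_that("masking once can expose new motif junctions (single pass by design)", {
  aln <- c(r1 = "TCTCGGA")
  mask <- build_site_mask(aln)
  expect_equal(mask, c(3L, 4L, 5L))
  masked <- apply_mask(aln, mask)
  expect_equal(unname(masked), "TCGA")
  expect_gt(length(build_site_mask(masked)), 0L)  # deletion created TCG/CGA
})

test_that("RIP calling requires exact mutated motif with conserved flanks", {
  # ancestor ATCGA holds TCG (2-4) and CGA (3-5); copy ATTGA: TCG RIP'd,
  # CGA uncallable because its first flank is mutated
  x <- count_rip_mutations("ATCGA", "ATTGA")
  expect_equal(x$n_rip_mutations, 1L)
  expect_equal(x$n_intact_targets, 0L)
  expect_equal(x$n_ancestral_targets, 2L)

  anc <- "TCGATCGATCGA"  # TCG at 1,5,9; CGA at 2,6,10
  y <- count_rip_mutations(anc, anc)
  expect_equal(y$n_rip_mutations, 0L)
  expect_equal(y$n_intact_targets, 6L)
  expect_equal(y$n_ancestral_targets, 6L)

  # gap in the copy makes the site uncallable, not mutated
  z <- count_rip_mutations("ATCGA", "AT-GA")
  expect_equal(z$n_rip_mutations, 0L)
  expect_equal(z$n_intact_targets, 0L)
  # N in the copy likewise
  zn <- count_rip_mutations("ATCGA", "ATNGA")
  expect_equal(zn$n_rip_mutations, 0L)

  # ancestor gaps are skipped: targets counted on the degapped ancestor
  g <- count_rip_mutations("AT-CGA", "ATTTGA")
  expect_equal(g$n_ancestral_targets, 2L)
  expect_equal(g$n_rip_mutations, 1L)

  expect_error(count_rip_mutations("ATCGA", "ATCG"), "unequal")
})

test_that("self-comparison never yields RIP mutations", {
  set.seed(9)
  for (i in 1:10) {
    s <- random_seq(100)
    expect_equal(count_rip_mutations(s, s)$n_rip_mutations, 0L)
  }
})

test_that("rip_profile summarises per-copy counts", {
  aln <- c(anc = "ATCGAATCGA", c1 = "ATCGAATCGA", c2 = "ATTGAATTGA")
  prof <- rip_profile(aln, "anc")
  expect_equal(prof$copy_id, c("c1", "c2"))
  expect_equal(prof$n_rip_mutations, c(0L, 2L))
  expect_equal(attr(prof, "fraction_mutated"), 0.5)
  expect_equal(attr(prof, "mean_rip"), 1)
  expect_error(rip_profile(aln, "nope"), "not found")
  ident <- c(anc = "ATCGA", c1 = "ATCGA")
  expect_equal(attr(rip_profile(ident, "anc"), "fraction_mutated"), 0)
})

test_that("with background mutation off, profiling recovers simulator truth exactly", {
  sim <- small_sim(seed = 21, n_max = 40, mu = 0)
  aln <- setNames(sim$copies$sequence, sim$copies$id)
  ids <- sim$truth$table$id
  prof <- rip_profile(c(aln[ids], ancestor = sim$truth$mrca_sequence), "ancestor")
  m <- merge(prof, sim$truth$table, by.x = "copy_id", by.y = "id")
  expect_equal(m$n_rip_mutations, m$n_rip_events_since_mrca)
  expect_equal(unique(prof$n_ancestral_targets), 35L)
})
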