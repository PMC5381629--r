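#' Hypermutation target motif set
#'
#' Defines the sequence contexts targeted by the RIP-like hypermutation
#' process. The default is the trinucleotide TpCpG together with its reverse
#' complement CpGpA (so both strands are covered on the forward strand), and
#' their single-transition products TpTpG and CpApA. Each mutated motif must
#' differ from its unmutated partner at exactly one position, by a transition
#' (C to T or G to A on the written strand).
#'
#' @param unmutated Character vector of intact target motifs.
#' @param mutated Character vector of the same length: the hypermutated
#'   product of the corresponding `unmutated` motif.
#' @return An object of class `rip_motifs`: a data frame with columns
#'   `unmutated`, `mutated` and `mut_pos` (position within the motif that
#'   changes).
#' @examples
#' rip_motifs()                      # Microbotryum-style TCG/CGA
#' rip_motifs("CA", "TA")            # Neurospora-style CpA (one strand)
#' @export
rip_motifs <- function(unmutated = c("TCG", "CGA"), mutated = c("TTG", "CAA")) {
  unmutated <- toupper(unmutated); mutated <- toupper(mutated)
  if (length(unmutated) != length(mutated) || !length(unmutated))
    stop("'unmutated' and 'mutated' must be non-empty and the same length")
  k <- unique(nchar(c(unmutated, mutated)))
  if (length(k) != 1L) stop("all motifs must have the same length")
  mut_pos <- integer(length(unmutated))
  transitions <- c(C = "T", G = "A", T = "C", A = "G")
  for (i in seq_along(unmutated)) {
    a <- strsplit(unmutated[i], "")[[1L]]; b <- strsplit(mutated[i], "")[[1L]]
    d <- which(a != b)
    if (length(d) != 1L)
      stop("motif pair ", unmutated[i], "/", mutated[i],
           " must differ at exactly one position")
    if (transitions[[a[d]]] != b[d])
      stop("motif pair ", unmutated[i], "/", mutated[i],
           " is not related by a transition")
    mut_pos[i] <- d
  }
  out <- data.frame(unmutated = unmutated, mutated = mutated, mut_pos = mut_pos,
                    stringsAsFactors = FALSE)
  class(out) <- c("rip_motifs", "data.frame")
  out
}

motif_width <- function(motifs) nchar(motifs$unmutated[1L])

#' Scan a sequence for motif occurrences
#'
#' Reports every occurrence of any of the given motifs in an ungapped
#' nucleotide sequence, in ascending position order. Overlapping occurrences
#' are all reported; windows containing `N` never match.
#'
#' @param seq A single ungapped nucleotide string over `A,C,G,T,N`.
#' @param motifs Character vector of equal-length motifs, or a [rip_motifs()]
#'   object (in which case its *unmutated* motifs are scanned).
#' @return A data frame with columns `pos` (1-based start) and `motif`.
#' @examples
#' scan_motifs("AATCGAA", c("TCG", "CGA"))  # hits at 3 and 4
#' @export
scan_motifs <- function(seq, motifs) {
  if (inherits(motifs, "rip_motifs")) motifs <- motifs$unmutated
  motifs <- toupper(as.character(motifs))
  empty <- data.frame(pos = integer(), motif = character(), stringsAsFactors = FALSE)
  if (!length(motifs)) return(empty)
  k <- unique(nchar(motifs))
  if (length(k) != 1L) stop("all motifs must have the same length")
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < k) return(empty)
  ch <- strsplit(seq, "")[[1L]]
  win <- ch[seq_len(L - k + 1L)]
  if (k > 1L) for (j in 2L:k) win <- paste0(win, ch[j:(L - k + j)])
  hit <- win %in% motifs
  data.frame(pos = which(hit), motif = win[hit], stringsAsFactors = FALSE)
}

#' Columns of an alignment touched by hypermutation target sites
#'
#' For every row of the alignment, all four motif forms (intact and mutated,
#' both strands) are located on the *degapped* sequence and the hit positions
#' are mapped back to alignment columns; the union over rows and over all
#' motif columns is returned. Scanning degapped rows ensures gap placement
#' cannot hide a target site. These columns should be removed before tree
#' building because hypermutation makes them phylogenetically misleading.
#'
#' @param aln Named character vector of equal-width gapped sequences.
#' @param motifs A [rip_motifs()] object.
#' @return Sorted integer vector of 1-based alignment columns (the site mask).
#' @export
build_site_mask <- function(aln, motifs = rip_motifs()) {
  aln <- as_alignment(aln)
  if (!length(aln)) stop("alignment is empty")
  stopifnot(inherits(motifs, "rip_motifs"))
  all_motifs <- c(motifs$unmutated, motifs$mutated)
  k <- motif_width(motifs)
  cols <- logical(aln_width(aln))
  for (row in aln) {
    ch <- strsplit(row, "")[[1L]]
    map <- which(ch != "-")       # degapped index -> alignment column
    hits <- scan_motifs(paste(ch[map], collapse = ""), all_motifs)
    for (p in hits$pos) cols[map[p:(p + k - 1L)]] <- TRUE
  }
  which(cols)
}

#' Delete masked columns from an alignment
#'
#' @param aln Named character vector of equal-width gapped sequences.
#' @param mask Integer vector of 1-based columns to delete (e.g. from
#'   [build_site_mask()]).
#' @return The alignment with those columns removed; row order and ids kept.
#' @export
apply_mask <- function(aln, mask) {
  aln <- as_alignment(aln)
  mask <- unique(as.integer(mask))
  if (!length(mask)) return(aln)
  w <- aln_width(aln)
  if (any(mask < 1L | mask > w))
    stop("mask index out of range [1, ", w, "]")
  m <- aln_char_matrix(aln)[, -mask, drop = FALSE]
  out <- apply(m, 1L, paste, collapse = "")
  if (ncol(m) == 0L) out <- setNames(rep("", nrow(m)), rownames(m))
  out
}

#' Score RIP-like mutations in one copy against an ancestor
#'
#' Target sites are the occurrences of the *unmutated* motifs on the degapped
#' ancestor row. For each such site, mapped to its alignment columns, the copy
#' is called: a RIP-like mutation if the copy carries the mutated motif
#' exactly (mutated base changed, flanking context conserved); intact if the
#' copy matches the unmutated motif exactly; otherwise the site is uncallable
#' (gap, `N`, or a mutated flank makes its RIP status ambiguous).
#'
#' @param ancestor_row,copy_row Gapped rows from the same alignment.
#' @param motifs A [rip_motifs()] object.
#' @return A list with `n_rip_mutations`, `n_intact_targets`,
#'   `n_ancestral_targets`.
#' @examples
#' count_rip_mutations("ATCGA", "ATTGA")  # one RIP'd TCG, CGA uncallable
#' @export
count_rip_mutations <- function(ancestor_row, copy_row, motifs = rip_motifs()) {
  if (nchar(ancestor_row) != nchar(copy_row))
    stop("ancestor and copy rows have unequal lengths")
  stopifnot(inherits(motifs, "rip_motifs"))
  anc <- strsplit(toupper(ancestor_row), "")[[1L]]
  cop <- strsplit(toupper(copy_row), "")[[1L]]
  map <- which(anc != "-")
  k <- motif_width(motifs)
  hits <- scan_motifs(paste(anc[map], collapse = ""), motifs$unmutated)
  n_rip <- 0L; n_intact <- 0L
  for (h in seq_len(nrow(hits))) {
    i <- match(hits$motif[h], motifs$unmutated)
    cols <- map[hits$pos[h]:(hits$pos[h] + k - 1L)]
    copy_site <- paste(cop[cols], collapse = "")
    if (copy_site == motifs$mutated[i]) n_rip <- n_rip + 1L
    else if (copy_site == motifs$unmutated[i]) n_intact <- n_intact + 1L
  }
  list(n_rip_mutations = n_rip, n_intact_targets = n_intact,
       n_ancestral_targets = nrow(hits))
}

#' Per-copy RIP-like mutation profile of an alignment
#'
#' Scores every non-ancestor row of the alignment against the given ancestor
#' row with [count_rip_mutations()]. The returned data frame carries the
#' population summary used throughout the analysis: the fraction of copies
#' with at least one RIP-like mutation, and the mean and standard deviation
#' of the per-copy mutation count.
#'
#' @param aln Named character vector of equal-width gapped sequences,
#'   including the ancestor row (typically the reconstructed ancestral
#'   sequence appended under its node id).
#' @param ancestor_id Row name of the ancestor.
#' @param motifs A [rip_motifs()] object.
#' @return A data frame (class `rip_profile`) with one row per non-ancestor
#'   copy and columns `copy_id`, `n_rip_mutations`, `n_intact_targets`,
#'   `n_ancestral_targets`; attributes `fraction_mutated`, `mean_rip`,
#'   `sd_rip`.
#' @export
rip_profile <- function(aln, ancestor_id, motifs = rip_motifs()) {
  aln <- as_alignment(aln)
  if (!ancestor_id %in% names(aln))
    stop("ancestor id '", ancestor_id, "' not found in alignment")
  anc <- aln[[ancestor_id]]
  ids <- setdiff(names(aln), ancestor_id)
  counts <- lapply(aln[ids], count_rip_mutations, ancestor_row = anc, motifs = motifs)
  out <- data.frame(
    copy_id = ids,
    n_rip_mutations = vapply(counts, `[[`, 0L, "n_rip_mutations"),
    n_intact_targets = vapply(counts, `[[`, 0L, "n_intact_targets"),
    n_ancestral_targets = vapply(counts, `[[`, 0L, "n_ancestral_targets"),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fraction_mutated") <- mean(out$n_rip_mutations >= 1L)
  attr(out, "mean_rip") <- mean(out$n_rip_mutations)
  attr(out, "sd_rip") <- stats::sd(out$n_rip_mutations)
  class(out) <- c("rip_profile", "data.frame")
  out
}
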