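#' Read TE copy sequences from a FASTA file
#'
#' Reads a FASTA file of transposable-element copy sequences whose headers
#' carry the copy id, strain of origin, and chromosome of origin as
#' delimiter-separated fields (default `id|strain|chromosome`). An optional
#' tab-separated metadata table (columns `id`, `strain`, `chromosome`)
#' overrides header parsing, in which case the full header is taken as the id.
#'
#' @param path Path to a FASTA file (single- or multi-line records).
#' @param delim Field delimiter used in the headers (default `"|"`).
#' @param metadata Optional path to a TSV file with columns
#'   `id`, `strain`, `chromosome`, or a data frame with those columns.
#' @return A data frame with columns `id`, `strain`, `chromosome`,
#'   `sequence` (uppercase, alphabet `A,C,G,T,N` plus `-` if the input is
#'   aligned), one row per record in file order. Gaps are preserved so that
#'   pre-aligned input keeps its coordinates; length filtering and duplicate
#'   collapsing always act on the ungapped sequence.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">c1|V|chr01", "ACGT"), tf)
#' read_te_fasta(tf)
#' @seealso [write_te_fasta()], [filter_by_length()], [dedupe_within_chromosome()]
#' @export
read_te_fasta <- function(path, delim = "|", metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(te_copies(character(), character(), character(), character()))
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("not a FASTA file (first non-empty line is not a header): ", path)
  rec <- cumsum(hdr)
  headers <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, "", collapse = "")
  if (length(seqs) < sum(hdr)) { # records with no sequence lines
    full <- rep("", sum(hdr)); full[as.integer(names(seqs))] <- seqs; seqs <- full
  }
  seqs <- toupper(gsub("[ \t]", "", unname(seqs)))
  bad <- regexpr("[^ACGTN-]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' at position %d of record '%s'",
                 substr(seqs[i], bad[i], bad[i]), bad[i], headers[i]))
  }
  if (!is.null(metadata)) {
    md <- if (is.data.frame(metadata)) metadata else
      utils::read.delim(metadata, stringsAsFactors = FALSE)
    need <- c("id", "strain", "chromosome")
    if (!all(need %in% names(md))) stop("metadata must have columns id, strain, chromosome")
    idx <- match(headers, md$id)
    if (anyNA(idx)) stop("metadata has no entry for record '", headers[which(is.na(idx))[1L]], "'")
    return(te_copies(headers, md$strain[idx], md$chromosome[idx], seqs))
  }
  parts <- strsplit(headers, delim, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("malformed header (expected id", delim, "strain", delim,
         "chromosome): '>", headers[which(nf < 3L)[1L]], "'")
  te_copies(vapply(parts, `[[`, "", 1L),
            vapply(parts, `[[`, "", 2L),
            vapply(parts, `[[`, "", 3L),
            seqs)
}

# Internal constructor + validator for the TE copy table
te_copies <- function(id, strain, chromosome, sequence) {
  df <- data.frame(id = as.character(id), strain = as.character(strain),
                   chromosome = as.character(chromosome),
                   sequence = as.character(sequence), stringsAsFactors = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate copy ids: ", paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (nrow(df) && any(!nzchar(df$id))) stop("empty copy id")
  rownames(df) <- NULL
  df
}

#' Write TE copies to FASTA
#'
#' Inverse of [read_te_fasta()]: headers are `id<delim>strain<delim>chromosome`.
#'
#' @param copies Data frame with columns `id`, `strain`, `chromosome`, `sequence`.
#' @param path Output file path.
#' @param delim Header field delimiter.
#' @return `path`, invisibly.
#' @export
write_te_fasta <- function(copies, path, delim = "|") {
  stopifnot(all(c("id", "strain", "chromosome", "sequence") %in% names(copies)))
  out <- character(2L * nrow(copies))
  out[c(TRUE, FALSE)] <- paste0(">", copies$id, delim, copies$strain, delim, copies$chromosome)
  out[c(FALSE, TRUE)] <- copies$sequence
  writeLines(out, path)
  invisible(path)
}

#' Drop short TE copies
#'
#' Removes copies whose ungapped sequence is shorter than `min_length`
#' nucleotides. Short clones are typically truncated amplification or
#' sequencing products rather than genuine full-length element fragments.
#'
#' @param copies TE copy data frame (see [read_te_fasta()]).
#' @param min_length Minimum retained length in bp (default 700).
#' @return The filtered data frame, original order preserved.
#' @export
filter_by_length <- function(copies, min_length = 700) {
  stopifnot(min_length >= 1)
  keep <- nchar(degap(copies$sequence)) >= min_length
  out <- copies[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse identical sequences within a chromosome sample
#'
#' Within each (strain, chromosome) group, exact duplicate sequences are
#' collapsed to their first occurrence: identical clones from the same
#' chromosome may be amplification products of a single locus. Identical
#' sequences on *different* chromosomes are distinct insertions and are all
#' retained -- this is the point of chromosome-structured sampling.
#'
#' @param copies TE copy data frame.
#' @return The deduplicated data frame, original order preserved.
#' @export
dedupe_within_chromosome <- function(copies) {
  key <- paste(copies$strain, copies$chromosome,
               toupper(degap(copies$sequence)), sep = "\r")
  out <- copies[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
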