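#' Write a rip_burst run to disk
#'
#' Serialises the analysis to plain-text reports: per-strain RIP profile and
#' fitness TSVs, rooted trees in newick format, reconstructed ancestor
#' sequences in FASTA, a JSON summary of all headline statistics, and a
#' MANIFEST (JSON) recording the parameters and stage counts from which the
#' run can be reproduced. No timestamps are written, so identical runs give
#' byte-identical reports.
#'
#' @param x A [rip_burst()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_rip_burst <- function(x, dir) {
  stopifnot(inherits(x, "rip_burst"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, file)
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  meta <- x$copies[, c("id", "strain", "chromosome")]
  for (s in x$strains) {
    ps <- x$per_strain[[s]]
    prof <- merge(ps$rip, meta, by.x = "copy_id", by.y = "id", sort = FALSE)
    tsv(prof[order(prof$copy_id), ], paste0("rip_profile_", s, ".tsv"))
    fit <- merge(ps$scores,
                 ps$rip[, c("copy_id", "n_rip_mutations")],
                 by.x = "leaf_id", by.y = "copy_id", sort = FALSE)
    tsv(fit[order(fit$rank), ], paste0("fitness_", s, ".tsv"))
    write_newick(ps$tree, file.path(dir, paste0("tree_", s, ".nwk")))
    writeLines(c(paste0(">ancestor_", s), ps$ancestor),
               file.path(dir, paste0("ancestor_", s, ".fasta")))
  }
  if (length(x$strains) > 1L)
    write_newick(x$combined$tree, file.path(dir, "tree_combined.nwk"))
  smry <- summary(x)
  jsonlite::write_json(unclass(smry), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    stages = c("read", "length_filter", "dedupe", "mask", "tree", "root",
               "ancestor", "rip_profile", "diversity", "expansion", "fitness"),
    counts = as.list(x$counts),
    outgroup = x$outgroup,
    n_masked_columns = length(x$mask),
    params = list(min_length = x$params$min_length, dedupe = x$params$dedupe,
                  motifs = as.list(as.data.frame(x$params$motifs)),
                  min_identity = x$params$min_identity,
                  min_size = x$params$min_size,
                  tau = x$params$tau, max_distance = x$params$max_distance,
                  external_tree = x$params$external_tree),
    files = list.files(dir))
  jsonlite::write_json(manifest, file.path(dir, "MANIFEST.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
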