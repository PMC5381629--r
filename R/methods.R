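#' Print a rip_burst analysis
#'
#' @param x A [rip_burst()] object.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
print.rip_burst <- function(x, ...) {
  cat("TE expansion / RIP / fitness analysis\n")
  cat(sprintf("  copies: %d read, %d after length filter, %d after dedupe (+1 outgroup counted)\n",
              x$counts[["input"]], x$counts[["after_length_filter"]],
              x$counts[["after_dedupe"]]))
  cat(sprintf("  alignment width %d; %d hypermutation-site columns masked for tree building\n",
              x$width, length(x$mask)))
  for (s in x$strains) {
    ps <- x$per_strain[[s]]
    cat(sprintf("  %s: n=%d  RIP-mutated copies %.0f%%  RIP load %.2f +/- %.2f  rho(RIP, rank)=%.2f\n",
                s, length(ps$ids), 100 * attr(ps$rip, "fraction_mutated"),
                attr(ps$rip, "mean_rip"), attr(ps$rip, "sd_rip"),
                ps$correlation$rho))
  }
  if (!is.null(x$combined$clade)) {
    print(x$combined$clade)
    cr <- x$combined$clade_rip
    if (!is.null(cr) && !is.null(cr$test))
      cat(sprintf("  RIP load median inside/outside clade: %g / %g (Mann-Whitney p = %.2g)\n",
                  cr$median_inside, cr$median_outside, cr$test$p_value))
  } else {
    cat("  no expanded clade detected\n")
  }
  if (!is.null(x$tests)) {
    for (i in seq_len(nrow(x$tests)))
      cat(sprintf("  %s vs %s: KS(identity to ancestor) D=%.3f p=%.2g; MW(pairwise identity) p=%.2g\n",
                  x$tests$strain_a[i], x$tests$strain_b[i],
                  x$tests$ks_identity_to_ancestor_D[i],
                  x$tests$ks_identity_to_ancestor_p[i],
                  x$tests$mw_pairwise_identity_p[i]))
  }
  invisible(x)
}

#' Summarise a rip_burst analysis
#'
#' @param object A [rip_burst()] object.
#' @param ... Unused.
#' @return A list of headline quantities: per-strain RIP summaries and
#'   fitness correlations, the expanded-clade call, RIP load inside vs
#'   outside the clade, and between-strain tests.
#' @export
summary.rip_burst <- function(object, ...) {
  per_strain <- lapply(object$per_strain, function(ps) list(
    n = length(ps$ids),
    fraction_rip_mutated = attr(ps$rip, "fraction_mutated"),
    mean_rip = attr(ps$rip, "mean_rip"),
    sd_rip = attr(ps$rip, "sd_rip"),
    mean_identity_to_ancestor = mean(ps$diversity$identity_to_ancestor),
    spearman_rho = ps$correlation$rho,
    spearman_p = ps$correlation$p_value,
    quartile_summary = ps$correlation$quartile_summary))
  clade <- object$combined$clade
  out <- list(
    counts = object$counts,
    n_masked_columns = length(object$mask),
    per_strain = per_strain,
    clade = if (is.null(clade)) NULL else list(
      strain = clade$strain, n = length(clade$leaf_ids),
      fraction_of_strain_sample = clade$fraction_of_strain_sample,
      mean_pairwise_identity = clade$mean_pairwise_identity),
    clade_rip = object$combined$clade_rip,
    tests = object$tests)
  class(out) <- "summary.rip_burst"
  out
}

#' @export
print.summary.rip_burst <- function(x, ...) {
  utils::str(x, max.level = 3, give.attr = FALSE)
  invisible(x)
}

#' Diagnostic plots for a rip_burst analysis
#'
#' Draws, per strain, the distribution of sequence identity to the
#' reconstructed ancestor and of pairwise identity (the signatures of a
#' burst), and the RIP load against fitness rank for the strain with the
#' strongest correlation.
#'
#' @param x A [rip_burst()] object.
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.rip_burst <- function(x, ...) {
  ns <- length(x$strains)
  op <- graphics::par(mfrow = c(ns + 1L, 2L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in x$strains) {
    d <- x$per_strain[[s]]$diversity
    graphics::hist(d$identity_to_ancestor, breaks = 30,
                   main = paste(s, "- identity to ancestor"),
                   xlab = "identity", col = "grey80", ...)
    graphics::hist(d$pairwise_identities, breaks = 30,
                   main = paste(s, "- pairwise identity"),
                   xlab = "identity", col = "grey80", ...)
  }
  best <- x$strains[which.max(vapply(x$per_strain,
                                     function(p) p$correlation$rho, 0)[x$strains])]
  tab <- x$per_strain[[best]]$correlation$table
  plot(tab$rank, tab$n_rip_mutations, pch = 16,
       col = adjustcolor("steelblue", 0.6),
       xlab = "fitness rank (0 = fittest)", ylab = "RIP-like mutations",
       main = paste(best, "- RIP load vs fitness"))
  graphics::boxplot(n_rip_mutations ~ quartile, data = tab,
                    xlab = "fitness quartile (1 = highest)",
                    ylab = "RIP-like mutations", main = paste(best, "- quartiles"),
                    col = "grey80")
  invisible(x)
}
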