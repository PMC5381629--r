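#' Simulate two strains from a common ancestor, with a burst in one
#'
#' Generates a common ancestral element, lets two strain founders diverge
#' from it independently for `t_div` time units of background substitution,
#' then runs [simulate_strain()] in each strain -- with the burst
#' (`burst_factor`, `burst_time` from `params`) enabled only in the first
#' strain -- and emits one deeply diverged outgroup copy for rooting.
#'
#' @param params A [sim_params()] object; `params$seed` drives all
#'   randomness of the pair. `burst_factor`/`burst_time` apply to the first
#'   strain only.
#' @param strains Two strain labels (burst strain first).
#' @param t_div Divergence period per founder lineage (time units).
#' @param outgroup_divergence Expected substitutions/site separating the
#'   outgroup copy from the common ancestor.
#' @param motifs A [rip_motifs()] object.
#' @return A list with `copies` (both strains plus the outgroup copy,
#'   strain label `"outgroup"`), `outgroup` (its id), and `truth`: common
#'   `ancestor`, per-strain founder sequences, per-strain genealogies and
#'   truth tables (see [simulate_strain()]), and `params`.
#' @export
simulate_pair <- function(params, strains = c("V", "S"), t_div = 2,
                          outgroup_divergence = 0.12, motifs = rip_motifs()) {
  stopifnot(inherits(params, "sim_params"), length(strains) == 2L)
  if (is.null(params$seed)) stop("params$seed is required for simulate_pair")
  set.seed(params$seed)
  anc <- generate_ancestor(params$L, params$n_targets, motifs)
  anc_ch <- strsplit(anc, "")[[1L]]
  founders <- lapply(1:2, function(i)
    paste(mutate_background(anc_ch, stats::rpois(1L, params$mu * params$L * t_div)),
          collapse = ""))
  names(founders) <- strains
  par_burst <- params
  par_null <- params
  par_null$burst_factor <- 1
  par_null$burst_time <- Inf
  par_burst$seed <- par_null$seed <- NULL  # keep the single seeded stream
  simA <- simulate_strain(par_burst, founder = founders[[1L]],
                          strain = strains[1L], motifs = motifs)
  simB <- simulate_strain(par_null, founder = founders[[2L]],
                          strain = strains[2L], motifs = motifs)
  og_ch <- mutate_background(anc_ch, stats::rpois(1L, outgroup_divergence * params$L))
  og <- te_copies("OUT_001", "outgroup", "chr00", paste(og_ch, collapse = ""))
  list(copies = rbind(simA$copies, simB$copies, og),
       outgroup = "OUT_001",
       truth = list(ancestor = anc, founders = founders,
                    strain = setNames(list(simA$truth, simB$truth), strains),
                    params = params))
}
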