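#' Parameters for the TE proliferation simulator
#'
#' Bundles and validates the parameters of the forward-time birth process
#' (see [simulate_strain()]). Defaults emulate the scale of a field-isolate
#' TE population: ~1 kb elements carrying 35 hypermutation target sites,
#' sampled to 250 copies across 12 chromosomes, with a per-copy RIP load of
#' order one mutated site and background diversity of a few percent.
#'
#' @param L Element length in nt.
#' @param n_targets Number of TCG/CGA target sites seeded in the ancestor.
#' @param lambda0 Base transposition rate (events per copy per unit time).
#' @param s RIP fitness multiplier per mutated target site, in (0, 1]: a copy
#'   carrying `k` RIP-mutated sites transposes at rate `lambda0 * s^k`.
#' @param p_rip Probability that a new insertion is RIP-processed at birth
#'   (duplication-triggered processing).
#' @param f_rip Per-intact-site mutation probability given a processing
#'   event (either kind).
#' @param rip_rate Rate (per copy per unit time) of RIP processing events on
#'   resident copies, modelling hypermutation of repeats during recurrent
#'   sexual cycles. Each event mutates each currently intact target site of
#'   that copy independently with probability `f_rip`. This exposure over
#'   time is what lets an old, slow lineage accumulate a heavy RIP load while
#'   a young burst clade stays comparatively clean.
#' @param mu Background substitution rate per site per unit time.
#' @param burst_factor Rate multiplier `B >= 1` applied, from `burst_time`
#'   on, to the burst-founder lineage (see Details in [simulate_strain()]).
#' @param burst_time Time at which the burst begins; inert while
#'   `burst_factor = 1`. The default (2.5) falls when a default-rate run has
#'   grown to a few tens of copies, so a burst started then dominates the
#'   final sample the way a real expansion dominates a genome.
#' @param n_init Number of identical resident copies seeding the family at
#'   time 0 (a TE family enters a genome as an established cluster, and a
#'   single seed could be sterilised by an unlucky early processing event).
#' @param n_max Stop when this many copies exist (`Inf` allowed when a
#'   finite `t_end` is given; a hard cap of 20,000 copies guards against
#'   runaway growth in time-limited runs).
#' @param t_end Stop at this time (whichever of `n_max`/`t_end` comes first).
#' @param n_chromosomes Number of chromosomes insertions land on.
#' @param seed Integer RNG seed (mandatory for reproducible pipelines).
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(L = 938, n_targets = 35, lambda0 = 1, s = 0.5,
                       p_rip = 0.3, f_rip = 0.05, rip_rate = 0.3, mu = 0.015,
                       burst_factor = 1, burst_time = 2.5,
                       n_init = 5, n_max = 250, t_end = Inf,
                       n_chromosomes = 12, seed = NULL) {
  p <- list(L = as.integer(L), n_targets = as.integer(n_targets),
            lambda0 = lambda0, s = s, p_rip = p_rip, f_rip = f_rip,
            rip_rate = rip_rate, mu = mu,
            burst_factor = burst_factor, burst_time = burst_time,
            n_init = as.integer(n_init), n_max = as.numeric(n_max),
            t_end = t_end,
            n_chromosomes = as.integer(n_chromosomes), seed = seed)
  with(p, {
    stopifnot(L >= 3, n_targets >= 0, 3 * n_targets <= L,
              lambda0 >= 0, s > 0, s <= 1,
              p_rip >= 0, p_rip <= 1, f_rip >= 0, f_rip <= 1,
              rip_rate >= 0, mu >= 0,
              burst_factor >= 1, burst_time > 0,
              n_init >= 1, n_max >= n_init || is.finite(t_end),
              n_chromosomes >= 1)
  })
  if (!is.finite(p$n_max) && !is.finite(p$t_end))
    stop("one of n_max / t_end must be finite (n_max = Inf needs a t_end)")
  class(p) <- "sim_params"
  p
}

#' Generate an ancestral element sequence with seeded target sites
#'
#' Builds a random sequence of length `L` containing exactly `n_targets`
#' non-overlapping occurrences of the unmutated target motifs (TCG or CGA,
#' chosen at random per site) and no accidental occurrence of any of the four
#' motif forms elsewhere, so that every target site is attributable.
#'
#' @param L Sequence length.
#' @param n_targets Number of target sites.
#' @param motifs A [rip_motifs()] object (default TCG/CGA with TTG/CAA).
#' @param seed Optional RNG seed (if `NULL`, uses the current RNG stream).
#' @return The ancestor sequence, with attribute `target_pos` giving the
#'   1-based start position of each planted site.
#' @export
generate_ancestor <- function(L, n_targets, motifs = rip_motifs(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- motif_width(motifs)
  if (n_targets * k > L) stop("infeasible packing: ", n_targets, " sites of width ",
                              k, " cannot fit in ", L, " nt")
  all_motifs <- c(motifs$unmutated, motifs$mutated)
  ch <- sample(BASES, L, replace = TRUE)
  # choose spaced target start positions (>= 1 nt buffer between blocks)
  pos <- integer(0)
  if (n_targets > 0) {
    # uniform spaced placement: sample distinct offsets, then shift so that
    # consecutive sites are >= k+1 apart (one buffer base between blocks)
    range <- L - k + 1L - (n_targets - 1L) * (k + 1L)
    if (range < n_targets)
      stop("infeasible packing: could not place ", n_targets,
           " spaced sites in ", L, " nt")
    pos <- sort(sample.int(range + n_targets - 1L, n_targets)) +
      (seq_len(n_targets) - 1L) * k
    if (max(pos) > L - k + 1L) stop("internal error in site placement")
    motif_idx <- sample.int(nrow(motifs), n_targets, replace = TRUE)
    for (i in seq_len(n_targets))
      ch[pos[i]:(pos[i] + k - 1L)] <- strsplit(motifs$unmutated[motif_idx[i]], "")[[1L]]
  }
  in_target <- logical(L)
  for (p in pos) in_target[p:(p + k - 1L)] <- TRUE
  # destroy accidental motif occurrences without touching planted blocks
  for (iter in 1:1000) {
    hits <- scan_motifs(paste(ch, collapse = ""), all_motifs)
    stray <- hits$pos[!(hits$pos %in% pos & hits$motif %in% motifs$unmutated)]
    if (!length(stray)) break
    for (p in stray) {
      free <- (p:(p + k - 1L))[!in_target[p:(p + k - 1L)]]
      if (!length(free)) next  # overlaps targets only; resolved via neighbours
      j <- free[sample.int(length(free), 1L)]
      ch[j] <- sample(setdiff(BASES, ch[j]), 1L)
    }
    if (iter == 1000L) stop("infeasible packing: could not remove stray motifs")
  }
  structure(paste(ch, collapse = ""), target_pos = pos)
}

# Apply n random substitutions (uniform site, uniform alternative base)
mutate_background <- function(ch, n) {
  if (n == 0L) return(ch)
  sites <- sample.int(length(ch), n, replace = TRUE)
  for (j in sites) ch[j] <- sample(setdiff(BASES, ch[j]), 1L)
  ch
}

#' Simulate one strain's TE population
#'
#' Forward-time Gillespie birth process of intragenomic TE proliferation.
#' Each copy transposes at rate `lambda0 * s^k` where `k` is its cumulative
#' count of RIP-mutated target sites; retrotransposition is copy-and-paste
#' (no excision, no death). RIP-like processing events mutate each currently
#' intact target motif of the processed copy independently with probability
#' `f_rip` (TCG to TTG / CGA to CAA), and occur through two routes: at
#' birth, a new insertion is processed with probability `p_rip`
#' (duplication-triggered processing), and every resident copy is processed
#' at rate `rip_rate` per unit time (hypermutation of repeats during
#' recurrent sexual cycles). The time-based route is what differentiates
#' lineages: a young, rapidly expanding clade has had little exposure while
#' old lineages carry the accumulated load. A new insertion copies its
#' parent's sequence and lands on a uniformly random chromosome. Background
#' substitutions accrue on every extant lineage as a Poisson process with
#' rate `mu * L`, at uniform sites with uniform alternative bases (they may
#' hit target sites by chance; such sites are subsequently scored by their
#' sequence state, as any observer of the sequences would). Transposition
#' rates are held fixed between consecutive birth events and refreshed at
#' each event.
#'
#' From `burst_time` on, the transposition rate of one lineage -- an extant
#' copy of the least-RIP-mutated class, drawn uniformly among ties -- and of
#' all its subsequent descendants is multiplied by `burst_factor`.
#' Restricting the burst to one founder lineage makes the expansion a clade,
#' as observed in real expansions; taking the founder from the fittest class
#' reflects that an observed massive expansion is conditioned on having
#' succeeded, which under a per-site fitness penalty concentrates the
#' founder on elements that escaped the defense.
#'
#' @param params A [sim_params()] object.
#' @param founder Optional founder sequence (default: a fresh
#'   [generate_ancestor()] draw).
#' @param strain Strain label for the emitted copies.
#' @param motifs A [rip_motifs()] object.
#' @param outgroup_divergence If non-`NULL`, also emit a deeply diverged
#'   outgroup copy: the founder with `Poisson(outgroup_divergence * L)`
#'   random substitutions (expected substitutions/site on that lineage).
#' @return A list with `copies` (TE copy data frame, see [read_te_fasta()];
#'   the outgroup copy, if any, has strain `"outgroup"`) and `truth`, a list
#'   with `tree` (the genealogy as a `phylo`, branch lengths in time,
#'   ultrametric over the copies), `ancestor` (founder sequence),
#'   `mrca_sequence` (the founder lineage's state at the first birth: the
#'   true most recent common ancestor of all extant copies, the quantity the
#'   analysis reconstructs), `table` (per-copy chromosome, birth time, RIP
#'   event count since time 0 and since the MRCA, background mutation count,
#'   burst membership), `final_time`, and `params`.
#' @export
simulate_strain <- function(params, founder = NULL, strain = "A",
                            motifs = rip_motifs(), outgroup_divergence = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  L <- params$L
  if (is.null(founder)) founder <- generate_ancestor(L, params$n_targets, motifs)
  founder_ch <- strsplit(toupper(founder), "")[[1L]]
  if (length(founder_ch) != L) stop("founder length does not match params$L")

  hard_cap <- if (is.finite(params$n_max)) max(params$n_max, 20000) else 20000
  n_init <- as.integer(min(params$n_init, params$n_max))
  seqs <- rep(list(founder_ch), n_init)
  mrca_seq <- founder_ch
  mrca_k <- 0L
  k <- rep(0L, n_init)         # RIP-mutated site count per copy
  nbg <- rep(0L, n_init)       # background substitutions per copy
  burst <- rep(FALSE, n_init)  # burst-lineage membership
  chrom <- sample.int(params$n_chromosomes, n_init, replace = TRUE)
  birth <- rep(0, n_init)
  # seed copies enter the genealogy as instantaneous births from the founder
  ev_parent <- rep(1L, n_init - 1L)
  ev_child <- seq_len(n_init - 1L) + 1L
  ev_time <- rep(0, n_init - 1L)
  t <- 0
  burst_armed <- is.finite(params$burst_time) && params$burst_factor > 1
  burst_on <- FALSE
  # long waiting times (possible when RIP load has collapsed every rate) are
  # consumed in bounded chunks; by memorylessness this is exact
  dt_max <- 25 / max(params$lambda0, 1e-12)
  steps <- 0L
  max_steps <- 200 * min(params$n_max, 20000) + 1000

  rip_process <- function(ch) {
    # one RIP processing event: each intact target motif mutates w.p. f_rip
    hits <- scan_motifs(paste(ch, collapse = ""), motifs$unmutated)
    nmut <- 0L
    if (nrow(hits)) {
      mut <- stats::runif(nrow(hits)) < params$f_rip
      for (h in which(mut)) {
        mi <- match(hits$motif[h], motifs$unmutated)
        pos <- hits$pos[h] + motifs$mut_pos[mi] - 1L
        ch[pos] <- substr(motifs$mutated[mi], motifs$mut_pos[mi],
                          motifs$mut_pos[mi])
      }
      nmut <- sum(mut)
    }
    list(ch = ch, nmut = nmut)
  }

  apply_background <- function(dt) {
    # background substitutions plus time-based RIP exposure over an interval
    if (dt <= 0) return(invisible())
    if (params$mu > 0) {
      n <- stats::rpois(length(seqs), params$mu * L * dt)
      for (i in which(n > 0L)) {
        seqs[[i]] <<- mutate_background(seqs[[i]], n[i])
        nbg[i] <<- nbg[i] + n[i]
      }
    }
    if (params$rip_rate > 0) {
      ne <- stats::rpois(length(seqs), params$rip_rate * dt)
      for (i in which(ne > 0L)) {
        for (ev in seq_len(ne[i])) {
          res <- rip_process(seqs[[i]])
          seqs[[i]] <<- res$ch
          k[i] <<- k[i] + res$nmut
        }
      }
    }
  }

  repeat {
    n <- length(seqs)
    rate <- params$lambda0 * params$s^k
    if (burst_on) rate[burst] <- rate[burst] * params$burst_factor
    R <- sum(rate)
    if (n >= params$n_max || R <= 0) break
    steps <- steps + 1L
    if (steps > max_steps)
      stop("population growth stalled: RIP load has collapsed every ",
           "transposition rate; increase s or reduce rip_rate/f_rip")
    dt <- stats::rexp(1L, R)
    if (burst_armed && !burst_on && t + min(dt, dt_max) > params$burst_time) {
      apply_background(params$burst_time - t)
      t <- params$burst_time
      # burst founder: a copy of the least-mutated (fittest) class, uniform
      # among ties. An observed massive expansion is conditioned on having
      # succeeded, which under a per-site fitness penalty concentrates the
      # founder on elements that escaped the defense.
      cand <- which(k == min(k))
      burst[cand[sample.int(length(cand), 1L)]] <- TRUE
      burst_on <- TRUE
      next
    }
    if (t + min(dt, dt_max) > params$t_end) {
      apply_background(params$t_end - t)
      t <- params$t_end
      break
    }
    if (dt > dt_max) {         # consume a rate-free chunk and redraw
      apply_background(dt_max)
      t <- t + dt_max
      next
    }
    apply_background(dt)
    t <- t + dt
    parent <- sample.int(n, 1L, prob = rate)
    if (n == 1L) {          # state of the founder lineage at the first birth:
      mrca_seq <- seqs[[1L]]  # the true MRCA of all extant copies
      mrca_k <- k[1L]
    }
    child_ch <- seqs[[parent]]
    new_rip <- 0L
    if (stats::runif(1L) < params$p_rip) {   # duplication-triggered processing
      res <- rip_process(child_ch)
      child_ch <- res$ch
      new_rip <- res$nmut
    }
    seqs[[n + 1L]] <- child_ch
    k[n + 1L] <- k[parent] + new_rip
    nbg[n + 1L] <- nbg[parent]
    burst[n + 1L] <- burst_on && burst[parent]
    chrom[n + 1L] <- sample.int(params$n_chromosomes, 1L)
    birth[n + 1L] <- t
    ev_parent[length(ev_parent) + 1L] <- parent
    ev_child[length(ev_child) + 1L] <- n + 1L
    ev_time[length(ev_time) + 1L] <- t
    if (n + 1L >= hard_cap)
      stop("runaway growth: population exceeded ", hard_cap,
           " copies; reduce lambda0/burst_factor or n_max")
  }

  n <- length(seqs)
  ids <- sprintf("%s_%03d", strain, seq_len(n))
  copies <- te_copies(ids, rep(strain, n), sprintf("chr%02d", chrom),
                      vapply(seqs, paste, "", collapse = ""))
  truth_tab <- data.frame(
    id = ids, strain = strain, chromosome = sprintf("chr%02d", chrom),
    birth_time = birth, n_rip_events = k,
    n_rip_events_since_mrca = pmax(k - mrca_k, 0L),
    n_background_mutations = nbg,
    in_burst = burst, stringsAsFactors = FALSE)
  tree <- genealogy_tree(ids, ev_parent, ev_child, ev_time, final_time = t)
  out <- list(copies = copies,
              truth = list(tree = tree, ancestor = founder,
                           mrca_sequence = paste(mrca_seq, collapse = ""),
                           table = truth_tab,
                           final_time = t, params = params))
  if (!is.null(outgroup_divergence)) {
    og_ch <- mutate_background(founder_ch,
                               stats::rpois(1L, outgroup_divergence * L))
    og <- te_copies("OUT_001", "outgroup", "chr00", paste(og_ch, collapse = ""))
    out$copies <- rbind(out$copies, og)
    out$outgroup <- "OUT_001"
  }
  out
}

# Build the birth-process genealogy as a phylo object. Each birth event of
# child from parent creates an internal node on the parent's lineage; all
# extant copies terminate at final_time (ultrametric in time).
genealogy_tree <- function(ids, ev_parent, ev_child, ev_time, final_time) {
  n <- length(ids)
  if (n == 1L) {
    tr <- list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = ids,
               edge.length = final_time, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  births_of <- split(seq_along(ev_parent), ev_parent)  # event idx by parent copy
  # newick built iteratively over each copy's birth chain to avoid deep recursion
  node_label <- function(copy, from_event) {
    evs <- births_of[[as.character(copy)]]
    if (!is.null(from_event)) evs <- evs[evs > from_event]
    if (!length(evs)) {
      t0 <- if (is.null(from_event)) 0 else ev_time[from_event]
      return(sprintf("%s:%.10g", ids[copy], final_time - t0))
    }
    e <- evs[1L]
    t0 <- if (is.null(from_event)) 0 else ev_time[from_event]
    sprintf("(%s,%s):%.10g",
            node_label(copy, e), node_label(ev_child[e], e), ev_time[e] - t0)
  }
  txt <- paste0(node_label(1L, NULL), ";")
  tr <- ape::read.tree(text = txt)
  # the root edge length (founder stem) is dropped by read.tree; fine
  tr
}
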