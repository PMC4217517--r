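# Independent reference computations used to validate the compiled engine.
# reference_simulate() is a deliberately plain R re-statement of the
# replication rules, sharing no code with the engine, restricted to toy
# problem sizes where clarity beats speed.

#' Closed-form timing for deterministic landscapes
#'
#' With unit fork-progress probability and no stochastic release, a fork
#' advances exactly one bin per sweep, so once every origin of a delta /
#' multi-delta landscape has fired (on the same sweep), each bin is
#' replicated `min_o |b - o|` sweeps later: the timing profile is the
#' lower envelope of V shapes rooted at the origins.
#'
#' @param landscape an `ipls_landscape` whose probabilities are exactly 0
#'   or 1 (a delta / multi-delta landscape).
#' @return integer vector of per-bin replication-sweep offsets relative to
#'   the common firing sweep.
#' @export
analytic_timing <- function(landscape) {
  validate_landscape(landscape)
  p <- landscape$init_prob
  if (!all(p %in% c(0, 1)))
    stop_replisim(
      "analytic timing requires a deterministic (0/1) landscape",
      "replisim_contract_error")
  origins <- which(p == 1)
  bins <- seq_along(p)
  apply(abs(outer(bins, origins, "-")), 1L, min)
}

#' Reference Monte Carlo simulator (independent oracle)
#'
#' A straightforward re-implementation of the per-sweep replication rules
#' -- advance engaged forks (recycle on boundary or collision), release
#' stochastically, one initiation attempt per free fork pair (or per
#' cell) at a uniformly drawn unreplicated bin -- written for clarity and
#' kept independent of the compiled engine. Cycles are simulated one at a
#' time, each starting at S entry, using R's own RNG.
#'
#' @param landscape an `ipls_landscape` with at most 12 bins.
#' @param nfork forks per cell (at most 4).
#' @param n_cycles number of complete S phases to simulate.
#' @param pprogress,prelease global fork kinetics (overridden by landscape
#'   columns).
#' @param init_rule `"per_pair"` or `"per_cell"`.
#' @param seed seed for R's RNG.
#' @return list with per-bin `mean`, `var`, and `n` of the replication
#'   sweep (relative to S entry), plus the matrix of per-cycle
#'   `rep_sweep` values.
#' @export
reference_simulate <- function(landscape, nfork = 2L, n_cycles = 1000L,
                               pprogress = 1, prelease = 0,
                               init_rule = c("per_pair", "per_cell"),
                               seed = 1L) {
  init_rule <- match.arg(init_rule)
  validate_landscape(landscape)
  nb <- n_bins(landscape)
  if (nb > 12L)
    stop_replisim("reference simulator is limited to 12 bins",
                  "replisim_contract_error")
  if (nfork > 4L)
    stop_replisim("reference simulator is limited to 4 forks",
                  "replisim_contract_error")
  kin <- resolve_kinetics(landscape, pprogress, prelease)
  p_init <- landscape$init_prob

  set.seed(seed)
  rep_sweeps <- matrix(NA_integer_, nrow = n_cycles, ncol = nb)

  for (cyc in seq_len(n_cycles)) {
    replicated <- rep(FALSE, nb)
    when <- rep(NA_integer_, nb)
    fork_pos <- rep(NA_integer_, nfork)
    fork_dir <- rep(0L, nfork)
    engaged <- rep(FALSE, nfork)
    s <- 0L
    while (!all(replicated)) {
      # 1. advance (pool order; blocked forks are recycled)
      for (f in seq_len(nfork)) {
        if (!engaged[f]) next
        if (runif(1) < kin$pprog[fork_pos[f]]) {
          tgt <- fork_pos[f] + fork_dir[f]
          if (tgt < 1L || tgt > nb || replicated[tgt]) {
            engaged[f] <- FALSE
          } else {
            fork_pos[f] <- tgt
            replicated[tgt] <- TRUE
            when[tgt] <- s
          }
        }
      }
      # 2. stochastic release
      for (f in seq_len(nfork)) {
        if (engaged[f] && runif(1) < kin$prel[fork_pos[f]])
          engaged[f] <- FALSE
      }
      # 3. initiation attempts
      free <- sum(!engaged)
      attempts <- if (init_rule == "per_pair") free %/% 2L
                  else as.integer(free >= 2L)
      for (a in seq_len(attempts)) {
        open <- which(!replicated)
        if (length(open) == 0L) break
        bin <- open[sample.int(length(open), 1L)]
        if (runif(1) < p_init[bin]) {
          replicated[bin] <- TRUE
          when[bin] <- s
          pair <- which(!engaged)[1:2]
          engaged[pair] <- TRUE
          fork_pos[pair] <- bin
          fork_dir[pair] <- c(-1L, 1L)
        }
      }
      s <- s + 1L
    }
    rep_sweeps[cyc, ] <- when
  }

  list(mean = colMeans(rep_sweeps),
       var = apply(rep_sweeps, 2L, var),
       n = n_cycles,
       rep_sweeps = rep_sweeps)
}
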