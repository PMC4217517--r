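#' Fork velocity constant (bp per second)
#'
#' Replication forks synthesize DNA at a constant 50 bp/s; together with
#' the bin size this fixes the wall-clock meaning of one simulation sweep.
#' @export
FORK_VELOCITY_BPS <- 50

#' Seconds of real time represented by one simulation sweep
#'
#' An engaged fork traverses exactly one bin per sweep, so one sweep
#' corresponds to `binsize / 50` seconds (e.g. 10 s at the default 500 bp
#' resolution).
#'
#' @param binsize bin width in bp.
#' @return seconds per sweep.
#' @export
sweep_seconds <- function(binsize) {
  if (any(binsize <= 0)) stop_replisim("binsize must be > 0",
                                       "replisim_validation_error")
  binsize / FORK_VELOCITY_BPS
}

#' Simulation configuration
#'
#' Collects the population-level simulation parameters. Defaults follow
#' the tool's standard command-line settings.
#'
#' @param ncells number of independent virtual cells (default 1000).
#' @param nfork replication forks available per cell (default 50); forks
#'   engage in bidirectional pairs, so at least 2 are required. As a
#'   whole-genome sizing rule, one fork per 80 Mb of genome works well.
#' @param ntherm thermalization (burn-in) sweeps that desynchronize the
#'   initially all-G population before anything is recorded (default 80000).
#' @param nmeas number of measurement epochs (default 2000).
#' @param stepsize sweeps between consecutive measurements (default 20000).
#' @param pprogress global per-sweep probability that an engaged fork
#'   advances one bin (default 1); overridden bin-by-bin by a landscape
#'   `fork_progress` column.
#' @param prelease global per-sweep probability that an engaged fork is
#'   released (default 0); overridden by a landscape `fork_release` column.
#' @param g_mean,g_sd mean and standard deviation, in sweeps, of the
#'   normally distributed G-phase duration (truncated at 1 sweep). When
#'   `NULL`, `g_mean` is set to the expected S-phase duration of the
#'   landscape (estimated from a small pilot run) and `g_sd` to
#'   `0.1 * g_mean`, which yields a well-mixed asynchronous population.
#' @param seed master random seed; every cell derives its own independent
#'   stream from it, so results do not depend on scheduling.
#' @param init_rule `"per_pair"` (default): each pair of free forks makes
#'   one initiation attempt per sweep, so firing opportunity scales with
#'   free replication factors; `"per_cell"`: at most one attempt per cell
#'   per sweep.
#' @param threads accepted for interface compatibility; the per-cell
#'   random streams make results independent of worker count.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(ncells = 1000L, nfork = 50L, ntherm = 80000,
                              nmeas = 2000, stepsize = 20000, pprogress = 1,
                              prelease = 0, g_mean = NULL, g_sd = NULL,
                              seed = 1L, init_rule = c("per_pair", "per_cell"),
                              threads = 1L) {
  init_rule <- match.arg(init_rule)
  bad <- function(msg) stop_replisim(msg, "replisim_validation_error")
  if (ncells < 1) bad("ncells must be >= 1")
  if (nfork < 2) bad("nfork must be >= 2 (forks engage in pairs)")
  if (ntherm < 0 || nmeas < 1 || stepsize < 1)
    bad("ntherm must be >= 0; nmeas and stepsize must be >= 1")
  if (pprogress < 0 || pprogress > 1 || prelease < 0 || prelease > 1)
    bad("pprogress and prelease must lie in [0, 1]")
  if (!is.null(g_mean) && g_mean <= 0) bad("g_mean must be > 0")
  if (!is.null(g_sd) && g_sd < 0) bad("g_sd must be >= 0")
  if (threads < 1) bad("threads must be >= 1")
  structure(list(ncells = as.integer(ncells), nfork = as.integer(nfork),
                 ntherm = as.numeric(ntherm), nmeas = as.numeric(nmeas),
                 stepsize = as.numeric(stepsize),
                 pprogress = as.numeric(pprogress),
                 prelease = as.numeric(prelease),
                 g_mean = g_mean, g_sd = g_sd, seed = as.numeric(seed),
                 init_rule = init_rule, threads = as.integer(threads)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Replication simulation configuration\n")
  cat(sprintf("  ncells %d, nfork %d, ntherm %g, nmeas %g, stepsize %g\n",
              x$ncells, x$nfork, x$ntherm, x$nmeas, x$stepsize))
  cat(sprintf("  pprogress %g, prelease %g, init_rule %s, seed %g\n",
              x$pprogress, x$prelease, x$init_rule, x$seed))
  cat(sprintf("  G duration: %s\n",
              if (is.null(x$g_mean)) "auto (pilot-estimated)"
              else sprintf("normal(%g, %g) sweeps", x$g_mean, x$g_sd)))
  invisible(x)
}

# Fill in pilot-estimated G-phase parameters; returns a fully resolved config.
resolve_config <- function(config, landscape, n_pilot = 16L) {
  if (is.null(config$g_mean)) {
    kin <- resolve_kinetics(landscape, config$pprogress, config$prelease)
    dur <- cpp_pilot_s_durations(landscape$init_prob, kin$pprog, kin$prel,
                                 config$nfork,
                                 match(config$init_rule,
                                       c("per_pair", "per_cell")) - 1L,
                                 config$seed, n_pilot,
                                 max_sweeps = 1e8)
    config$g_mean <- max(1, mean(dur))
  }
  if (is.null(config$g_sd)) config$g_sd <- 0.1 * config$g_mean
  config
}

#' Create a fresh virtual cell
#'
#' Cells start in G phase with a normally drawn resting duration and carry
#' their own random stream (derived from `seed` and `stream`), a per-bin
#' replication mask, per-bin replication-sweep records, and a pool of
#' `nfork` replication forks.
#'
#' @param landscape an `ipls_landscape`.
#' @param nfork forks in the cell's pool.
#' @param seed master seed.
#' @param stream stream identifier (e.g. the cell index).
#' @param g_mean,g_sd G-phase duration parameters in sweeps.
#' @return an object of class `cell_state` with fields `phase` (`"G"` or
#'   `"S"`), `phase_clock` (sweeps remaining in G / elapsed in S), `mask`,
#'   `rep_sweep`, `fork_engaged`, `fork_pos`, `fork_dir`, `init_log`, and
#'   `rng_state`.
#' @export
cell_state <- function(landscape, nfork = 2L, seed = 1L, stream = 1L,
                       g_mean = 10, g_sd = 0) {
  validate_landscape(landscape)
  if (nfork < 2) stop_replisim("nfork must be >= 2",
                               "replisim_validation_error")
  cpp_new_cell(landscape$init_prob, as.integer(nfork), as.numeric(seed),
               as.numeric(stream), g_mean, g_sd)
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("cell in %s phase (clock %g): %d/%d bins replicated, %d forks engaged\n",
              x$phase, x$phase_clock, sum(x$mask), length(x$mask),
              sum(x$fork_engaged)))
  invisible(x)
}

#' Apply one S-phase sweep to a single cell
#'
#' Executes the within-sweep event order on one S-phase cell: engaged
#' forks advance (or are recycled on collision / at the chromosome
#' boundary), still-engaged forks may be stochastically released, then
#' each free fork pair makes one initiation attempt at a uniformly drawn
#' unreplicated bin, firing with the landscape probability there. If the
#' genome completes, the cell returns to G and the finished cycle is
#' archived in `$last_cycle` (fields `rep_sweep`, `init_log`, `duration`).
#'
#' @param cell a `cell_state` in S phase (G-phase cells are a contract
#'   violation; use [population_sweep()] to run the full phase logic).
#' @param landscape an `ipls_landscape`.
#' @param pprogress,prelease global fork kinetics (overridden by landscape
#'   columns).
#' @param init_rule see [simulation_config()].
#' @param g_mean,g_sd G duration parameters used when the cell completes.
#' @return the updated `cell_state`.
#' @export
cell_sweep <- function(cell, landscape, pprogress = 1, prelease = 0,
                       init_rule = c("per_pair", "per_cell"),
                       g_mean = 10, g_sd = 0) {
  init_rule <- match.arg(init_rule)
  validate_landscape(landscape)
  if (!identical(cell$phase, "S"))
    stop_replisim("cell_sweep called on a cell in G phase",
                  "replisim_contract_error")
  kin <- resolve_kinetics(landscape, pprogress, prelease)
  cpp_cell_sweep(cell, landscape$init_prob, kin$pprog, kin$prel,
                 length(cell$fork_engaged),
                 match(init_rule, c("per_pair", "per_cell")) - 1L,
                 g_mean, g_sd)
}

#' Advance a population of cells by one or more sweeps
#'
#' G-phase cells count down their resting clock and enter S when it
#' expires (the transition is processed at sweep start, so a new S entrant
#' may initiate on its first sweep); S-phase cells undergo [cell_sweep()].
#' Cells are fully independent.
#'
#' @param cells list of `cell_state` objects.
#' @param landscape an `ipls_landscape`.
#' @param pprogress,prelease,init_rule,g_mean,g_sd as in [cell_sweep()].
#' @param nsweeps number of sweeps to run.
#' @return a list with `cells` (updated states) and `completed` (one entry
#'   per S phase finished during these sweeps: `cell` index, `rep_sweep`,
#'   `init_log`, `duration`).
#' @export
population_sweep <- function(cells, landscape, pprogress = 1, prelease = 0,
                             init_rule = c("per_pair", "per_cell"),
                             g_mean = 10, g_sd = 0, nsweeps = 1L) {
  init_rule <- match.arg(init_rule)
  validate_landscape(landscape)
  if (length(cells) == 0L) return(list(cells = cells, completed = list()))
  nfork <- length(cells[[1L]]$fork_engaged)
  kin <- resolve_kinetics(landscape, pprogress, prelease)
  cpp_population_sweep(cells, landscape$init_prob, kin$pprog, kin$prel,
                       nfork,
                       match(init_rule, c("per_pair", "per_cell")) - 1L,
                       g_mean, g_sd, as.integer(nsweeps))
}

#' Run the full population simulation
#'
#' Initializes `ncells` cells in G phase with independently drawn resting
#' durations, runs `ntherm` thermalization sweeps (cycles that begin
#' during burn-in are discarded), then `nmeas` measurement epochs of
#' `stepsize` sweeps each. Per-bin replication-sweep statistics are
#' accumulated over every S phase that begins after burn-in and completes;
#' a population snapshot (phase, replicated fraction, engaged forks,
#' run-length-encoded replication mask) is taken at the end of every
#' epoch, and every initiation event is logged with the replicated
#' fraction of its cell at firing time.
#'
#' @param config a `sim_config`.
#' @param landscape an `ipls_landscape`.
#' @param snapshots set `FALSE` to skip snapshot collection (timing and
#'   event statistics are still accumulated).
#' @return an object of class `ensemble_record`; see [timing_profile()],
#'   [single_molecule_stats()], [flow_sort()], [initiation_rate()],
#'   [nascent_profile()] and [indices()] for the measurement devices that
#'   consume it.
#' @export
run_simulation <- function(config = simulation_config(), landscape,
                           snapshots = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  validate_landscape(landscape)
  config <- resolve_config(config, landscape)
  kin <- resolve_kinetics(landscape, config$pprogress, config$prelease)
  raw <- cpp_run_simulation(
    landscape$init_prob, kin$pprog, kin$prel, config$ncells, config$nfork,
    config$ntherm, config$nmeas, config$stepsize, config$g_mean, config$g_sd,
    config$seed, match(config$init_rule, c("per_pair", "per_cell")) - 1L,
    isTRUE(snapshots))

  rle_lengths <- if (length(raw$rle_nrun))
    split(raw$rle_lengths, rep.int(seq_along(raw$rle_nrun), raw$rle_nrun))
  else list()

  structure(list(
    chrom = landscape$chrom,
    n_bins = n_bins(landscape),
    binsize = landscape$binsize,
    velocity = FORK_VELOCITY_BPS,
    ncells = config$ncells,
    nfork = config$nfork,
    config = config,
    timing_sum = raw$timing_sum,
    timing_sumsq = raw$timing_sumsq,
    timing_count = raw$timing_count,
    n_cycles = raw$n_cycles,
    events = data.frame(sweep = raw$ev_sweep, bin = raw$ev_bin,
                        frac = raw$ev_frac),
    exposure = raw$exposure,
    snapshots = data.frame(epoch = raw$sn_epoch, cell = raw$sn_cell,
                           phase = ifelse(raw$sn_phase == 1, "S", "G"),
                           frac = raw$sn_frac, engaged = raw$sn_engaged,
                           time_in_s = raw$sn_time, rle_id = raw$sn_rle_id),
    mask_rle = list(first = raw$rle_first, lengths = unname(rle_lengths))),
    class = "ensemble_record")
}

#' @export
print.ensemble_record <- function(x, ...) {
  cat(sprintf("Replication ensemble record: %s, %d bins x %d bp\n",
              x$chrom, x$n_bins, x$binsize))
  cat(sprintf("  %g completed S phases observed, %d initiation events, %d snapshot rows\n",
              x$n_cycles, nrow(x$events), nrow(x$snapshots)))
  invisible(x)
}

# Rebuild the logical replication mask of one snapshot row.
snapshot_mask <- function(record, rle_id) {
  inverse.rle(structure(list(
    lengths = record$mask_rle$lengths[[rle_id]],
    values = rep(c(record$mask_rle$first[rle_id],
                   !record$mask_rle$first[rle_id]),
                 length.out = length(record$mask_rle$lengths[[rle_id]]))),
    class = "rle"))
}
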