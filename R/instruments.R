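# Simulated measurement devices: every observable is computed from an
# ensemble_record, never from engine internals.

bin_starts <- function(record) (seq_len(record$n_bins) - 1L) * record$binsize

#' Replication timing profile
#'
#' The headline output: for every genomic bin, the arithmetic mean of the
#' sweep (relative to S entry) at which that bin was replicated, averaged
#' over all observed completed S phases. The normalized column is the
#' z-scored profile with the sign flipped so that early-replicating bins
#' score high, the convention of early/late-ratio population timing data.
#'
#' @param record an `ensemble_record` with at least one completed cycle.
#' @return a `timing_profile` data frame with columns `bin`, `start`,
#'   `end`, `mean_sweep`, `count`, `normalized`; attributes carry `chrom`
#'   and `binsize`.
#' @export
timing_profile <- function(record) {
  stopifnot(inherits(record, "ensemble_record"))
  if (record$n_cycles < 1)
    stop_replisim("no completed S phases observed; nothing to average",
                  "replisim_validation_error")
  m <- record$timing_sum / record$timing_count
  s <- sd(m)
  normalized <- if (is.na(s) || s == 0) rep(0, length(m)) else -(m - mean(m)) / s
  out <- data.frame(bin = seq_along(m), start = bin_starts(record),
                    end = bin_starts(record) + record$binsize,
                    mean_sweep = m, count = record$timing_count,
                    normalized = normalized)
  structure(out, chrom = record$chrom, binsize = record$binsize,
            class = c("timing_profile", "data.frame"))
}

#' Per-bin Monte Carlo standard error of the timing profile
#'
#' @param record an `ensemble_record`.
#' @return numeric vector of standard errors of `mean_sweep`.
#' @export
timing_se <- function(record) {
  n <- record$timing_count
  m <- record$timing_sum / n
  v <- (record$timing_sumsq - n * m^2) / pmax(n - 1, 1)
  sqrt(pmax(v, 0) / n)
}

#' Simulated flow sorting (Repli-seq style readout)
#'
#' At every measurement snapshot, each S-phase cell is gated into the
#' fraction interval containing its replicated genome fraction (intervals
#' are half-open `[lo, hi)`; the last is closed; G cells are never
#' sorted). For every genomic bin and gate, the number of gated cells with
#' that bin already replicated is counted. The derived `timing` is, per
#' bin, the count-weighted mean of gate midpoints -- an S50-style summary
#' of when in S phase a bin is typically replicated.
#'
#' @param record an `ensemble_record` with snapshots.
#' @param boundaries strictly increasing gate boundaries within `[0, 1]`,
#'   e.g. `c(0, 0.25, 0.5, 0.75, 1)`.
#' @return a `flow_sort` list: `boundaries`, `counts` (gates x bins
#'   matrix), `n_sorted` cells per gate, and `timing` data frame.
#' @export
flow_sort <- function(record, boundaries) {
  stopifnot(inherits(record, "ensemble_record"))
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L || any(diff(boundaries) <= 0) ||
      any(boundaries < 0) || any(boundaries > 1))
    stop_replisim("boundaries must be strictly increasing within [0, 1]",
                  "replisim_validation_error")
  k <- length(boundaries) - 1L
  sn <- record$snapshots[record$snapshots$phase == "S", , drop = FALSE]
  gate <- findInterval(sn$frac, boundaries, rightmost.closed = TRUE)
  keep <- gate >= 1L & gate <= k
  sn <- sn[keep, , drop = FALSE]
  gate <- gate[keep]
  counts <- matrix(0L, nrow = k, ncol = record$n_bins,
                   dimnames = list(
                     gate = sprintf("[%g,%g%s", boundaries[-(k + 1L)],
                                    boundaries[-1L],
                                    c(rep(")", k - 1L), "]")),
                     NULL))
  n_sorted <- integer(k)
  for (i in seq_len(nrow(sn))) {
    g <- gate[i]
    n_sorted[g] <- n_sorted[g] + 1L
    counts[g, ] <- counts[g, ] + snapshot_mask(record, sn$rle_id[i])
  }
  mids <- (boundaries[-1L] + boundaries[-(k + 1L)]) / 2
  tot <- colSums(counts)
  s50 <- ifelse(tot > 0, colSums(counts * mids) / tot, NA_real_)
  structure(list(boundaries = boundaries, counts = counts,
                 n_sorted = n_sorted,
                 timing = data.frame(bin = seq_len(record$n_bins),
                                     start = bin_starts(record),
                                     s50 = s50)),
            class = "flow_sort")
}

# Eye / hole / eye-to-eye geometry of one molecule from its mask RLE.
# Lengths in bp; eye centers in bin-index units. Eyes touching a
# chromosome end are kept in the eye statistics but dropped from
# eye-to-eye distances (their centers are truncation artifacts).
mask_run_geometry <- function(first, lengths, binsize) {
  nr <- length(lengths)
  vals <- rep_len(c(first, !first), nr)
  starts <- cumsum(c(0L, lengths[-nr]))
  total <- sum(lengths)
  eye <- which(vals)
  hole <- which(!vals)
  eye_start <- starts[eye]
  eye_len <- lengths[eye]
  boundary <- eye_start == 0L | (eye_start + eye_len) == total
  centers <- eye_start + (eye_len - 1) / 2
  list(eyes_bp = eye_len * binsize,
       holes_bp = lengths[hole] * binsize,
       e2e_bp = diff(centers[!boundary]) * binsize)
}

#' Simulated DNA combing (single-molecule) statistics
#'
#' Treats every S-phase cell at every snapshot as one combed molecule:
#' eyes are maximal runs of replicated bins, holes are maximal runs of
#' unreplicated bins, and eye-to-eye distances separate the centers of
#' adjacent eyes (a proxy for inter-origin distance). Molecules are pooled
#' into equal-width time-in-S bins, yielding the characteristic picture of
#' eyes growing and merging while holes shrink as S phase proceeds.
#'
#' @param record an `ensemble_record` with snapshots.
#' @param time_bins number of equal-width time-in-S bins (sweeps).
#' @return a `combing_summary` data frame: `time_bin`, `t_lo`/`t_hi`
#'   (sweeps), `t_mid_s` (seconds), `n_molecules`, `mean_eye_bp`/`n_eyes`,
#'   `mean_hole_bp`/`n_holes`, `mean_e2e_bp`/`n_e2e`.
#' @export
single_molecule_stats <- function(record, time_bins = 10L) {
  stopifnot(inherits(record, "ensemble_record"))
  time_bins <- as.integer(time_bins)
  if (is.na(time_bins) || time_bins < 1L)
    stop_replisim("time_bins must be >= 1", "replisim_validation_error")
  sn <- record$snapshots[record$snapshots$phase == "S", , drop = FALSE]
  if (nrow(sn) == 0L)
    stop_replisim("no S-phase snapshots available",
                  "replisim_validation_error")
  span <- max(sn$time_in_s) + 1  # bins cover [0, max_t + 1)
  idx <- pmin(time_bins, floor(sn$time_in_s / span * time_bins) + 1L)
  acc <- matrix(0, nrow = time_bins, ncol = 7L,
                dimnames = list(NULL, c("n_molecules", "eye_sum", "n_eyes",
                                        "hole_sum", "n_holes", "e2e_sum",
                                        "n_e2e")))
  for (i in seq_len(nrow(sn))) {
    g <- mask_run_geometry(record$mask_rle$first[sn$rle_id[i]],
                           record$mask_rle$lengths[[sn$rle_id[i]]],
                           record$binsize)
    b <- idx[i]
    acc[b, ] <- acc[b, ] + c(1, sum(g$eyes_bp), length(g$eyes_bp),
                             sum(g$holes_bp), length(g$holes_bp),
                             sum(g$e2e_bp), length(g$e2e_bp))
  }
  t_lo <- (seq_len(time_bins) - 1L) / time_bins * span
  t_hi <- seq_len(time_bins) / time_bins * span
  out <- data.frame(
    time_bin = seq_len(time_bins), t_lo = t_lo, t_hi = t_hi,
    t_mid_s = (t_lo + t_hi) / 2 * sweep_seconds(record$binsize),
    n_molecules = acc[, "n_molecules"],
    mean_eye_bp = ifelse(acc[, "n_eyes"] > 0,
                         acc[, "eye_sum"] / acc[, "n_eyes"], NA_real_),
    n_eyes = acc[, "n_eyes"],
    mean_hole_bp = ifelse(acc[, "n_holes"] > 0,
                          acc[, "hole_sum"] / acc[, "n_holes"], NA_real_),
    n_holes = acc[, "n_holes"],
    mean_e2e_bp = ifelse(acc[, "n_e2e"] > 0,
                         acc[, "e2e_sum"] / acc[, "n_e2e"], NA_real_),
    n_e2e = acc[, "n_e2e"])
  structure(out, binsize = record$binsize,
            class = c("combing_summary", "data.frame"))
}

#' Global initiation rate as a function of S-phase progression
#'
#' Initiation events and exposure (unreplicated-bin sweeps) are
#' accumulated by the replicated fraction of the cell at the sweep of the
#' event; the rate in each fraction bin is events per unreplicated bin per
#' sweep. Bins without exposure report `NA` (undefined), not zero.
#'
#' @param record an `ensemble_record`.
#' @param fraction_bins number of equal-width S-fraction bins (max 1000,
#'   the resolution of the internal exposure grid).
#' @return a data frame with `frac_lo`, `frac_hi`, `events`, `exposure`,
#'   `rate`.
#' @export
initiation_rate <- function(record, fraction_bins = 10L) {
  stopifnot(inherits(record, "ensemble_record"))
  fb <- as.integer(fraction_bins)
  grid <- length(record$exposure)
  if (is.na(fb) || fb < 1L || fb > grid)
    stop_replisim(sprintf("fraction_bins must be in [1, %d]", grid),
                  "replisim_validation_error")
  fine_mid <- (seq_len(grid) - 0.5) / grid
  coarse_of_fine <- pmin(fb, floor(fine_mid * fb) + 1L)
  exposure <- as.numeric(tapply(record$exposure, coarse_of_fine, sum,
                                default = 0)[as.character(seq_len(fb))])
  exposure[is.na(exposure)] <- 0
  ev_idx <- pmin(fb, floor(record$events$frac * fb) + 1L)
  events <- tabulate(ev_idx, nbins = fb)
  data.frame(frac_lo = (seq_len(fb) - 1L) / fb, frac_hi = seq_len(fb) / fb,
             events = events, exposure = exposure,
             rate = ifelse(exposure > 0, events / exposure, NA_real_))
}

#' Nascent-strand initiation profile
#'
#' Counts initiation events per genomic bin across all observed cycles --
#' the simulated analog of short-nascent-strand / replication-bubble
#' enrichment at origins.
#'
#' @param record an `ensemble_record`.
#' @return a data frame with `bin`, `start`, `count`.
#' @export
nascent_profile <- function(record) {
  stopifnot(inherits(record, "ensemble_record"))
  data.frame(bin = seq_len(record$n_bins), start = bin_starts(record),
             count = tabulate(record$events$bin, nbins = record$n_bins))
}

#' Population phase and fork-engagement indices
#'
#' Per measurement snapshot: the fraction of cells in S phase, and the
#' fraction of the fork pool engaged among S-phase cells (0 when no cell
#' is in S).
#'
#' @param record an `ensemble_record` with snapshots.
#' @return a data frame with `epoch`, `s_fraction`, `fork_engagement`.
#' @export
indices <- function(record) {
  stopifnot(inherits(record, "ensemble_record"))
  sn <- record$snapshots
  if (nrow(sn) == 0L)
    stop_replisim("no snapshots available", "replisim_validation_error")
  epochs <- sort(unique(sn$epoch))
  out <- lapply(epochs, function(e) {
    rows <- sn[sn$epoch == e, , drop = FALSE]
    in_s <- rows$phase == "S"
    data.frame(epoch = e, s_fraction = mean(in_s),
               fork_engagement = if (any(in_s))
                 sum(rows$engaged[in_s]) / (record$nfork * sum(in_s)) else 0)
  })
  do.call(rbind, out)
}

#' Pearson correlation and root-mean-square deviation
#'
#' The agreement summary used to compare a predicted timing profile with
#' an observed one. Pairs with a missing value in either vector are
#' deleted before computing both statistics.
#'
#' @param predicted,observed numeric vectors of equal length (>= 3).
#' @return named numeric vector `c(pearson = r, rmsd = d)`.
#' @export
pearson_rmsd <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop_replisim("predicted and observed must have equal length",
                  "replisim_validation_error")
  ok <- stats::complete.cases(predicted, observed)
  x <- predicted[ok]
  y <- observed[ok]
  if (length(x) < 3L)
    stop_replisim("need at least 3 complete pairs",
                  "replisim_validation_error")
  if (sd(x) == 0 || sd(y) == 0)
    stop_replisim("correlation undefined: zero variance",
                  "replisim_validation_error")
  c(pearson = stats::cor(x, y), rmsd = sqrt(mean((x - y)^2)))
}

# ------------------------------- writers -----------------------------------

#' Write a timing profile as bedgraph
#'
#' @param profile a `timing_profile`.
#' @param path output path.
#' @param normalized write the normalized (z-scored, early-positive)
#'   column instead of the raw mean sweep.
#' @return `path`, invisibly.
#' @export
write_timing_bedgraph <- function(profile, path, normalized = FALSE) {
  stopifnot(inherits(profile, "timing_profile"))
  value <- if (normalized) profile$normalized else profile$mean_sweep
  df <- data.frame(chrom = attr(profile, "chrom"), start = profile$start,
                   end = profile$end, value = value)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write an instrument table as headered TSV
#'
#' @param x a data frame produced by an instrument (for [flow_sort()]
#'   results the gate-by-bin counts are written in long format together
#'   with the derived timing).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_instrument_tsv <- function(x, path) {
  if (inherits(x, "flow_sort")) {
    k <- nrow(x$counts)
    long <- data.frame(
      bin = rep(seq_len(ncol(x$counts)), each = k),
      gate = rep(rownames(x$counts), times = ncol(x$counts)),
      frac_lo = rep(x$boundaries[-(k + 1L)], times = ncol(x$counts)),
      frac_hi = rep(x$boundaries[-1L], times = ncol(x$counts)),
      count = as.vector(x$counts))
    long$s50 <- x$timing$s50[long$bin]
    x <- long
  }
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
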