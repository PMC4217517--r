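# Build a hand-specified ensemble_record so instruments can be unit-tested
# against arithmetic done on paper, independent of the engine.
fake_record <- function(masks, time_in_s = rep(0L, length(masks)),
                        frac = vapply(masks, mean, numeric(1)),
                        epoch = rep(1L, length(masks)),
                        engaged = rep(0L, length(masks)),
                        n_g_cells = 0L, g_epoch = 1L,
                        n_bins = if (length(masks)) length(masks[[1L]]) else 1L,
                        binsize = 500L, nfork = 2L,
                        timing_sum = rep(0, n_bins),
                        timing_sumsq = rep(0, n_bins),
                        timing_count = rep(1L, n_bins), n_cycles = 1,
                        events = data.frame(sweep = integer(),
                                            bin = integer(),
                                            frac = numeric()),
                        exposure = numeric(1000)) {
  rles <- lapply(masks, rle)
  sn <- data.frame(epoch = as.integer(epoch),
                   cell = seq_along(masks),
                   phase = rep("S", length(masks)),
                   frac = frac, engaged = as.integer(engaged),
                   time_in_s = as.integer(time_in_s),
                   rle_id = seq_along(masks))
  if (n_g_cells > 0L) {
    sn <- rbind(sn, data.frame(
      epoch = rep(as.integer(g_epoch), n_g_cells),
      cell = length(masks) + seq_len(n_g_cells), phase = "G",
      frac = NA_real_, engaged = 0L, time_in_s = NA_integer_,
      rle_id = NA_integer_))
  }
  structure(list(
    chrom = "chrT", n_bins = n_bins, binsize = as.integer(binsize),
    velocity = 50, ncells = nrow(sn), nfork = as.integer(nfork),
    config = NULL,
    timing_sum = timing_sum, timing_sumsq = timing_sumsq,
    timing_count = timing_count, n_cycles = n_cycles,
    events = events, exposure = exposure, snapshots = sn,
    mask_rle = list(
      first = vapply(rles, function(r) r$values[1L], logical(1)),
      lengths = lapply(rles, `[[`, "lengths"))),
    class = "ensemble_record")
}

# Parse "0011100110" into a logical mask.
bitmask <- function(s) as.logical(as.integer(strsplit(s, "")[[1L]]))

# Drive one or more cells sweep-by-sweep, collecting completed cycles.
collect_cycles <- function(landscape, nfork = 2L, nsweeps = 1000L,
                           ncells = 1L, seed = 1L, g_mean = 1, g_sd = 0,
                           init_rule = "per_pair") {
  cells <- lapply(seq_len(ncells), function(i)
    cell_state(landscape, nfork = nfork, seed = seed, stream = i,
               g_mean = g_mean, g_sd = g_sd))
  population_sweep(cells, landscape, init_rule = init_rule,
                   g_mean = g_mean, g_sd = g_sd, nsweeps = nsweeps)
}

write_tmp_ipls <- function(lines) {
  f <- tempfile(fileext = ".ipls")
  writeLines(lines, f)
  f
}
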