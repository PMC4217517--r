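test_that("timing profile is the per-bin mean over observed cycles", {
  rec <- fake_record(masks = list(rep(TRUE, 4)),
                     timing_sum = c(8, 6, 4, 10),
                     timing_count = rep(2L, 4), n_cycles = 2)
  tp <- timing_profile(rec)
  expect_equal(tp$mean_sweep, c(4, 3, 2, 5))
  expect_equal(tp$start, c(0, 500, 1000, 1500))
  # normalized: zero mean, unit sd, sign-flipped so early = high
  expect_equal(mean(tp$normalized), 0)
  expect_equal(sd(tp$normalized), 1)
  expect_equal(which.max(tp$normalized), which.min(tp$mean_sweep))

  rec0 <- fake_record(masks = list(rep(TRUE, 4)), n_cycles = 0)
  expect_error(timing_profile(rec0), class = "replisim_validation_error")
})

test_that("flow sorter gates cells by replicated fraction", {
  masks <- list(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                  FALSE, FALSE),                     # 30% replicated
                c(rep(TRUE, 5), rep(FALSE, 5)),      # exactly on boundary
                rep(c(TRUE, FALSE), 5))              # 50% too
  rec <- fake_record(masks)
  fs <- flow_sort(rec, c(0, 0.5, 1))
  expect_equal(fs$n_sorted, c(1L, 2L))            # 0.5 goes right (half-open)
  expect_equal(sum(fs$counts[1, ]), 3)            # cell 1: bins 1-3
  expect_equal(fs$counts[1, ], c(1, 1, 1, rep(0, 7)))
  # fraction exactly 1 lands in the (closed) last gate
  rec_full <- fake_record(list(rep(TRUE, 10)))
  expect_equal(flow_sort(rec_full, c(0, 0.5, 1))$n_sorted, c(0L, 1L))

  # a bin replicated only in the earliest gate: s50 = its midpoint
  expect_equal(fs$timing$s50[1], (0.25 * 1 + 0.75 * 2) / 3)  # bin 1 in all
  rec1 <- fake_record(masks[1])
  expect_equal(flow_sort(rec1, c(0, 0.5, 1))$timing$s50[1], 0.25)
  expect_true(is.na(flow_sort(rec1, c(0, 0.5, 1))$timing$s50[5]))

  expect_error(flow_sort(rec, c(0.5, 0.5, 1)),
               class = "replisim_validation_error")
  expect_error(flow_sort(rec, c(0, 1.5)),
               class = "replisim_validation_error")
})

test_that("flow sorter counts are conserved across gates", {
  L <- synthetic_landscape("peaks", 30, centers = c(8, 22), widths = 2)
  rec <- run_simulation(simulation_config(ncells = 5, nfork = 4, ntherm = 10,
                                          nmeas = 20, stepsize = 2,
                                          g_mean = 4, g_sd = 1, seed = 6), L)
  fs <- flow_sort(rec, c(0, 0.25, 0.5, 0.75, 1))
  sn <- rec$snapshots[rec$snapshots$phase == "S", ]
  expected <- Reduce(`+`, lapply(sn$rle_id, function(id) {
    r <- rec$mask_rle
    inverse.rle(structure(list(lengths = r$lengths[[id]],
                               values = rep(c(r$first[id], !r$first[id]),
                                            length.out = length(r$lengths[[id]]))),
                          class = "rle"))
  }))
  expect_equal(unname(colSums(fs$counts)), as.numeric(expected))
})

test_that("combing statistics recover eye/hole/eye-to-eye geometry", {
  rec <- fake_record(list(bitmask("0011100110")))
  cm <- single_molecule_stats(rec, time_bins = 1)
  expect_equal(cm$mean_eye_bp, (1500 + 1000) / 2)
  expect_equal(cm$n_eyes, 2)
  expect_equal(cm$mean_hole_bp, (1000 + 1000 + 500) / 3)
  expect_equal(cm$n_holes, 3)
  expect_equal(cm$mean_e2e_bp, 2250)  # centers at bins 3 and 7.5 (0-based)
  expect_equal(cm$n_e2e, 1)

  # all-unreplicated: one full-length hole, no eyes
  cm0 <- single_molecule_stats(fake_record(list(rep(FALSE, 10))), 1)
  expect_equal(cm0$n_eyes, 0)
  expect_equal(cm0$mean_hole_bp, 5000)
  expect_equal(cm0$n_e2e, 0)

  # all-replicated: one full-length eye, no holes
  cm1 <- single_molecule_stats(fake_record(list(rep(TRUE, 10))), 1)
  expect_equal(cm1$mean_eye_bp, 5000)
  expect_equal(cm1$n_holes, 0)

  # boundary-touching eyes count as eyes but not for eye-to-eye
  cmb <- single_molecule_stats(fake_record(list(bitmask("1100100011"))), 1)
  expect_equal(cmb$n_eyes, 3)
  expect_equal(cmb$n_e2e, 0)  # only one interior eye

  expect_error(single_molecule_stats(rec, 0),
               class = "replisim_validation_error")
})

test_that("molecules are pooled into equal-width time-in-S bins", {
  rec <- fake_record(list(bitmask("1100000000"), bitmask("1111110000")),
                     time_in_s = c(1L, 9L))
  cm <- single_molecule_stats(rec, time_bins = 2)
  expect_equal(cm$n_molecules, c(1, 1))
  expect_equal(cm$mean_eye_bp, c(1000, 3000))
})

test_that("initiation rate divides events by unreplicated-bin exposure", {
  expo <- numeric(1000)
  expo[1] <- 100                     # fraction ~0: coarse bin 1 of 10
  expo[501] <- 40                    # fraction 0.5005: coarse bin 6
  ev <- data.frame(sweep = c(0L, 0L), bin = c(3L, 7L), frac = c(0, 0))
  rec <- fake_record(list(rep(TRUE, 10)), events = ev, exposure = expo)
  ir <- initiation_rate(rec, 10)
  expect_equal(ir$rate[1], 2 / 100)
  expect_equal(ir$rate[6], 0)                   # exposure, no events
  expect_true(all(is.na(ir$rate[c(2:5, 7:10)])))  # no exposure: undefined
  expect_error(initiation_rate(rec, 0), class = "replisim_validation_error")
  expect_error(initiation_rate(rec, 5000),
               class = "replisim_validation_error")
})

test_that("nascent profile counts initiation events per bin", {
  L <- synthetic_landscape("delta", 9, origin = 4)
  rec <- run_simulation(simulation_config(ncells = 2, nfork = 2, ntherm = 0,
                                          nmeas = 2, stepsize = 150,
                                          g_mean = 2, g_sd = 0, seed = 21), L)
  np <- nascent_profile(rec)
  expect_gt(rec$n_cycles, 0)
  expect_equal(np$count[4], rec$n_cycles)  # single origin fires once a cycle
  expect_equal(sum(np$count[-4]), 0)
})

test_that("initiation sampling is uniform over unreplicated bins", {
  # Frozen forks (progress 0, instant release) make replication purely
  # initiation-driven, isolating the uniform bin sampler: every bin then
  # fires by initiation, and counts must pass a chi-square uniformity test.
  # (With moving forks, interior bins are passively replicated more often,
  # so observed events legitimately pile up near chromosome ends.)
  Lf <- landscape(rep(0.5, 8), fork_progress = rep(0, 8),
                  fork_release = rep(1, 8))
  rec <- run_simulation(simulation_config(ncells = 10, nfork = 4, ntherm = 10,
                                          nmeas = 1, stepsize = 2000,
                                          g_mean = 3, g_sd = 1, seed = 33), Lf)
  counts <- nascent_profile(rec)$count
  expect_gt(sum(counts), 500)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)

  # with moving forks the event profile is still symmetric about the center
  L <- synthetic_landscape("uniform", 8, p = 0.5)
  rec2 <- run_simulation(simulation_config(ncells = 10, nfork = 4,
                                           ntherm = 10, nmeas = 1,
                                           stepsize = 2000, g_mean = 3,
                                           g_sd = 1, seed = 33), L)
  c2 <- nascent_profile(rec2)$count
  expect_gt(stats::chisq.test(rbind(c2[1:4], rev(c2)[1:4]))$p.value, 0.01)
})

test_that("population indices summarize phase and fork engagement", {
  rec <- fake_record(list(bitmask("11000"), bitmask("11110"), bitmask("10000")),
                     engaged = c(4L, 4L, 2L), n_g_cells = 1L, nfork = 50L)
  ix <- indices(rec)
  expect_equal(ix$s_fraction, 0.75)
  expect_equal(ix$fork_engagement, 10 / (50 * 3))

  rec2 <- fake_record(list(bitmask("11000"), bitmask("11110")),
                      engaged = c(5L, 5L), nfork = 50L)
  expect_equal(indices(rec2)$fork_engagement, 0.1)

  recg <- fake_record(list(), n_g_cells = 4L, n_bins = 5L)
  ixg <- indices(recg)
  expect_equal(ixg$s_fraction, 0)
  expect_equal(ixg$fork_engagement, 0)
})

test_that("pearson_rmsd matches closed forms and handles missingness", {
  expect_equal(pearson_rmsd(c(1, 2, 7), c(1, 2, 7)),
               c(pearson = 1, rmsd = 0))
  v <- c(1, 5, 2, 8)
  expect_equal(unname(pearson_rmsd(v, -v)["pearson"]), -1)
  got <- pearson_rmsd(c(1, 2, 3), c(1, 2, 4))
  expect_equal(unname(got["pearson"]), 0.9819805, tolerance = 1e-6)
  expect_equal(unname(got["rmsd"]), sqrt(1 / 3))
  # pairwise deletion of missing values
  expect_equal(unname(pearson_rmsd(c(1, 2, 3, NA, 5),
                                   c(1, 2, 4, 9, NA))["rmsd"]),
               sqrt(1 / 3))
  expect_error(pearson_rmsd(c(1, 2), c(1, 2)),
               class = "replisim_validation_error")
  expect_error(pearson_rmsd(c(1, NA, 3, NA), c(1, 2, NA, 4)),
               class = "replisim_validation_error")
  expect_error(pearson_rmsd(c(2, 2, 2), c(1, 2, 3)),
               class = "replisim_validation_error")
})

test_that("instrument writers produce bedgraph and headered TSV", {
  rec <- fake_record(list(rep(TRUE, 4)), timing_sum = c(8, 6, 4, 10),
                     timing_count = rep(2L, 4), n_cycles = 2)
  tp <- timing_profile(rec)
  f <- tempfile(fileext = ".bedgraph")
  write_timing_bedgraph(tp, f)
  bg <- read.table(f, sep = "\t")
  expect_equal(dim(bg), c(4L, 4L))
  expect_equal(bg$V4, c(4, 3, 2, 5))
  expect_equal(bg$V2, c(0, 500, 1000, 1500))

  fs <- flow_sort(rec, c(0, 0.5, 1))
  f2 <- tempfile(fileext = ".tsv")
  write_instrument_tsv(fs, f2)
  tab <- read.delim(f2)
  expect_named(tab, c("bin", "gate", "frac_lo", "frac_hi", "count", "s50"))
  expect_equal(nrow(tab), 8)  # 2 gates x 4 bins
})
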