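test_that("compute_spta equals the per-spike segment-and-average oracle", {
  set.seed(41)
  for (case in 1:6) {
    n <- 6000
    sig <- matrix(abs(rnorm(2 * n, 1, 0.3)), 2)
    rec <- emg_recording(sig, fs = 1000, muscles = c("TA", "VL"))
    tt <- sort(runif(60, 0.1, 5.9))
    tt <- tt[c(TRUE, diff(tt) > 0.002)]
    prof <- compute_spta(spike_table("u", tt), rec, sf_config())
    for (m in 1:2) {
      orc <- oracle_spta_trace(sig[m, ], 1000, 0, tt)
      expect_lt(max(abs(prof$trace[[which(prof$muscle == rec$muscles[m])]] - orc$trace)),
                1e-12)
      expect_identical(prof$n_spikes[m], as.integer(orc$n))
    }
  }
})

test_that("SpTA windows have 81 samples and constant EMG gives zero increment", {
  rec <- make_flat_rec(values = rep(0.7, 2), n = 5000)
  tt <- seq(0.5, 4.4, by = 0.1)
  prof <- compute_spta(spike_table("u", tt), rec, sf_config())
  expect_identical(length(prof$trace[[1]]), 81L)
  expect_equal(prof$trace[[1]], rep(0.7, 81), tolerance = 1e-12)
  inc <- compute_increment(prof$trace[[1]], prof$baseline_mean[1],
                           prof$baseline_sd[1], sf_config())
  expect_identical(inc$increment_pct, 0)
  expect_false(inc$significant)
  expect_error(compute_spta(spike_table("u", c(0.5, 0.6)), rec, sf_config()),
               "insufficient triggers")
})

test_that("the increment rule matches an independent region-growing oracle", {
  cfg <- sf_config()
  times_ms <- -30:50
  trace <- rep(1, 81)
  trace[times_ms >= -30 & times_ms <= -10][20:21] <- c(0.8, 1.2)  # sd 0.0632
  trace[times_ms %in% 7:9] <- c(1.5, 2.0, 1.5)
  bl <- trace[times_ms >= -30 & times_ms <= -10]
  inc <- compute_increment(trace, mean(bl), sd(bl), cfg)
  expect_equal(inc$increment_pct, 100 * (mean(c(1.5, 2, 1.5)) - 1) / 1,
               tolerance = 1e-9)  # 66.667%
  expect_identical(inc$peak_latency_ms, 8)
  expect_identical(inc$region_ms, c(7, 9))
  orc <- oracle_increment(trace, times_ms, cfg$test_window_ms,
                          cfg$baseline_window_ms, cfg$baseline_sd_mult)
  expect_equal(inc$increment_pct, orc$increment, tolerance = 1e-12)

  # random traces: implementation vs oracle
  set.seed(17)
  for (i in 1:25) {
    tr <- abs(rnorm(81, 1, 0.2)) + 0.05
    bl2 <- tr[times_ms >= -30 & times_ms <= -10]
    got <- compute_increment(tr, mean(bl2), sd(bl2), cfg)
    ref <- oracle_increment(tr, times_ms, cfg$test_window_ms,
                            cfg$baseline_window_ms, cfg$baseline_sd_mult)
    expect_equal(got$increment_pct, ref$increment, tolerance = 1e-12)
    expect_identical(got$significant, ref$significant)
  }

  # percentage increments are invariant to rescaling the channel
  inc2 <- compute_increment(3.7 * trace, 3.7 * mean(bl), 3.7 * sd(bl), cfg)
  expect_equal(inc2$increment_pct, inc$increment_pct, tolerance = 1e-9)
  expect_error(compute_increment(trace, 0, 0.1, cfg), "positive")
})

test_that("onset and PWHM follow the half-maximum geometry", {
  cfg <- sf_config()
  times_ms <- -30:50
  tri <- pmax(0, 2 - abs(times_ms - 8) / 3)  # peak 8, half-max at 5 and 11
  ft <- compute_features(tri, baseline_mean = 0, baseline_sd = 0, cfg)
  expect_equal(ft$pwhm_ms, 6, tolerance = 1e-9)
  expect_identical(ft$onset_latency_ms, 3)  # first strictly positive sample

  # a narrow bump entirely after 4 ms has onset above the pure threshold
  bump <- numeric(81)
  bump[times_ms %in% 6:10] <- c(0.3, 0.8, 1, 0.8, 0.3)
  ft2 <- compute_features(bump, baseline_mean = 0, baseline_sd = 0, cfg)
  expect_gt(ft2$onset_latency_ms, 3.5)
  expect_lt(ft2$pwhm_ms, 7)

  flat <- rep(1, 81)
  ftn <- compute_features(flat, 1, 0.2, cfg)
  expect_true(is.na(ftn$onset_latency_ms) && is.na(ftn$pwhm_ms))
})

test_that("pure/synchrony classification partitions the feature plane", {
  expect_identical(classify_effect(6.0, 5.0), "pure")
  expect_identical(classify_effect(-0.4, 19.6), "synchrony")
  expect_identical(classify_effect(3.5, 7.0), "synchrony")  # strict boundary
  expect_identical(classify_effect(3.6, 6.9), "pure")
  # monotone in each feature
  onsets <- seq(-5, 20, by = 0.5)
  cls <- classify_effect(onsets, rep(5, length(onsets)))
  expect_true(all(diff(cls == "pure") >= 0))  # pure only after the threshold
  pwhms <- seq(0.5, 20, by = 0.5)
  cls2 <- classify_effect(rep(6, length(pwhms)), pwhms)
  expect_true(all(diff(cls2 == "pure") <= 0))
})

test_that("planted kernels are recovered at the right latency", {
  cfg <- sim_config(n_loci = 5, n_units = 1, conditions = "SST")
  dat <- generate_dataset(cfg, seed = 23)
  rec <- preprocess_emg(dat$emg, sf_config())$rec
  prof <- spta_profiles(dat$spikes, rec, dat$trials, sf_config())
  u <- dat$ground_truth$units[[1]]
  dominant <- dat$emg$muscles[which.max(u$fields$SST)]
  row <- prof[prof$muscle == dominant, ]
  expect_gte(row$n_spikes, 100)
  peak_true <- u$kernel_onset_ms + u$kernel_pwhm_ms
  expect_lte(abs(row$peak_latency_ms - peak_true), 1)
  expect_true(row$significant)
})

test_that("muscle fields assemble, normalize and flag degenerate cases", {
  prof <- tibble::tibble(
    unit_id = "u1", condition = "SST",
    muscle = DEFAULT_MUSCLES,
    increment_pct = c(10, 0, 5, 0, -3, 0),
    significant = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  f <- build_muscle_field(prof)
  expect_equal(f$value, c(10, 0, 5, 0, 0, 0))  # suppression clamped
  expect_equal(f$value_norm, c(10, 0, 5, 0, 0, 0) / sqrt(125), tolerance = 1e-12)
  expect_equal(f$value_norm[1], 0.8944272, tolerance = 1e-6)
  expect_false(any(f$all_zero))

  prof$increment_pct <- 0
  fz <- build_muscle_field(prof)
  expect_true(all(fz$all_zero))
  expect_error(field_matrix(fz, "SST"), "no usable fields")
})

test_that("trigger-shuffle significance finds planted effects", {
  cfg <- sim_config(n_loci = 4, n_units = 1, conditions = "SST")
  dat <- generate_dataset(cfg, seed = 29)
  rec <- preprocess_emg(dat$emg, sf_config())$rec
  u <- dat$ground_truth$units[[1]]
  dominant <- dat$emg$muscles[which.max(u$fields$SST)]
  tt <- dat$spikes$time_s
  res <- spta_significance(tt, rec, dominant, n_shuffles = 99, seed = 5)
  expect_true(res$significant)
  expect_identical(length(res$surrogate), 99L)
  expect_error(spta_significance(tt, rec, dominant, n_shuffles = 0),
               "positive")
})
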