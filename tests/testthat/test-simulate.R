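force_form <- function(form) {
  p <- c(merging = 0, unmatched = 0, preserved = 0)
  p[form] <- 1
  list(SSAT = p, CoST = p)
}

test_that("planted ground truth satisfies its own constraints", {
  cfg <- sim_config(n_units = 8)
  gt <- make_ground_truth(cfg, seed = 3)
  W <- gt$W_true
  expect_true(all(W >= 0))
  expect_equal(unname(colSums(W^2)), rep(1, ncol(W)), tolerance = 1e-12)
  # every muscle representable: weight > 0.25 in at least one synergy
  expect_true(all(apply(W, 1, max) > 0.25))
  for (u in gt$units) {
    expect_identical(u$fields$SST, as.numeric(W[, u$preferred_synergy]))
  }
})

test_that("preserved, merging and unmatched fields are planted as defined", {
  cfg_p <- sim_config(n_units = 4, mod_probs = force_form("preserved"))
  gt_p <- make_ground_truth(cfg_p, seed = 5)
  for (u in gt_p$units) {
    expect_gte(scalar_product(u$fields$SST, u$fields$SSAT), 0.8)
    expect_identical(u$modification$SSAT$form, "preserved")
  }

  cfg_m <- sim_config(n_units = 6, mod_probs = force_form("merging"))
  gt_m <- make_ground_truth(cfg_m, seed = 7)
  for (u in gt_m$units) {
    co <- u$modification$SSAT$coefficients
    expect_identical(sum(co > 0), 2L)
    expect_true(all(co[co > 0] >= 0.3))
    expect_gt(co[u$preferred_synergy], 0)
    # the NNLS oracle on the noiseless construction recovers both mixers
    fit <- nnls_reconstruct(u$fields$SSAT, gt_m$W_true)
    expect_identical(which(fit$coefficients > 0.2), which(co > 0))
    expect_gt(fit$reconstruction_sp, 0.999)
  }

  cfg_u <- sim_config(n_units = 6, mod_probs = force_form("unmatched"))
  gt_u <- make_ground_truth(cfg_u, seed = 9)
  for (u in gt_u$units) {
    fit <- nnls_reconstruct(u$fields$SSAT, gt_u$W_true)
    expect_lt(fit$reconstruction_sp, 0.6)
  }
})

test_that("a single planted synergy forces every unit to be preserved", {
  gt <- make_ground_truth(sim_config(n_synergies = 1, n_units = 4), seed = 2)
  for (u in gt$units) {
    expect_identical(u$modification$SSAT$form, "preserved")
    expect_identical(u$modification$CoST$form, "preserved")
  }
})

test_that("spike simulation follows the planted rate model", {
  # homogeneous case: stim rate equals base rate
  cfg <- sim_config(n_loci = 4, n_units = 1, conditions = "SST",
                    base_rate = 30, stim_rate = 30)
  gt <- make_ground_truth(cfg, seed = 1)
  trials <- make_trials(cfg, seed = 1)
  sp <- simulate_spikes(gt, trials, cfg, seed = 1)
  dur <- max(trials$stim_off_s) + cfg$lead_in_s
  in_stim <- purrr::map_lgl(sp$time_s, function(t)
    any(t >= trials$stim_on_s & t < trials$stim_off_s))
  stim_span <- sum(trials$stim_off_s - trials$stim_on_s)
  r_in <- sum(in_stim) / stim_span
  r_out <- sum(!in_stim) / (dur - stim_span)
  se <- sqrt(30 / stim_span) + sqrt(30 / (dur - stim_span))
  expect_lt(abs(r_in - r_out), 3 * se)

  # Poisson mean: 100 Hz for 200 ms over many trials, no baseline firing
  cfg2 <- sim_config(n_loci = 100, n_units = 1, trials_per_locus = 5,
                     conditions = "SST", base_rate = 0, stim_rate = 100,
                     rate_width_loci = 1e6)  # flat tuning: g ~ 1 everywhere
  gt2 <- make_ground_truth(cfg2, seed = 4)
  gt2$units[[1]]$rate_center <- 50  # centre the (flat) tuning
  trials2 <- make_trials(cfg2, seed = 4)
  sp2 <- simulate_spikes(gt2, trials2, cfg2, seed = 4)
  per_trial <- mean(purrr::map_int(seq_len(nrow(trials2)), function(i)
    sum(sp2$time_s >= trials2$stim_on_s[i] & sp2$time_s < trials2$stim_off_s[i])))
  # 20 expected spikes/trial minus the ~1 ms refractory thinning (~9%)
  expect_gt(per_trial, 20 * 0.88 - 3 * sqrt(20 / 500))
  expect_lt(per_trial, 20 + 3 * sqrt(20 / 500))
  expect_true(all(diff(sp2$time_s) >= 0.001 - 1e-12))

  # per-locus rate curve follows the unimodal tuning
  cfg3 <- sim_config(n_loci = 15, n_units = 1, conditions = "SST")
  gt3 <- make_ground_truth(cfg3, seed = 6)
  trials3 <- make_trials(cfg3, seed = 6)
  sp3 <- simulate_spikes(gt3, trials3, cfg3, seed = 6)
  rates <- firing_rate_by_locus(sp3, trials3, pad_s = 0)
  u <- gt3$units[[1]]
  g <- exp(-((seq_len(15) - u$rate_center)^2) / (2 * u$rate_width^2))
  expect_gt(cor(rates$rate_hz, g), 0.9)
})

test_that("EMG generation is non-negative with recoverable planted structure", {
  cfg <- sim_config(n_loci = 4, n_units = 1, conditions = "SST")
  dat <- generate_dataset(cfg, seed = 8)
  expect_true(all(dat$emg$signal >= 0))

  # kernel amplitude zero leaves no spike-locked increment
  cfg0 <- sim_config(n_loci = 4, n_units = 1, conditions = "SST", kernel_amp = 0)
  dat0 <- generate_dataset(cfg0, seed = 8)
  rec0 <- preprocess_emg(dat0$emg, sf_config())$rec
  prof0 <- spta_profiles(dat0$spikes, rec0, dat0$trials, sf_config())
  expect_true(all(prof0$increment_pct < 5))
  expect_true(mean(prof0$significant) <= 2 / 6)

  # SpTA increment grows monotonically with kernel amplitude
  dominant <- which.max(dat$ground_truth$units[[1]]$fields$SST)
  incs <- purrr::map_dbl(c(0.15, 0.4, 0.8), function(a) {
    cfga <- sim_config(n_loci = 4, n_units = 1, conditions = "SST",
                       kernel_amp = a)
    data <- generate_dataset(cfga, seed = 8)
    reca <- preprocess_emg(data$emg, sf_config())$rec
    profa <- spta_profiles(data$spikes, reca, data$trials, sf_config())
    profa$increment_pct[dominant]
  })
  expect_true(all(diff(incs) > 0))
})

test_that("a noiseless single-synergy envelope is rank one to NNMF", {
  cfg <- sim_config(n_synergies = 1, n_units = 1, n_loci = 3,
                    conditions = "SST", noise_sd = 0, kernel_amp = 0,
                    tonic = 0, trial_jitter = 0)
  dat <- generate_dataset(cfg, seed = 12)
  idx <- condition_samples(dat$trials, "SST", 1000, 0, ncol(dat$emg$signal))
  fit <- extract_at_order(dat$emg$signal[, idx], 1, restarts = 5, seed = 1)
  expect_gte(fit$R2, 0.99)
})

test_that("dataset generation is deterministic and follows the protocol", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- sim_config(n_loci = 2, n_units = 1)
  generate_dataset(cfg, seed = 21, dir = dir1)
  generate_dataset(cfg, seed = 21, dir = dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
                     label = f)
  }

  trials <- make_trials(sim_config(), seed = 1)  # study defaults: 13 loci
  expect_identical(sum(trials$condition == "SST"), 65L)  # 5 trials x 13 loci
  ssat <- trials[trials$condition == "SSAT", ]
  expect_true(all(ssat$power_frac >= 1.2 & ssat$power_frac <= 1.5))
  expect_true(all(is.finite(trials$locus2_um[trials$condition == "CoST"])))
  expect_identical(unique(round(trials$stim_off_s - trials$stim_on_s, 9)), 0.2)
})
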