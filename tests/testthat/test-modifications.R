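orthonormal_sources <- function() {
  S <- diag(6)[, 1:3]
  rownames(S) <- DEFAULT_MUSCLES
  S
}

test_that("NNLS reconstruction recovers exact mixtures and rejects others", {
  S <- orthonormal_sources()
  # target equal to a source
  fit <- nnls_reconstruct(S[, 1], S)
  expect_equal(fit$coefficients, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(fit$reconstruction_sp, 1, tolerance = 1e-9)

  # orthonormal sources: closed-form projection oracle
  tgt <- 0.6 * S[, 1] + 0.4 * S[, 2]
  tgt_n <- tgt / sqrt(sum(tgt^2))
  fit2 <- nnls_reconstruct(tgt, S)
  oracle <- as.numeric(t(S) %*% tgt_n)  # projections onto the basis
  expect_equal(fit2$coefficients, oracle, tolerance = 1e-9)
  expect_equal(fit2$coefficients[1] / fit2$coefficients[2], 0.6 / 0.4,
               tolerance = 1e-9)
  expect_true(all(fit2$coefficients[1:2] > 0.2))
  expect_equal(fit2$reconstruction_sp, 1, tolerance = 1e-9)

  # target orthogonal to the span
  fit3 <- nnls_reconstruct(diag(6)[, 5], S)
  expect_equal(fit3$coefficients, c(0, 0, 0), tolerance = 1e-12)
  expect_identical(fit3$reconstruction_sp, 0)
  expect_error(nnls_reconstruct(1:6, matrix(numeric(0), 6, 0)), "empty")
})

test_that("NNLS residuals are monotone in the source set and scale-free", {
  set.seed(71)
  for (i in 1:20) {
    tgt <- runif(6)
    S <- matrix(runif(6 * 3), 6)
    r1 <- sqrt(sum((tgt / sqrt(sum(tgt^2)) -
                      nnls_reconstruct(tgt, S)$reconstruction)^2))
    S4 <- cbind(S, runif(6))
    r2 <- sqrt(sum((tgt / sqrt(sum(tgt^2)) -
                      nnls_reconstruct(tgt, S4)$reconstruction)^2))
    expect_lte(r2, r1 + 1e-10)  # adding a source never hurts
    # positive rescaling of target or sources changes nothing
    a <- nnls_reconstruct(tgt, S)
    b <- nnls_reconstruct(5 * tgt, sweep(S, 2, c(2, 0.5, 3), "*"))
    expect_equal(a$reconstruction_sp, b$reconstruction_sp, tolerance = 1e-9)
  }
})

test_that("the merging / preserved / unmatched decision sequence is exact", {
  S <- orthonormal_sources()
  cfg <- sf_config()
  # identical preferred synergies: one contributor only, so preserved
  r1 <- classify_modification(S[, 1], S[, 1], S, 1, cfg)
  expect_identical(r1$form, "preserved")
  expect_identical(r1$n_contributing, 1L)
  expect_equal(r1$pairwise_sp, 1, tolerance = 1e-12)

  # a genuine two-synergy mixture including the source-preferred one
  tgt <- 0.55 * S[, 1] + 0.45 * S[, 2]
  r2 <- classify_modification(S[, 1], tgt / sqrt(sum(tgt^2)), S, 1, cfg)
  expect_identical(r2$form, "merging")
  expect_identical(r2$n_contributing, 2L)

  # same mixture, but the unit's preferred source is not a contributor
  r3 <- classify_modification(S[, 3], tgt / sqrt(sum(tgt^2)), S, 3, cfg)
  expect_false(r3$form == "merging")

  # orthogonal to the span of the sources
  r4 <- classify_modification(S[, 1], diag(6)[, 5], S, 1, cfg)
  expect_identical(r4$form, "unmatched")

  # scale invariance of the whole decision
  r5 <- classify_modification(3 * S[, 1], 7 * tgt, 2 * S, 1, cfg)
  expect_identical(r5$form, r2$form)
})

test_that("noiseless planted constructions are labelled perfectly", {
  cfg <- sim_config(n_units = 40)
  gt <- make_ground_truth(cfg, seed = 73)
  acfg <- sf_config()
  for (u in gt$units) {
    for (cond in c("SSAT", "CoST")) {
      got <- classify_modification(gt$W_true[, u$preferred_synergy],
                                   u$fields[[cond]], gt$W_true,
                                   u$preferred_synergy, acfg)
      expect_identical(got$form, u$modification[[cond]]$form,
                       label = paste(u$unit_id, cond))
    }
  }
})

test_that("prevalence tables partition units by form within condition pairs", {
  res <- tibble::tibble(
    unit_id = sprintf("u%d", 1:5),
    condition_pair = c(rep("SST->SSAT", 3), rep("SST->CoST", 2)),
    form = c("preserved", "preserved", "merging", "unmatched", "unmatched"))
  tab <- prevalence_table(res)
  expect_identical(nrow(tab), 6L)  # 2 pairs x 3 forms, zeros included
  s1 <- tab[tab$condition_pair == "SST->SSAT", ]
  expect_equal(sum(s1$fraction), 1, tolerance = 1e-12)
  expect_equal(s1$fraction[s1$form == "preserved"], 2 / 3, tolerance = 1e-12)
  s2 <- tab[tab$condition_pair == "SST->CoST", ]
  expect_equal(s2$fraction[s2$form == "unmatched"], 1, tolerance = 1e-12)
  expect_equal(s2$fraction[s2$form == "merging"], 0, tolerance = 1e-12)

  solo <- prevalence_table(res[3, ])
  expect_equal(solo$fraction[solo$form == "merging"], 1, tolerance = 1e-12)
  expect_error(prevalence_table(res[0, ]), "no modification")
})
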