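test_that("the scalar product is a normalized, bounded, symmetric similarity", {
  expect_equal(scalar_product(c(2, 1, 0), c(2, 1, 0)), 1, tolerance = 1e-12)
  expect_identical(scalar_product(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(scalar_product(c(1, 1, 0), c(1, 0, 1)), 0.5, tolerance = 1e-12)
  expect_error(scalar_product(c(0, 0), c(1, 1)), "zero vector")
  set.seed(61)
  for (i in 1:20) {
    u <- runif(6); v <- runif(6)
    s <- scalar_product(u, v)
    expect_gte(s, 0); expect_lte(s, 1 + 1e-12)
    expect_equal(s, scalar_product(v, u), tolerance = 1e-12)
    expect_equal(s, scalar_product(3.3 * u, 0.7 * v), tolerance = 1e-12)
  }
})

test_that("preferred pairs pick the argmax synergy per unit", {
  set.seed(62)
  W <- matrix(runif(18), 6, dimnames = list(DEFAULT_MUSCLES, NULL))
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  fit <- structure(list(W = W, N = 3L, muscles = DEFAULT_MUSCLES,
                        condition = "SST"), class = "synergy_fit")
  fields <- tibble::tibble(
    unit_id = rep("u1", 6), condition = "SST", muscle = DEFAULT_MUSCLES,
    value = W[, 2], value_norm = W[, 2], all_zero = FALSE)
  prefs <- preferred_pairs(fields, fit)
  best <- prefs[prefs$preferred, ]
  expect_identical(best$synergy, 2L)
  expect_equal(best$sp, 1, tolerance = 1e-12)
  expect_identical(nrow(prefs), 3L)

  fit1 <- structure(list(W = W[, 1, drop = FALSE], N = 1L,
                         muscles = DEFAULT_MUSCLES, condition = "SST"),
                    class = "synergy_fit")
  prefs1 <- preferred_pairs(fields, fit1)
  expect_true(all(prefs1$preferred))  # single synergy preferred by default

  fields0 <- dplyr::mutate(fields, value = 0, value_norm = 0, all_zero = TRUE)
  expect_warning(expect_error(preferred_pairs(fields0, fit), "no usable"),
                 "all-zero")
})

test_that("across-condition matching maximizes the total scalar product", {
  set.seed(63)
  A <- matrix(runif(24), 6)
  perm <- c(3, 1, 4, 2)
  B <- A[, perm]
  m <- match_across_conditions(A, B)
  expect_identical(m$index_b[order(m$index_a)], order(perm))
  expect_equal(attr(m, "mean_sp"), 1, tolerance = 1e-12)

  # orthogonal sets have zero total similarity
  O1 <- diag(6)[, 1:3]; O2 <- diag(6)[, 4:6]
  expect_equal(attr(match_across_conditions(O1, O2), "mean_sp"), 0,
               tolerance = 1e-12)

  # exhaustive-search oracle, square and rectangular, 200 instances
  for (i in 1:200) {
    na <- sample(2:4, 1); nb <- (na:4)[sample.int(length(na:4), 1)]
    A <- matrix(runif(6 * na), 6); B <- matrix(runif(6 * nb), 6)
    m <- match_across_conditions(A, B)
    S <- t(sweep(A, 2, sqrt(colSums(A^2)), "/")) %*%
      sweep(B, 2, sqrt(colSums(B^2)), "/")
    orc <- oracle_best_assignment(S)
    expect_equal(sum(m$sp), orc$total, tolerance = 1e-10)
    # optimal beats greedy row-wise assignment
    greedy <- 0; taken <- integer(0)
    for (r in seq_len(nrow(S))) {
      j <- which.max(replace(S[r, ], taken, -Inf))
      greedy <- greedy + S[r, j]; taken <- c(taken, j)
    }
    expect_gte(sum(m$sp) + 1e-10, greedy)
  }
})

test_that("consistency rate counts matched pairs above threshold", {
  m <- tibble::tibble(index_a = 1:4, index_b = 1:4,
                      sp = c(0.9, 0.5, 0.8, 0.7))
  expect_identical(consistency_rate(m, 0.78), 0.5)
  expect_identical(consistency_rate(m, 0), 1)
  expect_identical(consistency_rate(dplyr::mutate(m, sp = 1), 0.78), 1)
  expect_true(is.na(consistency_rate(m[0, ], 0.78)))
})

test_that("silhouette-guided k-means finds planted synergy clusters", {
  set.seed(64)
  protos <- abs(cbind(c(5, 4, 0.2, 0.1, 0.2, 0.1),
                      c(0.1, 0.2, 5, 4, 0.1, 0.2),
                      c(0.2, 0.1, 0.1, 0.2, 5, 4)))
  W <- do.call(cbind, purrr::map(1:24, function(i)
    abs(protos[, (i - 1) %% 3 + 1] + rnorm(6, 0, 0.15))))
  res <- cluster_synergies(W, seed = 3)
  expect_identical(res$k_selected, 3L)
  expect_gt(res$silhouette_selected, 0.7)
  truth <- rep(1:3, 8)
  purity <- sum(apply(table(res$labels, truth), 1, max)) / 24
  expect_identical(purity, 1)

  # duplicated vectors in two groups: perfect separation at k = 2
  Wd <- cbind(matrix(protos[, 1], 6, 4), matrix(protos[, 2], 6, 4))
  resd <- cluster_synergies(Wd, seed = 3)
  expect_identical(resd$k_selected, 2L)
  expect_gt(resd$silhouette_selected, 1 - 1e-9)

  # k range is capped at one less than the number of synergies
  W4 <- W[, 1:4]
  res4 <- cluster_synergies(W4, seed = 3)
  expect_identical(res4$silhouette_by_k$k, 2:3)
  expect_error(cluster_synergies(W[, 1:2]), "at least 3")
})
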