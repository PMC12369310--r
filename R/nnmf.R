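#' Reconstruction R-squared for a synergy factorization
#'
#' Fraction of EMG variation explained by the non-negative factorization
#' `D ~ W %*% t(C)`:
#' \deqn{R^2 = 1 - SSE/SST,\quad SST = \sum_{ij} (D_{ij} - \bar D_i)^2,\quad
#'       SSE = \sum_{ij} (D_{ij} - (W C^T)_{ij})^2}
#' where `\bar D_i` is the mean of muscle `i` over time.
#'
#' @param D Data matrix `[n_muscles x n_samples]`.
#' @param W Synergy matrix `[n_muscles x N]`.
#' @param C Activation-coefficient matrix `[n_samples x N]`.
#' @return R-squared (can be negative for a bad reconstruction).
#' @examples
#' D <- matrix(runif(60), 6)
#' r_squared(D, D[, 1, drop = FALSE] * 0 + 1, t(D) %*% rep(0, 6) + 1) < 1
#' @export
r_squared <- function(D, W, C) {
  D <- as.matrix(D); W <- as.matrix(W); C <- as.matrix(C)
  stopifnot(nrow(W) == nrow(D), nrow(C) == ncol(D), ncol(W) == ncol(C))
  sst <- sum((D - rowMeans(D))^2)
  if (sst == 0) stop("constant data: total sum of squares is zero")
  sse <- sum((D - W %*% t(C))^2)
  1 - sse / sst
}

# Normalize synergy columns to unit L2 norm, counter-scaling coefficients so
# the reconstruction W %*% t(C) is unchanged.
normalize_factors <- function(W, C) {
  nrm <- sqrt(colSums(W^2))
  nrm[nrm == 0] <- 1
  list(W = sweep(W, 2, nrm, "/"), C = sweep(C, 2, nrm, "*"))
}

#' Extract muscle synergies at a fixed model order
#'
#' Non-negative matrix factorization of the EMG envelope matrix by
#' multiplicative updates minimizing squared error, restarted from multiple
#' random initializations to avoid local minima. Each restart initializes
#' both factors from a uniform distribution between 0 and the maximum EMG
#' amplitude; the restart with the lowest final SSE is returned. Synergy
#' columns are reported L2-normalized, with activation coefficients scaled
#' to compensate.
#'
#' @param D Non-negative matrix `[n_muscles x n_samples]` (rownames used as
#'   muscle labels if present).
#' @param N Number of synergies, `1 <= N <= n_muscles`.
#' @param restarts Number of random restarts (protocol default 100).
#' @param seed Integer seed for the restart initializations.
#' @param max_iter,tol Convergence controls: stop when the relative SSE
#'   change per iteration falls below `tol` or after `max_iter` iterations.
#' @param condition Optional condition label stored on the fit.
#' @return An object of class `"synergy_fit"`: list with `W`
#'   `[n_muscles x N]`, `C` `[n_samples x N]`, `R2`, `N`, `restart_sse`,
#'   `iterations`, `muscles`, `condition`.
#' @seealso [select_model_order()], [tidy.synergy_fit()]
#' @export
extract_at_order <- function(D, N, restarts = 100, seed = 1L,
                             max_iter = 1000, tol = 1e-6, condition = NA_character_) {
  D <- as.matrix(D)
  if (any(D < 0)) stop("D must be non-negative for NNMF")
  m <- nrow(D); n <- ncol(D)
  stopifnot(N >= 1, N <= m, restarts >= 1)
  amax <- max(D)
  if (amax == 0) stop("all-zero data matrix")

  best <- NULL
  losses <- numeric(restarts)
  with_stage_seed(seed, paste0("nnmf_order_", N), {
    for (r in seq_len(restarts)) {
      W0 <- matrix(runif(m * N, 0, amax), m, N)
      H0 <- matrix(runif(N * n, 0, amax), N, n)
      fit <- nnmf_mu_cpp(D, W0, H0, as.integer(max_iter), tol)
      losses[r] <- fit$sse
      if (is.null(best) || fit$sse < best$sse) best <- fit
    }
  })

  fac <- normalize_factors(best$W, t(best$H))
  muscles <- rownames(D)
  if (is.null(muscles)) muscles <- paste0("m", seq_len(m))
  structure(
    list(W = `dimnames<-`(fac$W, list(muscles, paste0("W", seq_len(N)))),
         C = `colnames<-`(fac$C, paste0("C", seq_len(N))),
         R2 = r_squared(D, fac$W, fac$C),
         N = as.integer(N),
         restart_sse = losses,
         iterations = best$iterations,
         muscles = muscles,
         condition = condition),
    class = "synergy_fit"
  )
}

#' Select the number of synergies by the R-squared rule
#'
#' Evaluates model orders N = 1 up to the number of muscles and returns the
#' fit at the smallest N whose best-of-restarts reconstruction R-squared
#' reaches `r2_threshold` (protocol default 0.80). The full R-squared vs N
#' curve up to the selected order is attached as attribute `"order_scan"`.
#'
#' @inheritParams extract_at_order
#' @param r2_threshold Minimum acceptable reconstruction R-squared.
#' @return A `"synergy_fit"` at the selected order.
#' @export
select_model_order <- function(D, r2_threshold = 0.80, restarts = 100,
                               seed = 1L, max_iter = 1000, tol = 1e-6,
                               condition = NA_character_) {
  D <- as.matrix(D)
  m <- nrow(D)
  scan <- tibble::tibble(N = integer(), R2 = numeric())
  fit <- NULL
  for (N in seq_len(m)) {
    fit <- extract_at_order(D, N, restarts = restarts, seed = seed,
                            max_iter = max_iter, tol = tol, condition = condition)
    scan <- dplyr::bind_rows(scan, tibble::tibble(N = fit$N, R2 = fit$R2))
    if (fit$R2 >= r2_threshold) break
  }
  attr(fit, "order_scan") <- scan
  fit
}

#' @export
print.synergy_fit <- function(x, ...) {
  cat(sprintf("<synergy_fit> N = %d synergies, %d muscles, R2 = %.4f%s\n",
              x$N, length(x$muscles), x$R2,
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]")))
  print(round(x$W, 3))
  invisible(x)
}

#' Tidy a synergy fit into a long tibble of muscle weights
#'
#' @param x A `"synergy_fit"`.
#' @param ... Unused.
#' @return Tibble with columns `synergy`, `muscle`, `weight`.
#' @method tidy synergy_fit
#' @export
tidy.synergy_fit <- function(x, ...) {
  tibble::tibble(
    synergy = rep(seq_len(x$N), each = length(x$muscles)),
    muscle = rep(x$muscles, x$N),
    weight = as.vector(x$W)
  )
}

#' One-row summary of a synergy fit
#'
#' @param x A `"synergy_fit"`.
#' @param ... Unused.
#' @return Tibble with `N`, `R2`, `n_restarts`, `sse_best`, `sse_spread`
#'   (max/min final SSE across restarts) and `condition`.
#' @method glance synergy_fit
#' @export
glance.synergy_fit <- function(x, ...) {
  tibble::tibble(
    N = x$N, R2 = x$R2,
    n_restarts = length(x$restart_sse),
    sse_best = min(x$restart_sse),
    sse_spread = max(x$restart_sse) / min(x$restart_sse),
    condition = x$condition
  )
}

#' Per-locus activation-coefficient amplitudes
#'
#' For each synergy, the trial- and time-averaged activation coefficient at
#' each stimulation locus: within every trial the coefficient is averaged
#' over the response window (stimulus onset to offset plus `pad_s`), then
#' averaged across the trials of each locus.
#'
#' @param fit A `"synergy_fit"` whose `C` spans the recording that `trials`
#'   indexes, or a plain activation matrix `[n_samples x N]`.
#' @param trials Trial table restricted to the condition of interest.
#' @param fs Sampling rate of the coefficient time axis (Hz).
#' @param t0 Time of the first coefficient sample (s).
#' @param pad_s Post-offset padding of the response window in seconds.
#' @param sample_index Original sample indices of the rows of `fit$C`, for
#'   fits extracted from a concatenation of response windows; defaults to
#'   `1:nrow(C)` (fit on the full recording).
#' @return Tibble with columns `synergy`, `locus_um`, `amplitude`.
#' @export
coefficient_amplitudes <- function(fit, trials, fs = 1000, t0 = 0, pad_s = 0.1,
                                   sample_index = NULL) {
  if (!inherits(fit, "synergy_fit")) {
    C <- as.matrix(fit)
    fit <- structure(list(C = C, N = ncol(C)), class = "synergy_fit")
  }
  validate_trials(trials)
  if (is.null(sample_index)) sample_index <- seq_len(nrow(fit$C))
  stopifnot(length(sample_index) == nrow(fit$C))
  per_trial <- purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    i0 <- as.integer(floor((trials$stim_on_s[i] - t0) * fs)) + 1L
    i1 <- as.integer(floor((trials$stim_off_s[i] + pad_s - t0) * fs))
    rows <- which(sample_index >= i0 & sample_index <= i1)
    if (!length(rows)) return(NULL)
    tibble::tibble(
      locus_um = trials$locus_um[i],
      synergy = seq_len(fit$N),
      value = colMeans(fit$C[rows, , drop = FALSE])
    )
  })
  per_trial |>
    dplyr::group_by(.data$synergy, .data$locus_um) |>
    dplyr::summarise(amplitude = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$synergy, .data$locus_um)
}
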