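# Independent brute-force oracles. These deliberately re-derive each
# quantity with the most literal implementation possible (explicit loops,
# closed forms) and are kept free of the package's own code paths.

# Spike-triggered average by an explicit per-spike loop over one channel.
oracle_spta_trace <- function(sig, fs, t0, spike_times, win_ms = c(-30, 50)) {
  offs <- seq(win_ms[1], win_ms[2])
  acc <- numeric(length(offs))
  used <- 0
  for (t in spike_times) {
    i0 <- floor((t - t0) * fs) + 1
    idx <- i0 + offs
    if (idx[1] < 1 || idx[length(idx)] > length(sig)) next
    acc <- acc + sig[idx]
    used <- used + 1
  }
  list(trace = acc / used, n = used)
}

# R-squared by an explicit double loop.
oracle_r2 <- function(D, W, C) {
  R <- W %*% t(C)
  m <- nrow(D); n <- ncol(D)
  sst <- 0; sse <- 0
  for (i in seq_len(m)) {
    mi <- mean(D[i, ])
    for (j in seq_len(n)) {
      sst <- sst + (D[i, j] - mi)^2
      sse <- sse + (D[i, j] - R[i, j])^2
    }
  }
  1 - sse / sst
}

# Pearson correlation from first principles.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# All permutations of 1..n (recursive enumeration).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Best one-to-one assignment of rows to columns of a similarity matrix by
# exhaustive search; handles nrow <= ncol by enumerating injections.
oracle_best_assignment <- function(S) {
  stopifnot(nrow(S) <= ncol(S))
  best <- -Inf; best_cols <- NULL
  cols <- utils::combn(ncol(S), nrow(S))
  for (ci in seq_len(ncol(cols))) {
    sub <- cols[, ci]
    for (p in all_perms(nrow(S))) {
      tot <- sum(S[cbind(seq_len(nrow(S)), sub[unlist(p)])])
      if (tot > best) { best <- tot; best_cols <- sub[unlist(p)] }
    }
  }
  list(total = best, cols = best_cols)
}

# Region-growing increment rule, written as a filter over the full set of
# supra-threshold samples instead of the package's outward walk.
oracle_increment <- function(trace, times_ms, test_win, bl_win, sd_mult) {
  bl <- trace[times_ms >= bl_win[1] & times_ms <= bl_win[2]]
  bmean <- mean(bl); thr <- bmean + sd_mult * stats::sd(bl)
  test_idx <- which(times_ms >= test_win[1] & times_ms <= test_win[2])
  pk <- test_idx[which.max(trace[test_idx])]
  if (trace[pk] <= thr) return(list(increment = 0, significant = FALSE))
  above <- trace > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  k <- which(runs$values & starts <= pk & ends >= pk)
  region <- trace[starts[k]:ends[k]]
  list(increment = 100 * (mean(region) - bmean) / bmean, significant = TRUE,
       onset = times_ms[starts[k]])
}

# Small envelope-domain recording with known content.
make_flat_rec <- function(values = 1:6 / 10, n = 4000, fs = 1000) {
  emg_recording(matrix(rep(values, n), nrow = length(values)), fs = fs,
                muscles = DEFAULT_MUSCLES[seq_along(values)])
}
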