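#' Spike-triggered average of EMG
#'
#' Segments each muscle's preprocessed envelope from 30 ms before to 50 ms
#' after every spike (window endpoints inclusive, 1 ms resolution at the
#' 1 kHz analysis rate) and averages the segments across spikes. Only
#' reliable triggers are used: spikes whose window crosses a recording
#' boundary are dropped and counted, and, when a trial table is supplied,
#' so are spikes whose window is not fully contained in the stationary part
#' of one trial's response (from `trigger_settle_s` after stimulus onset —
#' past the EMG activation transient — to `response_pad_s` after offset).
#' Baseline statistics are taken over the 30-10 ms pre-trigger portion of
#' the averaged trace.
#'
#' @param spikes Spike table ([spike_table()] layout); may contain several
#'   units.
#' @param emg Preprocessed [emg_recording()] at the analysis rate.
#' @param config An [sf_config()] (windows, minimum spike count).
#' @param trials Optional trial table used for the reliable-trigger rule.
#' @return Tibble with one row per unit x muscle: `unit_id`, `muscle`,
#'   `n_spikes`, `n_dropped`, `trace` (list column, one sample per ms of the
#'   window), `baseline_mean`, `baseline_sd`.
#' @export
compute_spta <- function(spikes, emg, config = sf_config(), trials = NULL) {
  validate_spikes(spikes)
  stopifnot(inherits(emg, "emg_recording"))
  win <- config$spta_window_ms
  offs <- as.integer(round(seq(win[1], win[2]) * emg$fs / 1000))
  bl <- config$baseline_window_ms
  times_ms <- as.numeric(seq(win[1], win[2]))
  bl_idx <- which(times_ms >= bl[1] & times_ms <= bl[2])
  n <- ncol(emg$signal)

  purrr::map_dfr(split(spikes$time_s, spikes$unit_id), function(tt) {
    i0 <- as.integer(floor((tt - emg$t0) * emg$fs)) + 1L
    ok <- i0 + offs[1] >= 1L & i0 + offs[length(offs)] <= n
    if (!is.null(trials)) {
      w_lo <- tt + win[1] / 1000
      w_hi <- tt + win[2] / 1000
      in_trial <- purrr::map2_lgl(w_lo, w_hi, function(a, b) {
        any(a >= trials$stim_on_s + config$trigger_settle_s &
              b <= trials$stim_off_s + config$response_pad_s)
      })
      ok <- ok & in_trial
    }
    if (sum(ok) < config$min_spikes) {
      stop("insufficient triggers: ", sum(ok), " usable spikes (need ",
           config$min_spikes, ")")
    }
    idx <- outer(i0[ok], offs, "+")
    purrr::map_dfr(seq_along(emg$muscles), function(j) {
      seg <- matrix(emg$signal[j, ][idx], nrow = sum(ok))
      tr <- colMeans(seg)
      tibble::tibble(
        muscle = emg$muscles[j],
        n_spikes = sum(ok), n_dropped = sum(!ok),
        trace = list(tr),
        baseline_mean = mean(tr[bl_idx]),
        baseline_sd = sd(tr[bl_idx])
      )
    })
  }, .id = "unit_id")
}

# Contiguous supra-threshold region around the test-window peak.
# Returns NULL when the peak itself does not exceed the threshold.
peak_region <- function(trace, times_ms, test_window_ms, baseline_mean,
                        baseline_sd, sd_mult) {
  test_idx <- which(times_ms >= test_window_ms[1] & times_ms <= test_window_ms[2])
  pk <- test_idx[which.max(trace[test_idx])]  # ties break to the earlier latency
  thr <- baseline_mean + sd_mult * baseline_sd
  if (trace[pk] <= thr) return(NULL)
  lo <- pk
  while (lo > 1 && trace[lo - 1] > thr) lo <- lo - 1
  hi <- pk
  while (hi < length(trace) && trace[hi + 1] > thr) hi <- hi + 1
  list(peak = pk, lo = lo, hi = hi, thr = thr)
}

#' Mean percentage increment of post-spike facilitation
#'
#' Finds the SpTA peak in the 3-16 ms post-trigger test window, then extends
#' a contiguous region backward and forward from the peak while the trace
#' stays above `baseline_mean + 2 * baseline_sd`, and reports the mean of
#' that region as a percentage increment over the baseline mean. A peak
#' that does not exceed the threshold yields increment 0 and
#' `significant = FALSE`.
#'
#' @param trace Averaged SpTA trace (one sample per ms of the window).
#' @param baseline_mean,baseline_sd Baseline statistics of the trace.
#' @param config An [sf_config()].
#' @return List with `increment_pct`, `peak_latency_ms`, `significant`,
#'   `region_ms` (onset/offset times of the supra-threshold region, `NA`
#'   when not significant).
#' @export
compute_increment <- function(trace, baseline_mean, baseline_sd,
                              config = sf_config()) {
  if (!is.finite(baseline_mean) || baseline_mean <= 0) {
    stop("baseline mean must be positive (non-negative envelope expected)")
  }
  win <- config$spta_window_ms
  times_ms <- as.numeric(seq(win[1], win[2]))
  stopifnot(length(trace) == length(times_ms))
  reg <- peak_region(trace, times_ms, config$test_window_ms, baseline_mean,
                     baseline_sd, config$baseline_sd_mult)
  if (is.null(reg)) {
    test_idx <- which(times_ms >= config$test_window_ms[1] &
                        times_ms <= config$test_window_ms[2])
    pk <- test_idx[which.max(trace[test_idx])]
    return(list(increment_pct = 0, peak_latency_ms = times_ms[pk],
                significant = FALSE, region_ms = c(NA_real_, NA_real_)))
  }
  list(
    increment_pct = 100 * (mean(trace[reg$lo:reg$hi]) - baseline_mean) / baseline_mean,
    peak_latency_ms = times_ms[reg$peak],
    significant = TRUE,
    region_ms = c(times_ms[reg$lo], times_ms[reg$hi])
  )
}

#' Onset latency and peak width at half maximum of a SpTA effect
#'
#' Onset latency is the time of the earliest sample of the contiguous
#' supra-threshold region around the test-window peak (searched backward
#' from the peak without a lower time bound, so it may be negative). PWHM is
#' the width of the interval where the trace stays at or above
#' `baseline_mean + (peak - baseline_mean) / 2`, with the crossings located
#' by linear interpolation.
#'
#' @inheritParams compute_increment
#' @return List with `onset_latency_ms` and `pwhm_ms`, or both `NA` for a
#'   non-significant profile.
#' @export
compute_features <- function(trace, baseline_mean, baseline_sd,
                             config = sf_config()) {
  win <- config$spta_window_ms
  times_ms <- as.numeric(seq(win[1], win[2]))
  stopifnot(length(trace) == length(times_ms))
  reg <- peak_region(trace, times_ms, config$test_window_ms, baseline_mean,
                     baseline_sd, config$baseline_sd_mult)
  if (is.null(reg)) return(list(onset_latency_ms = NA_real_, pwhm_ms = NA_real_))
  pk <- reg$peak
  half <- baseline_mean + (trace[pk] - baseline_mean) / 2

  left <- times_ms[1]
  for (k in pk:1) {
    if (trace[k] < half) {
      # linear interpolation between samples k and k + 1
      left <- times_ms[k] + (half - trace[k]) / (trace[k + 1] - trace[k])
      break
    }
  }
  right <- times_ms[length(times_ms)]
  for (k in pk:length(trace)) {
    if (trace[k] < half) {
      right <- times_ms[k - 1] + (trace[k - 1] - half) / (trace[k - 1] - trace[k])
      break
    }
  }
  list(onset_latency_ms = times_ms[reg$lo], pwhm_ms = right - left)
}

#' Classify a post-spike effect as pure or synchrony
#'
#' Pure post-spike effects — consistent with a direct, last-order premotor
#' connection — require onset latency strictly greater than 3.5 ms and PWHM
#' strictly less than 7 ms; everything else is a synchrony effect (broad or
#' early SpTA deflections reflecting correlated firing of unrecorded
#' neurons).
#'
#' @param onset_latency_ms,pwhm_ms SpTA features from [compute_features()].
#' @param config An [sf_config()].
#' @return `"pure"` or `"synchrony"` (vectorized).
#' @examples
#' classify_effect(6, 5)     # pure
#' classify_effect(-0.4, 19.6) # synchrony
#' classify_effect(3.5, 7)   # synchrony (boundary is strict)
#' @export
classify_effect <- function(onset_latency_ms, pwhm_ms, config = sf_config()) {
  ifelse(onset_latency_ms > config$pure_onset_ms & pwhm_ms < config$pure_pwhm_ms,
         "pure", "synchrony")
}

#' Full per-condition SpTA feature table
#'
#' Runs [compute_spta()] per condition (using the spikes falling inside that
#' condition's trials, stimulus onset to offset plus the response pad) and
#' annotates every unit x muscle profile with increment, latency, PWHM and
#' effect class.
#'
#' @param spikes Spike table.
#' @param emg Preprocessed [emg_recording()].
#' @param trials Trial table; `NULL` pools all spikes under condition
#'   `"all"`.
#' @param config An [sf_config()].
#' @return Tibble: one row per unit x condition x muscle with columns
#'   `unit_id`, `condition`, `muscle`, `n_spikes`, `trace`, `baseline_mean`,
#'   `baseline_sd`, `increment_pct`, `peak_latency_ms`, `significant`,
#'   `onset_latency_ms`, `pwhm_ms`, `effect_class`.
#' @export
spta_profiles <- function(spikes, emg, trials = NULL, config = sf_config()) {
  conditions <- if (is.null(trials)) "all" else unique(trials$condition)
  purrr::map_dfr(conditions, function(cond) {
    tr <- if (is.null(trials)) NULL else trials[trials$condition == cond, ]
    prof <- compute_spta(spikes, emg, config, trials = tr)
    feats <- purrr::pmap_dfr(
      prof[, c("trace", "baseline_mean", "baseline_sd")],
      function(trace, baseline_mean, baseline_sd) {
        inc <- compute_increment(trace, baseline_mean, baseline_sd, config)
        ft <- compute_features(trace, baseline_mean, baseline_sd, config)
        tibble::tibble(
          increment_pct = inc$increment_pct,
          peak_latency_ms = inc$peak_latency_ms,
          significant = inc$significant,
          onset_latency_ms = ft$onset_latency_ms,
          pwhm_ms = ft$pwhm_ms,
          effect_class = ifelse(inc$significant,
                                classify_effect(ft$onset_latency_ms, ft$pwhm_ms,
                                                config),
                                NA_character_)
        )
      })
    dplyr::bind_cols(tibble::tibble(condition = cond), prof, feats) |>
      dplyr::relocate("unit_id", "condition")
  })
}

#' Per-unit effect class
#'
#' A unit's overall post-spike effect class (pure vs synchrony) is read
#' from its dominant muscle: the significant profile with the largest
#' percentage increment. Units with no significant profile get `NA`.
#'
#' @param profiles Output of [spta_profiles()].
#' @return Tibble with one row per unit x condition: `unit_id`,
#'   `condition`, `effect_class`, `dominant_muscle`,
#'   `onset_latency_ms`, `pwhm_ms`.
#' @export
classify_unit_effects <- function(profiles) {
  profiles |>
    dplyr::filter(.data$significant) |>
    dplyr::group_by(.data$unit_id, .data$condition) |>
    dplyr::slice_max(.data$increment_pct, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("unit_id", "condition", "effect_class",
                  dominant_muscle = "muscle", "onset_latency_ms", "pwhm_ms")
}

#' Surrogate test for a significant post-spike effect
#'
#' Trigger-shuffle test: the unit's spike train is circularly shifted by a
#' uniform random offset within the recording span `n_shuffles` times, the
#' test-window peak elevation (peak minus baseline mean) is recomputed for
#' each surrogate, and the observed peak elevation is called significant
#' when it exceeds the 97.5th percentile of the surrogate distribution
#' (two-sided alpha = 0.05 on the facilitation peak).
#'
#' @param spike_times Spike times of one unit (seconds).
#' @param emg Preprocessed [emg_recording()].
#' @param muscle Muscle label to test.
#' @param n_shuffles Number of circular-shift surrogates (> 0).
#' @param seed Integer seed.
#' @param config An [sf_config()].
#' @return List with `significant` (logical), `observed` (peak elevation)
#'   and `surrogate` (vector of surrogate peak elevations).
#' @export
spta_significance <- function(spike_times, emg, muscle, n_shuffles = 200,
                              seed = 1L, config = sf_config()) {
  if (n_shuffles <= 0) stop("n_shuffles must be positive")
  stopifnot(muscle %in% emg$muscles)
  if (length(spike_times) < config$min_spikes) {
    stop("insufficient triggers: ", length(spike_times), " spikes (need ",
         config$min_spikes, ")")
  }
  dur <- rec_duration(emg)
  sig <- emg$signal[muscle, ]
  n <- length(sig)
  win <- config$spta_window_ms
  tw <- config$test_window_ms
  bl <- config$baseline_window_ms
  # only the test-window and baseline lags of the trace are needed
  test_offs <- as.integer(round(seq(tw[1], tw[2]) * emg$fs / 1000))
  bl_offs <- as.integer(round(seq(bl[1], bl[2]) * emg$fs / 1000))
  off_lo <- as.integer(round(win[1] * emg$fs / 1000))
  off_hi <- as.integer(round(win[2] * emg$fs / 1000))
  peak_elev <- function(tt) {
    i0 <- as.integer(floor((tt - emg$t0) * emg$fs)) + 1L
    i0 <- i0[i0 + off_lo >= 1L & i0 + off_hi <= n]
    test_trace <- colMeans(matrix(sig[outer(i0, test_offs, "+")],
                                  nrow = length(i0)))
    bl_trace <- matrix(sig[outer(i0, bl_offs, "+")], nrow = length(i0))
    max(test_trace) - mean(colMeans(bl_trace))
  }
  obs <- peak_elev(spike_times)
  surr <- with_stage_seed(seed, "spta_significance", {
    purrr::map_dbl(seq_len(n_shuffles), function(i) {
      off <- runif(1, 0, dur)
      peak_elev(emg$t0 + (spike_times - emg$t0 + off) %% dur)
    })
  })
  list(significant = obs > quantile(surr, 0.975, names = FALSE),
       observed = obs, surrogate = surr)
}

#' Assemble muscle fields from SpTA profiles
#'
#' A unit's muscle field is the vector of its mean percentage increments
#' across the recorded muscles, with suppression (negative increments)
#' clamped at zero, plus an L2-normalized copy used for all scalar-product
#' comparisons. Units whose field is all-zero are flagged and excluded from
#' matching.
#'
#' @param profiles Output of [spta_profiles()].
#' @return Tibble: one row per unit x condition x muscle with `value`
#'   (clamped increment), `value_norm` and `all_zero`.
#' @export
build_muscle_field <- function(profiles) {
  profiles |>
    dplyr::group_by(.data$unit_id, .data$condition) |>
    dplyr::mutate(
      value = pmax(.data$increment_pct, 0),
      all_zero = all(.data$value == 0),
      value_norm = if (all(.data$value == 0)) .data$value else
        .data$value / sqrt(sum(.data$value^2))
    ) |>
    dplyr::ungroup() |>
    dplyr::select("unit_id", "condition", "muscle", "value", "value_norm",
                  "all_zero")
}

#' Muscle-field matrix for one condition
#'
#' @param fields Output of [build_muscle_field()].
#' @param condition Condition to extract.
#' @param muscles Muscle order for the rows.
#' @param normalized Use the L2-normalized values?
#' @return Matrix `[muscles x units]`; all-zero fields are dropped.
#' @export
field_matrix <- function(fields, condition, muscles = NULL, normalized = TRUE) {
  f <- fields[fields$condition == condition & !fields$all_zero, ]
  if (!nrow(f)) stop("no usable fields for condition ", condition)
  if (is.null(muscles)) muscles <- unique(f$muscle)
  wide <- tidyr::pivot_wider(
    f, id_cols = "muscle",
    names_from = "unit_id",
    values_from = if (normalized) "value_norm" else "value")
  m <- as.matrix(wide[match(muscles, wide$muscle), -1, drop = FALSE])
  rownames(m) <- muscles
  m
}
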