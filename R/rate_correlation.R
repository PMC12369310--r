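#' Per-locus firing rates
#'
#' For each unit and stimulation locus: the spike count inside each trial's
#' response window (stimulus onset to offset plus `pad_s`) divided by the
#' window duration, averaged across the trials of that locus.
#'
#' @param spikes Spike table.
#' @param trials Trial table (typically one condition).
#' @param pad_s Post-offset padding of the response window in seconds.
#' @return Tibble with columns `unit_id`, `condition`, `locus_um`,
#'   `rate_hz`, ordered rostral to caudal within unit and condition.
#' @export
firing_rate_by_locus <- function(spikes, trials, pad_s = 0.1) {
  validate_spikes(spikes)
  validate_trials(trials)
  units <- unique(spikes$unit_id)
  grid <- tidyr::expand_grid(unit_id = units,
                             trial = seq_len(nrow(trials)))
  per_trial <- grid |>
    dplyr::mutate(
      condition = trials$condition[.data$trial],
      locus_um = trials$locus_um[.data$trial],
      rate = purrr::map2_dbl(.data$unit_id, .data$trial, function(u, i) {
        on <- trials$stim_on_s[i]; off <- trials$stim_off_s[i] + pad_s
        tt <- spikes$time_s[spikes$unit_id == u]
        sum(tt >= on & tt < off) / (off - on)
      }))
  per_trial |>
    dplyr::group_by(.data$unit_id, .data$condition, .data$locus_um) |>
    dplyr::summarise(rate_hz = mean(.data$rate), .groups = "drop") |>
    dplyr::arrange(.data$unit_id, .data$condition, .data$locus_um)
}

#' Correlate a unit's rate profile with synergy activation amplitudes
#'
#' Pearson correlation, across stimulation loci, between the unit's
#' trial-averaged firing rate and each synergy's trial- and time-averaged
#' activation coefficient. Signed coefficients are retained; absolute
#' values are used to select the best-correlated synergy. `C_corres` is the
#' absolute correlation with the unit's preferred synergy; `C_prefer` is
#' the synergy (and absolute correlation) with the maximal absolute
#' correlation.
#'
#' @param rate_profile One unit's rows from [firing_rate_by_locus()].
#' @param amplitudes [coefficient_amplitudes()] table for the same
#'   condition.
#' @param preferred_index The unit's preferred synergy index.
#' @return List with `by_synergy` (tibble `synergy`, `r`, `abs_r`),
#'   `c_corres_r`, `c_prefer_index`, `c_prefer_r`.
#' @export
correlate_rates <- function(rate_profile, amplitudes, preferred_index) {
  wide <- tidyr::pivot_wider(amplitudes, id_cols = "locus_um",
                             names_from = "synergy", values_from = "amplitude")
  merged <- dplyr::inner_join(rate_profile, wide, by = "locus_um")
  if (nrow(merged) < 3) stop("need at least 3 loci with both rate and amplitude")
  syn_cols <- setdiff(names(wide), "locus_um")
  by_syn <- purrr::map_dfr(seq_along(syn_cols), function(i) {
    y <- merged[[syn_cols[i]]]
    r <- if (sd(merged$rate_hz) == 0 || sd(y) == 0) {
      warning("zero-variance series; correlation undefined")
      NA_real_
    } else cor(merged$rate_hz, y)
    tibble::tibble(synergy = as.integer(syn_cols[i]), r = r, abs_r = abs(r))
  })
  best <- which.max(by_syn$abs_r)
  list(by_synergy = by_syn,
       c_corres_r = by_syn$abs_r[by_syn$synergy == preferred_index],
       c_prefer_index = by_syn$synergy[best],
       c_prefer_r = by_syn$abs_r[best])
}

#' Pooled regression of activation amplitude on firing rate
#'
#' Ordinary least squares over pooled unit-locus points, with the
#' t-statistic p-value for the slope.
#'
#' @param points Tibble (or data frame) with columns `rate_hz` and
#'   `amplitude`, one row per unit-locus pair.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `t_p`, `df`,
#'   `n`.
#' @export
pooled_regression <- function(points) {
  stopifnot(all(c("rate_hz", "amplitude") %in% names(points)))
  if (nrow(points) < 3) stop("need at least 3 points")
  if (sd(points$rate_hz) == 0) stop("degenerate predictor: zero variance")
  fit <- lm(amplitude ~ rate_hz, data = points)
  sm <- summary(fit)
  tibble::tibble(
    slope = coef(fit)[["rate_hz"]],
    intercept = coef(fit)[["(Intercept)"]],
    r_squared = sm$r.squared,
    t_p = sm$coefficients["rate_hz", "Pr(>|t|)"],
    df = fit$df.residual,
    n = nrow(points)
  )
}
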