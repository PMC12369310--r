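#' Plot a synergy fit as muscle-weight bars
#'
#' @param object A `"synergy_fit"`.
#' @param ... Unused.
#' @return A ggplot: one facet per synergy, bars over muscles.
#' @method autoplot synergy_fit
#' @export
autoplot.synergy_fit <- function(object, ...) {
  td <- tidy(object)
  td$muscle <- factor(td$muscle, levels = object$muscles)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$muscle, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~synergy, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "muscle weight (L2-normalized)",
                  title = sprintf("%d muscle synergies, R² = %.3f",
                                  object$N, object$R2)) +
    ggplot2::theme_minimal()
}

#' Plot the silhouette curve of a synergy clustering
#'
#' @param object A `"cluster_result"`.
#' @param ... Unused.
#' @return A ggplot of mean silhouette vs k with the selected k marked.
#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, ...) {
  ggplot2::ggplot(object$silhouette_by_k,
                  ggplot2::aes(x = .data$k, y = .data$silhouette)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_selected, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters k", y = "mean silhouette",
                  title = sprintf("k selected = %d (first local maximum)",
                                  object$k_selected)) +
    ggplot2::theme_minimal()
}

#' Plot SpTA traces for one unit
#'
#' Averaged spike-triggered EMG per muscle with the baseline band and the
#' 3-16 ms test window shaded.
#'
#' @param profiles Output of [spta_profiles()].
#' @param unit_id Unit to plot.
#' @param condition Condition to plot (default: first available).
#' @param config An [sf_config()] (window definitions).
#' @return A ggplot faceted by muscle.
#' @export
plot_spta <- function(profiles, unit_id, condition = NULL,
                      config = sf_config()) {
  pr <- profiles[profiles$unit_id == unit_id, ]
  if (is.null(condition)) condition <- pr$condition[1]
  pr <- pr[pr$condition == condition, ]
  if (!nrow(pr)) stop("no profiles for that unit/condition")
  win <- config$spta_window_ms
  times <- seq(win[1], win[2])
  long <- purrr::map_dfr(seq_len(nrow(pr)), function(i) {
    tibble::tibble(muscle = pr$muscle[i], lag_ms = times,
                   value = pr$trace[[i]],
                   baseline = pr$baseline_mean[i],
                   threshold = pr$baseline_mean[i] +
                     config$baseline_sd_mult * pr$baseline_sd[i])
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lag_ms, y = .data$value)) +
    ggplot2::annotate("rect", xmin = config$test_window_ms[1],
                      xmax = config$test_window_ms[2], ymin = -Inf, ymax = Inf,
                      alpha = 0.08, fill = "red") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~muscle, scales = "free_y") +
    ggplot2::labs(x = "lag from spike (ms)", y = "SpTA of EMG envelope",
                  title = paste0("unit ", unit_id, " (", condition, ")")) +
    ggplot2::theme_minimal()
}

#' Plot a unit's muscle field against its preferred synergy
#'
#' @param fields Output of [build_muscle_field()].
#' @param fit A `"synergy_fit"` of the same condition.
#' @param unit_id Unit to plot.
#' @param condition Condition label.
#' @return A ggplot comparing the normalized field and synergy weights.
#' @export
plot_field_match <- function(fields, fit, unit_id, condition = fit$condition) {
  prefs <- preferred_pairs(fields, fit, condition)
  best <- prefs[prefs$unit_id == unit_id & prefs$preferred, ]
  f <- fields[fields$unit_id == unit_id & fields$condition == condition, ]
  df <- dplyr::bind_rows(
    tibble::tibble(muscle = f$muscle, value = f$value_norm, what = "muscle field"),
    tibble::tibble(muscle = fit$muscles, value = fit$W[, best$synergy],
                   what = sprintf("synergy W%d (sp = %.2f)", best$synergy, best$sp)))
  df$muscle <- factor(df$muscle, levels = fit$muscles)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$muscle, y = .data$value,
                                   fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "L2-normalized weight", fill = NULL,
                  title = paste0("unit ", unit_id, " (", condition, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
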