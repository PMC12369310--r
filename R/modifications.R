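#' Non-negative least-squares reconstruction of a synergy
#'
#' Finds non-negative coefficients `c` minimizing
#' `|| target - sources %*% c ||_2` and reports the reconstruction together
#' with its scalar-product similarity to the target. Target and sources are
#' L2-normalized before the fit; the coefficients are used as-is against the
#' 0.2 contributor threshold.
#'
#' @param target Non-negative vector (a preferred synergy).
#' @param sources Non-negative matrix `[n_muscles x N]` of source-condition
#'   synergies.
#' @return List with `coefficients`, `reconstruction` and
#'   `reconstruction_sp` (0 when the reconstruction is identically zero).
#' @export
nnls_reconstruct <- function(target, sources) {
  sources <- as.matrix(sources)
  if (!ncol(sources)) stop("empty source synergy set")
  stopifnot(length(target) == nrow(sources))
  tn <- target / sqrt(sum(target^2))
  Sn <- sweep(sources, 2, sqrt(colSums(sources^2)), "/")
  fit <- pracma::lsqnonneg(Sn, tn)
  coefs <- as.numeric(fit$x)
  recon <- as.numeric(Sn %*% coefs)
  sp <- if (all(recon == 0)) 0 else scalar_product(recon, tn)
  list(coefficients = coefs, reconstruction = recon, reconstruction_sp = sp)
}

#' Classify an across-condition change of a unit's preferred synergy
#'
#' Decision sequence for how a unit's preferred synergy in a target
#' condition (SSAT or CoST) relates to the synergies of the source (SST)
#' condition:
#' 1. **merging** — the target preferred synergy is well explained
#'    (reconstruction scalar product >= 0.8) by a non-negative combination
#'    of source synergies in which at least two synergies contribute
#'    (coefficient > 0.2) and the unit's own source-preferred synergy is
#'    among the contributors;
#' 2. otherwise **preserved** — the pairwise scalar product between the two
#'    preferred synergies is >= 0.8;
#' 3. otherwise **unmatched**.
#'
#' @param preferred_src Unit's preferred synergy in the source condition.
#' @param preferred_tgt Unit's preferred synergy in the target condition.
#' @param source_synergies Matrix `[n_muscles x N]` of all source-condition
#'   synergies.
#' @param src_index Column of `source_synergies` that is the unit's
#'   source-preferred synergy.
#' @param config An [sf_config()] (thresholds `merge_coef_min`,
#'   `merge_sp_min`, `preserved_sp_min`).
#' @return One-row tibble: `form`, `reconstruction_sp`, `pairwise_sp`,
#'   `n_contributing`, and `coefficients` (list column).
#' @export
classify_modification <- function(preferred_src, preferred_tgt,
                                  source_synergies, src_index,
                                  config = sf_config()) {
  source_synergies <- as.matrix(source_synergies)
  stopifnot(src_index >= 1, src_index <= ncol(source_synergies))
  fit <- nnls_reconstruct(preferred_tgt, source_synergies)
  contributing <- which(fit$coefficients > config$merge_coef_min)
  pairwise_sp <- scalar_product(preferred_src, preferred_tgt)
  form <- if (fit$reconstruction_sp >= config$merge_sp_min &&
              length(contributing) >= 2 && src_index %in% contributing) {
    "merging"
  } else if (pairwise_sp >= config$preserved_sp_min) {
    "preserved"
  } else {
    "unmatched"
  }
  tibble::tibble(
    form = form,
    reconstruction_sp = fit$reconstruction_sp,
    pairwise_sp = pairwise_sp,
    n_contributing = length(contributing),
    coefficients = list(fit$coefficients)
  )
}

#' Classify all units' modifications between two conditions
#'
#' Applies [classify_modification()] to every unit present in both the
#' source and target condition, using each condition's preferred pairs and
#' synergy sets.
#'
#' @param prefs_src,prefs_tgt [preferred_pairs()] tables for the source and
#'   target conditions.
#' @param fit_src,fit_tgt `"synergy_fit"` objects for the two conditions.
#' @param config An [sf_config()].
#' @return Tibble with one row per unit: `unit_id`, `condition_pair`,
#'   `form`, `reconstruction_sp`, `pairwise_sp`, `n_contributing`,
#'   `coefficients`.
#' @export
classify_modifications <- function(prefs_src, prefs_tgt, fit_src, fit_tgt,
                                   config = sf_config()) {
  src <- dplyr::filter(prefs_src, .data$preferred)
  tgt <- dplyr::filter(prefs_tgt, .data$preferred)
  units <- intersect(src$unit_id, tgt$unit_id)
  pair <- paste0(unique(src$condition), "->", unique(tgt$condition))
  purrr::map_dfr(units, function(u) {
    i_src <- src$synergy[src$unit_id == u]
    i_tgt <- tgt$synergy[tgt$unit_id == u]
    dplyr::bind_cols(
      tibble::tibble(unit_id = u, condition_pair = pair),
      classify_modification(fit_src$W[, i_src], fit_tgt$W[, i_tgt],
                            fit_src$W, i_src, config)
    )
  })
}

#' Prevalence of modification forms
#'
#' @param results Tibble from [classify_modifications()] (possibly several
#'   condition pairs bound together).
#' @return Tibble with one row per condition pair x form: `n`, `fraction`
#'   (fractions sum to 1 within each pair; absent forms appear with 0).
#' @export
prevalence_table <- function(results) {
  if (!nrow(results)) stop("no modification results")
  forms <- c("merging", "unmatched", "preserved")
  results |>
    dplyr::mutate(form = factor(.data$form, levels = forms)) |>
    dplyr::group_by(.data$condition_pair, .data$form, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop_last") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(form = as.character(.data$form))
}
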