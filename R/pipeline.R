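#' Sample indices of one condition's response windows
#'
#' Indices (into the recording's sample axis) covered by the response
#' windows (stimulus onset to offset + `pad_s`) of a condition's trials.
#' Synergy sets are extracted per condition from this concatenation.
#'
#' @param trials Trial table.
#' @param condition Condition label.
#' @param fs Sampling rate (Hz).
#' @param t0 Recording start time (s).
#' @param n_samples Number of samples in the recording.
#' @param pad_s Post-offset padding (s).
#' @return Sorted integer vector of sample indices.
#' @export
condition_samples <- function(trials, condition, fs, t0, n_samples, pad_s = 0.1) {
  tr <- trials[trials$condition == condition, ]
  if (!nrow(tr)) stop("no trials for condition ", condition)
  idx <- purrr::map(seq_len(nrow(tr)), function(i) {
    i0 <- max(1L, as.integer(floor((tr$stim_on_s[i] - t0) * fs)) + 1L)
    i1 <- min(n_samples, as.integer(floor((tr$stim_off_s[i] + pad_s - t0) * fs)))
    if (i1 < i0) integer(0) else i0:i1
  })
  sort(unique(unlist(idx)))
}

write_tsv_out <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.list),
                                        ~ purrr::map_chr(.x, function(v)
                                          paste(sprintf("%.10g", v), collapse = ","))))
  write_num_tsv(as.data.frame(df), path)
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Simulates a dataset, preprocesses the EMG, computes per-condition SpTA
#' profiles and muscle fields, extracts per-condition synergy sets with the
#' R-squared model-order rule, identifies preferred field-synergy pairs,
#' matches fields and synergies across conditions (with consistency rates),
#' clusters the SST synergies, classifies the across-condition modification
#' form of every unit's preferred synergy, and correlates per-locus firing
#' rates with activation-coefficient amplitudes. All randomness derives
#' from `seed`; with the same seed the written outputs are byte-identical
#' across runs.
#'
#' @param seed Integer master seed.
#' @param sim A [sim_config()].
#' @param config An [sf_config()].
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as TSV/JSON (plus the dataset bundle under `bundle/`).
#' @return A list with elements `data`, `profiles`, `fields`, `fits`,
#'   `preferred`, `field_matches`, `synergy_matches`, `consistency`,
#'   `clusters`, `modifications`, `prevalence`, `rates`, `correlations`,
#'   `regressions`.
#' @export
run_pipeline <- function(seed = 1L, sim = sim_config(), config = sf_config(),
                         out_dir = NULL) {
  dat <- generate_dataset(sim, seed,
                          dir = if (is.null(out_dir)) NULL else
                            file.path(out_dir, "bundle"),
                          config = config)
  prep <- preprocess_emg(dat$emg, config)
  rec <- prep$rec
  conds <- intersect(CONDITIONS, unique(dat$trials$condition))

  profiles <- spta_profiles(dat$spikes, rec, dat$trials, config)
  fields <- build_muscle_field(profiles)

  n <- ncol(rec$signal)
  fits <- list(); samples <- list(); amplitudes <- list()
  for (cond in conds) {
    idx <- condition_samples(dat$trials, cond, rec$fs, rec$t0, n,
                             config$response_pad_s)
    fit <- select_model_order(rec$signal[, idx], config$r2_threshold,
                              restarts = config$nnmf_restarts,
                              seed = stage_seed(seed, paste0("nnmf_", cond)),
                              max_iter = config$nnmf_max_iter,
                              tol = config$nnmf_tol, condition = cond)
    fits[[cond]] <- fit
    samples[[cond]] <- idx
    amplitudes[[cond]] <- coefficient_amplitudes(
      fit, dat$trials[dat$trials$condition == cond, ], fs = rec$fs, t0 = rec$t0,
      pad_s = config$response_pad_s, sample_index = idx)
  }

  preferred <- purrr::map_dfr(conds, function(cond)
    preferred_pairs(fields, fits[[cond]], cond))

  pair_conds <- if (length(conds) > 1) {
    purrr::map(setdiff(conds, conds[1]), ~ c(conds[1], .x))
  } else list()
  field_matches <- list(); synergy_matches <- list()
  consistency <- tibble::tibble(pair = character(), kind = character(),
                                mean_sp = numeric(), consistency = numeric())
  for (pc in pair_conds) {
    key <- paste(pc, collapse = "->")
    fm <- tryCatch(
      match_across_conditions(field_matrix(fields, pc[1]),
                              field_matrix(fields, pc[2])),
      error = function(e) NULL)
    sm <- match_across_conditions(fits[[pc[1]]]$W, fits[[pc[2]]]$W)
    field_matches[[key]] <- fm
    synergy_matches[[key]] <- sm
    if (!is.null(fm)) {
      consistency <- dplyr::add_row(consistency, pair = key, kind = "fields",
                                    mean_sp = attr(fm, "mean_sp"),
                                    consistency = consistency_rate(fm, config$consistency_sp))
    }
    consistency <- dplyr::add_row(consistency, pair = key, kind = "synergies",
                                  mean_sp = attr(sm, "mean_sp"),
                                  consistency = consistency_rate(sm, config$consistency_sp))
  }

  clusters <- if (fits[[conds[1]]]$N >= 3) {
    cluster_synergies(fits[[conds[1]]]$W, config$k_range,
                      seed = stage_seed(seed, "cluster"),
                      nstart = config$kmeans_restarts)
  } else NULL

  modifications <- purrr::map_dfr(pair_conds, function(pc) {
    classify_modifications(
      dplyr::filter(preferred, .data$condition == pc[1]),
      dplyr::filter(preferred, .data$condition == pc[2]),
      fits[[pc[1]]], fits[[pc[2]]], config)
  })
  prevalence <- if (nrow(modifications)) prevalence_table(modifications) else NULL

  rates <- firing_rate_by_locus(dat$spikes, dat$trials, config$response_pad_s)
  correlations <- purrr::map_dfr(conds, function(cond) {
    pref_cond <- dplyr::filter(preferred, .data$condition == cond, .data$preferred)
    purrr::map_dfr(unique(pref_cond$unit_id), function(u) {
      rp <- dplyr::filter(rates, .data$unit_id == u, .data$condition == cond)
      res <- correlate_rates(rp, amplitudes[[cond]],
                             pref_cond$synergy[pref_cond$unit_id == u])
      tibble::tibble(unit_id = u, condition = cond,
                     c_corres_r = res$c_corres_r,
                     c_prefer_index = res$c_prefer_index,
                     c_prefer_r = res$c_prefer_r,
                     r_by_synergy = list(res$by_synergy))
    })
  })

  # pooled unit-locus points: rate vs amplitude of the unit's preferred
  # synergy (corresponding) and of the best-correlated synergy (preferred)
  points <- purrr::map_dfr(conds, function(cond) {
    pref_cond <- dplyr::filter(preferred, .data$condition == cond, .data$preferred)
    purrr::map_dfr(unique(pref_cond$unit_id), function(u) {
      rp <- dplyr::filter(rates, .data$unit_id == u, .data$condition == cond)
      ci <- dplyr::filter(correlations, .data$unit_id == u, .data$condition == cond)
      amp <- amplitudes[[cond]]
      corres <- dplyr::filter(amp, .data$synergy ==
                                pref_cond$synergy[pref_cond$unit_id == u])
      prefc <- dplyr::filter(amp, .data$synergy == ci$c_prefer_index)
      dplyr::bind_rows(
        dplyr::inner_join(rp, corres, by = "locus_um") |>
          dplyr::mutate(kind = "corresponding"),
        dplyr::inner_join(rp, prefc, by = "locus_um") |>
          dplyr::mutate(kind = "preferred"))
    })
  })
  regressions <- points |>
    dplyr::group_by(.data$kind) |>
    dplyr::group_modify(~ pooled_regression(.x)) |>
    dplyr::ungroup()

  res <- list(data = dat, profiles = profiles, fields = fields, fits = fits,
              samples = samples, amplitudes = amplitudes, preferred = preferred,
              field_matches = field_matches, synergy_matches = synergy_matches,
              consistency = consistency, clusters = clusters,
              modifications = modifications, prevalence = prevalence,
              rates = rates, correlations = correlations,
              regression_points = points, regressions = regressions)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_out(dplyr::select(res$profiles, -"trace"),
                file.path(out_dir, "spta_profiles.tsv"))
  write_tsv_out(res$fields, file.path(out_dir, "muscle_fields.tsv"))
  for (cond in names(res$fits)) {
    fit <- res$fits[[cond]]
    write_tsv_out(tidy(fit), file.path(out_dir, paste0("synergies_", cond, ".tsv")))
    jsonlite::write_json(
      list(N = fit$N, R2 = fit$R2,
           order_scan = attr(fit, "order_scan")),
      file.path(out_dir, paste0("model_order_", cond, ".json")),
      auto_unbox = TRUE, digits = NA)
    write_tsv_out(res$amplitudes[[cond]],
                  file.path(out_dir, paste0("coefficients_", cond, ".tsv")))
  }
  write_tsv_out(res$preferred, file.path(out_dir, "preferred_pairs.tsv"))
  for (key in names(res$synergy_matches)) {
    safe <- gsub("->", "_to_", key, fixed = TRUE)
    if (!is.null(res$field_matches[[key]])) {
      write_tsv_out(res$field_matches[[key]],
                    file.path(out_dir, paste0("matches_fields_", safe, ".tsv")))
    }
    write_tsv_out(res$synergy_matches[[key]],
                  file.path(out_dir, paste0("matches_synergies_", safe, ".tsv")))
  }
  write_tsv_out(res$consistency, file.path(out_dir, "consistency.tsv"))
  if (!is.null(res$clusters)) {
    write_tsv_out(tidy(res$clusters), file.path(out_dir, "clusters.tsv"))
    write_tsv_out(res$clusters$silhouette_by_k,
                  file.path(out_dir, "silhouette.tsv"))
  }
  if (nrow(res$modifications)) {
    write_tsv_out(res$modifications, file.path(out_dir, "modifications.tsv"))
    jsonlite::write_json(res$prevalence, file.path(out_dir, "prevalence.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write_tsv_out(res$rates, file.path(out_dir, "rate_profiles.tsv"))
  write_tsv_out(dplyr::select(res$correlations, -"r_by_synergy"),
                file.path(out_dir, "correlations.tsv"))
  jsonlite::write_json(res$regressions, file.path(out_dir, "pooled_regression.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
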