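#' Analysis configuration
#'
#' Collects every window, threshold and solver setting used by the pipeline.
#' Defaults follow the published analysis protocol this package implements:
#' SpTA segments span -30 to +50 ms around each spike, post-spike effects are
#' sought in the 3-16 ms test window against a baseline taken 30-10 ms before
#' the trigger (2 SD criterion), pure post-spike effects require onset
#' latency > 3.5 ms and PWHM < 7 ms, NNMF is restarted 100 times per model
#' order and the smallest order reaching R-squared 0.80 is kept, k-means is
#' scanned over k = 2..10, synergy merging requires combination
#' coefficients above 0.2, preserved synergies require a pairwise scalar
#' product of at least 0.8, and
#' across-condition consistency uses a 0.78 scalar-product cut-off. EMG is
#' down-sampled to 1 kHz and conditioned with 50th-order FIR filters
#' (high-pass 50 Hz, rectification, low-pass 20 Hz); artifacts are replaced
#' with the per-channel 99.9th percentile.
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class `"sf_config"`.
#' @examples
#' cfg <- sf_config()
#' cfg$r2_threshold
#' sf_config(nnmf_restarts = 20)$nnmf_restarts
#' @export
sf_config <- function(...) {
  cfg <- list(
    spta_window_ms     = c(-30, 50),
    test_window_ms     = c(3, 16),
    baseline_window_ms = c(-30, -10),
    baseline_sd_mult   = 2,
    pure_onset_ms      = 3.5,
    pure_pwhm_ms       = 7,
    min_spikes         = 30,
    n_shuffles         = 200,
    r2_threshold       = 0.80,
    nnmf_restarts      = 100,
    nnmf_max_iter      = 1000,
    nnmf_tol           = 1e-6,
    k_range            = c(2, 10),
    kmeans_restarts    = 50,
    merge_coef_min     = 0.2,
    merge_sp_min       = 0.8,
    preserved_sp_min   = 0.8,
    consistency_sp     = 0.78,
    target_fs          = 1000,
    hp_order           = 50,
    hp_cut             = 50,
    lp_order           = 50,
    lp_cut             = 20,
    artifact_pctl      = 99.9,
    artifact_sd_mult   = 8,
    artifact_dilate_ms = 5,
    response_pad_s     = 0.1,
    trigger_settle_s   = 0.05,
    rng_seed           = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "sf_config")
}

#' @export
print.sf_config <- function(x, ...) {
  cat("<sf_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Read / write a configuration as YAML
#'
#' @param cfg An [sf_config()] object.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   an `sf_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sf_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- lapply(vals, function(v) if (is.list(v)) unlist(v) else v)
  do.call(sf_config, vals)
}
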