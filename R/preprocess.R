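# EMG conditioning chain: down-sample to 1 kHz, zero-phase 50th-order FIR
# high-pass at 50 Hz, rectification, zero-phase 50th-order FIR low-pass at
# 20 Hz, artifact replacement by the channel 99.9th percentile, variance
# normalization. Raw-domain recordings get the full chain; envelope-domain
# recordings (already rectified/smoothed, e.g. simulator output) skip the
# filter stages.

fir_filtfilt <- function(x, order, cut, fs, type) {
  b <- as.numeric(signal::fir1(order, cut / (fs / 2), type))
  # pin the gain exactly: unit DC gain for low-pass, a true DC null for
  # high-pass (fir1's window scaling is only approximate at short orders)
  if (type == "low") b <- b / sum(b) else b <- b - sum(b) / length(b)
  # mirror-pad so the forward-backward pass has clean edge conditions
  n <- length(x)
  pad <- min(3L * (order + 1L), n - 1L)
  xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
  # forward-backward application: zero phase, squared magnitude response
  y <- as.numeric(signal::filtfilt(signal::Ma(b), xp))
  y[(pad + 1):(pad + n)]
}

#' Down-sample an EMG recording
#'
#' Anti-alias low-pass filters each channel at `0.45 * target_fs` (zero
#' phase) and resamples it onto the exact `target_fs` grid by linear
#' interpolation. Duration is preserved to within one output sample.
#'
#' @param rec An [emg_recording()].
#' @param target_fs Target sampling rate in Hz (must not exceed `rec$fs`).
#' @return The resampled [emg_recording()].
#' @export
downsample <- function(rec, target_fs = 1000) {
  stopifnot(inherits(rec, "emg_recording"))
  if (target_fs <= 0) stop("target_fs must be positive")
  if (target_fs > rec$fs) stop("target_fs exceeds the recording rate")
  if (target_fs == rec$fs) return(rec)
  n_in <- ncol(rec$signal)
  n_out <- round(n_in * target_fs / rec$fs)
  t_in <- rec$t0 + (seq_len(n_in) - 1) / rec$fs
  t_out <- rec$t0 + (seq_len(n_out) - 1) / target_fs
  out <- matrix(0, nrow(rec$signal), n_out)
  for (j in seq_len(nrow(out))) {
    lp <- fir_filtfilt(rec$signal[j, ], order = 50,
                       cut = 0.45 * target_fs, fs = rec$fs, type = "low")
    out[j, ] <- stats::approx(t_in, lp, xout = t_out, rule = 2)$y
  }
  emg_recording(out, fs = target_fs, muscles = rec$muscles, t0 = rec$t0,
                domain = rec$domain)
}

#' Apply the FIR conditioning chain
#'
#' Zero-phase 50th-order FIR high-pass (cut-off 50 Hz), full-wave
#' rectification, then zero-phase 50th-order FIR low-pass (cut-off 20 Hz),
#' clamped at zero. Zero-phase (forward-backward) application is used so
#' that post-spike latencies in the 3-16 ms test window are not shifted by
#' the ~25-sample group delay a causal 50th-order filter would add at 1 kHz.
#'
#' @param rec An [emg_recording()] already at the analysis rate.
#' @param config An [sf_config()] providing filter orders and cut-offs.
#' @return An envelope-domain [emg_recording()].
#' @export
filter_chain <- function(rec, config = sf_config()) {
  stopifnot(inherits(rec, "emg_recording"))
  n <- ncol(rec$signal)
  if (n < 3 * (max(config$hp_order, config$lp_order) + 1)) {
    stop("signal shorter than 3x the filter length")
  }
  out <- rec$signal
  for (j in seq_len(nrow(out))) {
    hp <- fir_filtfilt(out[j, ], config$hp_order, config$hp_cut, rec$fs, "high")
    out[j, ] <- fir_filtfilt(abs(hp), config$lp_order, config$lp_cut, rec$fs, "low")
  }
  out[out < 0] <- 0
  emg_recording(out, fs = rec$fs, muscles = rec$muscles, t0 = rec$t0,
                domain = "envelope")
}

#' Detect high-amplitude artifact samples
#'
#' Deterministic surrogate for visual artifact marking: flags samples whose
#' deviation from the channel median exceeds `sd_mult` channel SDs, dilated
#' by `dilate_ms` on each side.
#'
#' @param rec An [emg_recording()].
#' @param sd_mult Threshold in channel SD units (default 8).
#' @param dilate_ms Dilation of each flagged sample in ms (default 5).
#' @return Logical matrix with the dimensions of `rec$signal`.
#' @export
detect_artifacts <- function(rec, sd_mult = 8, dilate_ms = 5) {
  sig <- rec$signal
  mask <- matrix(FALSE, nrow(sig), ncol(sig))
  w <- max(0L, as.integer(round(dilate_ms / 1000 * rec$fs)))
  for (j in seq_len(nrow(sig))) {
    dev <- abs(sig[j, ] - stats::median(sig[j, ]))
    hit <- which(dev > sd_mult * sd(sig[j, ]))
    if (length(hit)) {
      idx <- unique(pmax(1L, pmin(ncol(sig), rep(hit, each = 2L * w + 1L) +
                                    rep(-w:w, times = length(hit)))))
      mask[j, idx] <- TRUE
    }
  }
  mask
}

#' Replace artifact samples with the channel 99.9th percentile
#'
#' Masked samples of each channel are replaced by that channel's 99.9th
#' percentile computed over the unmasked samples. Percentiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7).
#'
#' @param rec An [emg_recording()].
#' @param mask Logical matrix matching `rec$signal`; `NULL` runs
#'   [detect_artifacts()] with the config thresholds.
#' @param config An [sf_config()].
#' @return List with `rec` (cleaned recording) and `report` (tibble with one
#'   row per muscle: samples replaced, replacement value, pre/post variance).
#' @export
replace_artifacts <- function(rec, mask = NULL, config = sf_config()) {
  stopifnot(inherits(rec, "emg_recording"))
  if (is.null(mask)) {
    mask <- detect_artifacts(rec, config$artifact_sd_mult, config$artifact_dilate_ms)
  }
  stopifnot(is.logical(mask), all(dim(mask) == dim(rec$signal)))
  frac <- rowMeans(mask)
  if (any(frac > 0.5)) {
    stop("artifact mask covers > 50% of channel ",
         rec$muscles[which.max(frac)], "; percentile replacement unreliable")
  }
  sig <- rec$signal
  report <- tibble::tibble(
    muscle = rec$muscles,
    n_replaced = integer(nrow(sig)),
    replacement_value = NA_real_,
    variance_pre = apply(sig, 1, var),
    variance_post = NA_real_
  )
  for (j in seq_len(nrow(sig))) {
    hit <- which(mask[j, ])
    report$n_replaced[j] <- length(hit)
    if (length(hit)) {
      p <- as.numeric(quantile(sig[j, -hit], config$artifact_pctl / 100,
                               type = 7, names = FALSE))
      sig[j, hit] <- p
      report$replacement_value[j] <- p
    }
    report$variance_post[j] <- var(sig[j, ])
  }
  rec$signal <- sig
  list(rec = rec, report = report)
}

#' Variance-normalize each EMG channel
#'
#' Divides each channel by its standard deviation (no mean subtraction, so
#' non-negativity — required by NNMF — is preserved).
#'
#' @param rec An [emg_recording()].
#' @return The normalized [emg_recording()]; each channel has variance 1.
#' @export
variance_normalize <- function(rec) {
  stopifnot(inherits(rec, "emg_recording"))
  sds <- apply(rec$signal, 1, sd)
  if (any(sds == 0)) {
    stop("zero-variance channel: ", paste(rec$muscles[sds == 0], collapse = ", "))
  }
  rec$signal <- rec$signal / sds
  rec
}

#' Run the full preprocessing chain
#'
#' Down-sampling to the analysis rate, the FIR conditioning chain (raw-domain
#' recordings only), artifact replacement and variance normalization, in
#' that order.
#'
#' @param rec An [emg_recording()].
#' @param config An [sf_config()].
#' @param mask Optional manual artifact mask (at the analysis rate).
#' @return List with `rec` (preprocessed, envelope-domain, unit-variance
#'   recording) and `report` (artifact/variance tibble).
#' @export
preprocess_emg <- function(rec, config = sf_config(), mask = NULL) {
  rec <- downsample(rec, config$target_fs)
  if (rec$domain == "raw") rec <- filter_chain(rec, config)
  cleaned <- replace_artifacts(rec, mask, config)
  list(rec = variance_normalize(cleaned$rec), report = cleaned$report)
}
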