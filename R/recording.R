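#' EMG recording container
#'
#' A multichannel EMG recording: a muscles-by-samples signal matrix plus its
#' sampling rate, ordered muscle labels and the time of the first sample.
#' `domain` records whether the signal is raw (bipolar, signed) or already an
#' envelope (post-rectification, non-negative); the preprocessing chain
#' applies the FIR filter stages only to raw-domain recordings.
#'
#' @param signal Numeric matrix `[n_muscles x n_samples]`.
#' @param fs Sampling rate in Hz (> 0).
#' @param muscles Character vector of channel labels, one per row.
#' @param t0 Time of the first sample in seconds.
#' @param domain `"raw"` or `"envelope"`.
#' @return An object of class `"emg_recording"`.
#' @examples
#' rec <- emg_recording(matrix(abs(rnorm(60)), 6), fs = 1000)
#' rec
#' @export
emg_recording <- function(signal, fs,
                          muscles = DEFAULT_MUSCLES[seq_len(nrow(signal))],
                          t0 = 0, domain = c("envelope", "raw")) {
  domain <- match.arg(domain)
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop("signal must be numeric")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (is.null(muscles) || anyNA(muscles) || !all(nzchar(muscles))) {
    stop("missing channel labels: every EMG row needs a muscle name")
  }
  if (length(muscles) != nrow(signal)) {
    stop("number of muscle labels (", length(muscles),
         ") does not match number of signal rows (", nrow(signal), ")")
  }
  if (anyDuplicated(muscles)) stop("duplicate muscle labels")
  rownames(signal) <- muscles
  structure(
    list(signal = signal, fs = as.numeric(fs), muscles = as.character(muscles),
         t0 = as.numeric(t0), domain = domain),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d muscles x %d samples @ %.6g Hz (%s domain)\n",
              nrow(x$signal), ncol(x$signal), x$fs, x$domain))
  cat("  muscles:", paste(x$muscles, collapse = ", "), "\n")
  cat(sprintf("  span: [%.4g, %.4g] s\n", x$t0, x$t0 + ncol(x$signal) / x$fs))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An [emg_recording()].
#' @return Numeric scalar.
#' @export
rec_duration <- function(rec) ncol(rec$signal) / rec$fs

#' Sample index of a time point
#'
#' Uses the half-open binning convention: the sample covering time `t` at
#' rate `fs` has (1-based) index `floor((t - t0) * fs) + 1`.
#'
#' @param rec An [emg_recording()].
#' @param t Time(s) in seconds.
#' @return Integer sample indices (may fall outside the recording).
#' @export
sample_index <- function(rec, t) {
  as.integer(floor((t - rec$t0) * rec$fs)) + 1L
}

#' Build a spike table
#'
#' Spikes are kept in long form: one row per spike with its unit id and time
#' in seconds. Times must be strictly increasing within each unit.
#'
#' @param unit_id Unit identifier(s), recycled against `times`.
#' @param times Spike times in seconds.
#' @return A tibble with columns `unit_id`, `time_s`.
#' @examples
#' spike_table("u1", c(0.01, 0.05, 0.2))
#' @export
spike_table <- function(unit_id, times) {
  tbl <- tibble::tibble(unit_id = as.character(unit_id), time_s = as.numeric(times))
  validate_spikes(tbl)
  tbl
}

#' Validate a spike table
#' @param spikes Tibble with columns `unit_id`, `time_s`.
#' @param rec Optional [emg_recording()]; if given, all spikes must fall
#'   within the recording span.
#' @return `spikes`, invisibly.
#' @export
validate_spikes <- function(spikes, rec = NULL) {
  stopifnot(is.data.frame(spikes), all(c("unit_id", "time_s") %in% names(spikes)))
  if (anyNA(spikes$time_s)) stop("NA spike times")
  for (u in unique(spikes$unit_id)) {
    tt <- spikes$time_s[spikes$unit_id == u]
    if (is.unsorted(tt, strictly = TRUE)) {
      stop("non-monotone spike times for unit ", u)
    }
  }
  if (!is.null(rec)) {
    lo <- rec$t0
    hi <- rec$t0 + rec_duration(rec)
    if (any(spikes$time_s < lo | spikes$time_s > hi)) {
      stop("spike times outside the recording span")
    }
  }
  invisible(spikes)
}

#' Build a trial table
#'
#' One row per stimulation trial. `condition` is one of `SST` (single-fibre
#' stimulation at threshold power), `SSAT` (single-fibre at 120-150% of
#' threshold) or `CoST` (two-fibre co-stimulation at threshold); `locus_um`
#' is the rostrocaudal position of the (moving) fibre in micrometres and
#' `locus2_um` the second, fixed fibre for CoST trials.
#'
#' @param trial_id Trial identifiers.
#' @param condition Condition labels.
#' @param locus_um Stimulation locus in micrometres.
#' @param power_frac Laser power as a fraction of threshold power.
#' @param stim_on_s,stim_off_s Stimulus onset/offset in seconds.
#' @param locus2_um Second locus (CoST only; `NA` otherwise).
#' @return A validated tibble of trials, sorted by `stim_on_s`.
#' @export
trial_table <- function(trial_id, condition, locus_um, power_frac,
                        stim_on_s, stim_off_s, locus2_um = NA_real_) {
  tbl <- tibble::tibble(
    trial_id = as.character(trial_id),
    condition = as.character(condition),
    locus_um = as.numeric(locus_um),
    locus2_um = as.numeric(locus2_um),
    power_frac = as.numeric(power_frac),
    stim_on_s = as.numeric(stim_on_s),
    stim_off_s = as.numeric(stim_off_s)
  )
  tbl <- dplyr::arrange(tbl, .data$stim_on_s)
  validate_trials(tbl)
  tbl
}

#' Validate a trial table
#' @param trials Tibble in the [trial_table()] layout.
#' @return `trials`, invisibly.
#' @export
validate_trials <- function(trials) {
  need <- c("trial_id", "condition", "locus_um", "locus2_um", "power_frac",
            "stim_on_s", "stim_off_s")
  stopifnot(is.data.frame(trials), all(need %in% names(trials)))
  if (!all(trials$condition %in% CONDITIONS)) {
    stop("condition must be one of ", paste(CONDITIONS, collapse = ", "))
  }
  if (any(trials$stim_off_s - trials$stim_on_s <= 0)) {
    stop("stim_off_s must exceed stim_on_s")
  }
  co <- trials$condition == "CoST"
  if (any(co & !is.finite(trials$locus2_um))) {
    stop("CoST trials require a second stimulation locus (locus2_um)")
  }
  ssat <- trials$condition == "SSAT"
  if (any(ssat & (trials$power_frac < 1.2 | trials$power_frac > 1.5))) {
    stop("SSAT trials must have power_frac in [1.2, 1.5]")
  }
  ord <- order(trials$stim_on_s)
  on <- trials$stim_on_s[ord]
  off <- trials$stim_off_s[ord]
  if (any(on[-1] < off[-length(off)])) stop("overlapping trials")
  invisible(trials)
}
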