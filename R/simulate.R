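#' Simulation configuration
#'
#' Settings for the spike/EMG co-simulator. Defaults reproduce the study's
#' stimulation protocol: 13 rostrocaudal loci per condition spaced 200 um
#' apart, 5 trials per locus, 200 ms pulse trains (5 ms pulses at 100 Hz)
#' with a 1000 ms intertrial interval, SSAT laser power drawn from 120-150%
#' of threshold. EMG is generated directly in the non-negative envelope
#' (post-rectification) domain at the 1 kHz analysis rate: a planted
#' synergy mixture with smooth per-trial activation envelopes, plus
#' spike-locked raised-cosine muscle-field kernels, plus clamped Gaussian
#' noise. Noise level and kernel amplitude were fixed once by a pilot
#' calibration so that planted structure is recoverable but not trivially so
#' (see the methods vignette).
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_muscles        = 6,
    muscles          = DEFAULT_MUSCLES,
    n_synergies      = 3,      # planted synergies (the study found 3-4)
    n_units          = 2,      # units per animal (1-2 in the study)
    n_loci           = 13,     # mean loci per animal in the study
    locus_step_um    = 200,
    trials_per_locus = 5,
    conditions       = c("SST", "SSAT", "CoST"),
    pulse_width_ms   = 5,
    pulse_rate_hz    = 100,
    train_ms         = 200,
    intertrial_s     = 1.0,
    lead_in_s        = 0.5,
    base_rate        = 5,      # Hz, spontaneous firing
    stim_rate        = 100,    # Hz, peak stimulus-locked firing
    rate_width_loci  = NA,     # SD of the per-unit locus tuning; default n_loci/5
    fs               = 1000,
    tonic            = 0.2,    # resting envelope level
    envelope_amp     = 0.6,    # peak synergy activation amplitude
    envelope_ramp_s  = 0.05,
    trial_jitter     = 0.25,   # per-trial multiplicative amplitude jitter
    kernel_amp       = 0.8,    # spike-locked kernel amplitude
    pure_onset_ms    = 6,      # pure-type kernel: onset 6 ms, PWHM 5 ms
    pure_pwhm_ms     = 5,
    sync_onset_ms    = 0,      # synchrony-type: onset ~0, PWHM 10 ms
    sync_pwhm_ms     = 10,
    noise_sd         = 0.1,
    artifact_frac    = 0,      # fraction of samples hit by 10x-SD artifacts
    mod_probs        = list(   # across-condition rewiring prevalences
      SSAT = c(merging = 0.5, unmatched = 0.2, preserved = 0.3),
      CoST = c(merging = 0.2, unmatched = 0.6, preserved = 0.2)
    ),
    unmatched_sp_max = 0.6,    # NNLS-mixture similarity bound for unmatched
    merge_coef_range = c(0.35, 0.65)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown sim_config fields: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$n_synergies <= cfg$n_muscles, cfg$base_rate >= 0, cfg$stim_rate >= 0)
  structure(cfg, class = "sim_config")
}

# Raised-cosine post-spike kernel, parameterized by onset and PWHM:
# support [onset, onset + 2*pwhm], peak at onset + pwhm, value in [0, 1].
raised_cosine_kernel <- function(onset_ms, pwhm_ms, fs = 1000) {
  tau <- seq(0, onset_ms + 2 * pwhm_ms, by = 1000 / fs)
  peak <- onset_ms + pwhm_ms
  k <- ifelse(abs(tau - peak) <= pwhm_ms,
              0.5 * (1 + cos(pi * (tau - peak) / pwhm_ms)), 0)
  list(lag_ms = tau, values = k, peak_ms = peak)
}

#' Plant ground-truth synergies, fields and rewiring labels
#'
#' Builds the generative ground truth the recovery tests are scored
#' against: a non-negative, column-normalized synergy matrix `W_true` in
#' which every muscle carries weight > 0.25 in at least one synergy; per
#' unit, a preferred synergy (its SST muscle field equals that synergy), a
#' pure- or synchrony-type post-spike kernel, a smooth locus tuning for its
#' firing rate centred on its preferred synergy's active loci, and SSAT /
#' CoST muscle fields generated as preserved (same field), merging (a
#' non-negative mixture of >= 2 planted synergies including the preferred
#' one, per-synergy coefficients >= 0.3) or unmatched (rejection-sampled so
#' that no non-negative mixture of the planted synergies reconstructs the
#' field at scalar product >= 0.6).
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `"ground_truth"`: `muscles`, `W_true`
#'   `[n_muscles x n_synergies]`, `synergy_tuning` (per-synergy locus
#'   tuning), and `units` (list; see fields above).
#' @export
make_ground_truth <- function(cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  with_stage_seed(seed, "ground_truth", {
    m <- cfg$n_muscles; N <- cfg$n_synergies
    # partition muscles into synergy groups: dominant + secondary weights
    groups <- split(seq_len(m), rep(seq_len(N), length.out = m))
    W <- matrix(runif(m * N, 0, 0.08), m, N)
    for (i in seq_len(N)) {
      g <- groups[[i]]
      W[g[1], i] <- runif(1, 0.85, 0.95)
      if (length(g) > 1) W[g[-1], i] <- runif(length(g) - 1, 0.38, 0.5)
    }
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
    dimnames(W) <- list(cfg$muscles, paste0("W", seq_len(N)))

    # per-synergy locus tuning: centres spread across the rostrocaudal range
    centers <- seq(2, cfg$n_loci - 1, length.out = N)
    tuning <- tibble::tibble(
      synergy = seq_len(N),
      center = centers + runif(N, -0.5, 0.5),
      width = cfg$n_loci / 5
    )

    units <- purrr::map(seq_len(cfg$n_units), function(u) {
      pref <- ((u - 1) %% N) + 1
      type <- if (u %% 2 == 1) "pure" else "synchrony"
      unit <- list(
        unit_id = sprintf("unit%02d", u),
        type = type,
        kernel_onset_ms = if (type == "pure") cfg$pure_onset_ms else cfg$sync_onset_ms,
        kernel_pwhm_ms = if (type == "pure") cfg$pure_pwhm_ms else cfg$sync_pwhm_ms,
        preferred_synergy = pref,
        rate_center = tuning$center[pref] + runif(1, -0.5, 0.5),
        rate_width = if (is.na(cfg$rate_width_loci)) cfg$n_loci / 5 else
          cfg$rate_width_loci
      )
      fields <- list(SST = as.numeric(W[, pref]))
      modification <- list()
      for (cond in intersect(cfg$conditions, c("SSAT", "CoST"))) {
        if (N == 1) {
          form <- "preserved"  # no second synergy to merge with
        } else {
          p <- cfg$mod_probs[[cond]]
          form <- sample(names(p), 1, prob = p)
        }
        gen <- switch(form,
          preserved = list(field = fields$SST, coefficients = NULL),
          merging = {
            other <- sample(setdiff(seq_len(N), pref), 1)
            c1 <- runif(1, cfg$merge_coef_range[1], cfg$merge_coef_range[2])
            co <- numeric(N); co[pref] <- c1; co[other] <- 1 - c1
            v <- as.numeric(W %*% co)
            list(field = v / sqrt(sum(v^2)), coefficients = co)
          },
          unmatched = {
            field <- NULL
            for (try in seq_len(1000)) {
              supp <- sample(m, 2)
              v <- numeric(m); v[supp] <- runif(2, 0.4, 1)
              v <- v / sqrt(sum(v^2))
              if (nnls_reconstruct(v, W)$reconstruction_sp < cfg$unmatched_sp_max) {
                field <- v; break
              }
            }
            if (is.null(field)) {
              stop("infeasible unmatched-field constraints after 1000 attempts")
            }
            list(field = field, coefficients = NULL)
          })
        fields[[cond]] <- gen$field
        modification[[cond]] <- list(form = form, coefficients = gen$coefficients)
      }
      c(unit, list(fields = fields, modification = modification))
    })
    structure(list(muscles = cfg$muscles, W_true = W, synergy_tuning = tuning,
                   units = units),
              class = "ground_truth")
  })
}

# Unit-scaled Gaussian locus tuning evaluated at locus index i.
locus_gain <- function(i, center, width) exp(-((i - center)^2) / (2 * width^2))

#' Build the stimulation trial table
#'
#' Rostral-to-caudal mapping with `trials_per_locus` SST then SSAT trials
#' per locus, followed by the CoST co-stimulation series (moving fibre
#' caudal-to-rostral, second fibre fixed at the rostral-most locus), with
#' the study's train/intertrial timing.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (SSAT power draws).
#' @return A [trial_table()] tibble with a `locus_index` column appended.
#' @export
make_trials <- function(cfg = sim_config(), seed = 1L) {
  with_stage_seed(seed, "trials", {
    train_s <- cfg$train_ms / 1000
    period <- train_s + cfg$intertrial_s
    rows <- list()
    k <- 0
    add <- function(cond, locus_idx, locus2_idx = NA) {
      k <<- length(rows) + 1
      on <- cfg$lead_in_s + (k - 1) * period
      rows[[k]] <<- tibble::tibble(
        trial_id = sprintf("t%04d", k),
        condition = cond,
        locus_index = locus_idx,
        locus_um = (locus_idx - 1) * cfg$locus_step_um,
        locus2_um = if (is.na(locus2_idx)) NA_real_ else
          (locus2_idx - 1) * cfg$locus_step_um,
        power_frac = if (cond == "SSAT") runif(1, 1.2, 1.5) else 1,
        stim_on_s = on, stim_off_s = on + train_s
      )
    }
    for (loc in seq_len(cfg$n_loci)) {
      if ("SST" %in% cfg$conditions) {
        for (r in seq_len(cfg$trials_per_locus)) add("SST", loc)
      }
      if ("SSAT" %in% cfg$conditions) {
        for (r in seq_len(cfg$trials_per_locus)) add("SSAT", loc)
      }
    }
    if ("CoST" %in% cfg$conditions) {
      for (loc in rev(seq_len(cfg$n_loci))) {
        for (r in seq_len(cfg$trials_per_locus)) add("CoST", loc, locus2_idx = 1)
      }
    }
    out <- dplyr::bind_rows(rows)
    validate_trials(out)
    out
  })
}

#' Simulate stimulus-locked spike trains
#'
#' Inhomogeneous Poisson spiking: `base_rate` outside stimulation and
#' `stim_rate * g(locus)` during each 200 ms train, where `g` is the unit's
#' smooth (Gaussian, unit-peak) locus tuning. A 1 ms refractory period is
#' enforced by thinning.
#'
#' @param gt A [make_ground_truth()] object.
#' @param trials Trial table from [make_trials()] (needs `locus_index`).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param duration_s Recording length; default covers all trials plus lead
#'   out.
#' @return A spike table ([spike_table()] layout).
#' @export
simulate_spikes <- function(gt, trials, cfg = sim_config(), seed = 1L,
                            duration_s = NULL) {
  if (is.null(duration_s)) duration_s <- max(trials$stim_off_s) + cfg$lead_in_s
  with_stage_seed(seed, "spikes", {
    purrr::map_dfr(gt$units, function(unit) {
      times <- numeric(0)
      if (cfg$base_rate > 0) {
        n_base <- stats::rpois(1, cfg$base_rate * duration_s)
        times <- runif(n_base, 0, duration_s)
      }
      for (i in seq_len(nrow(trials))) {
        g <- locus_gain(trials$locus_index[i], unit$rate_center, unit$rate_width)
        extra <- max(cfg$stim_rate * g - cfg$base_rate, 0)
        if (extra > 0) {
          span <- trials$stim_off_s[i] - trials$stim_on_s[i]
          n_stim <- stats::rpois(1, extra * span)
          times <- c(times, runif(n_stim, trials$stim_on_s[i], trials$stim_off_s[i]))
        }
      }
      times <- sort(times)
      if (length(times) > 1) {  # 1 ms refractory enforcement
        keep <- logical(length(times)); keep[1] <- TRUE
        last <- times[1]
        for (j in 2:length(times)) {
          if (times[j] - last >= 0.001) { keep[j] <- TRUE; last <- times[j] }
        }
        times <- times[keep]
      }
      tibble::tibble(unit_id = unit$unit_id, time_s = times)
    })
  })
}

#' Simulate envelope-domain EMG
#'
#' The signal is `tonic + W_true %*% t(C) + spike-locked kernels + noise`,
#' clamped at zero. Activation envelopes `C` are smooth raised-cosine
#' ramps over each trial's response window, scaled per synergy by its locus
#' tuning, the trial's laser power fraction and a per-trial jitter; CoST
#' trials superpose the moving and fixed-locus drives. Every spike adds a
#' raised-cosine kernel (the unit's planted onset/PWHM) times the unit's
#' condition-specific muscle field; spikes outside any trial use the SST
#' field.
#'
#' @param gt Ground truth from [make_ground_truth()].
#' @param spikes Spike table from [simulate_spikes()].
#' @param trials Trial table from [make_trials()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param duration_s Recording length (defaults as in [simulate_spikes()]).
#' @return An envelope-domain [emg_recording()] at `cfg$fs`, with ground
#'   truth attached as attributes: `"activations"` (the true
#'   activation-envelope matrix `[n_samples x n_synergies]`) and
#'   `"artifact_idx"` (per-muscle sample indices of injected artifacts).
#' @export
simulate_emg <- function(gt, spikes, trials, cfg = sim_config(), seed = 1L,
                         duration_s = NULL) {
  if (is.null(duration_s)) duration_s <- max(trials$stim_off_s) + cfg$lead_in_s
  fs <- cfg$fs
  n <- as.integer(round(duration_s * fs))
  m <- length(gt$muscles)
  N <- ncol(gt$W_true)

  with_stage_seed(seed, "emg", {
    # synergy activation envelopes: cosine ramp up over envelope_ramp_s from
    # stimulus onset, plateau through offset + 100 ms (motor responses
    # outlast the train), then a 100 ms cosine decay. The plateau spans the
    # stationary-trigger region used by the SpTA stage, so trigger-aligned
    # envelope averages are flat there.
    C <- matrix(0, n, N)
    decay_s <- 0.1
    for (i in seq_len(nrow(trials))) {
      i0 <- as.integer(floor(trials$stim_on_s[i] * fs)) + 1L
      i1 <- min(as.integer(floor((trials$stim_off_s[i] + 0.1 + decay_s) * fs)), n)
      len <- i1 - i0 + 1L
      ramp_n <- max(1L, as.integer(cfg$envelope_ramp_s * fs))
      decay_n <- max(1L, as.integer(decay_s * fs))
      shape <- rep(1, len)
      up <- seq_len(min(ramp_n, len))
      shape[up] <- 0.5 * (1 - cos(pi * up / ramp_n))
      dn <- seq_len(min(decay_n, len))
      shape[len - dn + 1L] <- pmin(shape[len - dn + 1L],
                                   0.5 * (1 - cos(pi * dn / decay_n)))
      for (s in seq_len(N)) {
        gain <- locus_gain(trials$locus_index[i], gt$synergy_tuning$center[s],
                           gt$synergy_tuning$width[s])
        if (trials$condition[i] == "CoST" && is.finite(trials$locus2_um[i])) {
          idx2 <- trials$locus2_um[i] / cfg$locus_step_um + 1
          gain <- gain + locus_gain(idx2, gt$synergy_tuning$center[s],
                                    gt$synergy_tuning$width[s])
        }
        amp <- cfg$envelope_amp * gain * trials$power_frac[i] *
          runif(1, 1 - cfg$trial_jitter, 1 + cfg$trial_jitter)
        C[i0:i1, s] <- C[i0:i1, s] + amp * shape
      }
    }
    sig <- cfg$tonic + gt$W_true %*% t(C)

    # spike-locked muscle-field kernels
    for (unit in gt$units) {
      kern <- raised_cosine_kernel(unit$kernel_onset_ms, unit$kernel_pwhm_ms, fs)
      kv <- cfg$kernel_amp * kern$values
      lag0 <- as.integer(round(kern$lag_ms[1] * fs / 1000))
      tt <- spikes$time_s[spikes$unit_id == unit$unit_id]
      if (!length(tt)) next
      tr_idx <- findInterval(tt, trials$stim_on_s)
      cond <- rep("SST", length(tt))
      inside <- tr_idx >= 1 &
        tt <= trials$stim_off_s[pmax(tr_idx, 1)] + 0.1
      cond[inside] <- trials$condition[tr_idx[inside]]
      for (j in seq_along(tt)) {
        f <- unit$fields[[cond[j]]]
        if (is.null(f)) f <- unit$fields$SST
        i0 <- as.integer(floor(tt[j] * fs)) + 1L + lag0
        span <- i0:(i0 + length(kv) - 1L)
        ok <- span >= 1L & span <= n
        if (!any(ok)) next
        sig[, span[ok]] <- sig[, span[ok]] + outer(f, kv[ok])
      }
    }

    sig <- sig + matrix(rnorm(m * n, 0, cfg$noise_sd), m, n)
    sig[sig < 0] <- 0
    # optional high-amplitude artifact injection (10x the recorded SD)
    artifact_idx <- vector("list", m)
    if (cfg$artifact_frac > 0) {
      for (j in seq_len(m)) {
        n_art <- as.integer(round(cfg$artifact_frac * n))
        if (n_art > 0) {
          at <- sample.int(n, n_art)
          sig[j, at] <- sig[j, at] + 10 * sd(sig[j, ])
          artifact_idx[[j]] <- sort(at)
        }
      }
    }
    rec <- emg_recording(sig, fs = fs, muscles = gt$muscles, t0 = 0,
                         domain = "envelope")
    attr(rec, "activations") <- C
    attr(rec, "artifact_idx") <- artifact_idx
    rec
  })
}

#' Generate a complete synthetic dataset
#'
#' Ground truth, trials, spikes and EMG from one seed; optionally writes the
#' dataset bundle (plus `ground_truth.json`) to a directory. Deterministic:
#' the same seed yields byte-identical bundles.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer master seed.
#' @param dir Optional bundle directory.
#' @param config Analysis [sf_config()] stored with the bundle.
#' @return List with `emg`, `spikes`, `trials`, `ground_truth`, `config`.
#' @export
generate_dataset <- function(cfg = sim_config(), seed = 1L, dir = NULL,
                             config = sf_config()) {
  gt <- make_ground_truth(cfg, seed)
  trials <- make_trials(cfg, seed)
  spikes <- simulate_spikes(gt, trials, cfg, seed)
  emg <- simulate_emg(gt, spikes, trials, cfg, seed)
  out <- list(emg = emg, spikes = spikes, trials = trials, ground_truth = gt,
              config = config)
  if (!is.null(dir)) {
    write_dataset(dir, emg, spikes, trials, config,
                  ground_truth = ground_truth_json(gt))
  }
  out
}

# JSON-friendly ground-truth schema: W_true as a list of columns, units as
# records with per-condition fields and modification labels.
ground_truth_json <- function(gt) {
  list(
    muscles = gt$muscles,
    W_true = lapply(seq_len(ncol(gt$W_true)), function(i) unname(gt$W_true[, i])),
    synergy_tuning = as.list(gt$synergy_tuning),
    units = lapply(gt$units, function(u) {
      u$fields <- lapply(u$fields, unname)
      u$modification <- lapply(u$modification, function(mm) {
        list(form = mm$form,
             coefficients = if (is.null(mm$coefficients)) NULL else unname(mm$coefficients))
      })
      u
    })
  )
}
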