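# Dataset bundle layout (one directory):
#   emg.tsv       samples x muscles, tab-delimited, header = muscle labels,
#                 numbers printed with 17 significant digits (lossless)
#   emg_meta.yaml fs, t0, domain
#   spikes.tsv    unit_id, time_s
#   trials.tsv    trial_id, condition, locus_um, locus2_um, power_frac,
#                 stim_on_s, stim_off_s
#   config.yaml   sf_config
#   ground_truth.json (optional, written by the simulator)

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_num_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) if (is.numeric(df2[[j]])) df2[[j]] <- fmt_num(df2[[j]])
  lines <- c(paste(names(df2), collapse = "\t"),
             do.call(paste, c(unname(as.list(df2)), sep = "\t")))
  writeLines(lines, path)
}

#' Write a dataset bundle
#'
#' Serializes an EMG recording, spike table, trial table and configuration
#' into a directory of plain-text files. Numbers are written with 17
#' significant digits so that `read_dataset(write_dataset(...))` is
#' bit-identical.
#'
#' @param dir Target directory (created if absent).
#' @param emg An [emg_recording()].
#' @param spikes A spike table ([spike_table()] layout).
#' @param trials A trial table ([trial_table()] layout).
#' @param config An [sf_config()].
#' @param ground_truth Optional ground-truth list (from the simulator),
#'   written as `ground_truth.json`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dir, emg, spikes, trials, config = sf_config(),
                          ground_truth = NULL) {
  stopifnot(inherits(emg, "emg_recording"))
  validate_spikes(spikes)
  validate_trials(trials)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  m <- t(emg$signal)  # samples x muscles
  lines <- c(paste(emg$muscles, collapse = "\t"),
             do.call(paste, c(lapply(seq_len(ncol(m)), function(j) fmt_num(m[, j])),
                              sep = "\t")))
  writeLines(lines, file.path(dir, "emg.tsv"))
  yaml::write_yaml(list(fs = emg$fs, t0 = emg$t0, domain = emg$domain),
                   file.path(dir, "emg_meta.yaml"))
  write_num_tsv(spikes[, c("unit_id", "time_s")], file.path(dir, "spikes.tsv"))
  write_num_tsv(trials[, c("trial_id", "condition", "locus_um", "locus2_um",
                           "power_frac", "stim_on_s", "stim_off_s")],
                file.path(dir, "trials.tsv"))
  write_config(config, file.path(dir, "config.yaml"))
  if (!is.null(ground_truth)) {
    jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Read a dataset bundle
#'
#' @param dir Directory written by [write_dataset()] (or by hand in the same
#'   layout).
#' @return A list with elements `emg` ([emg_recording()]), `spikes` (tibble),
#'   `trials` (tibble), `config` ([sf_config()]) and, when present,
#'   `ground_truth` (list).
#' @export
read_dataset <- function(dir) {
  need <- c("emg.tsv", "emg_meta.yaml", "spikes.tsv", "trials.tsv", "config.yaml")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) stop("dataset bundle incomplete; missing: ",
                            paste(missing, collapse = ", "))

  meta <- yaml::read_yaml(file.path(dir, "emg_meta.yaml"))
  con <- file(file.path(dir, "emg.tsv"), "r")
  on.exit(close(con), add = TRUE)
  header <- strsplit(readLines(con, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!length(header) || !all(nzchar(header))) stop("missing channel labels in emg.tsv")
  vals <- scan(con, what = numeric(), sep = "\t", quiet = TRUE)
  sig <- matrix(vals, nrow = length(header))  # muscles x samples (column-major fill)
  emg <- emg_recording(sig, fs = meta$fs, muscles = header, t0 = meta$t0,
                       domain = meta$domain)

  spikes <- tibble::as_tibble(utils::read.delim(
    file.path(dir, "spikes.tsv"),
    colClasses = c(unit_id = "character", time_s = "numeric")))
  validate_spikes(spikes, emg)

  trials <- tibble::as_tibble(utils::read.delim(
    file.path(dir, "trials.tsv"),
    colClasses = c(trial_id = "character", condition = "character",
                   locus_um = "numeric", locus2_um = "numeric",
                   power_frac = "numeric", stim_on_s = "numeric",
                   stim_off_s = "numeric")))
  validate_trials(trials)

  out <- list(emg = emg, spikes = spikes, trials = trials,
              config = read_config(file.path(dir, "config.yaml")))
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    out$ground_truth <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  }
  out
}
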