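#' Construct an epoch set
#'
#' Single-trial EEG epochs time-locked to critical-word onset. The default
#' grid is the half-open window [-100, 900) ms sampled at 250 Hz: 250
#' samples, sample k (0-based) at (-100 + 4k) ms. Voltages are in microvolts.
#'
#' @param voltages numeric array `trials x channels x samples` (µV).
#' @param channel_labels character vector, one unique label per channel.
#' @param trial_meta tibble with one row per trial (columns such as
#'   `subject`, `frame_id`, `condition`, `critical_word`).
#' @param srate sampling rate in Hz.
#' @param window numeric length-2, epoch span in ms relative to word onset
#'   (half-open on the right).
#' @param rejected logical per trial; defaults to none rejected.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(voltages, channel_labels, trial_meta,
                      srate = 250, window = c(-100, 900),
                      rejected = NULL) {
  stopifnot(length(dim(voltages)) == 3L)
  n_trials <- dim(voltages)[1]
  n_chan <- dim(voltages)[2]
  n_samp <- dim(voltages)[3]
  if (length(channel_labels) != n_chan || anyDuplicated(channel_labels)) {
    stop("channel_labels must be unique and match the channel dimension",
         call. = FALSE)
  }
  expected <- round((window[2] - window[1]) * srate / 1000)
  if (n_samp != expected) {
    stop("sample count ", n_samp, " inconsistent with window/srate (expected ",
         expected, ")", call. = FALSE)
  }
  if (nrow(trial_meta) != n_trials) {
    stop("trial_meta must have one row per trial", call. = FALSE)
  }
  if (is.null(rejected)) rejected <- rep(FALSE, n_trials)
  stopifnot(length(rejected) == n_trials)
  structure(list(
    voltages = voltages,
    channel_labels = channel_labels,
    trial_meta = tibble::as_tibble(trial_meta),
    srate = srate,
    window = window,
    rejected = rejected
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set>", dim(x$voltages)[1], "trials x",
      dim(x$voltages)[2], "channels x", dim(x$voltages)[3], "samples @",
      x$srate, "Hz,", sum(x$rejected), "rejected\n")
  invisible(x)
}

#' Sample times of an epoch set (ms)
#' @param epochs an `epoch_set`.
#' @return numeric vector of sample times in ms (left edge of each sample).
#' @export
epoch_times <- function(epochs) {
  step <- 1000 / epochs$srate
  epochs$window[1] + step * (seq_len(dim(epochs$voltages)[3]) - 1L)
}

# indices of samples falling in the half-open interval [from, to) ms
window_samples <- function(epochs, from, to) {
  t <- epoch_times(epochs)
  which(t >= from & t < to)
}

#' Re-reference epochs to the mastoid average
#'
#' Subtracts, sample-wise, the mean of the left and right mastoid channels
#' from every channel.
#'
#' @param epochs an `epoch_set`.
#' @param mastoid_labels character length-2, the mastoid channel labels.
#' @return a re-referenced `epoch_set`.
#' @export
rereference <- function(epochs, mastoid_labels = c("A1", "A2")) {
  stopifnot(inherits(epochs, "epoch_set"), length(mastoid_labels) == 2L)
  idx <- match(mastoid_labels, epochs$channel_labels)
  if (anyNA(idx)) {
    stop("mastoid channel(s) missing: ",
         paste(mastoid_labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  ref <- (epochs$voltages[, idx[1], , drop = FALSE] +
          epochs$voltages[, idx[2], , drop = FALSE]) / 2
  out <- epochs
  out$voltages <- epochs$voltages - ref[, rep(1, dim(epochs$voltages)[2]), ,
                                        drop = FALSE]
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean voltage over the pre-onset
#' baseline window (default the 100 ms preceding word onset).
#'
#' @param epochs an `epoch_set`.
#' @param baseline numeric length-2 span in ms, half-open.
#' @return a baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline = c(-100, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$window[1] > baseline[1] || epochs$window[2] < baseline[2]) {
    stop("epoch window does not cover the baseline span", call. = FALSE)
  }
  idx <- window_samples(epochs, baseline[1], baseline[2])
  if (length(idx) == 0L) stop("baseline span contains no samples",
                              call. = FALSE)
  base <- apply(epochs$voltages[, , idx, drop = FALSE], c(1, 2), mean)
  out <- epochs
  out$voltages <- epochs$voltages -
    array(base, dim = dim(epochs$voltages))
  out
}

#' Flag artifact trials
#'
#' A trial is flagged if, on any examined channel, the peak-to-peak voltage
#' range exceeds `p2p_threshold` (blinks, eye movements, saturation) or the
#' range stays below `flat_threshold` (flat channel). Flagging is monotone:
#' a stricter peak-to-peak threshold flags a superset of trials.
#'
#' @param epochs an `epoch_set`.
#' @param p2p_threshold peak-to-peak rejection threshold in µV.
#' @param flat_threshold flatline range threshold in µV.
#' @param channels channel labels to examine; defaults to all channels.
#' @return the `epoch_set` with its `rejected` flags updated (a trial
#'   already rejected stays rejected).
#' @export
reject_artifacts <- function(epochs, p2p_threshold = 100,
                             flat_threshold = 0.5, channels = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (p2p_threshold <= 0 || flat_threshold <= 0) {
    stop("artifact thresholds must be positive", call. = FALSE)
  }
  if (is.null(channels)) channels <- epochs$channel_labels
  idx <- match(channels, epochs$channel_labels)
  if (anyNA(idx)) {
    stop("unknown channel(s): ", paste(channels[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  v <- epochs$voltages[, idx, , drop = FALSE]
  rng <- apply(v, c(1, 2), function(x) max(x) - min(x))
  bad <- apply(rng > p2p_threshold | rng < flat_threshold, 1, any)
  out <- epochs
  out$rejected <- epochs$rejected | bad
  out
}

#' Extract single-trial N400 amplitudes
#'
#' Mean voltage over the N400 window (default 300-500 ms post-onset,
#' half-open) for each retained trial at each electrode of the
#' centroparietal cluster. One row per trial x electrode; rejected trials
#' are dropped.
#'
#' @param epochs a baseline-corrected `epoch_set`.
#' @param cluster_labels electrode labels to extract; defaults to the nine
#'   centroparietal N400 electrodes.
#' @param window numeric length-2 span in ms, half-open.
#' @return a tibble (`trial_amplitude_table`) with trial metadata plus
#'   `electrode` and `amplitude` (µV).
#' @export
n400_amplitude <- function(epochs, cluster_labels = N400_CLUSTER,
                           window = c(300, 500)) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- match(cluster_labels, epochs$channel_labels)
  if (anyNA(idx)) {
    stop("unknown electrode label(s): ",
         paste(cluster_labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  sidx <- window_samples(epochs, window[1], window[2])
  if (length(sidx) == 0L) stop("amplitude window contains no samples",
                               call. = FALSE)
  keep <- which(!epochs$rejected)
  amp <- apply(epochs$voltages[keep, idx, sidx, drop = FALSE], c(1, 2), mean)
  meta <- epochs$trial_meta[keep, , drop = FALSE]
  out <- tibble::tibble(
    trial = rep(seq_along(keep), each = length(cluster_labels)),
    electrode = rep(cluster_labels, times = length(keep)),
    amplitude = as.vector(t(amp))
  )
  dplyr::bind_cols(
    meta[out$trial, , drop = FALSE],
    out[c("electrode", "amplitude")]
  )
}

#' Grand-average waveforms by condition
#'
#' Sample-wise mean over retained trials within each condition, per channel.
#'
#' @param epochs an `epoch_set`.
#' @param by trial-metadata column to average within (default
#'   `"condition"`).
#' @return a tibble with columns `by`, `channel`, `time_ms`, `voltage`.
#' @export
grand_average <- function(epochs, by = "condition") {
  stopifnot(inherits(epochs, "epoch_set"), by %in% names(epochs$trial_meta))
  keep <- !epochs$rejected
  groups <- epochs$trial_meta[[by]][keep]
  if (length(groups) == 0L) stop("no retained trials", call. = FALSE)
  v <- epochs$voltages[keep, , , drop = FALSE]
  t_ms <- epoch_times(epochs)
  out <- lapply(unique(groups), function(g) {
    rows <- which(groups == g)
    m <- apply(v[rows, , , drop = FALSE], c(2, 3), mean)
    tibble::tibble(
      group = g,
      channel = rep(epochs$channel_labels, times = length(t_ms)),
      time_ms = rep(t_ms, each = length(epochs$channel_labels)),
      voltage = as.vector(m)
    )
  })
  out <- dplyr::bind_rows(out)
  names(out)[1] <- by
  out
}

#' Difference wave between two conditions
#'
#' Sample-wise `condition - reference` on grand averages; by convention the
#' reference is the Best Completion condition.
#'
#' @param grand a grand-average tibble from [grand_average()].
#' @param condition condition to contrast.
#' @param reference reference condition (default `"Best"`).
#' @return tibble `channel`, `time_ms`, `voltage` of the difference wave.
#' @export
difference_wave <- function(grand, condition, reference = "Best") {
  by <- names(grand)[1]
  present <- unique(grand[[by]])
  for (g in c(condition, reference)) {
    if (!g %in% present) stop("condition not present: ", g, call. = FALSE)
  }
  a <- grand[grand[[by]] == condition, ]
  b <- grand[grand[[by]] == reference, ]
  stopifnot(identical(a$channel, b$channel), identical(a$time_ms, b$time_ms))
  tibble::tibble(channel = a$channel, time_ms = a$time_ms,
                 voltage = a$voltage - b$voltage)
}
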