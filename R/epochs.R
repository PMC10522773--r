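# Core containers: epochs_set (trials x channels x samples) and evoked
# (channels x samples). Times are seconds relative to stimulus onset; sample
# i (1-based) lies at t0 + (i-1)/srate; windows are [start, end).

#' Construct an epoched multichannel EEG container
#'
#' The central data structure of the package: a `trials x channels x samples`
#' array of voltages together with its sampling metadata, per-trial condition
#' labels, subject identifiers and (for simulated data) the ground-truth
#' latency of the injected component.
#'
#' @param data numeric array `[n_trials, n_channels, n_samples]`, volts.
#' @param srate sampling rate in Hz.
#' @param t0 time of the first sample in seconds relative to stimulus onset
#'   (negative for a pre-stimulus baseline).
#' @param channel_names character vector of channel labels (10-20 system).
#' @param subject per-trial subject identifier (recycled if length 1).
#' @param condition per-trial condition label, e.g. `"standard"`/`"deviant"`
#'   (recycled if length 1).
#' @param source_subject per-trial identifier of the subject whose data
#'   donated the background EEG; used for subject-grouped cross-validation.
#'   Defaults to `subject`.
#' @param true_latency optional per-trial ground-truth latency of the
#'   component peak, seconds (`NA` for trials without an injected component).
#' @return An object of class `epochs_set`.
#' @export
epochs_set <- function(data, srate, t0, channel_names,
                       subject = "s01", condition = "deviant",
                       source_subject = NULL, true_latency = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  n <- dim(data)[1L]
  if (dim(data)[2L] != length(channel_names))
    stop("n_channels does not match length(channel_names)")
  if (!all(is.finite(data))) stop("non-finite samples in epoch data")
  if (!(is.numeric(srate) && srate > 0)) stop("srate must be positive")
  subject <- rep_len(as.character(subject), n)
  condition <- rep_len(as.character(condition), n)
  source_subject <- if (is.null(source_subject)) subject
                    else rep_len(as.character(source_subject), n)
  if (is.null(true_latency)) true_latency <- rep(NA_real_, n)
  true_latency <- rep_len(as.numeric(true_latency), n)
  span <- c(t0, t0 + dim(data)[3L] / srate)
  ok <- is.na(true_latency) |
    (true_latency >= span[1L] & true_latency <= span[2L])
  if (!all(ok)) stop("true_latency outside the epoch span for trial(s): ",
                     paste(which(!ok), collapse = ", "))
  structure(list(data = data, srate = srate, t0 = t0,
                 channel_names = as.character(channel_names),
                 subject = subject, condition = condition,
                 source_subject = source_subject,
                 true_latency = true_latency),
            class = "epochs_set")
}

#' Construct an averaged (evoked) response
#'
#' @param data numeric matrix `[n_channels, n_samples]`, volts.
#' @param srate sampling rate, Hz.
#' @param t0 time of the first sample, seconds.
#' @param channel_names channel labels.
#' @param n_trials_averaged number of trials entering the average.
#' @return An object of class `evoked`.
#' @export
evoked <- function(data, srate, t0, channel_names, n_trials_averaged = 1L) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_names),
            all(is.finite(data)), n_trials_averaged >= 1)
  structure(list(data = data, srate = srate, t0 = t0,
                 channel_names = as.character(channel_names),
                 n_trials_averaged = as.integer(n_trials_averaged)),
            class = "evoked")
}

#' @export
print.epochs_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epochs_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$srate))
  cat(sprintf("  span %.3f..%.3f s | subjects: %d | conditions: %s\n",
              x$t0, x$t0 + d[3L] / x$srate,
              length(unique(x$subject)),
              paste(names(table(x$condition)), table(x$condition),
                    sep = ":", collapse = " ")))
  if (any(!is.na(x$true_latency)))
    cat(sprintf("  ground-truth latencies on %d trials\n",
                sum(!is.na(x$true_latency))))
  invisible(x)
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("<evoked> %d channels x %d samples @ %g Hz (avg of %d trials)\n",
              nrow(x$data), ncol(x$data), x$srate, x$n_trials_averaged))
  invisible(x)
}

#' Number of trials in an epochs set
#' @param epochs an `epochs_set`.
#' @return Integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1L]

#' Sample times of an epochs set or evoked
#' @param x an `epochs_set` or `evoked`.
#' @return Numeric vector of sample times in seconds.
#' @export
sample_times <- function(x) {
  n <- if (inherits(x, "evoked")) ncol(x$data) else dim(x$data)[3L]
  x$t0 + (seq_len(n) - 1L) / x$srate
}

# Indices of samples falling in the half-open window [w[1], w[2]).
window_idx <- function(x, window) {
  tt <- sample_times(x)
  idx <- which(tt >= window[1L] - 1e-9 & tt < window[2L] - 1e-9)
  if (!length(idx)) stop("window [", window[1L], ", ", window[2L],
                         ") contains no samples")
  idx
}

# Index of the sample closest to time `t` (seconds).
time_to_sample <- function(x, t) {
  i <- round((t - x$t0) * x$srate) + 1L
  n <- if (inherits(x, "evoked")) ncol(x$data) else dim(x$data)[3L]
  as.integer(pmin(pmax(i, 1L), n))
}

chan_idx <- function(x, channel) {
  i <- match(channel, x$channel_names)
  if (is.na(i)) stop("channel '", channel, "' not found")
  i
}

#' Select trials from an epochs set
#'
#' @param epochs an `epochs_set`.
#' @param i integer or logical trial index.
#' @return The subsetted `epochs_set`.
#' @export
subset_trials <- function(epochs, i) {
  epochs_set(epochs$data[i, , , drop = FALSE], epochs$srate, epochs$t0,
             epochs$channel_names, epochs$subject[i], epochs$condition[i],
             epochs$source_subject[i], epochs$true_latency[i])
}

#' Grand average over trials of a condition
#'
#' Per-sample arithmetic mean of all trials carrying the requested condition
#' label, or of a list of already-averaged `evoked` objects (in which case
#' each input is weighted equally, the conventional grand average).
#'
#' @param x an `epochs_set`, or a list of `evoked` objects.
#' @param condition condition label to select; `NULL` averages all trials.
#' @return An `evoked`.
#' @export
grand_average <- function(x, condition = NULL) {
  if (inherits(x, "epochs_set")) {
    keep <- if (is.null(condition)) rep(TRUE, n_trials(x))
            else x$condition == condition
    if (!any(keep)) stop("empty selection: no trials with condition '",
                         condition, "'")
    m <- apply(x$data[keep, , , drop = FALSE], c(2L, 3L), mean)
    return(evoked(m, x$srate, x$t0, x$channel_names, sum(keep)))
  }
  stopifnot(is.list(x), length(x) >= 1L, all(vapply(x, inherits, TRUE, "evoked")))
  e1 <- x[[1L]]
  for (e in x[-1L])
    if (e$srate != e1$srate || abs(e$t0 - e1$t0) > 1e-9 ||
        !identical(e$channel_names, e1$channel_names))
      stop("incompatible epochs: srate/t0/channels differ across inputs")
  m <- Reduce(`+`, lapply(x, `[[`, "data")) / length(x)
  evoked(m, e1$srate, e1$t0, e1$channel_names,
         sum(vapply(x, `[[`, 1L, "n_trials_averaged")))
}

#' Difference wave between two evoked responses
#'
#' @param a,b `evoked` objects on identical sampling grids and montages.
#' @return An `evoked` holding `a - b`.
#' @export
difference_wave <- function(a, b) {
  if (!identical(a$channel_names, b$channel_names)) {
    bad <- which(a$channel_names != b$channel_names)[1L]
    stop("channel mismatch at position ", bad, ": '",
         a$channel_names[bad], "' vs '", b$channel_names[bad], "'")
  }
  if (a$srate != b$srate || abs(a$t0 - b$t0) > 1e-9)
    stop("incompatible epochs: srate/t0 differ")
  evoked(a$data - b$data, a$srate, a$t0, a$channel_names,
         min(a$n_trials_averaged, b$n_trials_averaged))
}

#' Automatic epoch rejection
#'
#' Drops trials whose signal on any channel exceeds an absolute-amplitude
#' threshold, whose peak-to-peak amplitude exceeds a maximum, or whose
#' peak-to-peak amplitude falls below a minimum (flat channels).
#'
#' @param epochs an `epochs_set`.
#' @param abs_max absolute-amplitude threshold, volts (default 100 uV).
#' @param ptp_max peak-to-peak maximum, volts (default 150 uV).
#' @param ptp_min peak-to-peak minimum, volts (default 0.5 uV).
#' @return A list with elements `epochs` (surviving trials) and `log`
#'   (data frame of rejected trial indices and the triggering rule).
#' @export
reject_epochs <- function(epochs, abs_max = 100e-6, ptp_max = 150e-6,
                          ptp_min = 0.5e-6) {
  stopifnot(abs_max > 0, ptp_max > 0, ptp_min > 0, ptp_min < ptp_max)
  n <- n_trials(epochs)
  rule <- character(0); idx <- integer(0)
  for (i in seq_len(n)) {
    x <- epochs$data[i, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    ptp <- apply(x, 1L, function(r) diff(range(r)))
    r <- if (max(abs(x)) > abs_max) "abs_max"
         else if (max(ptp) > ptp_max) "ptp_max"
         else if (min(ptp) < ptp_min) "ptp_min"
         else NA_character_
    if (!is.na(r)) { idx <- c(idx, i); rule <- c(rule, r) }
  }
  keep <- setdiff(seq_len(n), idx)
  if (!length(keep))
    warning("all trials rejected; returning an empty epochs_set")
  out <- subset_trials(epochs, if (length(keep)) keep else logical(n))
  list(epochs = out, log = data.frame(trial = idx, rule = rule,
                                      stringsAsFactors = FALSE))
}

#' Realign trials to estimated latencies and average
#'
#' Each trial is shifted by an integer number of samples so that its
#' (estimated) component latency lands on `anchor`, then averaged. Samples
#' shifted in from outside the epoch are treated as missing: the average at
#' each output sample uses only the trials that have valid data there.
#'
#' @param epochs an `epochs_set`.
#' @param latencies numeric vector, one latency (seconds) per trial, or a
#'   latency table (see [latency_table()]) matching the trials.
#' @param anchor target time, seconds, that all latencies are aligned to.
#' @return A list: `evoked` (the realigned average), `counts` (per-sample
#'   trial counts) and `log` (trials excluded because their latency fell
#'   outside the epoch span).
#' @export
realign_and_average <- function(epochs, latencies, anchor) {
  if (is.data.frame(latencies)) latencies <- latencies$latency
  n <- n_trials(epochs)
  stopifnot(length(latencies) == n)
  span <- c(epochs$t0, epochs$t0 + dim(epochs$data)[3L] / epochs$srate)
  if (anchor < span[1L] || anchor >= span[2L])
    stop("anchor outside the epoch span")
  ns <- dim(epochs$data)[3L]
  acc <- matrix(0, dim(epochs$data)[2L], ns)
  cnt <- matrix(0L, dim(epochs$data)[2L], ns)
  bad <- integer(0)
  for (i in seq_len(n)) {
    li <- latencies[i]
    if (is.na(li) || li < span[1L] || li > span[2L]) { bad <- c(bad, i); next }
    k <- round_half_down((anchor - li) * epochs$srate)
    src <- seq_len(ns) - k                     # output j takes input j - k
    ok <- src >= 1L & src <= ns
    acc[, ok] <- acc[, ok] + epochs$data[i, , src[ok]]
    cnt[, ok] <- cnt[, ok] + 1L
  }
  if (all(cnt == 0L)) stop("no trial could be realigned")
  avg <- acc / pmax(cnt, 1L)
  avg[cnt == 0L] <- 0
  list(evoked = evoked(avg, epochs$srate, epochs$t0, epochs$channel_names,
                       n - length(bad)),
       counts = cnt,
       log = data.frame(trial = bad))
}

#' Downsample an epochs set by an integer factor
#'
#' Applies a zero-phase anti-alias low-pass (order-6 Butterworth at 80% of
#' the new Nyquist frequency, forward-backward) along time before keeping
#' every `factor`-th sample, so latencies are not biased by filter delay.
#' Used to bring 500 Hz recordings to the 250 Hz rate the neural networks
#' expect.
#'
#' @param epochs an `epochs_set`.
#' @param factor integer decimation factor.
#' @return The downsampled `epochs_set`.
#' @export
decimate_epochs <- function(epochs, factor = 2L) {
  stopifnot(factor >= 1L)
  if (factor == 1L) return(epochs)
  d <- dim(epochs$data)
  keep <- seq(1L, d[3L], by = factor)
  out <- array(0, c(d[1L], d[2L], length(keep)))
  bf <- signal::butter(6, 0.8 / factor, type = "low")
  for (i in seq_len(d[1L]))
    for (c in seq_len(d[2L])) {
      filtered <- signal::filtfilt(bf, epochs$data[i, c, ])
      out[i, c, ] <- filtered[keep]
    }
  epochs_set(out, epochs$srate / factor, epochs$t0, epochs$channel_names,
             epochs$subject, epochs$condition, epochs$source_subject,
             epochs$true_latency)
}
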