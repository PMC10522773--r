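# Single-trial latency estimators based on template matching: multichannel
# cross-correlation (with optional Woody-style iteration), multichannel
# dynamic time warping, a spatiotemporal LCMV beamformer, and ICA-based
# subspace matching.

#' Build a matching template from a condition difference
#'
#' The template is the difference between the grand averages of the deviant
#' and standard trials, zero-phase low-pass filtered (5 Hz by default) and
#' cropped to the component window. Built from training subjects only when
#' used inside cross-validation.
#'
#' @param epochs an `epochs_set` containing both conditions, or a `list` of
#'   two `evoked` objects (deviant, standard).
#' @param window component window, seconds (P300: `c(0.300, 0.600)`).
#' @param lowpass_hz low-pass cut-off applied to the difference wave.
#' @param channel target channel used to define the template peak.
#' @param search_window admissible window for the component PEAK latency;
#'   defaults to `window`.
#' @return An object of class `template_model`: `waveform`
#'   (channels x samples), `window`, `srate`, `channel`, `channel_names`,
#'   `peak_offset` (seconds from template start to its peak at the target
#'   channel) and `search_window`.
#' @export
build_template <- function(epochs, window = c(0.300, 0.600), lowpass_hz = 5,
                           channel = "Pz", search_window = window) {
  if (inherits(epochs, "epochs_set")) {
    dev <- grand_average(epochs, "deviant")
    std <- grand_average(epochs, "standard")
  } else {
    dev <- epochs[[1L]]; std <- epochs[[2L]]
  }
  d <- difference_wave(dev, std)
  filt <- lowpass_matrix(d$data, d$srate, lowpass_hz)
  idx <- window_idx(d, window)
  wf <- filt[, idx, drop = FALSE]
  ci <- chan_idx(d, channel)
  peak_offset <- (which.max(wf[ci, ]) - 1L) / d$srate
  structure(list(waveform = wf, window = window, srate = d$srate,
                 channel = channel, channel_names = d$channel_names,
                 peak_offset = peak_offset, search_window = search_window),
            class = "template_model")
}

#' @export
print.template_model <- function(x, ...) {
  cat(sprintf(
    "<template_model> %d channels x %d samples @ %g Hz, peak %+.3f s into template\n",
    nrow(x$waveform), ncol(x$waveform), x$srate, x$peak_offset))
  invisible(x)
}

# admissible template start samples (1-based) such that the template peak
# falls inside the search window and the template fits inside the epoch
admissible_starts <- function(epochs, tpl) {
  ns <- dim(epochs$data)[3L]
  lt <- ncol(tpl$waveform)
  po_smp <- round(tpl$peak_offset * epochs$srate)
  pk_lo <- time_to_sample(epochs, tpl$search_window[1L])
  pk_hi <- time_to_sample(epochs, tpl$search_window[2L] - 1 / epochs$srate)
  starts <- (pk_lo:pk_hi) - po_smp
  starts <- starts[starts >= 1L & starts + lt - 1L <= ns]
  if (!length(starts)) stop("search window leaves no admissible template position")
  starts
}

#' Single-trial latency by multichannel cross-correlation
#'
#' For each channel, the Pearson correlation between the template and the
#' trial segment is computed at every admissible lag; the per-channel
#' correlation curves are averaged and the latency is the lag maximizing
#' the averaged curve (plus the template peak offset). Ties break toward
#' the earliest lag. Zero-variance segments contribute a correlation of 0.
#'
#' @param epochs an `epochs_set`.
#' @param tpl a `template_model`.
#' @param channels `"all"` (default) or a character subset of channels to
#'   enter the average.
#' @param weights optional per-channel weights for the curve average
#'   (default unweighted).
#' @param normalized use Pearson correlation (default) or raw
#'   cross-covariance when `FALSE`.
#' @return A latency table.
#' @export
xcorr_latencies <- function(epochs, tpl, channels = "all", weights = NULL,
                            normalized = TRUE) {
  sel <- if (identical(channels, "all")) seq_along(epochs$channel_names)
         else match(channels, epochs$channel_names)
  if (anyNA(sel)) stop("unknown channel in subset")
  starts <- admissible_starts(epochs, tpl)
  lt <- ncol(tpl$waveform)
  seg_cols <- outer(starts, 0:(lt - 1L), `+`)
  if (is.null(weights)) weights <- rep(1, length(sel))
  weights <- weights / sum(weights)
  tt <- sample_times(epochs)
  po_smp <- round(tpl$peak_offset * epochs$srate)
  lat <- numeric(n_trials(epochs))
  for (i in seq_len(n_trials(epochs))) {
    curve <- numeric(length(starts))
    for (jc in seq_along(sel)) {
      c0 <- sel[jc]
      u <- tpl$waveform[c0, ]
      segs <- matrix(epochs$data[i, c0, ][seg_cols], nrow = length(starts))
      if (normalized) {
        sm <- rowMeans(segs)
        ss <- sqrt(rowSums(segs^2) - lt * sm^2)
        um <- mean(u); us <- sqrt(sum(u^2) - lt * um^2)
        num <- segs %*% u - lt * sm * um
        r <- ifelse(ss > 0 & us > 0, num / (ss * us), 0)
      } else {
        r <- segs %*% (u - mean(u)) / lt
      }
      curve <- curve + weights[jc] * as.numeric(r)
    }
    lat[i] <- tt[starts[which.max(curve)] + po_smp]
  }
  latency_table(epochs, lat, method = "xcorr")
}

#' Single-trial latency by multichannel dynamic time warping
#'
#' Dependent multichannel DTW: the local cost between template sample `i`
#' and trial sample `j` is the squared Euclidean distance summed over
#' channels; steps are (1,0), (0,1), (1,1) and the template is fully
#' aligned onto the trial's search region. The latency is the mean trial
#' time of the samples matched to the template's peak sample, constrained
#' to the search window. Note the method is amplitude-sensitive by
#' construction (the cost is an unnormalized distance).
#'
#' @param epochs an `epochs_set`.
#' @param tpl a `template_model`.
#' @return A latency table.
#' @export
dtw_latencies <- function(epochs, tpl) {
  starts <- admissible_starts(epochs, tpl)
  lt <- ncol(tpl$waveform)
  region <- starts[1L]:(starts[length(starts)] + lt - 1L)
  if (length(region) < lt) stop("search region shorter than template")
  tt <- sample_times(epochs)
  i_peak <- round(tpl$peak_offset * epochs$srate) + 1L
  lat <- numeric(n_trials(epochs))
  for (i in seq_len(n_trials(epochs))) {
    seg <- epochs$data[i, , region, drop = TRUE]
    if (is.null(dim(seg))) seg <- matrix(seg, nrow = 1L)
    al <- dtw_align_cpp(tpl$waveform, seg)
    matched <- al$path_j[al$path_i == i_peak]
    est <- mean(tt[region[matched]])
    lat[i] <- min(max(est, tpl$search_window[1L]),
                  tpl$search_window[2L] - 1 / epochs$srate)
  }
  latency_table(epochs, lat, method = "dtw")
}

# covariance of vectorized trial segments across trials and (strided) lags,
# shrunk toward a scaled identity with sample-size-based intensity; a
# degenerate (all-zero) covariance falls back to the identity so the filter
# degenerates gracefully to a matched filter
segment_covariance <- function(epochs, tpl, starts, lag_stride = 8L,
                               shrinkage = "auto") {
  lt <- ncol(tpl$waveform)
  nc <- dim(epochs$data)[2L]
  p <- nc * lt
  use_starts <- starts[seq(1L, length(starts), by = lag_stride)]
  n_seg <- n_trials(epochs) * length(use_starts)
  acc <- matrix(0, p, p)
  mu_acc <- numeric(p)
  for (s in use_starts) {
    # segments for all trials at this lag: (n_trials x p), channel-major
    seg <- epochs$data[, , s:(s + lt - 1L), drop = FALSE]
    X <- matrix(seg, nrow = dim(seg)[1L])
    acc <- acc + crossprod(X)
    mu_acc <- mu_acc + colSums(X)
  }
  mu <- mu_acc / n_seg
  R <- acc / n_seg - tcrossprod(mu)
  scale <- mean(diag(R))
  if (scale <= 0) return(diag(p))
  gamma <- if (identical(shrinkage, "auto")) p / (n_seg + p)
           else as.numeric(shrinkage)
  (1 - gamma) * R + gamma * scale * diag(p)
}

#' Single-trial latency by a spatiotemporal LCMV beamformer
#'
#' The template is vectorized into an activation pattern `h`
#' (channels x samples, flattened channel-major); the covariance `R` of
#' equally sized vectorized trial segments (pooled across trials and
#' strided lags) is shrinkage-regularized; the spatiotemporal filter is
#' `w = R^-1 h / (h' R^-1 h)` (unit gain on the template pattern, minimum
#' variance elsewhere). The beamformer output `w' x(lag)` is computed at
#' every admissible lag and the latency is the argmax plus the template
#' peak offset.
#'
#' @param epochs an `epochs_set`.
#' @param tpl a `template_model`.
#' @param shrinkage `"auto"` (intensity `p / (n_segments + p)` toward a
#'   scaled identity) or a numeric value in `[0, 1]`.
#' @param lag_stride stride of the lags pooled into the covariance.
#' @param noise_epochs optional component-free trials (e.g. the standard
#'   condition) whose segments estimate the covariance; using them avoids
#'   the signal-cancellation bias that arises when the component itself
#'   dominates the covariance. Default: the processed epochs themselves.
#' @return A latency table; the filter is attached as attribute
#'   `"weights"`.
#' @export
beamformer_latencies <- function(epochs, tpl, shrinkage = "auto",
                                 lag_stride = 8L, noise_epochs = NULL) {
  starts <- admissible_starts(epochs, tpl)
  lt <- ncol(tpl$waveform)
  nc <- dim(epochs$data)[2L]
  p <- nc * lt
  cov_src <- if (is.null(noise_epochs)) epochs else noise_epochs
  if (n_trials(cov_src) < p / 10)
    warning("few trials relative to feature count; covariance may be unstable")
  h <- as.numeric(tpl$waveform)          # channel-major vectorization
  R <- segment_covariance(cov_src, tpl, admissible_starts(cov_src, tpl),
                          lag_stride, shrinkage)
  Rh <- tryCatch(solve(R, h), error = function(e)
    stop("singular segment covariance (condition number ~ ",
         format(kappa(R), digits = 3), "); increase shrinkage"))
  w <- Rh / sum(h * Rh)
  tt <- sample_times(epochs)
  po_smp <- round(tpl$peak_offset * epochs$srate)
  lat <- numeric(n_trials(epochs))
  for (i in seq_len(n_trials(epochs))) {
    out <- vapply(starts, function(s)
      sum(w * as.numeric(epochs$data[i, , s:(s + lt - 1L)])), 0)
    lat[i] <- tt[starts[which.max(out)] + po_smp]
  }
  structure(latency_table(epochs, lat, method = "bf"), weights = w)
}

#' Single-trial latency by ICA subspace matching
#'
#' FastICA is fitted on the concatenated deviant epochs; each component is
#' scored by the absolute correlation between its back-projected
#' trial-averaged time course at the target channel and the template's
#' target-channel waveform. The best component (mode `"single"`) or the
#' top-`k` components (mode `"multiple"`, default `k = 3`) span the
#' component subspace; the sensor-space signal reconstructed from that
#' subspace is then passed to [xcorr_latencies()].
#'
#' @param epochs an `epochs_set` (deviant trials).
#' @param tpl a `template_model`.
#' @param mode `"single"` or `"multiple"`.
#' @param k number of components kept in multiple mode.
#' @param seed seed for the unmixing initialisation.
#' @return A latency table; selected components and scores attached as
#'   attribute `"ica"`.
#' @export
ica_latencies <- function(epochs, tpl, mode = c("single", "multiple"),
                          k = 3L, seed = 11L) {
  mode <- match.arg(mode)
  d <- dim(epochs$data)
  nc <- d[2L]; ns <- d[3L]
  # concatenate trials: rows = (time within trial, trial), cols = channels
  Xc <- matrix(aperm(epochs$data, c(3L, 1L, 2L)), ncol = nc)
  fit <- NULL
  for (attempt in 0:1) {
    fit <- with_seed(seed + attempt,
                     ica::icafast(Xc, nc = nc, maxit = 200, tol = 1e-6))
    if (isTRUE(fit$converged) || attempt == 1L) break
  }
  if (!isTRUE(fit$converged))
    warning("ICA did not converge after retry; using last iterate")
  ci <- chan_idx(epochs, tpl$channel)
  idx <- window_idx(epochs, tpl$window)
  tpl_tc <- tpl$waveform[ci, ]
  score <- vapply(seq_len(nc), function(j) {
    bp <- fit$S[, j] * fit$M[ci, j]              # back-projected at target
    avg <- rowMeans(matrix(bp, nrow = ns))       # trial-averaged time course
    suppressWarnings(r <- cor(avg[idx], tpl_tc))
    if (is.na(r)) 0 else abs(r)
  }, 0)
  keep <- if (mode == "single") which.max(score)
          else order(score, decreasing = TRUE)[seq_len(min(k, nc))]
  Xr <- fit$S[, keep, drop = FALSE] %*% t(fit$M[, keep, drop = FALSE])
  rec <- epochs
  rec$data <- aperm(array(Xr, c(ns, d[1L], nc)), c(2L, 3L, 1L))
  out <- xcorr_latencies(rec, tpl)
  out$method <- if (mode == "single") "ica1" else "icak"
  structure(out, ica = list(components = keep, scores = score))
}

#' Iterative (Woody-style) template refinement
#'
#' Per subject: estimate latencies, realign the trials to the mean
#' estimate, re-average, low-pass and re-crop to obtain a subject-specific
#' template, and re-estimate; stops when the mean absolute latency change
#' drops below `tol_samples` or after `max_iter` iterations. A cycle in the
#' latency vectors is detected and stops the iteration with a flag.
#'
#' @param epochs an `epochs_set`.
#' @param tpl0 the initial (training-set) `template_model`.
#' @param base `"xcorr"`, `"dtw"` or `"bf"`.
#' @param max_iter maximum number of iterations.
#' @param tol_samples convergence tolerance on the mean absolute latency
#'   change, in samples.
#' @param lowpass_hz low-pass applied to each updated template.
#' @param ... passed to the base estimator.
#' @return A latency table; per-subject iteration counts attached as
#'   attribute `"trace"`.
#' @export
iterate_latencies <- function(epochs, tpl0, base = c("xcorr", "dtw", "bf"),
                              max_iter = 10L, tol_samples = 1,
                              lowpass_hz = 5, ...) {
  base <- match.arg(base)
  est_fn <- switch(base, xcorr = xcorr_latencies, dtw = dtw_latencies,
                   bf = beamformer_latencies)
  lat <- rep(NA_real_, n_trials(epochs))
  trace <- list()
  for (s in unique(epochs$subject)) {
    sel <- which(epochs$subject == s)
    sub <- subset_trials(epochs, sel)
    tpl <- tpl0
    cur <- est_fn(sub, tpl, ...)$latency
    seen <- list(round(cur * sub$srate))
    n_it <- 1L; flag <- "converged"
    while (n_it < max_iter) {
      anchor <- min(max(mean(cur), tpl0$window[1L]),
                    tpl0$window[2L] - 1 / sub$srate)
      ra <- realign_and_average(sub, cur, anchor)
      tpl <- tryCatch(
        build_template(list(ra$evoked,
                            evoked(matrix(0, nrow(ra$evoked$data),
                                          ncol(ra$evoked$data)),
                                   sub$srate, sub$t0, sub$channel_names)),
                       window = tpl0$window, lowpass_hz = lowpass_hz,
                       channel = tpl0$channel,
                       search_window = tpl0$search_window),
        error = function(e) NULL)
      if (is.null(tpl)) { flag <- "degenerate_template"; break }
      nxt <- est_fn(sub, tpl, ...)$latency
      n_it <- n_it + 1L
      key <- round(nxt * sub$srate)
      if (mean(abs(nxt - cur)) < tol_samples / sub$srate) {
        cur <- nxt; break
      }
      if (any(vapply(seen, identical, TRUE, key))) {
        cur <- nxt; flag <- "cycle"; break
      }
      seen[[length(seen) + 1L]] <- key
      cur <- nxt
    }
    lat[sel] <- cur
    trace[[s]] <- list(iterations = n_it, status = flag)
  }
  structure(latency_table(epochs, lat, method = paste0(base, "_iter")),
            trace = trace)
}
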