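# Averaging-based latency measures: peak latency and fractional-area
# latency on an evoked response at a target channel and window.

#' Measurement configuration for averaging-based latency measures
#'
#' @param channel target electrode.
#' @param window measurement window `[start, end)`, seconds.
#' @param fraction area fraction for [fractional_area_latency()] (0.5 gives
#'   the 50%-area latency).
#' @param polarity `"positive"` (P300-like) or `"negative"` (N400-like).
#' @return An object of class `measure_config`.
#' @export
measure_config <- function(channel = "Pz", window = c(0.250, 0.650),
                           fraction = 0.5, polarity = "positive") {
  stopifnot(fraction > 0, fraction < 1,
            polarity %in% c("positive", "negative"))
  structure(list(channel = channel, window = window, fraction = fraction,
                 polarity = polarity), class = "measure_config")
}

#' Preset measurement configurations
#'
#' `"p300"`: Pz, 0.250-0.650 s, positive polarity. `"n400"`: Cz,
#' 0.200-0.600 s, negative polarity.
#'
#' @param name preset name.
#' @return A `measure_config`.
#' @export
measure_preset <- function(name = c("p300", "n400")) {
  switch(match.arg(name),
         p300 = measure_config("Pz", c(0.250, 0.650), 0.5, "positive"),
         n400 = measure_config("Cz", c(0.200, 0.600), 0.5, "negative"))
}

#' Peak latency of an evoked response
#'
#' Time of the maximum (positive polarity) or minimum (negative polarity)
#' at the configured channel within the window; ties are broken toward the
#' earliest time.
#'
#' @param evk an `evoked`.
#' @param cfg a `measure_config`.
#' @return Latency in seconds.
#' @export
peak_latency <- function(evk, cfg = measure_preset("p300")) {
  idx <- window_idx(evk, cfg$window)
  if (length(idx) < 3L) stop("window contains fewer than 3 samples")
  x <- evk$data[chan_idx(evk, cfg$channel), idx]
  if (cfg$polarity == "negative") x <- -x
  if (diff(range(x)) == 0)
    warning("degenerate peak: flat signal in window")
  sample_times(evk)[idx[which.max(x)]]
}

#' Fractional-area latency of an evoked response
#'
#' The signal is rectified to the configured polarity (opposite-sign values
#' clipped to zero), the cumulative trapezoidal area over the window is
#' computed, and the time at which the cumulative area first reaches
#' `fraction` of the total is returned, linearly interpolated between
#' samples.
#'
#' @param evk an `evoked`.
#' @param cfg a `measure_config`.
#' @return Latency in seconds.
#' @export
fractional_area_latency <- function(evk, cfg = measure_preset("p300")) {
  idx <- window_idx(evk, cfg$window)
  x <- evk$data[chan_idx(evk, cfg$channel), idx]
  if (cfg$polarity == "negative") x <- -x
  x <- pmax(x, 0)
  tt <- sample_times(evk)[idx]
  # cumulative trapezoid
  seg <- (x[-1L] + x[-length(x)]) / 2 * diff(tt)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("no area in window")
  target <- cfg$fraction * total
  j <- which(cum >= target)[1L]
  if (j == 1L) return(tt[1L])
  # linear interpolation inside segment j-1
  excess <- target - cum[j - 1L]
  tt[j - 1L] + diff(tt)[j - 1L] * excess / seg[j - 1L]
}

#' Averaging-based per-subject latency estimates
#'
#' Applies an averaging-based measure per subject: trials of each subject
#' are averaged, the measure is read off the average, and the resulting
#' single latency is assigned to all of that subject's trials (the
#' averaging methods carry no single-trial information).
#'
#' @param epochs an `epochs_set` (deviant trials).
#' @param measure `"peak"` or `"area"`.
#' @param cfg a `measure_config`.
#' @return A latency table (see [latency_table()]).
#' @export
avg_latencies <- function(epochs, measure = c("peak", "area"),
                          cfg = measure_preset("p300")) {
  measure <- match.arg(measure)
  fn <- if (measure == "peak") peak_latency else fractional_area_latency
  lat <- rep(NA_real_, n_trials(epochs))
  for (s in unique(epochs$subject)) {
    sel <- epochs$subject == s
    evk <- grand_average(subset_trials(epochs, sel))
    lat[sel] <- fn(evk, cfg)
  }
  latency_table(epochs, lat, method = measure)
}
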