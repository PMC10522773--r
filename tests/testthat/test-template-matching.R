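# Estimator tests on noise-free and toy data, with brute-force oracles.

make_template <- function(ep, window = c(0.3, 0.6)) {
  ga <- grand_average(ep)
  zero <- evoked(matrix(0, nrow(ga$data), ncol(ga$data)), ep$srate, ep$t0,
                 ep$channel_names)
  build_template(list(ga, zero), window = window)
}

test_that("build_template reproduces the injected component shape", {
  ep <- noise_free_epochs(n = 30, seed = 21, lat_range = c(0.45, 0.45))
  tpl <- make_template(ep)
  pz <- match("Pz", ep$channel_names)
  # compare with the average component at Pz over the same window
  ga <- grand_average(ep)
  idx <- which(sample_times(ga) >= 0.3 - 1e-9 & sample_times(ga) < 0.6 - 1e-9)
  expect_gt(cor(tpl$waveform[pz, ], ga$data[pz, idx]), 0.99)
  # the 5 Hz low-pass is idempotent up to passband ripple: filtering the
  # full-epoch difference twice barely changes the windowed template
  once <- ertrial:::lowpass_matrix(ga$data, ep$srate, 5)
  twice <- ertrial:::lowpass_matrix(once, ep$srate, 5)
  expect_lt(max(abs(twice[pz, idx] - once[pz, idx])) /
              max(abs(once[pz, idx])), 0.05)
})

test_that("xcorr recovers an embedded template exactly and matches the scan oracle", {
  ep <- noise_free_epochs(n = 25, seed = 22)
  tpl <- make_template(ep)
  est <- xcorr_latencies(ep, tpl)
  expect_lt(mean(abs(est$latency - ep$true_latency)), 1.01 / ep$srate)

  # brute-force oracle: per lag, mean over channels of cor()
  oracle_one <- function(trial) {
    starts <- ertrial:::admissible_starts(ep, tpl)
    lt <- ncol(tpl$waveform)
    curve <- vapply(starts, function(s) {
      r <- vapply(1:20, function(c0) {
        seg <- ep$data[trial, c0, s:(s + lt - 1)]
        if (sd(seg) == 0 || sd(tpl$waveform[c0, ]) == 0) return(0)
        cor(seg, tpl$waveform[c0, ])
      }, 0)
      mean(r)
    }, 0)
    sample_times(ep)[starts[which.max(curve)] +
                       round(tpl$peak_offset * ep$srate)]
  }
  for (i in c(1, 7, 13)) expect_equal(est$latency[i], oracle_one(i))
})

test_that("xcorr estimates are shift-equivariant and amplitude-invariant", {
  ep <- noise_free_epochs(n = 6, seed = 23, lat_range = c(0.40, 0.46))
  tpl <- make_template(ep)
  base <- xcorr_latencies(ep, tpl)$latency

  k <- 10  # delay trials by 10 samples (40 ms at 250 Hz)
  shifted <- ep
  ns <- dim(ep$data)[3]
  shifted$data[, , (k + 1):ns] <- ep$data[, , 1:(ns - k)]
  shifted$data[, , 1:k] <- 0
  shifted$true_latency <- ep$true_latency + k / ep$srate
  est_s <- xcorr_latencies(shifted, tpl)$latency
  expect_equal(est_s, base + k / ep$srate, tolerance = 1e-9)

  scaled <- ep
  scaled$data <- scaled$data * 5.5
  expect_equal(xcorr_latencies(scaled, tpl)$latency, base)
})

test_that("dtw matches a hand-run dynamic-programming oracle", {
  # 5x5 single-channel toy
  tplm <- matrix(c(0, 1, 2, 1, 0), nrow = 1)
  segm <- matrix(c(1, 0, 1, 2, 1), nrow = 1)
  al <- ertrial:::dtw_align_cpp(tplm, segm)
  local <- outer(tplm[1, ], segm[1, ], function(a, b) (a - b)^2)
  D <- matrix(NA, 5, 5)
  D[1, 1] <- local[1, 1]
  for (i in 2:5) D[i, 1] <- D[i - 1, 1] + local[i, 1]
  for (j in 2:5) D[1, j] <- D[1, j - 1] + local[1, j]
  for (i in 2:5) for (j in 2:5)
    D[i, j] <- local[i, j] + min(D[i - 1, j], D[i, j - 1], D[i - 1, j - 1])
  expect_equal(al$cost, D)

  # multichannel: cost sums over channels
  tpl2 <- rbind(tplm, 2 * tplm)
  seg2 <- rbind(segm, 2 * segm)
  al2 <- ertrial:::dtw_align_cpp(tpl2, seg2)
  local2 <- local + outer(2 * tplm[1, ], 2 * segm[1, ], function(a, b) (a - b)^2)
  expect_equal(al2$cost[1, 1], local2[1, 1])
})

test_that("dtw on an identical segment follows the diagonal at zero cost", {
  ep <- noise_free_epochs(n = 8, seed = 24)
  tpl <- make_template(ep)
  # build one trial equal to the template placed at a known peak time
  ns <- dim(ep$data)[3]
  trial <- array(0, c(1, 20, ns))
  start_t <- 0.45 - tpl$peak_offset
  i0 <- round((start_t - ep$t0) * ep$srate) + 1
  trial[1, , i0:(i0 + ncol(tpl$waveform) - 1)] <- tpl$waveform
  one <- epochs_set(trial, ep$srate, ep$t0, ep$channel_names,
                    condition = "deviant")
  est <- dtw_latencies(one, tpl)
  expect_lt(abs(est$latency - 0.45), 2 / ep$srate)

  al <- ertrial:::dtw_align_cpp(tpl$waveform, tpl$waveform)
  expect_equal(al$cost[nrow(al$cost), ncol(al$cost)], 0)
  expect_equal(al$path_i, al$path_j)
})

test_that("dtw latencies are amplitude-sensitive (documented negative property)", {
  ep <- noise_free_epochs(n = 10, seed = 25)
  tpl <- make_template(ep)
  base <- dtw_latencies(ep, tpl)$latency
  scaled <- ep
  scaled$data <- scaled$data * 4
  est2 <- dtw_latencies(scaled, tpl)$latency
  expect_false(isTRUE(all.equal(base, est2)))
})

test_that("beamformer weights satisfy unit gain and match an explicit solve", {
  # 3-channel, 4-sample toy: weights equal R^-1 h / (h' R^-1 h)
  with_seed(31, {
    tplw <- matrix(rnorm(12), 3, 4)
    dat <- array(rnorm(30 * 3 * 40, sd = 1), c(30, 3, 40))
  })
  ep <- epochs_set(dat * 1e-6, 100, 0, c("a", "b", "Pz"),
                   condition = "deviant")
  tpl <- structure(list(waveform = tplw * 1e-6, window = c(0.1, 0.14),
                        srate = 100, channel = "Pz",
                        channel_names = c("a", "b", "Pz"),
                        peak_offset = 0.02, search_window = c(0.1, 0.3)),
                   class = "template_model")
  est <- beamformer_latencies(ep, tpl, lag_stride = 1L)
  w <- attr(est, "weights")
  h <- as.numeric(tpl$waveform)
  expect_equal(sum(w * h), 1, tolerance = 1e-10)

  starts <- ertrial:::admissible_starts(ep, tpl)
  R <- ertrial:::segment_covariance(ep, tpl, starts, 1L, "auto")
  w_oracle <- solve(R, h); w_oracle <- w_oracle / sum(h * w_oracle)
  expect_lt(max(abs(w - w_oracle)), 1e-10)
})

test_that("with full shrinkage the beamformer reduces to a matched filter", {
  ep <- noise_free_epochs(n = 12, seed = 26)
  tpl <- make_template(ep)
  est <- beamformer_latencies(ep, tpl, shrinkage = 1)
  # matched-filter oracle: argmax over lags of h' x(lag)
  starts <- ertrial:::admissible_starts(ep, tpl)
  lt <- ncol(tpl$waveform)
  h <- as.numeric(tpl$waveform)
  tt <- sample_times(ep)
  po <- round(tpl$peak_offset * ep$srate)
  for (i in c(2, 9)) {
    out <- vapply(starts, function(s)
      sum(h * as.numeric(ep$data[i, , s:(s + lt - 1)])), 0)
    expect_equal(est$latency[i], tt[starts[which.max(out)] + po])
  }
})

test_that("beamformer recovers noise-free latencies", {
  # subject-like jitter width (uniform +-0.087 s ~ SD 50 ms)
  ep <- noise_free_epochs(n = 25, seed = 27, lat_range = c(0.38, 0.55))
  tpl <- make_template(ep)
  # component-free standards carry the (here: zero) noise covariance
  est <- suppressWarnings(
    beamformer_latencies(ep, tpl, noise_epochs = zero_standards(ep)))
  expect_lt(mean(abs(est$latency - ep$true_latency)), 1.01 / ep$srate)
})

test_that("ICA isolates a rank-1 component and scores it first", {
  ep <- noise_free_epochs(n = 40, seed = 28)
  with_seed(29, {
    ep$data <- ep$data + array(rnorm(length(ep$data), sd = 1e-8),
                               dim(ep$data))
  })
  tpl <- make_template(ep)
  est <- ica_latencies(ep, tpl, mode = "single")
  info <- attr(est, "ica")
  expect_lt(mean(abs(est$latency - ep$true_latency)), 2 / ep$srate)
  expect_equal(info$components, which.max(info$scores))

  # full-subspace multiple mode degenerates to xcorr on the original data
  est_k <- ica_latencies(ep, tpl, mode = "multiple", k = 20L)
  base <- xcorr_latencies(ep, tpl)
  expect_equal(mean(abs(est_k$latency - base$latency)) * ep$srate, 0,
               tolerance = 1)
})

test_that("iteration is a fixed point on clean data and respects max_iter", {
  ep <- noise_free_epochs(n = 20, seed = 30, subjects = 2)
  tpl <- make_template(ep)
  base <- xcorr_latencies(ep, tpl)
  it1 <- iterate_latencies(ep, tpl, "xcorr", max_iter = 1L)
  expect_equal(it1$latency, base$latency)

  it <- iterate_latencies(ep, tpl, "xcorr")
  tr <- attr(it, "trace")
  expect_true(all(vapply(tr, function(x) x$iterations, 0L) <= 10L))
  # noise-free: iteration must not degrade the estimates
  expect_lt(mean(abs(it$latency - ep$true_latency)), 1.51 / ep$srate)
})

test_that("all template estimates stay inside the search window", {
  ep <- noise_free_epochs(n = 15, seed = 32)
  tpl <- make_template(ep)
  for (fn in list(xcorr_latencies, dtw_latencies, beamformer_latencies)) {
    est <- fn(ep, tpl)
    expect_true(all(est$latency >= tpl$search_window[1] - 1e-9))
    expect_true(all(est$latency <= tpl$search_window[2] + 1e-9))
  }
})
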