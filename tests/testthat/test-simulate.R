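test_that("make_half_sine matches its closed form", {
  hs <- make_half_sine(0.2, 1, 500)
  expect_equal(length(hs$wave), 101)
  expect_equal(which.max(hs$wave), 51)          # peak at L/2 = sample 50 (0-based)
  expect_equal(max(hs$wave), 1, tolerance = 1e-12)
  expect_equal(hs$peak_offset, 0.1)

  # pointwise closed form: L = 0.1 s, A = 2, srate = 250
  hs2 <- make_half_sine(0.1, 2, 250)
  k <- 0:25
  expect_equal(hs2$wave, 2 * sin(pi * k / 25), tolerance = 1e-12)

  expect_equal(make_half_sine(0.2, 0, 500)$wave, rep(0, 101))
  expect_error(make_half_sine(0.004, 1, 500), "too short")
})

test_that("snr_db follows the decibel definition", {
  expect_equal(snr_db(1, 1), 0)
  expect_equal(snr_db(4, 1), 10 * log10(4), tolerance = 1e-12)
  expect_error(snr_db(0, 1), "positive")
  expect_error(snr_db(1, -2), "positive")
})

test_that("topography_from_difference extracts the peak-time column", {
  ch <- c("Fz", "Cz", "Pz")
  base <- matrix(0, 3, 100)
  std <- evoked(base, 100, 0, ch)
  dev_dat <- base
  dev_dat[3, 45] <- 1e-6                 # 1 uV bump on Pz only at 0.44 s
  dev <- evoked(dev_dat, 100, 0, ch)
  w <- topography_from_difference(dev, std, window = c(0.3, 0.6), channel = "Pz")
  expect_equal(unname(w), c(0, 0, 1))

  # two-channel toy against a hand-computed argmax + column extraction
  ch2 <- c("Cz", "Pz")
  d2 <- matrix(0, 2, 50)
  d2[2, ] <- sin(seq(0, pi, length.out = 50)) * 2e-6
  d2[1, ] <- 0.5 * d2[2, ]
  dev2 <- evoked(d2, 100, 0, ch2)
  std2 <- evoked(matrix(0, 2, 50), 100, 0, ch2)
  w2 <- topography_from_difference(dev2, std2, window = c(0.0, 0.5),
                                   channel = "Pz")
  pk <- which.max(d2[2, 1:50])
  expect_equal(unname(w2), d2[, pk] / max(abs(d2[, pk])))
  expect_error(topography_from_difference(std2, std2, c(0, 0.5), "Pz"),
               "degenerate")
})

test_that("latency plans have the requested moments and exclusion bounds", {
  spec <- sim_spec(mean_latency_range = c(0.45, 0.45),
                   sd_latency_range = c(0.04, 0.04))
  plan <- sample_latency_plan(rep(1, 41), 500, spec, seed = 2)
  half <- 0.04 * sqrt(3)
  expect_true(all(plan$latency >= 0.45 - half - 1e-12))
  expect_true(all(plan$latency <= 0.45 + half + 1e-12))
  expect_false(any(plan$excluded))

  # Monte-Carlo moment check at fixed mu, sigma
  plan2 <- sample_latency_plan(rep(1, 41), 1e5,
                               sim_spec(mean_latency_range = c(0.5, 0.5),
                                        sd_latency_range = c(0.06, 0.06)),
                               seed = 7)
  expect_lt(abs(mean(plan2$latency) - 0.5) / 0.5, 0.01)
  expect_lt(abs(sd(plan2$latency) - 0.06) / 0.06, 0.01)

  # exclusion flags use the 0.300 / 0.600 s bounds
  plan3 <- sample_latency_plan(rep(1, 41), 2000,
                               sim_spec(mean_latency_range = c(0.55, 0.55),
                                        sd_latency_range = c(0.08, 0.08)),
                               seed = 8)
  expect_equal(plan3$excluded, plan3$latency > 0.6 | plan3$latency < 0.3)
  expect_gt(sum(plan3$excluded), 0)
})

test_that("background synthesis is deterministic and has EEG-like structure", {
  a <- synthesize_background(2, 6, seed = 42)
  b <- synthesize_background(2, 6, seed = 42)
  expect_identical(a$data, b$data)
  c <- synthesize_background(2, 6, seed = 43)
  expect_false(identical(a$data, c$data))

  # channel SDs in the physiological 5-15 uV range (subject-level mean)
  sds <- apply(a$data, c(1, 2), sd)
  expect_gt(mean(sds), 3e-6)
  expect_lt(mean(sds), 20e-6)

  # no stimulus-locked component: averaging attenuates amplitude
  big <- synthesize_background(1, 150, seed = 7)
  avg <- grand_average(big)
  expect_lt(max(abs(avg$data)), mean(apply(big$data, c(1, 2), sd)) / 2)

  # 1/f-like spectrum: negative log-log PSD slope between 1 and 30 Hz
  x <- a$data[1, 11, ]
  ps <- Mod(fft(x))^2
  freqs <- (seq_along(ps) - 1) * a$srate / length(ps)
  sel <- freqs >= 1 & freqs <= 30
  fit <- lm(log(ps[sel]) ~ log(freqs[sel]))
  expect_lt(coef(fit)[2], 0)
})

test_that("build_dataset injects the component where it says it does", {
  ch <- oddball20_channels()
  topo <- synthetic_topography()
  bg0 <- epochs_set(array(0, c(20, 20, 550)), 500, -0.1, ch,
                    subject = "s01", condition = "standard")
  spec <- sim_spec(repeats_per_subject = 1L,
                   mean_latency_range = c(0.45, 0.45),
                   sd_latency_range = c(0.04, 0.04))
  ds <- build_dataset(bg0, topo, 5e-6, spec, seed = 3)
  expect_equal(n_trials(ds), 20)
  expect_equal(sum(ds$condition == "deviant"), 10)
  dev <- which(ds$condition == "deviant")
  # noise-free limit: the Pz argmax equals the true latency sample
  tt <- sample_times(ds)
  pz <- match("Pz", ch)
  for (i in dev) {
    pk <- tt[which.max(ds$data[i, pz, ])]
    expect_lt(abs(pk - ds$true_latency[i]), 1.01 / ds$srate)
  }
  # standards untouched (zero background stays zero)
  expect_true(all(ds$data[ds$condition == "standard", , ] == 0))

  # zero amplitude leaves the background bit-identical
  bg <- synthesize_background(1, 10, seed = 2)
  ds0 <- build_dataset(bg, topo, 0, spec, seed = 3)
  expect_identical(ds0$data, bg$data)
})

test_that("datasets are byte-identical under identical specs and seeds", {
  bg <- synthesize_background(2, 10, seed = 6)
  topo <- synthetic_topography()
  spec <- sim_spec(repeats_per_subject = 2L)
  d1 <- build_dataset(bg, topo, 4e-6, spec, seed = 9)
  d2 <- build_dataset(bg, topo, 4e-6, spec, seed = 9)
  expect_identical(d1$data, d2$data)
  expect_identical(d1$true_latency, d2$true_latency)
  expect_identical(d1$subject, d2$subject)
})

test_that("no retained deviant has a latency outside the inclusion window", {
  st <- small_study()
  ds <- st$datasets[[1]]
  lat <- ds$true_latency[ds$condition == "deviant"]
  expect_true(all(lat >= 0.300 & lat <= 0.600))
})

test_that("doubling the amplitude raises the jitter-free SNR by ~6 dB", {
  ch <- oddball20_channels()
  topo <- synthetic_topography()
  # near-zero jitter, background noise far below the component amplitude
  bg_dat <- with_seed(13, array(rnorm(20 * 20 * 550, sd = 5e-8),
                                c(20, 20, 550)))
  bg <- epochs_set(bg_dat, 500, -0.1, ch, subject = "s01",
                   condition = "standard")
  spec <- sim_spec(repeats_per_subject = 1L,
                   mean_latency_range = c(0.45, 0.45),
                   sd_latency_range = c(0.001, 0.001))
  s1 <- measure_snr(build_dataset(bg, topo, 5e-6, spec, seed = 4))
  s2 <- measure_snr(build_dataset(bg, topo, 10e-6, spec, seed = 4))
  expect_lt(abs((s2 - s1) - 20 * log10(2)), 0.2)
})
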