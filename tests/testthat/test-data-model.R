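test_that("epochs_set validates its invariants", {
  dat <- array(0, c(2, 3, 10))
  expect_error(epochs_set(dat, 100, -0.1, c("a", "b")), "n_channels")
  dat[1, 1, 1] <- NA
  expect_error(epochs_set(dat, 100, -0.1, c("a", "b", "c")), "finite")
  expect_error(epochs_set(array(0, c(2, 3, 10)), -5, -0.1, c("a", "b", "c")),
               "srate")
  expect_error(epochs_set(array(0, c(2, 3, 10)), 100, -0.1, c("a", "b", "c"),
                          true_latency = c(5, NA)), "span")
})

test_that("grand_average matches the elementwise-mean oracle", {
  ep <- tiny_epochs()
  ga <- grand_average(ep)
  oracle <- apply(ep$data, c(2, 3), mean)
  expect_equal(ga$data, oracle, tolerance = 1e-15)
  expect_equal(ga$n_trials_averaged, 4L)
  expect_equal(ga$srate, ep$srate)
  expect_equal(ga$t0, ep$t0)

  # identity / symmetry special cases
  two <- subset_trials(ep, c(1, 1))
  expect_equal(grand_average(two)$data, ep$data[1, , ])
  sym <- ep
  sym$data[2, , ] <- -sym$data[1, , ]
  expect_equal(grand_average(subset_trials(sym, 1:2))$data,
               matrix(0, 3, 50))
})

test_that("grand_average rejects empty selections and mismatched inputs", {
  ep <- tiny_epochs()
  expect_error(grand_average(ep, "nonexistent"), "empty selection")
  e1 <- grand_average(ep)
  e2 <- e1; e2$srate <- 200
  expect_error(grand_average(list(e1, e2)), "incompatible")
})

test_that("difference_wave subtracts elementwise and names bad channels", {
  ep <- tiny_epochs()
  a <- grand_average(subset_trials(ep, 1:2))
  b <- grand_average(subset_trials(ep, 3:4))
  expect_equal(difference_wave(a, b)$data, a$data - b$data)
  expect_equal(difference_wave(a, a)$data, matrix(0, 3, 50))
  z <- a; z$data[] <- 0
  expect_equal(difference_wave(a, z)$data, a$data)
  swapped <- b
  swapped$channel_names <- c("Cz", "Fz", "Pz")
  expect_error(difference_wave(a, swapped), "Fz")
})

test_that("averaging is linear across subjects when trial counts balance", {
  ep <- tiny_epochs()
  conds <- c("deviant", "standard", "deviant", "standard")
  ep$condition <- conds
  d_all <- difference_wave(grand_average(ep, "deviant"),
                           grand_average(ep, "standard"))
  per_subj <- lapply(c("a", "b"), function(s) {
    sub <- subset_trials(ep, ep$subject == s)
    difference_wave(grand_average(sub, "deviant"),
                    grand_average(sub, "standard"))
  })
  expect_equal(d_all$data, grand_average(per_subj)$data, tolerance = 1e-12)
})

test_that("reject_epochs applies the three amplitude rules", {
  ep <- tiny_epochs()
  ep$data[1, 2, 5] <- 120e-6          # absolute amplitude violation
  ep$data[2, , ] <- 0                 # flat trial: peak-to-peak below minimum
  res <- reject_epochs(ep)
  expect_setequal(res$log$trial, c(1, 2))
  expect_equal(res$log$rule[res$log$trial == 1], "abs_max")
  expect_equal(res$log$rule[res$log$trial == 2], "ptp_min")
  expect_equal(n_trials(res$epochs), 2)
})

test_that("reject_epochs agrees with a per-trial rule-check oracle and is idempotent", {
  with_seed(9, {
    dat <- array(rnorm(10 * 2 * 40, sd = 20e-6), c(10, 2, 40))
  })
  dat[3, 1, 10] <- 200e-6
  dat[7, 2, ] <- seq(-80e-6, 80e-6, length.out = 40)  # ptp 160 uV
  ep <- epochs_set(dat, 100, 0, c("c1", "c2"))
  res <- reject_epochs(ep)
  keep_oracle <- vapply(1:10, function(i) {
    x <- dat[i, , ]
    ptp <- apply(x, 1, function(r) diff(range(r)))
    max(abs(x)) <= 100e-6 && max(ptp) <= 150e-6 && min(ptp) >= 0.5e-6
  }, TRUE)
  expect_equal(n_trials(res$epochs), sum(keep_oracle))
  expect_setequal(res$log$trial, which(!keep_oracle))
  # idempotence
  res2 <- reject_epochs(res$epochs)
  expect_equal(nrow(res2$log), 0)
  expect_equal(res2$epochs$data, res$epochs$data)
})

test_that("reject_epochs returns an empty set with a warning when all fail", {
  ep <- tiny_epochs()
  ep$data[] <- 0
  expect_warning(res <- reject_epochs(ep), "all trials")
  expect_equal(n_trials(res$epochs), 0)
})

test_that("realignment with zero shifts reproduces the plain average exactly", {
  ep <- tiny_epochs()
  anchor <- 0.2
  out <- realign_and_average(ep, rep(anchor, 4), anchor)
  expect_equal(out$evoked$data, grand_average(ep)$data, tolerance = 1e-14)
  expect_true(all(out$counts == 4))
})

test_that("realignment matches a manual two-trial shift oracle", {
  ep <- tiny_epochs()
  two <- subset_trials(ep, c(1, 1))
  anchor <- 0.2
  delta <- 0.05  # 5 samples at 100 Hz
  out <- realign_and_average(two, c(anchor - delta, anchor + delta), anchor)
  x <- ep$data[1, , ]
  ns <- ncol(x)
  k <- 5
  shifted_fwd <- cbind(matrix(NA, 3, k), x[, 1:(ns - k)])   # shift +5
  shifted_bwd <- cbind(x[, (k + 1):ns], matrix(NA, 3, k))   # shift -5
  oracle <- (shifted_fwd + shifted_bwd) / 2
  middle <- (k + 1):(ns - k)
  expect_equal(out$evoked$data[, middle], oracle[, middle], tolerance = 1e-12)
  # edges fall back to the single valid trial
  expect_equal(out$evoked$data[, 1:k], shifted_bwd[, 1:k])
  expect_true(all(out$counts[, 1:k] == 1))
})

test_that("realigning simulated trials by their true latencies peaks at the anchor", {
  ep <- noise_free_epochs(n = 40, seed = 11)
  anchor <- 0.45
  out <- realign_and_average(ep, ep$true_latency, anchor)
  pk <- peak_latency(out$evoked, measure_config("Pz", c(0.3, 0.6)))
  expect_lt(abs(pk - anchor), 1.5 / ep$srate)
})

test_that("out-of-span latencies are excluded and logged", {
  ep <- tiny_epochs()
  lat <- c(0.2, 0.2, 5, 0.2)
  out <- realign_and_average(ep, lat, 0.2)
  expect_equal(out$log$trial, 3)
  expect_equal(out$evoked$n_trials_averaged, 3)
})

test_that("decimation halves the sample count and preserves slow content", {
  ep <- noise_free_epochs(n = 4, seed = 2, srate = 500)
  half <- decimate_epochs(ep, 2)
  expect_equal(half$srate, 250)
  expect_equal(dim(half$data)[3], length(seq(1, dim(ep$data)[3], by = 2)))
  # the (slow) component survives decimation: Pz peak time is preserved
  g1 <- grand_average(ep); g2 <- grand_average(half)
  p1 <- peak_latency(g1, measure_config("Pz", c(0.3, 0.6)))
  p2 <- peak_latency(g2, measure_config("Pz", c(0.3, 0.6)))
  expect_lt(abs(p1 - p2), 2 / 250)
})
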