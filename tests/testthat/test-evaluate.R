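test_that("grouped folds partition subjects evenly", {
  f7 <- grouped_kfold(sprintf("s%02d", 1:7), 7, seed = 1)
  expect_equal(sort(table(f7$fold)), sort(table(1:7)))
  expect_equal(nrow(f7), 7)

  f71 <- grouped_kfold(sprintf("s%02d", 1:71), 7, seed = 2)
  sizes <- as.integer(table(f71$fold))
  expect_true(all(sizes %in% c(10L, 11L)))
  expect_equal(sum(sizes), 71)
  expect_false(any(duplicated(f71$subject)))

  expect_error(grouped_kfold(c("a", "b"), 7), "fewer subjects")
})

test_that("latency MAEs follow their definitions", {
  ep <- tiny_epochs()
  truth <- latency_table(ep, c(0.40, 0.44, 0.50, 0.46), "truth")
  est <- truth; est$method <- "est"
  expect_equal(mae_single_trial(est, truth), 0)
  est2 <- est; est2$latency <- est2$latency + 0.02
  expect_equal(mae_single_trial(est2, truth), 0.02, tolerance = 1e-12)
  # subject means: subject a mean 0.42 -> est 0.44; b 0.48 -> 0.50
  expect_equal(mae_subject_mean(est2, truth), 0.02, tolerance = 1e-12)
  # one trial per subject degenerates to the single-trial error
  one <- subset_trials(ep, c(1, 3))
  t1 <- latency_table(one, c(0.4, 0.5), "truth")
  e1 <- latency_table(one, c(0.42, 0.47), "est")
  expect_equal(mae_subject_mean(e1, t1), mae_single_trial(e1, t1))
  # unbiased per-trial errors cancel in the subject mean
  with_seed(3, {
    big <- epochs_set(array(0, c(400, 1, 10)), 100, 0, "Pz",
                      subject = rep("a", 400))
    tb <- latency_table(big, runif(400, 0.4, 0.5), "truth")
    eb <- tb; eb$latency <- tb$latency + rnorm(400, 0, 0.05)
  })
  expect_lt(mae_subject_mean(eb, tb), 0.01)
  expect_gt(mae_single_trial(eb, tb), 0.02)
  # key mismatch is an error
  bad <- est2; bad$trial <- bad$trial + 100
  expect_error(mae_single_trial(bad, truth), "missing")
})

test_that("random guessing calibrates to (b - a) / 3", {
  expect_equal(random_guess_mae(c(0.3, 0.6)), 0.1)
  with_seed(11, {
    t <- runif(1e4, 0.3, 0.6)
    e <- runif(1e4, 0.3, 0.6)
  })
  expect_lt(abs(mean(abs(t - e)) - 0.1), 0.005)
})

test_that("topography and shape errors are normalized mean absolute errors", {
  ep <- noise_free_epochs(n = 20, seed = 12)
  ra <- realign_and_average(ep, ep$true_latency, 0.45)$evoked
  expect_equal(topography_rmae(ra, ra, 0.45), 0)
  expect_equal(shape_rmae(ra, ra, "Pz"), 0)

  half <- ra; half$data <- half$data * 0.5
  expect_equal(topography_rmae(half, ra, 0.45), 0.5, tolerance = 1e-12)
  expect_equal(shape_rmae(half, ra, "Pz"), 0.5, tolerance = 1e-12)

  # constant offset: c / mean |true| over the window at the channel
  off <- ra; off$data <- off$data + 2e-6
  idx <- which(sample_times(ra) >= 0.3 - 1e-9 & sample_times(ra) < 0.6 - 1e-9)
  pz <- match("Pz", ra$channel_names)
  expect_equal(shape_rmae(off, ra, "Pz"),
               2e-6 / mean(abs(ra$data[pz, idx])), tolerance = 1e-12)

  # random perturbation against an elementwise oracle
  pert <- ra
  pert$data <- pert$data + with_seed(13, matrix(rnorm(length(ra$data),
                                                      sd = 1e-7),
                                                nrow(ra$data)))
  i45 <- ertrial:::time_to_sample(ra, 0.45)
  oracle <- mean(abs(pert$data[, i45] - ra$data[, i45])) /
    mean(abs(ra$data[, i45]))
  expect_equal(topography_rmae(pert, ra, 0.45), oracle, tolerance = 1e-12)
})

test_that("reaction-time correlation behaves at its extremes and null", {
  ep <- noise_free_epochs(n = 200, seed = 14)
  est <- latency_table(ep, ep$true_latency, "est")
  expect_equal(as.numeric(rt_correlation(est, ep$true_latency + 0.3)), 1)
  expect_equal(as.numeric(rt_correlation(est, -ep$true_latency)), -1)
  rt_null <- with_seed(15, runif(200, 0.4, 0.8))
  expect_lt(abs(as.numeric(rt_correlation(est, rt_null))), 2 / sqrt(200))
  expect_error(rt_correlation(est, rep(0.5, 200)), "variance")
})

test_that("age regression matches the closed-form least squares", {
  age <- c(25, 40, 60, 75)
  lat <- 0.3 + 0.001 * age
  fit <- age_regression(lat, age)
  expect_equal(fit$slope, 0.001, tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-9)

  with_seed(16, {
    age2 <- runif(20, 20, 80)
    lat2 <- 0.35 + 0.0008 * age2 + rnorm(20, 0, 0.01)
  })
  f2 <- age_regression(lat2, age2)
  X <- cbind(1, age2)
  beta <- solve(crossprod(X), crossprod(X, lat2))
  expect_equal(f2$intercept, beta[1], tolerance = 1e-9)
  expect_equal(f2$slope, beta[2], tolerance = 1e-9)
  expect_error(age_regression(lat2, rep(50, 20)), "constant")
})

test_that("group ANOVA matches a hand-computed mean-squares oracle", {
  # textbook 3 x 5 table
  y <- c(6, 8, 4, 5, 3, 4,
         8, 12, 9, 11, 6, 8,
         13, 9, 11, 8, 7, 12)
  g <- rep(c("young", "middle", "elderly"), each = 6)
  res <- group_effects(y, g)
  k <- 3; n <- 18
  gm <- mean(y)
  means <- tapply(y, g, mean)
  ssb <- sum(6 * (means - gm)^2)
  ssw <- sum((y - means[g])^2)
  F_oracle <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(res$F, F_oracle, tolerance = 1e-12)
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$p_bonf <= 1))

  # identical group means: F ~ 0
  y0 <- rep(c(1, 2, 3), times = 3)
  res0 <- group_effects(y0, rep(c("a", "b", "c"), each = 3))
  expect_lt(res0$F, 1e-12)
  expect_gt(res0$p, 0.99)

  # huge separation
  y1 <- c(rnorm(5, 0, .01), rnorm(5, 10, .01), rnorm(5, 20, .01))
  res1 <- group_effects(y1, rep(c("a", "b", "c"), each = 5))
  expect_lt(res1$p, 1e-6)
  expect_error(group_effects(1:3, c("a", "b", "b")), "at least 2")
})

test_that("the N400 effect amplitude measures the injected difference", {
  ch <- oddball20_channels()
  srate <- 250
  ns <- 251  # 0 .. 1.0 s
  correct <- evoked(matrix(0, 20, ns), srate, 0, ch)
  base <- array(0, c(10, 20, ns))
  inc <- epochs_set(base, srate, 0, ch, condition = "incorrect")
  expect_equal(n400_effect_amplitude(inc, correct), 0)

  # flat -2 uV effect over the window, no jitter
  tt <- seq(0, 1, by = 1 / srate)
  cz <- match("Cz", ch)
  eff <- base
  eff[, cz, tt >= 0.3 & tt <= 0.5] <- -2e-6
  inc2 <- epochs_set(eff, srate, 0, ch, condition = "incorrect")
  expect_equal(n400_effect_amplitude(inc2, correct), -2e-6,
               tolerance = 1e-3)

  # jittered effect: realignment restores magnitude
  with_seed(17, lat <- runif(30, 0.35, 0.55))
  jit <- array(0, c(30, 20, ns))
  for (i in 1:30) {
    hs <- make_half_sine(0.15, -3e-6, srate)
    i0 <- round((lat[i] - 0.075) * srate) + 1
    jit[i, cz, i0:(i0 + length(hs$wave) - 1)] <- hs$wave
  }
  inc3 <- epochs_set(jit, srate, 0, ch, condition = "incorrect")
  plain <- n400_effect_amplitude(inc3, correct)
  realigned <- n400_effect_amplitude(inc3, correct, latencies = lat,
                                     anchor = 0.4)
  expect_gte(abs(realigned), abs(plain))
  expect_error(n400_effect_amplitude(
    epochs_set(jit[, 1:3, , drop = FALSE], srate, 0, c("a", "b", "c")),
    correct), "not found")
})

test_that("feeding ground-truth latencies is a fixed point of the metrics", {
  st <- small_study()
  ds <- st$datasets[[1]]
  dev <- subset_trials(ds, ds$condition == "deviant")
  truth <- latency_table(dev, dev$true_latency, "truth")
  expect_equal(mae_single_trial(truth, truth), 0)
  expect_equal(mae_subject_mean(truth, truth), 0)
  ra <- ertrial:::realign_by_subject(dev, truth)
  for (s in names(ra)[1:2]) {
    pk <- peak_latency(ra[[s]], measure_config("Pz", c(0.3, 0.6)))
    expect_equal(topography_rmae(ra[[s]], ra[[s]], pk), 0)
    expect_equal(shape_rmae(ra[[s]], ra[[s]], "Pz"), 0)
  }
})

test_that("realignment de-smears the averaged component", {
  st <- small_study()
  ds <- st$datasets[[1]]
  dev <- subset_trials(ds, ds$condition == "deviant")
  pz <- match("Pz", ds$channel_names)
  win <- window_idx(dev, c(0.3, 0.6))
  plain <- grand_average(dev)
  truth <- latency_table(dev, dev$true_latency, "truth")
  ra <- realign_and_average(dev, dev$true_latency, 0.45)$evoked
  expect_gt(max(ra$data[pz, win]), max(plain$data[pz, win]))
})
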