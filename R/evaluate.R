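# Cross-validated evaluation: subject-grouped folds, latency-error metrics,
# topography/shape fidelity after realignment, and the statistical analyses
# used on experimental recordings (reaction-time correlation, age
# regression, group ANOVA, N400 effect amplitude).

#' Subject-grouped k-fold plan
#'
#' Source subjects are shuffled (seeded) and dealt round-robin into folds,
#' so that all trials generated from one subject's data share a fold and
#' fold sizes are balanced to within one subject.
#'
#' @param subject_ids character vector of per-trial source-subject ids, or
#'   the unique subject ids themselves.
#' @param n_folds number of folds (study design: 7).
#' @param seed shuffle seed.
#' @return A `data.frame` mapping `subject` to `fold`.
#' @export
grouped_kfold <- function(subject_ids, n_folds = 7L, seed = 1L) {
  subjects <- unique(as.character(subject_ids))
  if (length(subjects) < n_folds)
    stop("fewer subjects (", length(subjects), ") than folds (", n_folds, ")")
  ord <- with_seed(seed, sample(subjects))
  data.frame(subject = ord,
             fold = rep_len(seq_len(n_folds), length(ord)),
             stringsAsFactors = FALSE)
}

check_keys <- function(est, truth) {
  ke <- paste(est$subject, est$trial)
  kt <- paste(truth$subject, truth$trial)
  if (length(ke) != length(kt) || !setequal(ke, kt)) {
    miss <- head(setdiff(kt, ke), 5L)
    stop("trial keys do not match; e.g. missing: ",
         paste(miss, collapse = ", "))
  }
  truth[match(ke, kt), , drop = FALSE]
}

#' Single-trial mean absolute latency error
#'
#' @param est,truth latency tables with matching (subject, trial) keys.
#' @return MAE in seconds, averaged over all trials of all subjects.
#' @export
mae_single_trial <- function(est, truth) {
  truth <- check_keys(est, truth)
  mean(abs(est$latency - truth$latency))
}

#' Subject-level mean absolute latency error
#'
#' Per-subject mean latencies are computed for estimate and truth first;
#' the absolute differences are then averaged across subjects. Also
#' accepts averaging-based estimators' single per-subject latency.
#'
#' @param est,truth latency tables with matching (subject, trial) keys.
#' @return MAE of the per-subject mean latency, seconds.
#' @export
mae_subject_mean <- function(est, truth) {
  truth <- check_keys(est, truth)
  me <- tapply(est$latency, est$subject, mean)
  mt <- tapply(truth$latency, truth$subject, mean)
  mean(abs(me - mt[names(me)]))
}

#' Relative topography error at the component peak
#'
#' Mean absolute channel-wise difference between the estimated and true
#' realigned topographies at the peak time, normalized by the mean
#' absolute amplitude of the true topography.
#'
#' @param est_realigned,true_realigned realigned-average `evoked` objects.
#' @param peak_time time at which topographies are read, seconds.
#' @return The relative mean absolute error (dimensionless).
#' @export
topography_rmae <- function(est_realigned, true_realigned, peak_time) {
  ie <- time_to_sample(est_realigned, peak_time)
  it <- time_to_sample(true_realigned, peak_time)
  te <- est_realigned$data[, ie]
  tt <- true_realigned$data[, it]
  denom <- mean(abs(tt))
  if (denom == 0) stop("zero true topography")
  mean(abs(te - tt)) / denom
}

#' Relative shape error over the component window
#'
#' Mean absolute difference between the estimated and true realigned
#' waveforms at the target channel over the window, normalized by the mean
#' absolute amplitude of the true waveform there. The same contract serves
#' the grand-average variant (the mean relative absolute error, MRAE).
#'
#' @param est_realigned,true_realigned realigned-average `evoked` objects.
#' @param channel target channel.
#' @param window comparison window, seconds.
#' @return The relative mean absolute error (dimensionless).
#' @export
shape_rmae <- function(est_realigned, true_realigned, channel = "Pz",
                       window = c(0.300, 0.600)) {
  idx <- window_idx(true_realigned, window)
  ci <- chan_idx(true_realigned, channel)
  e <- est_realigned$data[ci, idx]
  tr <- true_realigned$data[ci, idx]
  denom <- mean(abs(tr))
  if (denom == 0) stop("zero-area true waveform")
  mean(abs(e - tr)) / denom
}

#' Correlation between estimated latencies and reaction times
#'
#' Pearson correlation pooled over all trials and subjects (per-subject
#' correlations are returned as an attribute).
#'
#' @param est a latency table.
#' @param reaction_times per-trial reaction times, seconds, aligned with
#'   `est` rows.
#' @return Pooled Pearson r with attribute `"per_subject"`.
#' @export
rt_correlation <- function(est, reaction_times) {
  stopifnot(length(reaction_times) == nrow(est))
  if (nrow(est) < 3L) stop("need at least 3 pairs")
  if (sd(est$latency) == 0 || sd(reaction_times) == 0)
    stop("zero variance in latencies or reaction times")
  r <- cor(est$latency, reaction_times)
  per <- vapply(split(seq_len(nrow(est)), est$subject), function(i) {
    if (length(i) < 3L || sd(est$latency[i]) == 0 ||
        sd(reaction_times[i]) == 0) return(NA_real_)
    cor(est$latency[i], reaction_times[i])
  }, 0)
  structure(r, per_subject = per)
}

#' Linear regression of per-subject mean latency on age
#'
#' @param mean_latency per-subject mean latencies, seconds.
#' @param age per-subject ages, years.
#' @return A list: `slope` (s/year), `intercept` (s), `rmse` (s).
#' @export
age_regression <- function(mean_latency, age) {
  stopifnot(length(mean_latency) == length(age), length(age) >= 3L)
  if (sd(age) == 0) stop("constant age")
  fit <- lm(mean_latency ~ age)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       rmse = sqrt(mean(fit$residuals^2)))
}

#' One-way ANOVA across groups with Bonferroni post hocs
#'
#' Classical (equal-variance) one-way ANOVA of a per-subject outcome on a
#' grouping factor, with all pairwise two-sample t tests
#' Bonferroni-adjusted (multiplied by the number of comparisons, capped at
#' 1). A Welch variant is available by flag.
#'
#' @param outcome per-subject outcome (mean latency, latency SD, or effect
#'   amplitude).
#' @param group per-subject group labels (e.g. young / middle / elderly).
#' @param welch use Welch's ANOVA and t tests.
#' @return A list: `F`, `p`, `pairwise` (data frame with Bonferroni p).
#' @export
group_effects <- function(outcome, group, welch = FALSE) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs at least 2 subjects")
  if (welch) {
    ow <- stats::oneway.test(outcome ~ group, var.equal = FALSE)
    Fv <- unname(ow$statistic); pv <- ow$p.value
  } else {
    a <- stats::anova(lm(outcome ~ group))
    Fv <- a$`F value`[1L]; pv <- a$`Pr(>F)`[1L]
  }
  combs <- utils::combn(levels(group), 2L)
  m <- ncol(combs)
  pw <- data.frame(a = combs[1L, ], b = combs[2L, ], p_bonf = NA_real_)
  for (j in seq_len(m)) {
    tt <- stats::t.test(outcome[group == combs[1L, j]],
                        outcome[group == combs[2L, j]],
                        var.equal = !welch)
    pw$p_bonf[j] <- min(1, tt$p.value * m)
  }
  list(F = Fv, p = pv, pairwise = pw)
}

#' Amplitude of the N400 effect
#'
#' The per-trial difference between the incorrect trials and the averaged
#' correct response is (optionally) realigned by the estimated latencies
#' and averaged; the effect amplitude is the mean of this waveform within
#' 0.300-0.500 s at Cz.
#'
#' @param incorrect an `epochs_set` of incorrect-condition trials.
#' @param correct_avg the `evoked` average of the correct trials.
#' @param latencies optional latency table (or numeric vector) used to
#'   realign the difference trials; `NULL` gives the plain average.
#' @param anchor realignment anchor, seconds; default the mean latency.
#' @param channel,window measurement channel and window.
#' @return Mean amplitude in volts.
#' @export
n400_effect_amplitude <- function(incorrect, correct_avg, latencies = NULL,
                                  anchor = NULL, channel = "Cz",
                                  window = c(0.300, 0.500)) {
  ci <- chan_idx(incorrect, channel)
  diffs <- incorrect
  diffs$data <- sweep(incorrect$data, c(2L, 3L), correct_avg$data, `-`)
  if (is.null(latencies)) {
    evk <- grand_average(diffs)
  } else {
    lat <- if (is.data.frame(latencies)) latencies$latency else latencies
    if (is.null(anchor)) anchor <- mean(lat, na.rm = TRUE)
    evk <- realign_and_average(diffs, lat, anchor)$evoked
  }
  mean(evk$data[ci, window_idx(evk, window)])
}

#' Estimate latencies with any of the packaged methods
#'
#' Dispatcher used by the evaluation pipeline and the command-line tool.
#' Methods: `peak`, `area` (averaging-based); `xcorr`, `xcorr_iter`,
#' `dtw`, `dtw_iter`, `bf`, `bf_iter`, `ica1`, `icak` (template-based;
#' require `tpl`); `eegnet`, `convlstm` (require a trained `model`).
#'
#' @param epochs an `epochs_set` (deviant/component trials).
#' @param method method name.
#' @param tpl a `template_model` for the template-based methods.
#' @param model a trained `nn_model` for the network methods.
#' @param cfg a `measure_config` for the averaging-based methods.
#' @param ... further arguments for the underlying estimator.
#' @return A latency table.
#' @export
estimate_latencies <- function(epochs, method, tpl = NULL, model = NULL,
                               cfg = measure_preset("p300"), ...) {
  methods <- c("peak", "area", "xcorr", "xcorr_iter", "dtw", "dtw_iter",
               "bf", "bf_iter", "ica1", "icak", "eegnet", "convlstm")
  if (!method %in% methods)
    stop("unknown method '", method, "'; valid: ",
         paste(methods, collapse = ", "))
  need_tpl <- method %in% c("xcorr", "xcorr_iter", "dtw", "dtw_iter",
                            "bf", "bf_iter", "ica1", "icak")
  if (need_tpl && is.null(tpl)) stop("method '", method, "' needs a template")
  if (method %in% c("eegnet", "convlstm") && is.null(model))
    stop("method '", method, "' needs a trained model")
  switch(method,
    peak = avg_latencies(epochs, "peak", cfg),
    area = avg_latencies(epochs, "area", cfg),
    xcorr = xcorr_latencies(epochs, tpl, ...),
    xcorr_iter = iterate_latencies(epochs, tpl, "xcorr", ...),
    dtw = dtw_latencies(epochs, tpl),
    dtw_iter = iterate_latencies(epochs, tpl, "dtw", ...),
    bf = beamformer_latencies(epochs, tpl, ...),
    bf_iter = iterate_latencies(epochs, tpl, "bf", ...),
    ica1 = ica_latencies(epochs, tpl, "single", ...),
    icak = ica_latencies(epochs, tpl, "multiple", ...),
    eegnet = predict_latencies(model, epochs),
    convlstm = predict_latencies(model, epochs))
}

# realigned average of the deviant trials of one dataset given a latency
# table; anchor defaults to the per-subject mean estimate
realign_by_subject <- function(epochs, lat_tab, anchor = NULL) {
  evs <- list()
  for (s in unique(epochs$subject)) {
    sel <- epochs$subject == s
    sub <- subset_trials(epochs, sel)
    lat <- lat_tab$latency[sel]
    a <- if (is.null(anchor)) mean(lat) else anchor
    span <- c(sub$t0, sub$t0 + dim(sub$data)[3L] / sub$srate)
    a <- min(max(a, span[1L]), span[2L] - 1 / sub$srate)
    evs[[s]] <- realign_and_average(sub, lat, a)$evoked
  }
  evs
}

#' Cross-validated benchmark of the latency estimators
#'
#' The full evaluation pipeline on simulated data: subject-grouped k-fold
#' cross-validation; per fold, the template is built and the networks are
#' trained on the training subjects only, every requested method estimates
#' the test-set latencies, and single-trial MAE, subject-level MAE and the
#' relative topography/shape errors of the realigned averages (against the
#' ground-truth realignment) are recorded.
#'
#' @param datasets named list of `epochs_set`s, one per SNR level.
#' @param methods character vector of method names
#'   (see [estimate_latencies()]).
#' @param n_folds folds for [grouped_kfold()].
#' @param window,channel component window and target channel.
#' @param train_cfg a `train_config` for the network methods.
#' @param anchor realignment anchor for the fidelity metrics; `NULL` uses
#'   the per-subject mean estimate.
#' @param seed seed for fold assignment.
#' @param verbose print progress.
#' @return A `data.frame` (one row per method x SNR x fold) with columns
#'   `mae_trial`, `mae_subject`, `topo_rmae`, `shape_rmae` and
#'   `grand_mrae` (relative error of the realigned grand average).
#' @export
run_benchmark <- function(datasets, methods = c("peak", "area", "xcorr",
                                                "dtw", "bf", "ica1",
                                                "eegnet", "convlstm"),
                          n_folds = 7L, window = c(0.300, 0.600),
                          channel = "Pz", train_cfg = train_config(),
                          anchor = NULL, seed = 1L, verbose = FALSE) {
  rows <- list()
  nn_methods <- intersect(methods, c("eegnet", "convlstm"))
  for (snr in names(datasets)) {
    ds <- datasets[[snr]]
    folds <- grouped_kfold(ds$source_subject, n_folds, seed)
    for (f in sort(unique(folds$fold))) {
      test_src <- folds$subject[folds$fold == f]
      is_test <- ds$source_subject %in% test_src
      tr <- subset_trials(ds, !is_test)
      te <- subset_trials(ds, is_test)
      tpl <- build_template(tr, window = window, channel = channel)
      te_dev <- subset_trials(te, te$condition == "deviant")
      truth <- latency_table(te_dev, te_dev$true_latency, "truth")
      true_ra <- realign_by_subject(te_dev, truth, anchor)
      models <- list()
      for (mm in nn_methods) {
        tr_dev <- subset_trials(tr, tr$condition == "deviant")
        mdl <- if (mm == "eegnet")
          build_eegnet(length(ds$channel_names), seed = train_cfg$seed)
        else build_convlstm(seed = train_cfg$seed)
        models[[mm]] <- train_nn(mdl, tr_dev, cfg = train_cfg)
      }
      tr_std <- subset_trials(tr, tr$condition == "standard")
      for (m in methods) {
        if (verbose)
          message(sprintf("snr %s fold %d method %s", snr, f, m))
        extra <- if (m %in% c("bf", "bf_iter"))
          list(noise_epochs = tr_std) else list()
        est <- do.call(estimate_latencies,
                       c(list(te_dev, m, tpl = tpl, model = models[[m]]),
                         extra))
        est_ra <- realign_by_subject(te_dev, est, anchor)
        topo <- shape <- numeric(0)
        for (s in names(true_ra)) {
          pk <- peak_latency(true_ra[[s]],
                             measure_config(channel, window))
          topo <- c(topo, topography_rmae(est_ra[[s]], true_ra[[s]], pk))
          shape <- c(shape, shape_rmae(est_ra[[s]], true_ra[[s]],
                                       channel, window))
        }
        # grand-average fidelity: subject realignments averaged together
        grand_mrae <- shape_rmae(grand_average(unname(est_ra)),
                                 grand_average(unname(true_ra)),
                                 channel, window)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, snr = snr, fold = f,
          mae_trial = mae_single_trial(est, truth),
          mae_subject = mae_subject_mean(est, truth),
          topo_rmae = mean(topo), shape_rmae = mean(shape),
          grand_mrae = grand_mrae,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize a benchmark report across folds
#'
#' @param report output of [run_benchmark()].
#' @return A `data.frame` with mean and SD of each metric per method x SNR.
#' @export
summarize_benchmark <- function(report) {
  agg <- aggregate(cbind(mae_trial, mae_subject, topo_rmae, shape_rmae,
                         grand_mrae) ~ method + snr, data = report,
                   FUN = function(x) c(mean = mean(x), sd = sd(x)))
  do.call(data.frame, agg)
}

#' Expected error of random latency guessing
#'
#' For truth and estimate drawn independently and uniformly on
#' `[a, b]`, the expected absolute error is `(b - a) / 3` — the reference
#' chance level the estimators are compared against (0.1 s for the
#' 0.300-0.600 s window).
#'
#' @param window latency window, seconds.
#' @return Expected MAE in seconds.
#' @export
random_guess_mae <- function(window = c(0.300, 0.600)) diff(window) / 3
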