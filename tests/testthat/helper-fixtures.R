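# Shared fixtures, generated in code. Expensive objects are memoised in the
# session so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small deterministic epochs: 4 trials x 3 channels x 50 samples @ 100 Hz
tiny_epochs <- function(seed = 1) {
  with_seed(seed, {
    dat <- array(rnorm(4 * 3 * 50, sd = 1e-6), c(4, 3, 50))
    epochs_set(dat, srate = 100, t0 = -0.1,
               channel_names = c("Fz", "Cz", "Pz"),
               subject = c("a", "a", "b", "b"))
  })
}

# component-only (noise-free) trials at 250 Hz with known peak latencies
noise_free_epochs <- function(n = 60, seed = 3, srate = 250,
                              lat_range = c(0.32, 0.58), amp = 5e-6,
                              subjects = 1L) {
  ch <- oddball20_channels()
  topo <- synthetic_topography()
  t0 <- -0.1
  ns <- round(1.104 * srate)  # -0.1 .. 1.004 s
  with_seed(seed, {
    lat <- runif(n, lat_range[1], lat_range[2])
    subj <- rep_len(seq_len(subjects), n)
    L <- runif(subjects, 0.1, 0.3)[subj]   # component length per subject
    dat <- array(0, c(n, 20, ns))
    for (i in seq_len(n)) {
      hs <- make_half_sine(L[i], amp, srate)
      i0 <- round((lat[i] - hs$peak_offset - t0) * srate) + 1
      dat[i, , i0:(i0 + length(hs$wave) - 1)] <- outer(topo, hs$wave)
    }
    epochs_set(dat, srate, t0, ch,
               subject = sprintf("s%02d", subj),
               condition = "deviant", true_latency = lat)
  })
}

# matching standards (all zeros) so templates can be built from differences
zero_standards <- function(like, n = n_trials(like)) {
  d <- dim(like$data)
  epochs_set(array(0, c(n, d[2], d[3])), like$srate, like$t0,
             like$channel_names,
             subject = rep_len(unique(like$subject), n),
             condition = "standard")
}

# a small simulated multi-subject study at one SNR offset (memoised)
small_study <- function() {
  memo("small_study", {
    simulate_study(n_subjects = 4L, n_trials = 30L, offsets_db = 0,
                   spec = sim_spec(repeats_per_subject = 1L), seed = 5L)
  })
}

# zero-background study-condition dataset (noise-free recovery); the
# repeated injections average the per-subject mean-latency draws so the
# grand-average template is symmetric, as in the full-scale study design
noise_free_study <- function() {
  memo("noise_free_study", {
    ch <- oddball20_channels()
    bg <- epochs_set(array(0, c(5 * 24, 20, 550)), 500, -0.1, ch,
                     subject = rep(sprintf("s%02d", 1:5), each = 24),
                     condition = "standard")
    build_dataset(bg, synthetic_topography(), 5e-6,
                  sim_spec(repeats_per_subject = 6L), seed = 42)
  })
}

# the scaled-down two-SNR study: 14 subjects x 100 trials at -6 / +6 dB,
# decimated to 250 Hz (memoised; by far the most expensive fixture)
two_snr_study <- function() {
  memo("two_snr_study", {
    st <- simulate_study(n_subjects = 14L, n_trials = 100L,
                         offsets_db = c(-6, 6),
                         spec = sim_spec(repeats_per_subject = 1L),
                         seed = 1L)
    lapply(st$datasets, decimate_epochs, factor = 2L)
  })
}
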