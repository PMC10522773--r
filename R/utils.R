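#' @useDynLib ertrial, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate approx coef cor fft lm median pt quantile rnorm runif sd var
#' @importFrom utils head modifyList write.csv
NULL

#' Derive a reproducible child seed from a global seed and a stage name
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from the global seed plus a stage label, so that stages can be re-run in
#' isolation and the full pipeline is reproducible from a single integer.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # cheap string hash (djb2), folded together with the seed into 31 bits
  h <- 5381
  for (ch in utf8ToInt(stage)) h <- (h * 33 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# state is restored afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

# Nearest-sample rounding with ties toward -Inf (sample shifts are integer).
round_half_down <- function(x) ceiling(x - 0.5)

# Zero-phase Butterworth low-pass along the last (time) dimension of a
# channels x samples matrix. Order-4 filter applied forward and backward.
lowpass_matrix <- function(x, srate, cutoff_hz) {
  stopifnot(cutoff_hz > 0, cutoff_hz < srate / 2)
  bf <- signal::butter(4, cutoff_hz / (srate / 2), type = "low")
  t(apply(x, 1L, function(row) signal::filtfilt(bf, row)))
}
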