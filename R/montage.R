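# 10-20 montage handling and the 5x5 scalp grid used by the convolutional
# LSTM regressor.

#' The 20-channel oddball montage
#'
#' Channel labels of the 20-electrode 10-20 recording set-up used throughout
#' the package's presets: Fp1, Fpz, Fp2, F7, F3, Fz, F4, F8, T3, C3, Cz, C4,
#' T4, T5, P3, Pz, P4, T6, O1, Oz.
#'
#' @return Character vector of 20 channel labels.
#' @export
oddball20_channels <- function() {
  c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3",
    "Cz", "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "Oz")
}

#' Construct a 5x5 grid montage
#'
#' Maps channel labels to cells of a 5x5 scalp grid (rows front to back,
#' columns left to right). Unmapped cells are filled with `fill_value`.
#'
#' @param mapping named list or data frame: channel label -> `c(row, col)`
#'   with row/col in 1..5. The mapping must be injective.
#' @param dropped channels present in the data but deliberately left off the
#'   grid.
#' @param fill_value value for unmapped cells (default 0 V).
#' @return An object of class `grid_montage`.
#' @export
grid_montage <- function(mapping, dropped = character(0), fill_value = 0) {
  if (is.data.frame(mapping)) {
    m <- mapping
  } else {
    m <- data.frame(channel = names(mapping),
                    row = vapply(mapping, `[`, 0, 1L),
                    col = vapply(mapping, `[`, 0, 2L),
                    stringsAsFactors = FALSE)
  }
  stopifnot(all(m$row %in% 1:5), all(m$col %in% 1:5))
  key <- paste(m$row, m$col)
  if (anyDuplicated(key))
    stop("duplicate grid cell: ", key[duplicated(key)][1L])
  structure(list(table = m, dropped = as.character(dropped),
                 fill_value = fill_value),
            class = "grid_montage")
}

#' Canonical 5x5 grid for the 20-channel oddball montage
#'
#' A scalp-consistent assignment of the 20 channels to the 5x5 grid:
#' frontopolar row 1, frontal row 2, central/temporal row 3, parietal row 4,
#' occipital row 5. The five unused cells are zero-filled.
#'
#' @return A `grid_montage`.
#' @export
oddball20_grid <- function() {
  grid_montage(list(
    Fp1 = c(1, 2), Fpz = c(1, 3), Fp2 = c(1, 4),
    F7  = c(2, 1), F3  = c(2, 2), Fz  = c(2, 3), F4 = c(2, 4), F8 = c(2, 5),
    T3  = c(3, 1), C3  = c(3, 2), Cz  = c(3, 3), C4 = c(3, 4), T4 = c(3, 5),
    T5  = c(4, 1), P3  = c(4, 2), Pz  = c(4, 3), P4 = c(4, 4), T6 = c(4, 5),
    O1  = c(5, 2), Oz  = c(5, 3)))
}

#' Map epochs onto the 5x5 grid sequence expected by the ConvLSTM
#'
#' Converts each trial into a sequence of 5x5 spatial maps, one per time
#' sample; unmapped cells carry the montage fill value.
#'
#' @param epochs an `epochs_set`.
#' @param montage a `grid_montage`; every channel of `epochs` must be mapped
#'   or listed as dropped.
#' @return Numeric array `[n_trials, n_samples, 5, 5]`.
#' @export
map_to_grid <- function(epochs, montage = oddball20_grid()) {
  stopifnot(inherits(montage, "grid_montage"))
  unknown <- setdiff(epochs$channel_names,
                     c(montage$table$channel, montage$dropped))
  if (length(unknown))
    stop("channel(s) neither mapped nor dropped: ",
         paste(unknown, collapse = ", "))
  d <- dim(epochs$data)
  out <- array(montage$fill_value, c(d[1L], d[3L], 5L, 5L))
  for (j in seq_len(nrow(montage$table))) {
    ch <- montage$table$channel[j]
    ci <- match(ch, epochs$channel_names)
    if (is.na(ci)) next
    out[, , montage$table$row[j], montage$table$col[j]] <- epochs$data[, ci, ]
  }
  out
}

#' Assemble a latency table
#'
#' The common exchange format of all estimators: one row per trial with the
#' estimating method, subject and trial identifiers and the latency in
#' seconds.
#'
#' @param epochs the `epochs_set` the estimates belong to.
#' @param latency numeric vector of per-trial latencies, seconds.
#' @param method method label.
#' @param trial optional trial indices (default sequence).
#' @return A `data.frame` with columns subject, trial, method, latency.
#' @export
latency_table <- function(epochs, latency, method = "unknown", trial = NULL) {
  n <- n_trials(epochs)
  stopifnot(length(latency) == n)
  data.frame(subject = epochs$subject,
             trial = if (is.null(trial)) seq_len(n) else trial,
             method = method, latency = as.numeric(latency),
             stringsAsFactors = FALSE)
}
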