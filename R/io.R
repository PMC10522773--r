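# Epochs container I/O. Primary format: HDF5 (datasets /data and
# /true_latency plus metadata attributes). A plain-text TSV format (JSON
# metadata sidecar) is provided for small, inspectable fixtures.

#' Write an epochs set
#'
#' HDF5 layout: dataset `/data` (float64, trials x channels x samples),
#' `/true_latency`, `/subject`, `/source_subject`, `/condition`; root
#' attributes `srate`, `t0`, `channel_names`. The file is written to a
#' temporary path and atomically renamed, so an interrupted write leaves
#' no truncated file.
#'
#' @param epochs an `epochs_set`.
#' @param path output path.
#' @param format `"hdf5"` or `"tsv"` (a gzip-free long-format text table
#'   with a `.json` metadata sidecar).
#' @param overwrite allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path, format = c("hdf5", "tsv"),
                         overwrite = FALSE) {
  format <- match.arg(format)
  if (file.exists(path) && !overwrite)
    stop("'", path, "' exists; use overwrite = TRUE")
  if (format == "hdf5") {
    tmp <- paste0(path, ".tmp")
    if (file.exists(tmp)) unlink(tmp)
    rhdf5::h5createFile(tmp)
    rhdf5::h5write(epochs$data, tmp, "data")
    rhdf5::h5write(epochs$true_latency, tmp, "true_latency")
    rhdf5::h5write(epochs$subject, tmp, "subject")
    rhdf5::h5write(epochs$source_subject, tmp, "source_subject")
    rhdf5::h5write(epochs$condition, tmp, "condition")
    fid <- rhdf5::H5Fopen(tmp)
    rhdf5::h5writeAttribute(epochs$srate, fid, "srate")
    rhdf5::h5writeAttribute(epochs$t0, fid, "t0")
    rhdf5::h5writeAttribute(epochs$channel_names, fid, "channel_names")
    rhdf5::H5Fclose(fid)
    file.rename(tmp, path)
  } else {
    meta <- list(srate = epochs$srate, t0 = epochs$t0,
                 channel_names = epochs$channel_names,
                 subject = epochs$subject,
                 source_subject = epochs$source_subject,
                 condition = epochs$condition,
                 true_latency = epochs$true_latency,
                 dim = dim(epochs$data))
    tmp <- paste0(path, ".tmp")
    d <- dim(epochs$data)
    tab <- data.frame(trial = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
                      channel = rep(rep(epochs$channel_names,
                                        each = d[1L]), times = d[3L]),
                      sample = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
                      value = as.numeric(epochs$data))
    utils::write.table(tab, tmp, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    file.rename(tmp, path)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read an epochs set
#'
#' @param path file written by [write_epochs()].
#' @param format `"hdf5"` or `"tsv"`.
#' @param decimate_to optional target sampling rate (Hz); the data are
#'   anti-alias filtered and decimated after reading (e.g. 500 -> 250 Hz
#'   for the neural networks).
#' @return An `epochs_set`.
#' @export
read_epochs <- function(path, format = c("hdf5", "tsv"),
                        decimate_to = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "hdf5") {
    dat <- rhdf5::h5read(path, "data")
    tl <- as.numeric(rhdf5::h5read(path, "true_latency"))
    subj <- as.character(rhdf5::h5read(path, "subject"))
    src <- as.character(rhdf5::h5read(path, "source_subject"))
    cond <- as.character(rhdf5::h5read(path, "condition"))
    fid <- rhdf5::H5Fopen(path)
    srate <- as.numeric(rhdf5::h5readAttributes(fid, "/")$srate)
    t0 <- as.numeric(rhdf5::h5readAttributes(fid, "/")$t0)
    chn <- as.character(rhdf5::h5readAttributes(fid, "/")$channel_names)
    rhdf5::H5Fclose(fid)
    out <- epochs_set(dat, srate, t0, chn, subj, cond, src, tl)
  } else {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    d <- as.integer(meta$dim)
    dat <- array(tab$value, d)
    out <- epochs_set(dat, meta$srate, meta$t0, meta$channel_names,
                      meta$subject, meta$condition, meta$source_subject,
                      as.numeric(meta$true_latency))
  }
  if (!is.null(decimate_to)) {
    fac <- out$srate / decimate_to
    if (abs(fac - round(fac)) > 1e-9)
      stop("srate ", out$srate, " is not an integer multiple of ",
           decimate_to)
    out <- decimate_epochs(out, round(fac))
  }
  out
}

#' Write a provenance record beside an output artifact
#'
#' @param path artifact path; the record is written to `paste0(path,
#'   ".prov.json")`.
#' @param config the configuration list used for the run.
#' @param seed the global seed.
#' @return The provenance path, invisibly.
#' @export
write_provenance <- function(path, config, seed) {
  prov <- list(
    package = "ertrial",
    version = as.character(utils::packageVersion("ertrial")),
    seed = seed,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  pp <- paste0(path, ".prov.json")
  jsonlite::write_json(prov, pp, auto_unbox = TRUE)
  invisible(pp)
}
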