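#' Construct a multi-channel slice recording
#'
#' The in-memory container for an MEA recording: a channels x samples matrix
#' of extracellular voltage (uV), the sampling rate, the ordered electrode
#' ids, a start time, and optional epoch annotations (e.g. control / drug /
#' washout periods).
#'
#' @param data Numeric matrix, channels x samples, in uV.
#' @param sample_rate Sampling rate in Hz.
#' @param channels Character vector of electrode ids, one per row of `data`.
#' @param start_time_s Recording start time in seconds (default 0).
#' @param epochs `NULL` or a data.frame with columns `label`, `start_s`,
#'   `end_s`, `agent` (the perfusate/drug active during the epoch).
#' @return An object of class `mea_recording`.
#' @export
new_recording <- function(data, sample_rate, channels,
                          start_time_s = 0, epochs = NULL) {
  if (!is.matrix(data)) stop("`data` must be a channels x samples matrix")
  if (length(channels) != nrow(data))
    stop("length(channels) (", length(channels), ") != nrow(data) (", nrow(data), ")")
  if (anyDuplicated(channels)) stop("channel ids must be unique")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("`sample_rate` must be a positive number (Hz)")
  epochs <- validate_epochs(epochs)
  structure(
    list(data = data, sample_rate = sample_rate,
         channels = as.character(channels),
         start_time_s = start_time_s, epochs = epochs),
    class = "mea_recording"
  )
}

validate_epochs <- function(epochs) {
  if (is.null(epochs) || (is.data.frame(epochs) && nrow(epochs) == 0L))
    return(NULL)
  req <- c("label", "start_s", "end_s")
  if (!is.data.frame(epochs) || !all(req %in% names(epochs)))
    stop("`epochs` must be a data.frame with columns label, start_s, end_s")
  if (is.null(epochs$agent)) epochs$agent <- NA_character_
  if (any(epochs$end_s <= epochs$start_s))
    stop("epoch end_s must be greater than start_s")
  epochs[order(epochs$start_s), c("label", "start_s", "end_s", "agent"),
         drop = FALSE]
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("MEA recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sample_rate,
              ncol(x$data) / x$sample_rate))
  if (!is.null(x$epochs))
    cat("Epochs:", paste(sprintf("%s[%g-%g s]", x$epochs$label,
                                 x$epochs$start_s, x$epochs$end_s),
                         collapse = " "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An [new_recording()].
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$sample_rate

#' Time axis of a recording
#' @param rec An [new_recording()].
#' @return Numeric vector of sample times in seconds (start of each sample).
#' @export
recording_times <- function(rec)
  rec$start_time_s + (seq_len(ncol(rec$data)) - 1L) / rec$sample_rate

#' Write a recording to an HDF5 container
#'
#' Layout: dataset `/data` (channels x samples, uV) with attributes
#' `sample_rate` (Hz) and `start_time_s`; dataset `/channels` (ordered
#' electrode ids); group `/epochs` with one dataset per field (`label`,
#' `start_s`, `end_s`, `agent`) when epoch annotations are present.
#'
#' @param rec An [new_recording()].
#' @param path Output `.h5` path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "mea_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(rec$data, path, "data")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "data")
  rhdf5::h5writeAttribute(rec$sample_rate, did, "sample_rate")
  rhdf5::h5writeAttribute(rec$start_time_s, did, "start_time_s")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  rhdf5::h5write(rec$channels, path, "channels")
  if (!is.null(rec$epochs)) {
    rhdf5::h5createGroup(path, "epochs")
    rhdf5::h5write(as.character(rec$epochs$label), path, "epochs/label")
    rhdf5::h5write(rec$epochs$start_s, path, "epochs/start_s")
    rhdf5::h5write(rec$epochs$end_s, path, "epochs/end_s")
    rhdf5::h5write(as.character(rec$epochs$agent), path, "epochs/agent")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a recording from an HDF5 container
#'
#' Inverse of [write_recording()]: `read_recording(write_recording(rec, p))`
#' reproduces samples, rate, channel ids and epoch annotations exactly.
#'
#' @param path Path to an `.h5` file written by [write_recording()].
#' @return An [new_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  rhdf5::h5closeAll()
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  need <- c("data", "channels")
  missing_ds <- setdiff(need, contents$name[contents$group == "/"])
  if (length(missing_ds))
    stop("recording container lacks required dataset(s): ",
         paste(missing_ds, collapse = ", "))
  dat <- rhdf5::h5read(path, "data")
  attrs <- rhdf5::h5readAttributes(path, "data")
  if (is.null(attrs$sample_rate))
    stop("recording container lacks required attribute 'sample_rate' on /data")
  rate <- as.numeric(attrs$sample_rate)
  t0 <- if (!is.null(attrs$start_time_s)) as.numeric(attrs$start_time_s) else 0
  channels <- as.character(rhdf5::h5read(path, "channels"))
  epochs <- NULL
  if (any(contents$name == "epochs" & contents$group == "/")) {
    epochs <- data.frame(
      label = as.character(rhdf5::h5read(path, "epochs/label")),
      start_s = as.numeric(rhdf5::h5read(path, "epochs/start_s")),
      end_s = as.numeric(rhdf5::h5read(path, "epochs/end_s")),
      agent = as.character(rhdf5::h5read(path, "epochs/agent")),
      stringsAsFactors = FALSE
    )
  }
  new_recording(dat, rate, channels, start_time_s = t0, epochs = epochs)
}
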