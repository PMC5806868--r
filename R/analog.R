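#' Multichannel analog recordings
#'
#' An `analog_recording` bundles a channels x samples voltage matrix (in
#' microvolts) with its sampling rate, electrode labels and start time.
#'
#' @param data Numeric matrix, channels x samples, microvolts.
#' @param channel_ids Character vector of electrode labels, one per row of
#'   `data`.
#' @param sampling_rate Sampling frequency in Hz (> 0).
#' @param start_time Recording start time in seconds (default 0).
#' @return An object of class `analog_recording`.
#' @export
analog_recording <- function(data, channel_ids, sampling_rate, start_time = 0) {
  data <- as.matrix(data)
  channel_ids <- as.character(channel_ids)
  if (nrow(data) != length(channel_ids))
    rlang::abort("data must have one row per channel id",
                 class = "spikegrid_validation_error")
  if (anyDuplicated(channel_ids))
    rlang::abort("duplicate channel ids", class = "spikegrid_validation_error")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0)
    rlang::abort("sampling_rate must be a single positive number",
                 class = "spikegrid_validation_error")
  rownames(data) <- channel_ids
  structure(list(data = data, channel_ids = channel_ids,
                 sampling_rate = as.numeric(sampling_rate),
                 start_time = as.numeric(start_time)),
            class = "analog_recording")
}

#' @export
print.analog_recording <- function(x, ...) {
  cat(sprintf(
    "<analog_recording: %d channels x %d samples @ %g Hz (%.3f s)>\n",
    nrow(x$data), ncol(x$data), x$sampling_rate,
    ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' @rdname analog_recording
#' @param rec An `analog_recording`.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Time axis of a recording
#'
#' @param rec An `analog_recording`.
#' @return Numeric vector of sample times in seconds.
#' @export
sample_times <- function(rec) {
  rec$start_time + (seq_len(ncol(rec$data)) - 1) / rec$sampling_rate
}

#' Read and write analog recordings as HDF5
#'
#' The on-disk schema (version 1) is: dataset `/analog/data` (float32,
#' channels x samples, microvolts), dataset `/analog/channels` (electrode
#' label strings), and root attributes `sampling_rate_hz` and `start_time_s`.
#'
#' @param path Path to an HDF5 file.
#' @return `read_analog()`: an [analog_recording].
#' @export
read_analog <- function(path) {
  if (!file.exists(path))
    rlang::abort(sprintf("no such file: %s", path),
                 class = "spikegrid_io_error")
  contents <- rhdf5::h5ls(path)
  have <- paste0(sub("/$", "", contents$group), "/", contents$name)
  for (el in c("/analog/data", "/analog/channels")) {
    if (!el %in% have)
      rlang::abort(sprintf("not a spikegrid analog file: missing dataset %s",
                           el),
                   class = "spikegrid_format_error")
  }
  attrs <- rhdf5::h5readAttributes(path, "/")
  for (at in c("sampling_rate_hz", "start_time_s")) {
    if (is.null(attrs[[at]]))
      rlang::abort(sprintf(
        "not a spikegrid analog file: missing root attribute %s", at),
        class = "spikegrid_format_error")
  }
  data <- rhdf5::h5read(path, "/analog/data")
  channels <- as.character(rhdf5::h5read(path, "/analog/channels"))
  analog_recording(data, channels,
                   sampling_rate = as.numeric(attrs$sampling_rate_hz),
                   start_time = as.numeric(attrs$start_time_s))
}

#' @rdname read_analog
#' @param rec An [analog_recording].
#' @return `write_analog()`: `path`, invisibly.
#' @export
write_analog <- function(rec, path) {
  stopifnot(inherits(rec, "analog_recording"))
  if (file.exists(path)) file.remove(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok))
    rlang::abort(sprintf("cannot create HDF5 file at %s", path),
                 class = "spikegrid_io_error")
  rhdf5::h5createGroup(path, "analog")
  rhdf5::h5createDataset(path, "analog/data", dims = dim(rec$data),
                         H5type = "H5T_IEEE_F32LE")
  rhdf5::h5write(rec$data, path, "analog/data")
  rhdf5::h5write(rec$channel_ids, path, "analog/channels")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(rec$sampling_rate, fid, "sampling_rate_hz")
  rhdf5::h5writeAttribute(rec$start_time, fid, "start_time_s")
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}
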