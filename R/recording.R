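#' Continuous multichannel EEG recording
#'
#' Container for a continuous EEG signal: a channels-by-samples matrix in
#' microvolts plus the sampling rate and 10-20-system channel labels.
#'
#' @param data numeric matrix, channels in rows, samples in columns (uV).
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector of unique channel labels; defaults
#'   to `rownames(data)`.
#' @param subject_id,dataset_id opaque identifier strings.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(400), 2), fs = 100,
#'                      channel_names = c("Cz", "Pz"))
#' rec
#' @export
eeg_recording <- function(data, fs, channel_names = rownames(data),
                          subject_id = "", dataset_id = "") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be numeric", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data))
    stop("one channel name per data row is required", call. = FALSE)
  if (anyDuplicated(channel_names))
    stop("channel names must be unique", call. = FALSE)
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         subject_id = as.character(subject_id),
         dataset_id = as.character(dataset_id)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (nzchar(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  if (nzchar(x$dataset_id)) cat("  dataset:", x$dataset_id, "\n")
  cat("  channels:", paste(x$channel_names, collapse = " "), "\n")
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples  <- function(rec) ncol(rec$data)
rec_duration <- function(rec) ncol(rec$data) / rec$fs

unit_to_uv <- function(unit) {
  switch(tolower(unit),
         "uv" = , "µv" = 1,
         "mv" = 1e3,
         "v"  = 1e6,
         "nv" = 1e-3,
         stop("unknown amplitude unit: ", unit, call. = FALSE))
}

#' Read a plain delimited-matrix recording
#'
#' The fixture format: `#`-prefixed `key=value` header lines (at least `fs`;
#' optionally `subject_id`, `dataset_id`, `unit`), then a tab-separated table
#' with one column per channel (labels in the header row) and one row per
#' sample.  Values are converted to microvolts using the declared unit
#' (default `uV`).
#'
#' @param path file path.
#' @return An [eeg_recording()].
#' @export
read_recording_matrix <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr_n <- 0L
  meta <- list(unit = "uV", subject_id = "", dataset_id = "")
  for (ln in lines) {
    if (!startsWith(ln, "#")) break
    hdr_n <- hdr_n + 1L
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  if (is.null(meta$fs)) stop("header must declare fs", call. = FALSE)
  tab <- read.table(path, header = TRUE, sep = "\t", skip = hdr_n,
                    check.names = FALSE)
  scale <- unit_to_uv(meta$unit)
  eeg_recording(t(as.matrix(tab)) * scale, fs = as.numeric(meta$fs),
                channel_names = colnames(tab),
                subject_id = meta$subject_id, dataset_id = meta$dataset_id)
}

#' Write a recording in the delimited-matrix fixture format
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_matrix <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.10g", rec$fs),
               sprintf("# subject_id=%s", rec$subject_id),
               sprintf("# dataset_id=%s", rec$dataset_id),
               "# unit=uV"), con)
  tab <- as.data.frame(t(rec$data))
  names(tab) <- rec$channel_names
  write.table(format(tab, digits = 7, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a recording, dispatching on file extension
#'
#' `.edf` files go through [read_edf()], `.vhdr` through
#' [read_brainvision()], everything else through [read_recording_matrix()].
#'
#' @param path file path.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         edf  = read_edf(path),
         vhdr = read_brainvision(path),
         read_recording_matrix(path))
}
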