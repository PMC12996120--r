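# Minimal readers/writers for the two interchange formats used by public
# resting-state EEG repositories.  Only the features the analysis needs are
# supported: continuous (unfragmented) signals, one sampling rate across the
# retained channels, amplitude units convertible to microvolts.

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read a continuous EDF/EDF+ recording
#'
#' Parses the 256-byte fixed header and per-signal headers, decodes the
#' 16-bit little-endian samples and rescales them to physical units using
#' each signal's physical/digital calibration.  Annotation channels are
#' dropped.  All retained signals must share one sampling rate; amplitudes
#' are converted to microvolts from the declared physical dimension.
#'
#' @param path path to an `.edf` file.
#' @param dataset_id optional dataset tag stored on the recording.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, dataset_id = "") {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii(con, 8)
  patient <- read_ascii(con, 80)
  read_ascii(con, 80)                       # recording id
  read_ascii(con, 8); read_ascii(con, 8)    # start date/time
  read_ascii(con, 8)                        # header bytes
  read_ascii(con, 44)                       # reserved
  n_records <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  if (is.na(ns) || ns < 1L) stop("corrupt EDF header", call. = FALSE)
  fld <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), "")
  labels    <- fld(16)
  fld(80)                                   # transducer
  phys_dim  <- fld(8)
  phys_min  <- as.numeric(fld(8))
  phys_max  <- as.numeric(fld(8))
  dig_min   <- as.numeric(fld(8))
  dig_max   <- as.numeric(fld(8))
  fld(80)                                   # prefiltering
  spr       <- as.integer(fld(8))           # samples per record
  fld(32)                                   # reserved
  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  if (!any(keep)) stop("EDF file holds no signal channels", call. = FALSE)
  if (length(unique(spr[keep])) != 1L)
    stop("mixed sampling rates across EDF signals are not supported",
         call. = FALSE)
  fs <- spr[keep][1] / rec_dur
  total <- sum(spr)
  out <- matrix(0, nrow = sum(keep), ncol = n_records * spr[keep][1])
  offs <- c(0L, cumsum(spr))
  kidx <- which(keep)
  for (r in seq_len(n_records)) {
    block <- readBin(con, "integer", n = total, size = 2, signed = TRUE,
                     endian = "little")
    if (length(block) < total) stop("truncated EDF data", call. = FALSE)
    for (j in seq_along(kidx)) {
      i <- kidx[j]
      seg <- block[(offs[i] + 1L):(offs[i] + spr[i])]
      out[j, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- seg
    }
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  off  <- phys_max - gain * dig_max
  for (j in seq_along(kidx)) {
    i <- kidx[j]
    u <- phys_dim[i]; if (!nzchar(u)) u <- "uV"
    out[j, ] <- (out[j, ] * gain[i] + off[i]) * unit_to_uv(u)
  }
  eeg_recording(out, fs = fs, channel_names = labels[keep],
                subject_id = patient, dataset_id = dataset_id)
}

#' Write a recording as EDF
#'
#' One data record per second; samples are quantized to 16 bits over the
#' per-channel amplitude range.
#'
#' @param rec an [eeg_recording()]; `fs` must be a whole number and the
#'   duration a whole number of seconds.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF export needs an integer sampling rate",
                            call. = FALSE)
  n_rec <- ncol(rec$data) / fs
  if (n_rec != round(n_rec))
    stop("EDF export needs a whole number of seconds", call. = FALSE)
  n_rec <- as.integer(n_rec)
  ns <- nrow(rec$data)
  pmax_ <- apply(abs(rec$data), 1, max)
  pmax_[pmax_ == 0] <- 1
  wr <- function(con, s, w) {
    s <- sprintf(paste0("%-", w, "s"), substr(s, 1, w))
    writeBin(charToRaw(s), con)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr(con, "0", 8)
  wr(con, rec$subject_id, 80)
  wr(con, rec$dataset_id, 80)
  wr(con, "01.01.26", 8); wr(con, "00.00.00", 8)
  wr(con, as.character(256L * (1L + ns)), 8)
  wr(con, "", 44)
  wr(con, as.character(n_rec), 8)
  wr(con, "1", 8)
  wr(con, as.character(ns), 4)
  for (lab in rec$channel_names) wr(con, lab, 16)
  for (i in seq_len(ns)) wr(con, "", 80)
  for (i in seq_len(ns)) wr(con, "uV", 8)
  for (i in seq_len(ns)) wr(con, sprintf("%.6g", -pmax_[i]), 8)
  for (i in seq_len(ns)) wr(con, sprintf("%.6g", pmax_[i]), 8)
  for (i in seq_len(ns)) wr(con, "-32768", 8)
  for (i in seq_len(ns)) wr(con, "32767", 8)
  for (i in seq_len(ns)) wr(con, "", 80)
  for (i in seq_len(ns)) wr(con, as.character(as.integer(fs)), 8)
  for (i in seq_len(ns)) wr(con, "", 32)
  gain <- pmax_ / 32767
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- as.integer(round(rec$data[i, idx] / gain[i]))
      dig <- pmin(pmax(dig, -32768L), 32767L)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a BrainVision recording
#'
#' Supports the common export layout: a text `.vhdr` header, binary
#' multiplexed data in `IEEE_FLOAT_32` or `INT_16` with per-channel
#' resolution and unit.
#'
#' @param path path to the `.vhdr` header file.
#' @param dataset_id optional dataset tag.
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(path, dataset_id = "") {
  lines <- readLines(path, warn = FALSE)
  get_kv <- function(key) {
    ln <- grep(sprintf("^%s=", key), lines, value = TRUE)
    if (!length(ln)) return(NULL)
    sub("^[^=]*=", "", ln[1])
  }
  data_file <- get_kv("DataFile")
  if (is.null(data_file)) stop("vhdr lacks DataFile", call. = FALSE)
  fmt <- get_kv("DataFormat") %||% "BINARY"
  if (toupper(fmt) != "BINARY")
    stop("only binary BrainVision data are supported", call. = FALSE)
  orient <- toupper(get_kv("DataOrientation") %||% "MULTIPLEXED")
  if (orient != "MULTIPLEXED")
    stop("only multiplexed orientation is supported", call. = FALSE)
  bin_fmt <- toupper(get_kv("BinaryFormat") %||% "IEEE_FLOAT_32")
  n_ch <- as.integer(get_kv("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get_kv("SamplingInterval"))  # interval in us
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  if (length(ch_lines) != n_ch)
    stop("channel info count disagrees with NumberOfChannels", call. = FALSE)
  ord <- order(as.integer(sub("^Ch([0-9]+)=.*", "\\1", ch_lines)))
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines[ord]), ",")
  labels <- vapply(parts, `[`, "", 1)
  res <- vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, 0)
  unit <- vapply(parts, function(p)
    if (length(p) >= 4 && nzchar(p[4])) p[4] else "uV", "")
  bin_path <- file.path(dirname(path), data_file)
  sz <- file.info(bin_path)$size
  con <- file(bin_path, "rb")
  on.exit(close(con))
  if (bin_fmt == "IEEE_FLOAT_32") {
    n_val <- sz %/% 4
    raw_v <- readBin(con, "numeric", n = n_val, size = 4, endian = "little")
  } else if (bin_fmt == "INT_16") {
    n_val <- sz %/% 2
    raw_v <- readBin(con, "integer", n = n_val, size = 2, signed = TRUE,
                     endian = "little")
  } else stop("unsupported BinaryFormat: ", bin_fmt, call. = FALSE)
  n_samp <- length(raw_v) %/% n_ch
  mat <- matrix(raw_v[seq_len(n_samp * n_ch)], nrow = n_ch)  # multiplexed
  mat <- mat * res * vapply(unit, unit_to_uv, 0)
  eeg_recording(mat, fs = fs, channel_names = labels,
                dataset_id = dataset_id)
}
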