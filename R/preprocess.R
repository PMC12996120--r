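#' Zero-phase FIR bandpass filter
#'
#' Windowed-sinc (Hamming) FIR design applied forward and backward
#' ([signal::filtfilt()]), so the passband is shaped twice and the phase is
#' zero.  Transition bandwidths follow the usual heuristic of a quarter of
#' the band edge, clamped to \[2 Hz, edge\] at the low edge and to the room
#' below Nyquist at the high edge; the filter length is `3.3 / transition`
#' seconds.
#'
#' @param rec an [eeg_recording()].
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @return The filtered recording (same shape and labels).
#' @export
bandpass <- function(rec, lo = 1, hi = 45) {
  fs <- rec$fs
  if (!(lo > 0 && hi > lo)) stop("need 0 < lo < hi", call. = FALSE)
  if (hi >= fs / 2)
    stop("upper edge must lie below the Nyquist frequency", call. = FALSE)
  trans_lo <- min(max(0.25 * lo, 2), lo)
  trans_hi <- min(max(0.25 * hi, 2), fs / 2 - hi)
  ntaps <- ceiling(3.3 * fs / min(trans_lo, trans_hi))
  ntaps <- min(ntaps, max(3L, floor((ncol(rec$data) - 1) / 3)))
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1   # odd length, type-I linear phase
  h <- signal::fir1(ntaps - 1, c(lo, hi) / (fs / 2), type = "pass")
  out <- rec$data
  for (i in seq_len(nrow(out)))
    out[i, ] <- signal::filtfilt(h, out[i, ])
  rec$data <- out
  rec
}

#' Flag channels with outlying variance
#'
#' A channel is bad when its variance exceeds the mean channel variance by
#' more than `z_thresh` standard deviations of the channel variances.  When
#' the variances have zero spread (identical channels) nothing is flagged.
#'
#' @param rec an [eeg_recording()] with at least 3 channels.
#' @param z_thresh variance z-score threshold (default 3).
#' @return Character vector of bad channel labels (possibly empty).
#' @export
detect_bad_channels <- function(rec, z_thresh = 3) {
  if (nrow(rec$data) < 3L)
    stop("need at least 3 channels to judge channel variance", call. = FALSE)
  v <- apply(rec$data, 1, var)
  s <- sd(v)
  if (!is.finite(s) || s == 0) return(character(0))
  rec$channel_names[v > mean(v) + z_thresh * s]
}

#' Rebuild bad channels from good neighbours
#'
#' Bad channels are replaced by an inverse-squared-distance weighted average
#' of the good channels, using idealized 10-20 spherical coordinates
#' ([standard_1020_positions()]).  A bad channel with no tabulated position
#' falls back to the plain mean of the good channels (with a warning).  Good
#' channels pass through untouched.
#'
#' @param rec an [eeg_recording()].
#' @param bads character vector of channel labels to rebuild.
#' @return The repaired recording.
#' @export
interpolate_bad <- function(rec, bads) {
  if (length(bads) == 0) return(rec)
  bads <- unique(as.character(bads))
  unknown <- setdiff(bads, rec$channel_names)
  if (length(unknown))
    stop("bad channels not present in recording: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  good <- setdiff(rec$channel_names, bads)
  if (length(good) == 0)
    stop("all channels are bad; recording is unrecoverable", call. = FALSE)
  pos <- standard_1020_positions()
  gm <- colMeans(rec$data[good, , drop = FALSE])
  for (b in bads) {
    pb <- pos[pos$label == b, ]
    pg <- pos[match(good, pos$label), ]
    usable <- which(!is.na(pg$x))
    if (nrow(pb) == 0 || length(usable) == 0) {
      warning("no montage position for '", b,
              "'; using the mean of the good channels", call. = FALSE)
      rec$data[b, ] <- gm
      next
    }
    d2 <- (pg$x[usable] - pb$x)^2 + (pg$y[usable] - pb$y)^2 +
      (pg$z[usable] - pb$z)^2
    w <- 1 / pmax(d2, 1e-12)
    w <- w / sum(w)
    rec$data[b, ] <- w %*% rec$data[good[usable], , drop = FALSE]
  }
  rec
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels, so every sample has
#' zero mean over channels afterwards.  A single-channel recording is
#' returned unchanged with a warning.
#'
#' @param rec an [eeg_recording()].
#' @return The re-referenced recording.
#' @export
average_reference <- function(rec) {
  if (nrow(rec$data) < 2L) {
    warning("average reference needs at least 2 channels; returning input",
            call. = FALSE)
    return(rec)
  }
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Cut a recording into fixed epochs and reject on amplitude
#'
#' Consecutive non-overlapping epochs of `epoch_len_s` seconds; an epoch is
#' rejected when any sample on any channel exceeds `amp_thresh_uv` in
#' absolute value.
#'
#' @param rec an [eeg_recording()] at least one epoch long.
#' @param epoch_len_s epoch length in seconds (default 4).
#' @param amp_thresh_uv absolute rejection threshold in microvolts
#'   (default 100).
#' @return An object of class `eeg_epochs`: list with `epochs` (list of
#'   channels-by-samples matrices), `fs`, `channel_names`, `n_rejected`,
#'   `bad_channels`.
#' @export
epoch_and_reject <- function(rec, epoch_len_s = 4, amp_thresh_uv = 100) {
  len <- round(epoch_len_s * rec$fs)
  if (ncol(rec$data) < len)
    stop("recording shorter than one epoch", call. = FALSE)
  n_ep <- floor(ncol(rec$data) / len)
  keep <- vector("list", n_ep)
  n_rej <- 0L
  for (k in seq_len(n_ep)) {
    seg <- rec$data[, ((k - 1L) * len + 1L):(k * len), drop = FALSE]
    if (max(abs(seg)) > amp_thresh_uv) n_rej <- n_rej + 1L
    else keep[[k]] <- seg
  }
  keep <- keep[!vapply(keep, is.null, TRUE)]
  if (length(keep) == 0)
    warning("all epochs rejected", call. = FALSE)
  structure(list(epochs = keep, fs = rec$fs,
                 channel_names = rec$channel_names,
                 n_rejected = n_rej, bad_channels = character(0)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d retained epochs (%d rejected), %d channels @ %g Hz\n",
              length(x$epochs), x$n_rejected, length(x$channel_names), x$fs))
  if (length(x$bad_channels))
    cat("  interpolated:", paste(x$bad_channels, collapse = " "), "\n")
  invisible(x)
}

#' Full preprocessing chain for one recording
#'
#' Bandpass filter, bad-channel detection and interpolation, average
#' reference, epoching with amplitude rejection.
#'
#' @param rec an [eeg_recording()].
#' @param cfg a [pci_config()] list (filter band, bad-channel z, epoch
#'   length, rejection threshold).
#' @return An `eeg_epochs` object; `bad_channels` records what was
#'   interpolated.
#' @export
preprocess_recording <- function(rec, cfg = pci_config()) {
  rec <- bandpass(rec, cfg$filter_band[1], cfg$filter_band[2])
  bads <- if (nrow(rec$data) >= 3L)
    detect_bad_channels(rec, cfg$bad_channel_z) else character(0)
  if (length(bads)) rec <- interpolate_bad(rec, bads)
  if (nrow(rec$data) >= 2L) rec <- average_reference(rec)
  ep <- epoch_and_reject(rec, cfg$epoch_len_s, cfg$amp_thresh_uv)
  ep$bad_channels <- bads
  ep
}
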