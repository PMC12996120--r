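#' Frequency band definition
#'
#' Bands are half-open intervals `[lo, hi)`, so the 8 Hz bin belongs to
#' alpha, not theta, and no bin is counted twice.
#'
#' @param name band name.
#' @param lo,hi band edges in Hz, `lo < hi`.
#' @return A `band_definition` list.
#' @export
band_definition <- function(name, lo, hi) {
  if (!(lo < hi)) stop("band needs lo < hi", call. = FALSE)
  structure(list(name = name, lo = lo, hi = hi), class = "band_definition")
}

#' Canonical theta and alpha bands
#' @return Named list of [band_definition()]s: theta \[4, 8), alpha \[8, 13).
#' @export
default_bands <- function() {
  list(theta = band_definition("theta", 4, 8),
       alpha = band_definition("alpha", 8, 13))
}

#' Channel group
#' @param name group name.
#' @param labels non-empty character vector of channel labels.
#' @return A `channel_group` list.
#' @export
channel_group <- function(name, labels) {
  if (length(labels) == 0) stop("channel group needs labels", call. = FALSE)
  structure(list(name = name, labels = as.character(labels)),
            class = "channel_group")
}

#' Standard posterior and frontal channel groups
#'
#' Posterior: O1 O2 Oz P3 P4 Pz P7 P8 (where alpha is maximal);
#' frontal: Fz F3 F4 (where theta is maximal).
#'
#' @return Named list of [channel_group()]s.
#' @export
default_groups <- function() {
  list(posterior = channel_group(
         "posterior", c("O1", "O2", "Oz", "P3", "P4", "Pz", "P7", "P8")),
       frontal = channel_group("frontal", c("Fz", "F3", "F4")))
}

#' Power spectrum container
#'
#' @param freqs strictly increasing frequency grid in Hz.
#' @param power matrix of nonnegative PSD values, one column per channel
#'   (uV^2/Hz), or a vector for a single channel.
#' @param channel_names channel labels (one per column).
#' @return An `eeg_spectrum` object with fields `freqs`, `power`,
#'   `channel_names`, `resolution`.
#' @export
eeg_spectrum <- function(freqs, power, channel_names = NULL) {
  power <- as.matrix(power)
  if (length(freqs) != nrow(power))
    stop("freqs and power disagree in length", call. = FALSE)
  if (is.unsorted(freqs, strictly = TRUE))
    stop("freqs must be strictly increasing", call. = FALSE)
  if (any(power < 0)) stop("power must be nonnegative", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- colnames(power) %||% paste0("ch", seq_len(ncol(power)))
  colnames(power) <- channel_names
  res <- if (length(freqs) > 1) min(diff(freqs)) else NA_real_
  structure(list(freqs = as.numeric(freqs), power = power,
                 channel_names = channel_names, resolution = res),
            class = "eeg_spectrum")
}

#' @export
print.eeg_spectrum <- function(x, ...) {
  cat(sprintf("<eeg_spectrum> %d bins (%.4g-%.4g Hz, res %.4g Hz), %d channel(s)\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$resolution,
              ncol(x$power)))
  invisible(x)
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Welch power spectral density of an epoch set
#'
#' Hann-tapered segments of `win_s` seconds with the given overlap are taken
#' inside each retained epoch (a 4 s epoch yields exactly one 4 s window);
#' periodograms are averaged over windows and epochs, per channel.  The
#' one-sided PSD is scaled so that its integral equals signal variance
#' (power in uV^2/Hz); frequency resolution is `1/win_s` Hz.
#'
#' @param ep an `eeg_epochs` object with at least one retained epoch.
#' @param win_s window length in seconds (default 4).
#' @param overlap fractional window overlap in \[0, 1) (default 0.5).
#' @return An [eeg_spectrum()].
#' @export
welch_psd <- function(ep, win_s = 4, overlap = 0.5) {
  if (length(ep$epochs) == 0)
    stop("no retained epochs to estimate a spectrum from", call. = FALSE)
  fs <- ep$fs
  nwin <- round(win_s * fs)
  hop <- max(1L, round(nwin * (1 - overlap)))
  w <- hann_window(nwin)
  u <- sum(w^2)
  n_ch <- length(ep$channel_names)
  n_keep <- floor(nwin / 2) + 1L
  acc <- matrix(0, n_keep, n_ch)
  n_seg <- 0L
  for (seg in ep$epochs) {
    if (ncol(seg) < nwin) next
    starts <- seq(1L, ncol(seg) - nwin + 1L, by = hop)
    for (s in starts) {
      x <- seg[, s:(s + nwin - 1L), drop = FALSE] * rep(w, each = n_ch)
      sp <- Mod(stats::mvfft(t(x)))^2 / (fs * u)
      sp <- sp[seq_len(n_keep), , drop = FALSE]
      if (n_keep > 2L) sp[2:(n_keep - 1L), ] <- 2 * sp[2:(n_keep - 1L), ]
      if (nwin %% 2 == 1L) sp[n_keep, ] <- 2 * sp[n_keep, ]
      acc <- acc + sp
      n_seg <- n_seg + 1L
    }
  }
  if (n_seg == 0L)
    stop("epochs shorter than the Welch window", call. = FALSE)
  freqs <- (seq_len(n_keep) - 1L) * fs / nwin
  eeg_spectrum(freqs, acc / n_seg, ep$channel_names)
}

#' Average a spectrum into 1 Hz bins
#'
#' Power is averaged within consecutive half-open bins `[k - 0.5, k + 0.5)`
#' and labeled at the integer frequency `k`, matching the common-resolution
#' grid the cohort analysis runs on.
#'
#' @param spec an [eeg_spectrum()] with native resolution at most 1 Hz.
#' @return An [eeg_spectrum()] on the integer grid.
#' @export
bin_to_1hz <- function(spec) {
  if (is.finite(spec$resolution) && spec$resolution > 1 + 1e-9)
    stop("spectrum resolution is coarser than 1 Hz", call. = FALSE)
  k <- floor(spec$freqs + 0.5)          # [k - 0.5, k + 0.5) -> k
  ks <- sort(unique(k))
  pw <- matrix(0, length(ks), ncol(spec$power))
  for (i in seq_along(ks))
    pw[i, ] <- colMeans(spec$power[k == ks[i], , drop = FALSE])
  eeg_spectrum(ks, pw, spec$channel_names)
}

#' Average a spectrum over a channel group
#'
#' Unweighted mean over the group channels present in the spectrum; absent
#' labels are reported via `message()`.
#'
#' @param spec an [eeg_spectrum()].
#' @param group a [channel_group()].
#' @return A single-channel [eeg_spectrum()] named after the group.
#' @export
group_average <- function(spec, group) {
  present <- intersect(group$labels, spec$channel_names)
  if (length(present) == 0)
    stop("no '", group$name, "' channels present in the spectrum",
         call. = FALSE)
  missing <- setdiff(group$labels, present)
  if (length(missing))
    message("group '", group$name, "' missing channels: ",
            paste(missing, collapse = " "))
  pw <- rowMeans(spec$power[, present, drop = FALSE])
  eeg_spectrum(spec$freqs, matrix(pw, ncol = 1), group$name)
}

#' Band spectral centroid
#'
#' The power-weighted mean frequency over the grid points with
#' `lo <= f < hi`: `sum(f * P(f)) / sum(P(f))`.
#'
#' @param spec a single-channel [eeg_spectrum()].
#' @param band a [band_definition()].
#' @return Centroid frequency in Hz, guaranteed inside `[lo, hi)`.
#' @export
band_centroid <- function(spec, band) {
  if (ncol(spec$power) != 1L)
    stop("band_centroid expects a single-channel spectrum; ",
         "use group_average() first", call. = FALSE)
  sel <- spec$freqs >= band$lo & spec$freqs < band$hi
  p <- spec$power[sel, 1]
  if (length(p) == 0 || sum(p) <= 0)
    stop("undefined centroid: no in-band power in band '", band$name, "'",
         call. = FALSE)
  sum(spec$freqs[sel] * p) / sum(p)
}

#' Export a spectrum as delimited text
#' @param spec an [eeg_spectrum()].
#' @param path output path (tab-separated: freq column then one column per
#'   channel).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  tab <- data.frame(freq = spec$freqs, spec$power, check.names = FALSE)
  names(tab) <- c("freq", spec$channel_names)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#' @param path input path.
#' @return An [eeg_spectrum()].
#' @export
read_spectrum <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  eeg_spectrum(tab$freq, as.matrix(tab[, -1, drop = FALSE]),
               names(tab)[-1])
}
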