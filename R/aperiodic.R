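#' Fixed-mode aperiodic (1/f) fit
#'
#' Fits `log10 P(f) = offset - exponent * log10 f` over the fit range with a
#' robust two-pass procedure: an ordinary least-squares fit, then a refit
#' that keeps only the bins lying at or below the initial line (oscillatory
#' peaks protrude above it).  Concretely, positive residuals are clamped at
#' zero and bins whose clamped residual exceeds their 2.5th percentile are
#' excluded from the second pass, so narrow-band peaks do not tilt the
#' aperiodic estimate.
#'
#' @param spec a single-channel [eeg_spectrum()] in linear power units.
#' @param fit_range Hz interval to fit over (default `c(1, 40)`).
#' @return An `aperiodic_fit` object: `offset` (log10 power), `exponent`
#'   (positive for decaying spectra), `fit_range`, `n_bins_used`.
#' @export
fit_aperiodic <- function(spec, fit_range = c(1, 40)) {
  if (ncol(spec$power) != 1L)
    stop("fit_aperiodic expects a single-channel spectrum", call. = FALSE)
  sel <- spec$freqs >= fit_range[1] & spec$freqs <= fit_range[2] &
    spec$power[, 1] > 0
  if (sum(sel) < 5L)
    stop("aperiodic fit needs at least 5 positive-power bins in range",
         call. = FALSE)
  lf <- log10(spec$freqs[sel])
  lp <- log10(spec$power[sel, 1])
  fit1 <- lm.fit(cbind(1, lf), lp)
  resid_pos <- pmax(fit1$residuals, 0)
  thr <- quantile(resid_pos, 0.025, names = FALSE)
  keep <- resid_pos <= thr
  co <- if (sum(keep) >= 5L)
    lm.fit(cbind(1, lf[keep]), lp[keep])$coefficients
  else fit1$coefficients
  structure(list(offset = unname(co[1]), exponent = unname(-co[2]),
                 fit_range = fit_range, n_bins_used = sum(keep)),
            class = "aperiodic_fit")
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("<aperiodic_fit> offset %.3f, exponent %.3f (fit %g-%g Hz, %d bins)\n",
              x$offset, x$exponent, x$fit_range[1], x$fit_range[2],
              x$n_bins_used))
  invisible(x)
}

#' Aperiodic model line on a frequency grid
#' @param fit an `aperiodic_fit`.
#' @param freqs frequencies in Hz (> 0).
#' @return log10-power values of the fitted line.
#' @export
aperiodic_line <- function(fit, freqs) fit$offset - fit$exponent * log10(freqs)

#' Subtract the aperiodic component in log-power space
#'
#' `residual(f) = max(0, log10 P(f) - line(f))`: negative residuals are
#' clamped to zero, so what remains is the oscillatory power excess above
#' the 1/f background, in log10-power units.
#'
#' @param spec an [eeg_spectrum()] (any number of channels; the same fit is
#'   subtracted from each).
#' @param fit an `aperiodic_fit` from [fit_aperiodic()].
#' @return An [eeg_spectrum()] whose `power` holds the nonnegative log-power
#'   residual; bins at `f <= 0` or with nonpositive power get residual 0.
#' @export
subtract_aperiodic <- function(spec, fit) {
  line <- ifelse(spec$freqs > 0, aperiodic_line(fit, spec$freqs), Inf)
  resid <- spec$power
  for (j in seq_len(ncol(resid))) {
    lp <- ifelse(spec$power[, j] > 0, log10(spec$power[, j]), -Inf)
    resid[, j] <- pmax(0, lp - line)
  }
  out <- eeg_spectrum(spec$freqs, resid, spec$channel_names)
  attr(out, "units") <- "log10-power residual"
  out
}

#' Aperiodic-corrected band centroid
#'
#' [band_centroid()] applied to the clamped log-power residual; errors when
#' the whole band was clamped to zero (such subjects are excluded from the
#' corrected analysis).
#'
#' @param spec a single-channel [eeg_spectrum()] in linear power units.
#' @param band a [band_definition()].
#' @param fit an `aperiodic_fit`.
#' @return Corrected centroid in Hz.
#' @export
corrected_centroid <- function(spec, band, fit)
  band_centroid(subtract_aperiodic(spec, fit), band)
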