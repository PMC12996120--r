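# Brute-force oracles, kept deliberately independent of the package's own
# code paths: direct formula evaluation on small inputs.

oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

oracle_spearman <- function(x, y)
  oracle_pearson(rank(x), rank(y))

oracle_partial <- function(x, y, z) {
  rxy <- oracle_pearson(x, y)
  rxz <- oracle_pearson(x, z)
  ryz <- oracle_pearson(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

oracle_centroid <- function(freqs, power, lo, hi) {
  sel <- freqs >= lo & freqs < hi
  sum(freqs[sel] * power[sel]) / sum(power[sel])
}

oracle_bin1hz <- function(freqs, power) {
  k <- floor(freqs + 0.5)
  ks <- sort(unique(k))
  list(freqs = ks,
       power = vapply(ks, function(kk) mean(power[k == kk]), 0))
}

# Small deterministic helpers ------------------------------------------------

# Single-channel spectrum on a given grid.
spec1 <- function(freqs, power, name = "ch1")
  eeg_spectrum(freqs, matrix(power, ncol = 1), name)

# A sinusoid recording with the given channels, amplitude in uV.
sine_recording <- function(freq, fs = 160, dur = 60, amp = 10,
                           channels = c("O1", "O2", "Oz")) {
  t <- (0:(fs * dur - 1)) / fs
  x <- amp * sin(2 * pi * freq * t)
  eeg_recording(matrix(rep(x, each = length(channels)),
                       nrow = length(channels)),
                fs, channels, subject_id = "fix")
}

# Cohort table straight from frequency columns.
cohort_from <- function(f_theta, f_alpha, ...)
  ensure_cohort_metrics(data.frame(
    subject_id = sprintf("S%03d", seq_along(f_theta)),
    f_theta = f_theta, f_alpha = f_alpha, ...,
    stringsAsFactors = FALSE))

# A mid-sized plausible cohort for validation machinery tests: ratios around
# the empirical mean, theta uniform, mildly coupled so correlations are away
# from zero.
plausible_cohort <- function(n = 60, seed = 101) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  R <- pmin(pmax(rnorm(n, 1.677, 0.142), 1.26), 2.09)
  ft <- pmin(pmax(8.25 / R + runif(n, 0, 1.2), 4.05), 7.9)
  fa <- pmin(pmax(R * ft, 8.01), 12.99)
  cohort_from(ft, fa, age = round(runif(n, 20, 77), 1),
              sex = sample(c("F", "M"), n, TRUE))
}
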