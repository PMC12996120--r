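#' Specification for the synthetic resting-EEG generator
#'
#' The generator emulates eyes-closed resting EEG: one theta oscillator
#' (maximal frontally) and one alpha oscillator (maximal posteriorly)
#' superposed on 1/f^chi background noise, with the per-subject alpha/theta
#' ratio drawn from a normal distribution matched to the cohort statistics
#' the method targets (mean 1.677, SD 0.142).
#'
#' `snr` is the ratio of one oscillator's power (at unit channel gain) to
#' the total broadband noise power per channel.  `frontal_theta_gain` and
#' `posterior_alpha_gain` are amplitude boosts applied on top of a unit base
#' gain, so both rhythms are visible everywhere but each is maximal over
#' its canonical region.
#'
#' @param n_subjects number of subjects.
#' @param fs sampling rate in Hz (default 160).
#' @param duration_s recording length in seconds (default 60).
#' @param ratio_mean,ratio_sd normal parameters of the true alpha/theta
#'   ratio (defaults 1.677, 0.142).
#' @param theta_range uniform support of the true theta frequency
#'   (default `c(4.5, 7.5)` Hz).
#' @param alpha_clip allowed range of the true alpha frequency
#'   (default `c(8.25, 12.75)` Hz); the ratio is truncated per subject so
#'   the implied alpha stays inside it.
#' @param snr oscillation-to-background power ratio (default 2).
#' @param aperiodic_exponent chi of the 1/f^chi background (default 1).
#' @param frontal_theta_gain,posterior_alpha_gain regional amplitude boosts
#'   (default 2).
#' @param osc_amplitude_uv base oscillation amplitude in uV (default 15;
#'   keeps clean data clear of the 100 uV rejection threshold).
#' @param alpha_mod logical; slow waxing-waning amplitude modulation of the
#'   alpha oscillator (default off so spectra stay analytic).
#' @param seed RNG seed.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_subjects = 1, fs = 160, duration_s = 60,
                       ratio_mean = 1.677, ratio_sd = 0.142,
                       theta_range = c(4.5, 7.5),
                       alpha_clip = c(8.25, 12.75),
                       snr = 2, aperiodic_exponent = 1,
                       frontal_theta_gain = 2, posterior_alpha_gain = 2,
                       osc_amplitude_uv = 15, alpha_mod = FALSE,
                       seed = NULL) {
  stopifnot(n_subjects >= 1, fs > 0, duration_s > 0, snr > 0,
            theta_range[1] >= 4, theta_range[2] < 8,
            alpha_clip[1] >= 8, alpha_clip[2] < 13)
  structure(list(n_subjects = n_subjects, fs = fs, duration_s = duration_s,
                 ratio_mean = ratio_mean, ratio_sd = ratio_sd,
                 theta_range = theta_range, alpha_clip = alpha_clip,
                 snr = snr, aperiodic_exponent = aperiodic_exponent,
                 frontal_theta_gain = frontal_theta_gain,
                 posterior_alpha_gain = posterior_alpha_gain,
                 osc_amplitude_uv = osc_amplitude_uv,
                 alpha_mod = alpha_mod, seed = seed),
            class = "synth_spec")
}

synth_channels <- c("Fz", "F3", "F4", "Cz", "C3", "C4",
                    "O1", "O2", "Oz", "Pz", "P3")
synth_frontal <- c("Fz", "F3", "F4")
synth_posterior <- c("O1", "O2", "Oz", "Pz", "P3")

#' Draw ratios from a symmetrically truncated normal
#'
#' @param n number of draws.
#' @param mean,sd normal parameters (defaults 1.677, 0.142).
#' @param trunc_sd symmetric truncation in SD units (default 3).
#' @param seed RNG seed.
#' @return Numeric vector of ratios.
#' @export
sample_ratios <- function(n, mean = 1.677, sd = 0.142, trunc_sd = 3,
                          seed = NULL) {
  with_seed(seed,
            rtruncnorm(n, mean, sd, mean - trunc_sd * sd,
                       mean + trunc_sd * sd))
}

#' Sample per-subject true frequency pairs
#'
#' True theta frequencies are uniform on `theta_range`; the true ratio is
#' drawn from `Normal(ratio_mean, ratio_sd)` truncated per subject so the
#' implied alpha frequency `R * f_theta` stays inside `alpha_clip`
#' (`ratio_sd = 0` degenerates to `ratio_mean`, clipped into the feasible
#' interval).  Ages are uniform on 20-77 years and sex is balanced; no
#' demographic effect is planted.
#'
#' @param spec a [synth_spec()].
#' @return Truth table data.frame: `subject_id`, `f_theta_true`,
#'   `f_alpha_true`, `ratio_true`, `age`, `sex`.
#' @export
sample_frequency_pairs <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_subjects
    ft <- runif(n, spec$theta_range[1], spec$theta_range[2])
    r_lo <- spec$alpha_clip[1] / ft
    r_hi <- spec$alpha_clip[2] / ft
    if (any(r_lo >= r_hi)) stop("infeasible ranges", call. = FALSE)
    R <- vapply(seq_len(n), function(i)
      rtruncnorm(1, spec$ratio_mean, spec$ratio_sd, r_lo[i], r_hi[i]), 0)
    data.frame(subject_id = sprintf("S%03d", seq_len(n)),
               f_theta_true = ft, f_alpha_true = R * ft, ratio_true = R,
               age = round(runif(n, 20, 77), 1),
               sex = sample(c("F", "M"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

# 1/f^chi noise with unit variance, by spectral shaping of white noise.
pink_noise <- function(n, fs, exponent) {
  half <- floor(n / 2)
  f <- (1:half) * fs / n
  amp <- f^(-exponent / 2)
  phase <- runif(half, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(length.out = n)
  full[2:(half + 1)] <- spec
  if (n %% 2 == 0) {
    full[half + 1] <- complex(real = amp[half] *
                                sign(stats::rnorm(1)), imaginary = 0)
    if (half > 1) full[(half + 2):n] <- Conj(spec[(half - 1):1])
  } else {
    full[(half + 2):n] <- Conj(spec[half:1])
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate one synthetic resting-EEG recording
#'
#' An 11-channel 10-20 layout (Fz F3 F4 Cz C3 C4 O1 O2 Oz Pz P3) carrying
#' the two planted sinusoids with region-dependent gains plus independent
#' per-channel 1/f^chi noise scaled to the spec's `snr`.  Amplitudes are in
#' uV and sized so clean data passes the 100 uV rejection.
#'
#' @param f_theta,f_alpha planted frequencies in Hz (inside the canonical
#'   bands).
#' @param spec a [synth_spec()].
#' @param subject_id identifier for the recording.
#' @param seed RNG seed (optional; falls back to the spec's stream).
#' @return An [eeg_recording()].
#' @export
synth_recording <- function(f_theta, f_alpha, spec = synth_spec(),
                            subject_id = "sim", seed = NULL) {
  gen <- function() {
    n <- round(spec$fs * spec$duration_s)
    t <- (0:(n - 1)) / spec$fs
    a <- spec$osc_amplitude_uv
    noise_sd <- sqrt(a^2 / (2 * spec$snr))
    mod <- if (spec$alpha_mod)
      0.75 + 0.25 * cos(2 * pi * 0.1 * t) else 1
    dat <- matrix(0, length(synth_channels), n)
    for (i in seq_along(synth_channels)) {
      ch <- synth_channels[i]
      g_t <- if (ch %in% synth_frontal) spec$frontal_theta_gain else 1
      g_a <- if (ch %in% synth_posterior) spec$posterior_alpha_gain else 1
      dat[i, ] <- g_t * a * sin(2 * pi * f_theta * t + runif(1, 0, 2 * pi)) +
        g_a * a * mod * sin(2 * pi * f_alpha * t + runif(1, 0, 2 * pi)) +
        noise_sd * pink_noise(n, spec$fs, spec$aperiodic_exponent)
    }
    eeg_recording(dat, spec$fs, synth_channels, subject_id = subject_id,
                  dataset_id = "synthetic")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate a full synthetic cohort
#'
#' Samples true frequency pairs, renders one recording per subject and
#' (optionally) runs the analysis pipeline over them, so every downstream
#' module can be exercised without external data.  With `dir` set, the
#' recordings are written in the delimited-matrix fixture format together
#' with `truth.csv` and a `manifest.csv`.
#'
#' @param spec a [synth_spec()].
#' @param dir optional output directory for on-disk fixtures.
#' @param cfg a [pci_config()] used for the analysis pass.
#' @param analyze logical; run [analyze_recording()] on each subject
#'   (default TRUE).
#' @return List with `truth` (truth table), `recordings` (list, or paths
#'   when `dir` is set), `cohort` (analyzed cohort table or NULL), and
#'   `exclusions` (data.frame of skipped subjects).
#' @export
make_cohort <- function(spec = synth_spec(), dir = NULL,
                        cfg = pci_config(), analyze = TRUE) {
  truth <- sample_frequency_pairs(spec)
  # one derived, collision-free seed per subject (kept under 2^31)
  seeds <- if (is.null(spec$seed)) NULL
  else (as.numeric(spec$seed) + 7919 * seq_len(spec$n_subjects)) %%
    .Machine$integer.max
  recs <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects))
    recs[[i]] <- synth_recording(truth$f_theta_true[i],
                                 truth$f_alpha_true[i], spec,
                                 subject_id = truth$subject_id[i],
                                 seed = seeds[i])
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(dir, paste0(truth$subject_id, ".tsv"))
    for (i in seq_along(recs)) write_recording_matrix(recs[[i]], paths[i])
    write.table(truth, file.path(dir, "truth.csv"), sep = ",",
                quote = TRUE, row.names = FALSE)
    write.table(data.frame(subject_id = truth$subject_id,
                           file = basename(paths)),
                file.path(dir, "manifest.csv"), sep = ",", quote = TRUE,
                row.names = FALSE)
  }
  cohort <- NULL
  exclusions <- data.frame(subject_id = character(0), stage = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
  if (analyze) {
    res <- analyze_recordings(recs, cfg)
    cohort <- res$cohort
    exclusions <- res$exclusions
    if (!is.null(cohort)) {
      cohort$age <- truth$age[match(cohort$subject_id, truth$subject_id)]
      cohort$sex <- truth$sex[match(cohort$subject_id, truth$subject_id)]
      cohort$dataset <- "synthetic"
    }
  }
  list(truth = truth,
       recordings = if (is.null(dir)) recs else paths,
       cohort = cohort, exclusions = exclusions)
}

#' Construct a cohort with ratios clustered at a target constant
#'
#' Builds the specificity-sweep test bed: ratios are drawn from
#' `Normal(c_star, ratio_sd)` (clipped at 2.5 SD) and each subject's
#' theta/alpha pair is placed so that the centroid separation grows with
#' the subject's distance `|R - c_star|` (plus noise).  The separation is
#' chosen inside the band-feasibility window common to the whole cohort,
#' which removes the monotone drift of feasible separations in R that would
#' otherwise drag the sweep argmax off target.  On such a cohort the
#' PCI-convergence correlation peaks at reference constants near `c_star`.
#'
#' @param n subjects.
#' @param c_star target ratio constant (e.g. 1.5, phi, 1.9).
#' @param ratio_sd SD of the ratio cluster (default 0.04).
#' @param coupling_noise SD of the noise on the proximity-separation
#'   coupling (default 0.1).
#' @param seed RNG seed.
#' @param params a [phi_params()].
#' @return A cohort data.frame with full index columns.
#' @export
synth_coupled_cohort <- function(n, c_star, ratio_sd = 0.04,
                                 coupling_noise = 0.1, seed = NULL,
                                 params = phi_params()) {
  with_seed(seed, {
    R <- rnorm(n, c_star, ratio_sd)
    R <- pmin(pmax(R, c_star - 2.5 * ratio_sd), c_star + 2.5 * ratio_sd)
    r_min <- min(R); r_max <- max(R)
    lo <- max(4 * (r_max - 1), 8 * (r_max - 1) / r_max) + 0.02
    hi <- min(8 * (r_min - 1), 13 * (r_min - 1) / r_min) - 0.02
    if (hi <= lo)
      stop("no common feasible separation window; reduce ratio_sd",
           call. = FALSE)
    u <- pmin(abs(R - c_star) / (2.5 * ratio_sd), 1)
    u <- pmin(pmax(0.05 + 0.9 * u + rnorm(n, 0, coupling_noise), 0), 1)
    df <- lo + (hi - lo) * u
    ft <- df / (R - 1)
    ensure_cohort_metrics(
      data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                 f_theta = ft, f_alpha = R * ft,
                 stringsAsFactors = FALSE),
      params)
  })
}
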