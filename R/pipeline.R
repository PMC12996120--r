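#' Analysis configuration
#'
#' Collects every tunable of the recording-to-cohort pipeline in one
#' serializable list.
#'
#' @param filter_band bandpass edges in Hz (default `c(1, 45)`).
#' @param bad_channel_z variance z-score for bad channels (default 3).
#' @param epoch_len_s epoch length in seconds (default 4).
#' @param amp_thresh_uv epoch rejection threshold in uV (default 100).
#' @param welch_win_s,welch_overlap Welch window and overlap (defaults 4 s,
#'   0.5).
#' @param grid `"1hz"` (common 1 Hz bins, default) or `"native"` (the
#'   Welch resolution).
#' @param bands band definitions ([default_bands()]).
#' @param groups channel groups ([default_groups()]).
#' @param params a [phi_params()].
#' @param theta_source `"posterior"` or `"frontal"`: which group the theta
#'   centroid is taken from (alpha always comes from the posterior group).
#' @param aperiodic logical; subtract the 1/f component before the
#'   centroids (default FALSE).
#' @param fit_range aperiodic fit range in Hz (default `c(1, 40)`).
#' @param seed default seed for stochastic validation steps.
#' @return A `pci_config` list.
#' @export
pci_config <- function(filter_band = c(1, 45), bad_channel_z = 3,
                       epoch_len_s = 4, amp_thresh_uv = 100,
                       welch_win_s = 4, welch_overlap = 0.5,
                       grid = c("1hz", "native"),
                       bands = default_bands(), groups = default_groups(),
                       params = phi_params(),
                       theta_source = c("posterior", "frontal"),
                       aperiodic = FALSE, fit_range = c(1, 40),
                       seed = NULL) {
  grid <- match.arg(grid)
  theta_source <- match.arg(theta_source)
  structure(list(filter_band = filter_band, bad_channel_z = bad_channel_z,
                 epoch_len_s = epoch_len_s, amp_thresh_uv = amp_thresh_uv,
                 welch_win_s = welch_win_s, welch_overlap = welch_overlap,
                 grid = grid, bands = bands, groups = groups,
                 params = params, theta_source = theta_source,
                 aperiodic = aperiodic, fit_range = fit_range, seed = seed),
            class = "pci_config")
}

group_centroid <- function(spec, group, band, cfg) {
  gs <- group_average(spec, group)
  if (cfg$aperiodic) {
    fit <- fit_aperiodic(gs, cfg$fit_range)
    corrected_centroid(gs, band, fit)
  } else band_centroid(gs, band)
}

#' Analyze one recording into a cohort row
#'
#' Preprocess (filter, bad channels, reference, epoch/reject), Welch PSD,
#' optional 1 Hz binning, group averaging, band centroids (theta from the
#' configured source group, alpha from the posterior group), then the
#' per-subject indices.  When frontal channels are present a
#' `f_theta_frontal` column records the frontal theta centroid alongside
#' the configured one.
#'
#' @param rec an [eeg_recording()].
#' @param cfg a [pci_config()].
#' @return One-row cohort data.frame (see [subject_metrics()]) plus
#'   `dataset`, `n_rejected`, `n_bad_channels`, and `f_theta_frontal`
#'   (NA when no frontal channel is present).
#' @export
analyze_recording <- function(rec, cfg = pci_config()) {
  ep <- preprocess_recording(rec, cfg)
  if (length(ep$epochs) == 0)
    stop("no clean epochs for subject ", rec$subject_id, call. = FALSE)
  spec <- welch_psd(ep, cfg$welch_win_s, cfg$welch_overlap)
  if (cfg$grid == "1hz") spec <- bin_to_1hz(spec)
  post <- cfg$groups$posterior
  front <- cfg$groups$frontal
  f_alpha <- group_centroid(spec, post, cfg$bands$alpha, cfg)
  f_theta_post <- group_centroid(spec, post, cfg$bands$theta, cfg)
  f_theta_front <- if (any(front$labels %in% spec$channel_names))
    group_centroid(spec, front, cfg$bands$theta, cfg) else NA_real_
  f_theta <- if (cfg$theta_source == "frontal") {
    if (is.na(f_theta_front))
      stop("frontal theta requested but no frontal channel present",
           call. = FALSE)
    f_theta_front
  } else f_theta_post
  row <- subject_metrics(f_theta, f_alpha, cfg$params, cfg$theta_source,
                         subject_id = rec$subject_id)
  row$f_theta_frontal <- f_theta_front
  row$dataset <- rec$dataset_id
  row$n_rejected <- ep$n_rejected
  row$n_bad_channels <- length(ep$bad_channels)
  row
}

#' Analyze a list of in-memory recordings
#'
#' @param recs list of [eeg_recording()]s.
#' @param cfg a [pci_config()].
#' @return List with `cohort` (one row per subject that passed every
#'   stage) and `exclusions` (subject, stage, reason).
#' @export
analyze_recordings <- function(recs, cfg = pci_config()) {
  rows <- list()
  excl <- list()
  for (rec in recs) {
    row <- tryCatch(analyze_recording(rec, cfg), error = function(e) e)
    if (inherits(row, "error")) {
      excl[[length(excl) + 1L]] <-
        data.frame(subject_id = rec$subject_id, stage = "analysis",
                   reason = conditionMessage(row), stringsAsFactors = FALSE)
    } else rows[[length(rows) + 1L]] <- row
  }
  list(cohort = if (length(rows)) do.call(rbind, rows) else NULL,
       exclusions = if (length(excl)) do.call(rbind, excl)
       else data.frame(subject_id = character(0), stage = character(0),
                       reason = character(0), stringsAsFactors = FALSE))
}

#' Analyze a directory of recordings
#'
#' Reads every matching file ([read_recording()]), skipping unreadable
#' files with a logged reason, and analyzes the rest.  Exclusions are
#' bookkept per stage (read failure, no clean epochs, undefined centroid)
#' so the excluded count is decomposable.
#'
#' @param path directory of recordings.
#' @param cfg a [pci_config()].
#' @param pattern filename regexp (default matches `.tsv`, `.txt`, `.edf`,
#'   `.vhdr`).
#' @return Cohort data.frame with an `exclusions` attribute; errors if no
#'   recording could be analyzed.
#' @export
analyze_directory <- function(path, cfg = pci_config(),
                              pattern = "\\.(tsv|txt|edf|vhdr)$") {
  files <- list.files(path, pattern = pattern, full.names = TRUE)
  if (length(files) == 0)
    stop("no recordings found under ", path, call. = FALSE)
  recs <- list()
  excl <- list()
  for (f in files) {
    rec <- tryCatch(read_recording(f), error = function(e) e,
                    warning = function(w) w)
    if (inherits(rec, "condition")) {
      excl[[length(excl) + 1L]] <-
        data.frame(subject_id = basename(f), stage = "read",
                   reason = conditionMessage(rec), stringsAsFactors = FALSE)
      next
    }
    if (!nzchar(rec$subject_id))
      rec$subject_id <- sub("\\.[^.]*$", "", basename(f))
    recs[[length(recs) + 1L]] <- rec
  }
  res <- analyze_recordings(recs, cfg)
  excl <- c(excl, list(res$exclusions))
  excl <- do.call(rbind, excl)
  if (is.null(res$cohort))
    stop("no recording survived the pipeline", call. = FALSE)
  structure(res$cohort, exclusions = excl)
}
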