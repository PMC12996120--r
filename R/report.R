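report_schema_version <- "1.0"

cor_to_list <- function(cr) {
  if (is.null(cr)) return(NULL)
  list(pearson_r = cr$pearson_r, pearson_p = cr$pearson_p,
       spearman_rho = cr$spearman_rho, spearman_p = cr$spearman_p,
       ci_lo = cr$ci_lo, ci_hi = cr$ci_hi, n = cr$n)
}

null_to_list <- function(nr) {
  list(model = nr$model, n_draws = nr$n_draws,
       null_mean_r = nr$null_mean_r, null_sd_r = nr$null_sd_r,
       observed_r = nr$observed_r, z = nr$z, n_exceed = nr$n_exceed)
}

#' Full cohort validation report
#'
#' Runs the whole validation battery on a cohort table and collects the
#' results in one JSON-serializable list: ratio-distribution summary
#' (mean, SD, phi-organized percentage, percent deviation from phi and
#' from 2:1), the primary PCI-convergence correlation, both null models,
#' the specificity sweep, the regularization sensitivity table, the
#' median-split profile, per-dataset replication, and (when the columns
#' exist) subgroup tables and the frontal-theta comparison.  Sections
#' whose inputs are absent are marked `"absent"` rather than failing the
#' whole report.
#'
#' @param cohort cohort data.frame with `f_theta`, `f_alpha` and optional
#'   `age`, `sex`, `dataset`, `f_theta_frontal` columns.
#' @param cfg a [pci_config()].
#' @param n_draws_a draws for the marginal-resampling null
#'   (default 10000).
#' @param n_draws_b draws for the band-constrained null (default 2000);
#'   its truncated normals are matched to the cohort's empirical
#'   means/SDs.
#' @param n_boot bootstrap iterations (default 10000).
#' @param seed RNG seed for every stochastic section.
#' @param null_a_mode `"resample"` or `"permute"`.
#' @return A `pci_report` list (versioned schema).
#' @export
full_report <- function(cohort, cfg = pci_config(), n_draws_a = 10000,
                        n_draws_b = 2000, n_boot = 10000, seed = NULL,
                        null_a_mode = "resample") {
  params <- cfg$params
  cohort <- ensure_cohort_metrics(as.data.frame(cohort), params)
  n <- nrow(cohort)
  m <- mean(cohort$ratio)
  dev <- ratio_deviation(m, params)
  section <- function(expr) tryCatch(expr, error = function(e)
    list(error = conditionMessage(e)))
  primary <- section(cor_to_list(
    correlate(cohort$pci, cohort$conv_bounded, n_boot, seed)))
  null_a <- section(null_to_list(
    null_marginal_resample(cohort, n_draws_a, seed, mode = null_a_mode,
                           params = params)))
  null_b <- section(null_to_list(
    null_band_constrained(mean(cohort$f_theta), sd(cohort$f_theta),
                          mean(cohort$f_alpha), sd(cohort$f_alpha),
                          n_subjects = n, n_draws = n_draws_b, seed = seed,
                          params = params,
                          observed_r = cor(cohort$pci,
                                           cohort$conv_bounded))))
  sweep <- section({
    sw <- phi_sweep(cohort, params = params)
    list(constants = sw$table$c_ref, r_by_c = sw$table$r,
         argmax_c = sw$argmax_c, r_at_phi = sw$r_at_phi, form = sw$form)
  })
  eps_tab <- section(as.list(epsilon_sweep(cohort, params = params)))
  split <- section({
    ms <- median_split_profile(cohort, params)
    list(median_pci = ms$median_pci, low = as.list(ms$low),
         high = as.list(ms$high), n_low = ms$n_low, n_high = ms$n_high)
  })
  per_dataset <- "absent"
  if (!is.null(cohort$dataset) && length(unique(cohort$dataset)) > 1) {
    per_dataset <- lapply(split(cohort, cohort$dataset), function(d)
      section(cor_to_list(
        correlate(d$pci, d$conv_bounded, n_boot, seed))))
  }
  subgroups <- list(
    age = if (!is.null(cohort$age))
      section(lapply(subgroup_correlations(cohort, "age", params = params,
                                           n_boot = n_boot, seed = seed),
                     cor_to_list)) else "absent",
    sex = if (!is.null(cohort$sex))
      section(lapply(subgroup_correlations(cohort, "sex", params = params,
                                           n_boot = n_boot, seed = seed),
                     cor_to_list)) else "absent")
  frontal <- "absent"
  if (!is.null(cohort$f_theta_frontal) &&
      all(is.finite(cohort$f_theta_frontal))) {
    cf <- cohort
    cf$f_theta <- cf$f_theta_frontal
    frontal <- section({
      fv <- frontal_theta_variant(cf, cohort, params, n_boot, seed)
      list(frontal = cor_to_list(fv$frontal),
           posterior = cor_to_list(fv$posterior),
           theta_theta_r = fv$theta_theta_r, n = fv$n)
    })
  }
  structure(list(
    schema_version = report_schema_version,
    n = n,
    ratio_summary = list(mean = m, sd = sd(cohort$ratio),
                         pct_phi_organized = 100 * mean(cohort$pci > 0),
                         pct_dev_phi = unname(dev["phi"]),
                         pct_dev_harmonic = unname(dev["harmonic"])),
    primary = primary, null_a = null_a, null_b = null_b, sweep = sweep,
    epsilon = eps_tab, median_split = split, per_dataset = per_dataset,
    subgroups = subgroups, frontal = frontal, seed = seed),
    class = "pci_report")
}

#' Check a report against the shipped schema
#'
#' @param report a `pci_report` (or a list parsed back from JSON).
#' @return TRUE invisibly; errors describing the first violation
#'   otherwise.
#' @export
validate_report <- function(report) {
  need <- c("schema_version", "n", "ratio_summary", "primary", "null_a",
            "null_b", "sweep", "epsilon", "median_split", "per_dataset",
            "subgroups", "frontal")
  miss <- setdiff(need, names(report))
  if (length(miss))
    stop("report lacks sections: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rs <- report$ratio_summary
  for (k in c("mean", "sd", "pct_phi_organized", "pct_dev_phi",
              "pct_dev_harmonic"))
    if (is.null(rs[[k]])) stop("ratio_summary lacks ", k, call. = FALSE)
  if (!identical(as.character(report$schema_version),
                 report_schema_version))
    stop("unknown schema version", call. = FALSE)
  invisible(TRUE)
}

#' Write a report as JSON
#' @param report a `pci_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Render a report as Markdown
#' @param report a `pci_report` (or the same list parsed from JSON).
#' @return Character vector of Markdown lines.
#' @export
report_markdown <- function(report) {
  rs <- report$ratio_summary
  fmt_cor <- function(cr, label) {
    if (is.null(cr) || !is.null(cr$error))
      return(sprintf("- %s: unavailable", label))
    sprintf("- %s: r = %.3f (p = %.3g), 95%% CI [%.3f, %.3f], rho = %.3f, n = %d",
            label, cr$pearson_r, cr$pearson_p, cr$ci_lo, cr$ci_hi,
            cr$spearman_rho, cr$n)
  }
  lines <- c(
    "# Phi-coupling cohort report",
    "",
    sprintf("Subjects: %d", report$n),
    "",
    "## Ratio distribution",
    sprintf("- mean ratio %.3f (SD %.3f)", rs$mean, rs$sd),
    sprintf("- %.1f%% phi-organized (PCI > 0)", rs$pct_phi_organized),
    sprintf("- deviation from phi %.1f%%, from 2:1 %.0f%%",
            rs$pct_dev_phi, rs$pct_dev_harmonic),
    "",
    "## Primary association",
    fmt_cor(report$primary, "PCI ~ convergence"),
    "",
    "## Null models")
  for (nm in c("null_a", "null_b")) {
    nl <- report[[nm]]
    lines <- c(lines, if (!is.null(nl$error))
      sprintf("- %s: unavailable", nm)
      else sprintf("- %s (%d draws): null r = %.3f (SD %.3f), z = %.2f, exceedance %d",
                   nl$model, nl$n_draws, nl$null_mean_r, nl$null_sd_r,
                   nl$z, nl$n_exceed))
  }
  sw <- report$sweep
  if (is.null(sw$error))
    lines <- c(lines, "", "## Specificity sweep",
               sprintf("- argmax c = %.3f; r at phi = %.3f (%s form)",
                       sw$argmax_c, sw$r_at_phi, sw$form))
  ep <- report$epsilon
  if (is.null(ep$error))
    lines <- c(lines, "", "## Epsilon sensitivity",
               sprintf("- eps %.3g: r = %.3f", ep$eps, ep$r))
  ms <- report$median_split
  if (is.null(ms$error))
    lines <- c(lines, "", "## Median split",
               sprintf("- low  (n = %d): theta %.2f Hz, alpha %.2f Hz",
                       ms$n_low, ms$low$f_theta, ms$low$f_alpha),
               if (ms$n_high > 0)
                 sprintf("- high (n = %d): theta %.2f Hz, alpha %.2f Hz",
                         ms$n_high, ms$high$f_theta, ms$high$f_alpha))
  if (!identical(report$frontal, "absent") &&
      is.null(report$frontal$error))
    lines <- c(lines, "", "## Frontal-theta variant",
               fmt_cor(report$frontal$frontal, "frontal theta"),
               fmt_cor(report$frontal$posterior, "posterior theta"),
               sprintf("- frontal-posterior theta r = %.3f",
                       report$frontal$theta_theta_r))
  lines
}

#' Write a report as Markdown
#' @param report a `pci_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_md <- function(report, path) {
  writeLines(report_markdown(report), path)
  invisible(path)
}
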