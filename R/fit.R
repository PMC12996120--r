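#' Fit the phi-coupling association on a cohort
#'
#' The central estimator: given a cohort of theta and alpha band centroids,
#' computes each subject's alpha/theta ratio, Phi Coupling Index and
#' theta-alpha convergence, the phi-organized fraction and ratio summary,
#' and the PCI-convergence correlation with a bootstrap confidence
#' interval.  The returned object supports `print`, `summary`, `coef`,
#' `plot`, `residuals` and `simulate`.
#'
#' @param cohort data.frame with `f_theta` and `f_alpha` columns (plus
#'   optional `subject_id`, `dataset`, `age`, `sex`).
#' @param params a [phi_params()].
#' @param n_boot bootstrap iterations for the confidence interval
#'   (default 10000).
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `pci_fit`.
#' @examples
#' cohort <- synth_coupled_cohort(80, 1.618034, seed = 1)
#' fit <- pci_fit(cohort, n_boot = 500, seed = 1)
#' summary(fit)
#' coef(fit)
#' @export
pci_fit <- function(cohort, params = phi_params(), n_boot = 10000,
                    seed = NULL) {
  cohort <- ensure_cohort_metrics(as.data.frame(cohort), params)
  cors <- correlate(cohort$pci, cohort$conv_bounded, n_boot, seed)
  m <- mean(cohort$ratio)
  structure(list(cohort = cohort, params = params, correlation = cors,
                 ratio_mean = m, ratio_sd = sd(cohort$ratio),
                 frac_phi_organized = mean(cohort$pci > 0),
                 deviation_pct = ratio_deviation(m, params),
                 n = nrow(cohort), seed = seed),
            class = "pci_fit")
}

#' @export
print.pci_fit <- function(x, ...) {
  cat(sprintf("<pci_fit> n = %d subjects; r(PCI, convergence) = %.3f; %.1f%% phi-organized\n",
              x$n, x$correlation$pearson_r, 100 * x$frac_phi_organized))
  invisible(x)
}

#' @export
summary.pci_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.pci_fit")
}

#' @export
print.summary.pci_fit <- function(x, ...) {
  f <- x$fit
  cat("Phi-coupling cohort fit\n")
  cat(sprintf("  n subjects          : %d\n", f$n))
  cat(sprintf("  mean ratio (SD)     : %.3f (%.3f)\n",
              f$ratio_mean, f$ratio_sd))
  cat(sprintf("  deviation from phi  : %.1f%%   from 2:1 : %.0f%%\n",
              f$deviation_pct["phi"], f$deviation_pct["harmonic"]))
  cat(sprintf("  phi-organized (PCI>0): %.1f%%\n",
              100 * f$frac_phi_organized))
  cat("  PCI ~ convergence   : ")
  print(f$correlation)
  invisible(x)
}

#' @export
coef.pci_fit <- function(object, ...) {
  c(pearson_r = object$correlation$pearson_r,
    spearman_rho = object$correlation$spearman_rho,
    ratio_mean = object$ratio_mean,
    frac_phi_organized = object$frac_phi_organized)
}

#' Residuals of the convergence-on-PCI regression
#'
#' @param object a `pci_fit`.
#' @param ... unused.
#' @return Residuals of the least-squares line of bounded convergence on
#'   PCI, one per subject.
#' @export
residuals.pci_fit <- function(object, ...) {
  lm.fit(cbind(1, object$cohort$pci),
         object$cohort$conv_bounded)$residuals
}

#' Scatter plot of a phi-coupling fit
#'
#' PCI against bounded convergence, one point per subject, with the
#' least-squares line.
#'
#' @param x a `pci_fit`.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.pci_fit <- function(x, ...) {
  ch <- x$cohort
  plot.default(ch$pci, ch$conv_bounded,
               xlab = "Phi Coupling Index",
               ylab = "theta-alpha convergence",
               main = sprintf("r = %.3f (n = %d)",
                              x$correlation$pearson_r, x$n), ...)
  co <- coef(stats::lm(conv_bounded ~ pci, data = ch))
  abline(co[1], co[2], lty = 2)
  invisible(x)
}

#' Simulate cohorts from a fitted ratio distribution
#'
#' Draws `nsim` synthetic cohorts of the fitted size with ratios from
#' `Normal(ratio_mean, ratio_sd)` (truncated at 3 SD) and theta frequencies
#' uniform over the observed theta range, then completes the index columns.
#'
#' @param object a `pci_fit`.
#' @param nsim number of cohorts (default 1).
#' @param seed RNG seed.
#' @param ... unused.
#' @return List of cohort data.frames of length `nsim`.
#' @export
simulate.pci_fit <- function(object, nsim = 1, seed = NULL, ...) {
  ch <- object$cohort
  t_rng <- range(ch$f_theta)
  with_seed(seed, {
    lapply(seq_len(nsim), function(k) {
      R <- sample_ratios(object$n, object$ratio_mean, object$ratio_sd)
      ft <- runif(object$n, t_rng[1], t_rng[2])
      fa <- pmin(pmax(R * ft, 8.0001), 12.9999)
      ensure_cohort_metrics(
        data.frame(subject_id = sprintf("sim%03d", seq_len(object$n)),
                   f_theta = ft, f_alpha = fa, stringsAsFactors = FALSE),
        object$params)
    })
  })
}
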