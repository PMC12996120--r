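#' Correlation with bootstrap confidence interval
#'
#' Pearson and Spearman correlations with two-tailed p-values
#' ([stats::cor.test()]; Spearman p exact below n = 10 without ties,
#' approximate otherwise) plus a percentile bootstrap confidence interval
#' for the Pearson correlation over subject resamples.
#'
#' @param x,y numeric vectors of equal length >= 3 with finite values.
#' @param n_boot bootstrap iterations (default 10000).
#' @param seed RNG seed for the bootstrap (optional; reproducible when set).
#' @param conf confidence level (default 0.95).
#' @return A `correlation_report`: `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p`, `ci_lo`, `ci_hi`, `n`, `n_boot`, `conf`,
#'   `seed`.
#' @export
correlate <- function(x, y, n_boot = 10000, seed = NULL, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant vector", call. = FALSE)
  pe <- cor.test(x, y)
  sp <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = n < 10))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sd(x[idx]) == 0 || sd(y[idx]) == 0) NA_real_
      else cor(x[idx], y[idx])
    }, 0)
  })
  alpha <- (1 - conf) / 2
  ci <- quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  structure(list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
                 spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
                 ci_lo = ci[1], ci_hi = ci[2], n = n, n_boot = n_boot,
                 conf = conf, seed = seed),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("r = %.3f (p = %.3g), 95%% CI [%.3f, %.3f]; rho = %.3f (p = %.3g); n = %d\n",
              x$pearson_r, x$pearson_p, x$ci_lo, x$ci_hi,
              x$spearman_rho, x$spearman_p, x$n))
  invisible(x)
}

#' Partial Pearson correlation controlling for one covariate
#'
#' Pearson correlation of the least-squares residuals of `x` and `y` after
#' removing the covariate.  A constant covariate falls back to the plain
#' Pearson correlation with a warning.
#'
#' @param x,y numeric vectors, length >= 4.
#' @param covariate numeric vector of the same length.
#' @return Partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, covariate) {
  n <- length(x)
  if (length(y) != n || length(covariate) != n)
    stop("x, y and covariate must have equal length", call. = FALSE)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (sd(covariate) == 0) {
    warning("constant covariate; returning the plain Pearson correlation",
            call. = FALSE)
    return(cor(x, y))
  }
  zz <- cbind(1, covariate)
  rx <- lm.fit(zz, x)$residuals
  ry <- lm.fit(zz, y)$residuals
  # a variable fully explained by the covariate has nothing left to
  # correlate; report 0 rather than noise from ~1e-16 residuals
  if (sd(rx) <= 1e-10 * sd(x) || sd(ry) <= 1e-10 * sd(y)) return(0)
  cor(rx, ry)
}

# Exact truncated-normal sampling on [lo, hi) via the inverse CDF.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  plo <- pnorm(lo, mean, sd)
  phi_ <- pnorm(hi, mean, sd)
  if (phi_ <= plo) stop("empty truncation interval", call. = FALSE)
  qnorm(plo + runif(n) * (phi_ - plo), mean, sd)
}

new_null_result <- function(model, rs, n_draws, n_skipped, observed_r, seed) {
  n_exceed <- if (is.null(observed_r)) NA_integer_
  else sum(rs >= observed_r)
  z <- if (is.null(observed_r) || sd(rs) == 0) NA_real_
  else (observed_r - mean(rs)) / sd(rs)
  structure(list(model = model, n_draws = length(rs),
                 n_requested = n_draws, n_skipped = n_skipped,
                 null_mean_r = mean(rs), null_sd_r = sd(rs),
                 observed_r = observed_r %||% NA_real_, z = z,
                 n_exceed = n_exceed, seed = seed),
            class = "null_result")
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf("<null_result:%s> %d draws: null r = %.3f (SD %.3f)",
              x$model, x$n_draws, x$null_mean_r, x$null_sd_r))
  if (is.finite(x$z))
    cat(sprintf("; observed r = %.3f, z = %.2f, %d/%d draws >= observed",
                x$observed_r, x$z, x$n_exceed, x$n_draws))
  cat("\n")
  invisible(x)
}

#' Marginal-resampling null model (Null A)
#'
#' Destroys the joint theta-alpha dependence while preserving the marginal
#' distributions: each draw resamples `f_theta` and `f_alpha` independently
#' (with replacement by default, or as a permutation of the alpha column),
#' recomputes PCI and bounded convergence, and records their Pearson
#' correlation.  The observed correlation is summarized against this null
#' distribution as `z = (r_obs - mean(r_null)) / SD(r_null)` and as the
#' exceedance count.
#'
#' @param cohort cohort data.frame with `f_theta`, `f_alpha` (n >= 10).
#' @param n_draws number of null draws (default 100000).
#' @param seed RNG seed.
#' @param draw_size pseudo-cohort size per draw (default: the cohort size).
#' @param mode `"resample"` (with replacement) or `"permute"`.
#' @param params a [phi_params()].
#' @return A `null_result` with `model = "marginal_resample"`.
#' @export
null_marginal_resample <- function(cohort, n_draws = 100000, seed = NULL,
                                   draw_size = NULL,
                                   mode = c("resample", "permute"),
                                   params = phi_params()) {
  mode <- match.arg(mode)
  ft <- cohort$f_theta
  fa <- cohort$f_alpha
  n <- length(ft)
  if (n < 10) stop("null model needs a cohort of at least 10", call. = FALSE)
  if (sd(ft) == 0 || sd(fa) == 0)
    stop("degenerate cohort column", call. = FALSE)
  m <- draw_size %||% n
  observed <- cor(pci(fa / ft, params), convergence_bounded(ft, fa))
  rs <- with_seed(seed, {
    out <- numeric(n_draws)
    skip <- 0L
    for (i in seq_len(n_draws)) {
      if (mode == "resample") {
        t_i <- ft[sample.int(n, m, replace = TRUE)]
        a_i <- fa[sample.int(n, m, replace = TRUE)]
      } else {
        t_i <- ft
        a_i <- fa[sample.int(n)]
      }
      p <- pci(a_i / t_i, params)
      cv <- convergence_bounded(t_i, a_i)
      if (sd(p) == 0 || sd(cv) == 0) { out[i] <- NA; skip <- skip + 1L }
      else out[i] <- cor(p, cv)
    }
    attr(out, "skip") <- skip
    out
  })
  skip <- attr(rs, "skip")
  if (skip > 0)
    warning(skip, " degenerate null draws skipped", call. = FALSE)
  new_null_result("marginal_resample", rs[!is.na(rs)], n_draws, skip,
                  observed, seed)
}

#' Band-constrained Monte Carlo null model (Null B)
#'
#' Each draw samples `n_subjects` independent (theta, alpha) centroid pairs
#' from truncated normals on \[4, 8) and \[8, 13) matched to the supplied
#' means/SDs, then records the Pearson correlation of PCI with bounded
#' convergence.  Degenerate draws (zero variance, only possible as both SDs
#' approach 0) are skipped and counted with a warning.
#'
#' @param mu_theta,sd_theta truncated-normal parameters for theta
#'   (`4 <= mu_theta < 8`, `sd_theta > 0`).
#' @param mu_alpha,sd_alpha likewise for alpha (`8 <= mu_alpha < 13`).
#' @param n_subjects pairs per draw.
#' @param n_draws number of draws (default 10000).
#' @param seed RNG seed.
#' @param params a [phi_params()].
#' @param observed_r optional observed correlation to score against the
#'   null (gives `z` and `n_exceed`).
#' @return A `null_result` with `model = "band_constrained"`.
#' @export
null_band_constrained <- function(mu_theta, sd_theta, mu_alpha, sd_alpha,
                                  n_subjects, n_draws = 10000, seed = NULL,
                                  params = phi_params(), observed_r = NULL) {
  if (!(mu_theta >= 4 && mu_theta < 8))
    stop("mu_theta must lie in [4, 8)", call. = FALSE)
  if (!(mu_alpha >= 8 && mu_alpha < 13))
    stop("mu_alpha must lie in [8, 13)", call. = FALSE)
  if (sd_theta < 0 || sd_alpha < 0) stop("SDs must be >= 0", call. = FALSE)
  rs <- with_seed(seed, {
    out <- numeric(n_draws)
    skip <- 0L
    for (i in seq_len(n_draws)) {
      t_i <- rtruncnorm(n_subjects, mu_theta, sd_theta, 4, 8)
      a_i <- rtruncnorm(n_subjects, mu_alpha, sd_alpha, 8, 13)
      p <- pci(a_i / t_i, params)
      cv <- convergence_bounded(t_i, a_i)
      if (sd(p) == 0 || sd(cv) == 0) { out[i] <- NA; skip <- skip + 1L }
      else out[i] <- cor(p, cv)
    }
    attr(out, "skip") <- skip
    out
  })
  skip <- attr(rs, "skip")
  if (skip > 0)
    warning(skip, " degenerate null draws skipped", call. = FALSE)
  new_null_result("band_constrained", rs[!is.na(rs)], n_draws, skip,
                  observed_r, seed)
}

#' Default reference-constant grid for the specificity sweep
#'
#' 1.30 to 2.20 in steps of 0.05, with phi itself inserted so the sweep
#' evaluates the golden ratio exactly.
#'
#' @param params a [phi_params()].
#' @return Sorted numeric grid.
#' @export
sweep_grid <- function(params = phi_params())
  sort(unique(c(seq(1.30, 2.20, by = 0.05), params$phi)))

#' Phi-specificity parameter sweep
#'
#' Correlates the generalized PCI at each reference constant with bounded
#' convergence; if phi-organization is meaningful the correlation should
#' peak near `c = phi` rather than at an arbitrary constant.
#'
#' @param cohort cohort data.frame with `f_theta`, `f_alpha`.
#' @param grid reference constants (default [sweep_grid()]).
#' @param params a [phi_params()].
#' @param form PCI form passed to [generalized_pci()].
#' @return A `sweep_result`: data.frame `table` (`c_ref`, `r`), `argmax_c`,
#'   `r_at_phi`, `form`.  Constants where the correlation is undefined are
#'   recorded as `NA`, not errors.
#' @export
phi_sweep <- function(cohort, grid = sweep_grid(params),
                      params = phi_params(),
                      form = c("proximity", "two_anchor")) {
  form <- match.arg(form)
  cohort <- ensure_cohort_metrics(cohort, params)
  R <- cohort$ratio
  cv <- cohort$conv_bounded
  r <- vapply(grid, function(cc) {
    g <- suppressWarnings(generalized_pci(R, cc, params, form))
    if (any(is.na(g)) || sd(g) == 0 || sd(cv) == 0) NA_real_
    else cor(g, cv)
  }, 0)
  argmax <- if (all(is.na(r))) NA_real_ else grid[which.max(r)]
  at_phi <- r[which.min(abs(grid - params$phi))]
  structure(list(table = data.frame(c_ref = grid, r = r),
                 argmax_c = argmax, r_at_phi = at_phi, form = form),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result:%s> %d constants; argmax c = %.3f; r at phi = %.3f\n",
              x$form, nrow(x$table), x$argmax_c, x$r_at_phi))
  invisible(x)
}

#' Regularization sensitivity of the PCI-convergence correlation
#'
#' Recomputes PCI across a ladder of `eps` values and reports the Pearson
#' correlation with bounded convergence at each.  The Pearson r varies with
#' `eps` (the index is compressed toward 0 as `eps` grows) but its sign is
#' stable whenever the baseline correlation is away from zero; the Spearman
#' version is not `eps`-invariant in general because changing `eps` reorders
#' subjects lying on opposite sides of phi.
#'
#' @param cohort cohort data.frame.
#' @param eps_list regularization values
#'   (default `c(0.001, 0.01, 0.1, 0.5, 1.0)`).
#' @param params a [phi_params()] (anchors reused; `eps` replaced).
#' @return data.frame with columns `eps`, `r`, `rho`.
#' @export
epsilon_sweep <- function(cohort, eps_list = c(0.001, 0.01, 0.1, 0.5, 1.0),
                          params = phi_params()) {
  cohort <- ensure_cohort_metrics(cohort, params)
  cv <- cohort$conv_bounded
  rows <- lapply(eps_list, function(e) {
    p <- pci(cohort$ratio, phi_params(params$phi, params$harmonic, e))
    data.frame(eps = e, r = cor(p, cv),
               rho = cor(p, cv, method = "spearman"))
  })
  do.call(rbind, rows)
}

#' Compare frontal-theta and posterior-theta PCI variants
#'
#' Both cohorts must describe the same subjects; rows are aligned on
#' `subject_id` and any mismatch is an error.  Reports the PCI-convergence
#' correlation under each theta source plus the correlation between the two
#' theta centroid columns.
#'
#' @param cohort_frontal cohort computed with frontal theta.
#' @param cohort_posterior cohort computed with posterior theta.
#' @param params a [phi_params()].
#' @param n_boot,seed bootstrap settings passed to [correlate()].
#' @return List with `frontal` and `posterior` correlation reports,
#'   `theta_theta_r`, and `n`.
#' @export
frontal_theta_variant <- function(cohort_frontal, cohort_posterior,
                                  params = phi_params(), n_boot = 10000,
                                  seed = NULL) {
  if (nrow(cohort_frontal) != nrow(cohort_posterior))
    stop("alignment error: cohorts differ in size", call. = FALSE)
  idx <- match(cohort_posterior$subject_id, cohort_frontal$subject_id)
  if (any(is.na(idx)))
    stop("alignment error: subject ids do not match", call. = FALSE)
  cf <- ensure_cohort_metrics(cohort_frontal[idx, ], params)
  cp <- ensure_cohort_metrics(cohort_posterior, params)
  list(frontal = correlate(cf$pci, cf$conv_bounded, n_boot, seed),
       posterior = correlate(cp$pci, cp$conv_bounded, n_boot, seed),
       theta_theta_r = cor(cf$f_theta, cp$f_theta),
       n = nrow(cp))
}

#' Median-split frequency profiles
#'
#' Splits the cohort at the sample median of PCI (ties go to the low
#' group) and reports per-group means of the centroid columns and any
#' demographic covariates present.
#'
#' @param cohort cohort data.frame, n >= 4.
#' @param params a [phi_params()].
#' @return List with `median_pci`, `low`, `high` (named mean vectors),
#'   `n_low`, `n_high`.
#' @export
median_split_profile <- function(cohort, params = phi_params()) {
  if (nrow(cohort) < 4) stop("median split needs n >= 4", call. = FALSE)
  cohort <- ensure_cohort_metrics(cohort, params)
  med <- median(cohort$pci)
  low <- cohort$pci <= med
  if (!any(!low))
    warning("all PCI values tie at the median; high group is empty",
            call. = FALSE)
  cols <- intersect(c("f_theta", "f_alpha", "ratio", "pci", "age"),
                    names(cohort))
  grp_mean <- function(rows)
    vapply(cols, function(cc) mean(cohort[[cc]][rows]), 0)
  list(median_pci = med, low = grp_mean(low), high = grp_mean(!low),
       n_low = sum(low), n_high = sum(!low))
}

#' Subgroup PCI-convergence correlations
#'
#' Stratifies the cohort by age (younger/older than a cutoff) or by sex and
#' runs [correlate()] within each stratum; strata with fewer than 3
#' subjects are skipped with a warning.
#'
#' @param cohort cohort data.frame with an `age` or `sex` column.
#' @param by `"age"` or `"sex"`.
#' @param age_cut age cutoff in years (default 40, splitting at
#'   `age < 40`).
#' @param params a [phi_params()].
#' @param n_boot,seed bootstrap settings passed to [correlate()].
#' @return Named list of correlation reports, one per stratum.
#' @export
subgroup_correlations <- function(cohort, by = c("age", "sex"),
                                  age_cut = 40, params = phi_params(),
                                  n_boot = 10000, seed = NULL) {
  by <- match.arg(by)
  if (!by %in% names(cohort))
    stop("cohort lacks a '", by, "' column", call. = FALSE)
  cohort <- ensure_cohort_metrics(cohort, params)
  strata <- if (by == "age")
    ifelse(cohort$age < age_cut,
           sprintf("age<%g", age_cut), sprintf("age>=%g", age_cut))
  else as.character(cohort$sex)
  out <- list()
  for (s in unique(strata)) {
    rows <- strata == s
    if (sum(rows) < 3) {
      warning("stratum '", s, "' has fewer than 3 subjects; skipped",
              call. = FALSE)
      next
    }
    out[[s]] <- correlate(cohort$pci[rows], cohort$conv_bounded[rows],
                          n_boot, seed)
  }
  out
}
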