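#' Parameters of the Phi Coupling Index
#'
#' The PCI compares the distance of the alpha/theta centroid ratio from the
#' harmonic 2:1 anchor with its distance from the golden ratio, on a natural
#' log scale with additive regularization `eps`:
#' `PCI = log((|R - harmonic| + eps) / (|R - phi| + eps))`.
#' The log base only rescales PCI (sign and all correlation-based results
#' are base-invariant); the natural log is used throughout.
#'
#' @param phi golden-ratio anchor (default 1.618034).
#' @param harmonic harmonic anchor (default 2).
#' @param eps regularization constant, > 0 (default 0.01).
#' @return A `phi_params` list.
#' @export
phi_params <- function(phi = 1.618034, harmonic = 2, eps = 0.01) {
  if (!(eps > 0)) stop("eps must be > 0", call. = FALSE)
  if (phi == harmonic) stop("phi and harmonic must differ", call. = FALSE)
  structure(list(phi = phi, harmonic = harmonic, eps = eps),
            class = "phi_params")
}

#' The ratio equidistant from both anchors
#' @param params a [phi_params()].
#' @return `(phi + harmonic) / 2`; PCI is exactly zero there.
#' @export
phi_midpoint <- function(params = phi_params())
  (params$phi + params$harmonic) / 2

#' Phi Coupling Index
#'
#' Positive when the ratio is strictly closer to phi than to the harmonic
#' anchor, negative when closer to the harmonic, zero at the midpoint;
#' finite for every positive ratio and any `eps > 0`.
#'
#' @param R alpha/theta centroid ratio(s), > 0.  Vectorized.
#' @param params a [phi_params()].
#' @return PCI value(s) (natural-log units).
#' @examples
#' pci(1.618034)            #  3.67: on the golden ratio
#' pci(2)                   # -3.67: on the harmonic
#' pci(phi_midpoint())      #  0
#' @export
pci <- function(R, params = phi_params()) {
  if (any(!is.finite(R)) || any(R <= 0))
    stop("invalid ratio: R must be finite and > 0", call. = FALSE)
  log((abs(R - params$harmonic) + params$eps) /
        (abs(R - params$phi) + params$eps))
}

#' Generalized PCI for an arbitrary reference constant
#'
#' Two forms are exposed for the specificity sweep.  The primary
#' `"proximity"` form, `-log(|R - c| + eps)`, measures closeness to the
#' reference constant alone and is defined for every `c` (including the
#' harmonic anchor).  The `"two_anchor"` form keeps the harmonic 2:1 as the
#' fixed alternative, `log((|R - harmonic| + eps) / (|R - c| + eps))`, and
#' reduces to [pci()] at `c = phi`; at `c = harmonic` it is undefined by
#' convention and returns `NA` with a warning.
#'
#' @param R ratio(s), > 0.
#' @param c_ref reference constant, > 0.
#' @param params a [phi_params()].
#' @param form `"proximity"` (default) or `"two_anchor"`.
#' @return Generalized PCI value(s).
#' @export
generalized_pci <- function(R, c_ref, params = phi_params(),
                            form = c("proximity", "two_anchor")) {
  form <- match.arg(form)
  if (any(!is.finite(R)) || any(R <= 0))
    stop("invalid ratio: R must be finite and > 0", call. = FALSE)
  if (!is.finite(c_ref) || c_ref <= 0)
    stop("reference constant must be finite and > 0", call. = FALSE)
  if (form == "proximity")
    return(-log(abs(R - c_ref) + params$eps))
  if (c_ref == params$harmonic) {
    warning("two-anchor form is undefined at the harmonic anchor; ",
            "returning NA", call. = FALSE)
    return(rep(NA_real_, length(R)))
  }
  log((abs(R - params$harmonic) + params$eps) / (abs(R - c_ref) + params$eps))
}

#' Bounded theta-alpha convergence
#'
#' `1 / (|f_alpha - f_theta| + 0.5)`: large when both centroids approach the
#' 8 Hz band boundary, bounded in `(0, 2]` (maximum 2 when the centroids
#' coincide), about 0.1 at the physiological maximum separation of ~9 Hz.
#'
#' @param f_theta,f_alpha band centroids in Hz.  Vectorized.
#' @return Convergence value(s).
#' @export
convergence_bounded <- function(f_theta, f_alpha)
  1 / (abs(f_alpha - f_theta) + 0.5)

#' Unbounded theta-alpha convergence
#'
#' `1 / |f_alpha - f_theta|`; singular when the centroids coincide, which is
#' why the bounded form is primary.  A zero separation raises an error.
#'
#' @inheritParams convergence_bounded
#' @return Convergence value(s).
#' @export
convergence_unbounded <- function(f_theta, f_alpha) {
  d <- abs(f_alpha - f_theta)
  if (any(d == 0))
    stop("unbounded convergence is singular at zero separation",
         call. = FALSE)
  1 / d
}

#' 8 Hz symmetry metric
#'
#' Negative total distance of the two centroids from the 8 Hz boundary,
#' `-(|8 - f_theta| + |f_alpha - 8|)`; 0 only when both centroids sit at
#' 8 Hz, more negative the further they are.
#'
#' @inheritParams convergence_bounded
#' @return Symmetry value(s), <= 0.
#' @export
symmetry_8hz <- function(f_theta, f_alpha)
  -(abs(8 - f_theta) + abs(f_alpha - 8))

#' Assemble per-subject index values
#'
#' @param f_theta,f_alpha band centroids in Hz (theta in \[4, 8), alpha in
#'   \[8, 13)).
#' @param params a [phi_params()].
#' @param theta_source `"posterior"` or `"frontal"`; provenance of the theta
#'   centroid.
#' @param subject_id identifier stored with the row.
#' @return One-row data.frame with columns `subject_id`, `f_theta`,
#'   `f_alpha`, `ratio`, `pci`, `conv_bounded`, `conv_unbounded`, `sym8`,
#'   `theta_source`.
#' @export
subject_metrics <- function(f_theta, f_alpha, params = phi_params(),
                            theta_source = c("posterior", "frontal"),
                            subject_id = "") {
  theta_source <- match.arg(theta_source)
  if (!(f_theta >= 4 && f_theta < 8))
    stop("theta centroid outside [4, 8)", call. = FALSE)
  if (!(f_alpha >= 8 && f_alpha < 13))
    stop("alpha centroid outside [8, 13)", call. = FALSE)
  R <- f_alpha / f_theta
  data.frame(subject_id = subject_id, f_theta = f_theta, f_alpha = f_alpha,
             ratio = R, pci = pci(R, params),
             conv_bounded = convergence_bounded(f_theta, f_alpha),
             conv_unbounded = convergence_unbounded(f_theta, f_alpha),
             sym8 = symmetry_8hz(f_theta, f_alpha),
             theta_source = theta_source,
             stringsAsFactors = FALSE)
}

cohort_columns <- c("subject_id", "dataset", "age", "sex", "f_theta",
                    "f_alpha", "ratio", "pci", "conv_bounded",
                    "conv_unbounded", "sym8", "theta_source")

#' Fill the derived index columns of a cohort table
#'
#' Given at least `f_theta` and `f_alpha`, (re)computes `ratio`, `pci`,
#' `conv_bounded`, `conv_unbounded` and `sym8` with the supplied parameters;
#' other columns pass through.
#'
#' @param cohort data.frame with `f_theta` and `f_alpha` columns.
#' @param params a [phi_params()].
#' @return The completed cohort data.frame.
#' @export
ensure_cohort_metrics <- function(cohort, params = phi_params()) {
  if (!all(c("f_theta", "f_alpha") %in% names(cohort)))
    stop("cohort needs f_theta and f_alpha columns", call. = FALSE)
  cohort$ratio <- cohort$f_alpha / cohort$f_theta
  cohort$pci <- pci(cohort$ratio, params)
  cohort$conv_bounded <- convergence_bounded(cohort$f_theta, cohort$f_alpha)
  cohort$conv_unbounded <- convergence_unbounded(cohort$f_theta,
                                                 cohort$f_alpha)
  cohort$sym8 <- symmetry_8hz(cohort$f_theta, cohort$f_alpha)
  if (is.null(cohort$subject_id))
    cohort$subject_id <- sprintf("S%03d", seq_len(nrow(cohort)))
  if (is.null(cohort$theta_source)) cohort$theta_source <- "posterior"
  cohort
}

#' Write a cohort table as CSV
#' @param cohort cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = ",", quote = TRUE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#' @param path CSV path; must contain at least `subject_id`, `f_theta`,
#'   `f_alpha`.
#' @return Cohort data.frame.
#' @export
read_cohort <- function(path) {
  tab <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("subject_id", "f_theta", "f_alpha")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("cohort file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab
}

#' Percent deviation of a mean ratio from the two anchors
#'
#' `100 |m - phi| / phi` and `100 |m - harmonic| / harmonic`; with the
#' canonical anchors a mean ratio of 1.677 deviates 3.6% from phi and 16%
#' from 2:1.
#'
#' @param mean_ratio the cohort mean alpha/theta ratio.
#' @param params a [phi_params()].
#' @return Named numeric vector `c(phi = ..., harmonic = ...)` in percent.
#' @export
ratio_deviation <- function(mean_ratio, params = phi_params()) {
  c(phi = 100 * abs(mean_ratio - params$phi) / params$phi,
    harmonic = 100 * abs(mean_ratio - params$harmonic) / params$harmonic)
}

#' Closed-form probability of phi-organization under a normal ratio model
#'
#' For ratios drawn from a (possibly symmetrically truncated) normal
#' distribution, PCI > 0 exactly when the ratio falls below the anchor
#' midpoint, so the phi-organized fraction has the closed form
#' `P(R < (phi + harmonic)/2)` under that distribution.
#'
#' @param mean,sd normal parameters of the ratio distribution.
#' @param trunc_sd symmetric truncation in SD units (`Inf` = none).
#' @param params a [phi_params()].
#' @return Probability in \[0, 1\].
#' @export
phi_organized_prob <- function(mean, sd, trunc_sd = Inf,
                               params = phi_params()) {
  q <- phi_midpoint(params)
  if (!is.finite(trunc_sd)) return(pnorm(q, mean, sd))
  lo <- mean - trunc_sd * sd
  hi <- mean + trunc_sd * sd
  if (q <= lo) return(0)
  if (q >= hi) return(1)
  (pnorm(q, mean, sd) - pnorm(lo, mean, sd)) /
    (pnorm(hi, mean, sd) - pnorm(lo, mean, sd))
}
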