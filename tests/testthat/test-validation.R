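test_that("correlate matches brute-force formulas on a small fixture", {
  set.seed(5)
  x <- round(rnorm(10), 3)
  y <- round(0.6 * x + rnorm(10, sd = 0.5), 3)
  z <- round(rnorm(10), 3)
  cr <- correlate(x, y, n_boot = 200, seed = 1)
  expect_equal(cr$pearson_r, oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(cr$spearman_rho, oracle_spearman(x, y), tolerance = 1e-12)
  expect_equal(partial_correlation(x, y, z), oracle_partial(x, y, z),
               tolerance = 1e-12)
  expect_identical(cr$n, 10L)
})

test_that("correlate handles exact and monotone relations", {
  x <- 1:12
  lin <- correlate(x, 2 * x + 1, n_boot = 100, seed = 1)
  expect_equal(lin$pearson_r, 1)
  expect_equal(lin$spearman_rho, 1)
  mono <- correlate(x, exp(x), n_boot = 100, seed = 1)
  expect_equal(mono$spearman_rho, 1)
  expect_lt(mono$pearson_r, 1)
  expect_error(correlate(rep(1, 5), 1:5, n_boot = 10), "constant")
  expect_error(correlate(1:3, 1:4), "length")
  expect_error(correlate(c(1, 2, NA), 1:3), "finite")
  expect_error(correlate(1:2, 1:2), "at least 3")
})

test_that("bootstrap intervals are seed-stable and cover the estimate", {
  x <- plausible_cohort(30)$pci
  y <- plausible_cohort(30)$conv_bounded
  a <- correlate(x, y, n_boot = 500, seed = 7)
  b <- correlate(x, y, n_boot = 500, seed = 7)
  expect_identical(a$ci_lo, b$ci_lo)
  expect_identical(a$ci_hi, b$ci_hi)
  # coverage of the point estimate across cohorts
  hits <- 0L
  for (s in 1:25) {
    ch <- plausible_cohort(40, seed = 500 + s)
    cr <- correlate(ch$pci, ch$conv_bounded, n_boot = 400, seed = s)
    if (cr$pearson_r >= cr$ci_lo && cr$pearson_r <= cr$ci_hi)
      hits <- hits + 1L
  }
  expect_gte(hits, 24L)
})

test_that("partial correlation behaves at its documented limits", {
  set.seed(8)
  x <- rnorm(40)
  y <- 0.7 * x + rnorm(40, sd = 0.5)
  z_indep <- rnorm(40)
  # covariate unrelated to both: partial ~ plain
  expect_equal(partial_correlation(x, y, z_indep), cor(x, y),
               tolerance = 0.15)
  # y identical to the covariate: nothing left to correlate
  expect_lt(abs(partial_correlation(x, y, y)), 1e-10)
  expect_warning(r0 <- partial_correlation(x, y, rep(1, 40)), "constant")
  expect_equal(r0, cor(x, y))
  expect_error(partial_correlation(x, y, z_indep[1:5]), "equal length")
  expect_error(partial_correlation(1:3, 1:3, 1:3), "at least 4")
})

test_that("the marginal-resampling null is seed-deterministic and scores
          a strongly coupled cohort as extreme", {
  # a cohort whose ratio-proximity and convergence are tightly coupled:
  # breaking the joint dependence must destroy most of the correlation
  cohort <- synth_coupled_cohort(100, 1.618034, seed = 11)
  n1 <- suppressWarnings(
    null_marginal_resample(cohort, n_draws = 400, seed = 11))
  n2 <- suppressWarnings(
    null_marginal_resample(cohort, n_draws = 400, seed = 11))
  expect_identical(n1$null_mean_r, n2$null_mean_r)
  expect_identical(n1$n_exceed, n2$n_exceed)
  # the locked cohort's observed r beats essentially the whole null
  expect_gt(n1$observed_r, n1$null_mean_r)
  expect_lt(n1$n_exceed / n1$n_draws, 0.05)
  expect_gt(n1$z, 2)
  # z is 0 by construction when the observed r equals the null mean
  z0 <- (n1$null_mean_r - n1$null_mean_r) / n1$null_sd_r
  expect_identical(z0, 0)
  expect_error(null_marginal_resample(cohort_from(c(6, 6.5), c(10, 10.4))),
               "at least 10")
})

test_that("permutation mode preserves the marginals exactly", {
  ch <- plausible_cohort(20)
  np <- null_marginal_resample(ch, n_draws = 200, seed = 3,
                               mode = "permute")
  expect_s3_class(np, "null_result")
  expect_identical(np$n_draws, 200L)
})

test_that("the band-constrained null is deterministic and negative for
          slow-alpha/fast-theta cohorts", {
  a <- null_band_constrained(6.5, 0.5, 9.6, 0.8, n_subjects = 150,
                             n_draws = 300, seed = 21)
  b <- null_band_constrained(6.5, 0.5, 9.6, 0.8, n_subjects = 150,
                             n_draws = 300, seed = 21)
  expect_identical(a$null_mean_r, b$null_mean_r)
  expect_lt(a$null_mean_r, 0)
  expect_gt(a$null_sd_r, 0)
  expect_error(null_band_constrained(3, 1, 10, 1, 50), "mu_theta")
  expect_error(null_band_constrained(6, 1, 14, 1, 50), "mu_alpha")
})

test_that("degenerate zero-variance null draws are skipped with a warning", {
  expect_warning(
    res <- null_band_constrained(6, 0, 10, 0, n_subjects = 20,
                                 n_draws = 10, seed = 1),
    "degenerate")
  expect_identical(res$n_skipped, 10L)
  expect_identical(res$n_draws, 0L)
})

test_that("null exceedance converges as draws double", {
  ch <- plausible_cohort(40)
  p1 <- null_marginal_resample(ch, n_draws = 1000, seed = 5)
  p2 <- null_marginal_resample(ch, n_draws = 2000, seed = 6)
  f1 <- p1$n_exceed / p1$n_draws
  f2 <- p2$n_exceed / p2$n_draws
  se <- sqrt(max(f1, 1 / p1$n_draws) * (1 - min(f1, 1 - 1 / p1$n_draws)) /
               p1$n_draws)
  expect_true(f1 >= 0 && f1 <= 1)
  expect_lt(abs(f1 - f2), 3 * se + 1e-9)
})

test_that("the specificity sweep recovers planted reference constants", {
  for (cs in c(1.5, 1.618034, 1.9)) {
    ch <- synth_coupled_cohort(250, cs, seed = round(1000 * cs))
    sw <- phi_sweep(ch)
    expect_lte(abs(sw$argmax_c - cs), 0.0501,
               label = sprintf("argmax near %.3f", cs))
  }
  # phi itself is on the grid, evaluated exactly
  expect_true(any(abs(sweep_grid() - 1.618034) < 1e-12))
  # a single-constant grid trivially wins
  ch <- synth_coupled_cohort(50, 1.6, seed = 2)
  sw1 <- phi_sweep(ch, grid = 1.7)
  expect_identical(nrow(sw1$table), 1L)
  expect_equal(sw1$argmax_c, 1.7)
})

test_that("the two-anchor sweep form agrees on peak location", {
  ch <- synth_coupled_cohort(250, 1.618034, seed = 77)
  sw <- phi_sweep(ch, form = "two_anchor")
  expect_lte(abs(sw$argmax_c - 1.618034), 0.0501)
  # c = 2 is recorded as missing, not fatal
  expect_true(is.na(sw$table$r[abs(sw$table$c_ref - 2) < 1e-12]))
})

test_that("epsilon ladder keeps the pearson sign on a coupled cohort", {
  ch <- synth_coupled_cohort(150, 1.618034, seed = 13)
  tab <- epsilon_sweep(ch)
  expect_identical(tab$eps, c(0.001, 0.01, 0.1, 0.5, 1.0))
  base <- tab$r[tab$eps == 0.01]
  expect_gt(abs(base), 0.2)
  expect_true(all(sign(tab$r) == sign(base)))
})

test_that("spearman rho is not epsilon-invariant (frozen counterexample)", {
  # four subjects straddling phi: the eps = 0.001 and eps = 1 orderings of
  # PCI differ, so the rank correlation with convergence flips
  ft <- c(6.683, 6.899, 4.870, 6.913)
  fa <- c(9.927, 10.260, 8.050, 10.385)
  ch <- cohort_from(ft, fa)
  tab <- epsilon_sweep(ch, eps_list = c(0.001, 1.0))
  expect_equal(tab$rho[1], 0.2, tolerance = 1e-9)
  expect_equal(tab$rho[2], -1.0, tolerance = 1e-9)
})

test_that("huge eps drives pci to zero pointwise but keeps correlations
          defined", {
  ch <- plausible_cohort(30)
  p_huge <- pci(ch$ratio, phi_params(eps = 1e6))
  expect_lt(max(abs(p_huge)), 1e-5)
  expect_gt(sd(p_huge), 0)
  tab <- epsilon_sweep(ch, eps_list = 1e6)
  expect_true(is.finite(tab$r))
})

test_that("frontal-theta variant aligns subjects and degenerates correctly", {
  ch <- plausible_cohort(25)
  # identical frontal and posterior theta: identical reports, r = 1
  fv <- frontal_theta_variant(ch, ch, n_boot = 100, seed = 2)
  expect_equal(fv$frontal$pearson_r, fv$posterior$pearson_r)
  expect_equal(fv$theta_theta_r, 1)
  # shuffled ids cannot be aligned
  ch2 <- ch
  ch2$subject_id <- paste0("other_", ch2$subject_id)
  expect_error(frontal_theta_variant(ch2, ch, n_boot = 50), "alignment")
  expect_error(frontal_theta_variant(ch[1:10, ], ch, n_boot = 50),
               "alignment")
})

test_that("cleaner frontal theta yields the stronger correlation on average", {
  # table-level emulation of the regional-gain mechanism: frontal theta is
  # the true theta with less measurement noise than posterior theta
  wins <- 0L
  for (s in 1:12) {
    set.seed(s)
    n <- 80
    ft_true <- runif(n, 4.6, 7.4)
    R <- pmin(pmax(rnorm(n, 1.677, 0.142), 1.2), 2.1)
    fa <- pmin(pmax(R * ft_true, 8.05), 12.9)
    ft_frontal <- pmin(pmax(ft_true + rnorm(n, 0, 0.05), 4.01), 7.99)
    ft_posterior <- pmin(pmax(ft_true + rnorm(n, 0, 0.45), 4.01), 7.99)
    cf <- cohort_from(ft_frontal, fa)
    cp <- cohort_from(ft_posterior, fa)
    fv <- frontal_theta_variant(cf, cp, n_boot = 50, seed = s)
    if (fv$frontal$pearson_r >= fv$posterior$pearson_r) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("median split honors the tie rule and recovers planted profiles", {
  # two subjects: one per group
  ch2 <- cohort_from(c(6.0, 5.0), c(9.7, 10.0))
  ms2 <- median_split_profile(cohort_from(c(6, 5, 6.2, 5.1),
                                          c(9.7, 10, 9.8, 10.2)))
  expect_identical(ms2$n_low + ms2$n_high, 4L)
  # constructed cohort with known group means
  low_ft <- c(5.8, 5.9); low_fa <- c(10.9, 11.1)   # harmonic-ish, PCI < 0
  high_ft <- c(6.2, 6.3); high_fa <- c(10.0, 10.2) # phi-ish, PCI > 0
  ch <- cohort_from(c(low_ft, high_ft), c(low_fa, high_fa))
  ms <- median_split_profile(ch)
  expect_equal(unname(ms$low["f_theta"]), mean(low_ft))
  expect_equal(unname(ms$high["f_theta"]), mean(high_ft))
  expect_equal(unname(ms$high["f_alpha"]), mean(high_fa))
  # all-equal PCI: everyone ties into the low group
  same <- cohort_from(rep(6, 4), rep(10, 4))
  expect_warning(ms0 <- median_split_profile(same), "empty")
  expect_identical(ms0$n_low, 4L)
  expect_identical(ms0$n_high, 0L)
  expect_error(median_split_profile(ch2), "n >= 4")
})

test_that("subgroup correlations stratify, skip small strata and recover
          planted signs", {
  # one stratum only
  ch <- plausible_cohort(20)
  ch$sex <- "F"
  out <- subgroup_correlations(ch, "sex", n_boot = 50, seed = 1)
  expect_named(out, "F")
  # planted opposite signs across sex strata: in both strata the ratios
  # cluster at phi, but the centroid separation grows with |R - phi| for
  # the F stratum and shrinks for the M stratum
  set.seed(3)
  n <- 40
  phi <- 1.618034
  make_stratum <- function(sex, flip) {
    R <- pmin(pmax(rnorm(n, phi, 0.04), phi - 0.1), phi + 0.1)
    u <- pmin(abs(R - phi) / 0.1 + rnorm(n, 0, 0.1), 1)
    u <- pmax(u, 0)
    if (flip) u <- 1 - u
    df <- 3.36 + (4.12 - 3.36) * u
    ft <- df / (R - 1)
    data.frame(subject_id = sprintf("%s%02d", sex, 1:n),
               f_theta = ft, f_alpha = R * ft, sex = sex,
               stringsAsFactors = FALSE)
  }
  both <- rbind(make_stratum("F", flip = FALSE),
                make_stratum("M", flip = TRUE))
  rep2 <- subgroup_correlations(both, "sex", n_boot = 50, seed = 2)
  expect_length(rep2, 2)
  # F: separation grows away from phi, so PCI and convergence rise together
  expect_gt(rep2$F$pearson_r, 0)
  # M: coupling inverted, so the association flips sign
  expect_lt(rep2$M$pearson_r, 0)
  # age stratification with a small stratum
  ch$sex <- NULL
  ch$age <- c(rep(25, 18), 70, 71)
  expect_warning(out_age <- subgroup_correlations(ch, "age", n_boot = 50,
                                                  seed = 1), "skipped")
  expect_named(out_age, "age<40")
  expect_error(subgroup_correlations(plausible_cohort(10)[
    , c("subject_id", "f_theta", "f_alpha")], "sex"), "lacks")
})
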