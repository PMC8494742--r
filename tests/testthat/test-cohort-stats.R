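test_that("Snellen fractions convert to logMAR", {
  expect_equal(snellen_to_logmar(20, 20), 0)
  expect_equal(snellen_to_logmar(20, 200), 1)
  expect_equal(snellen_to_logmar(20, 32), -log10(20 / 32))
  expect_equal(snellen_to_logmar(fraction = c("20/20", "20/40")),
               c(0, -log10(0.5)))
  expect_error(snellen_to_logmar(0, 20), "positive")
})

test_that("Mann-Whitney U behaves at the null and on small exact samples", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  r <- compare_groups(x, x, test = "mann_whitney")
  expect_equal(r$statistic, length(x)^2 / 2)
  expect_equal(r$p_value, 1, tolerance = 1e-9)
  # exact enumeration: all 20 rank assignments, one extreme split each side
  r2 <- compare_groups(c(1, 2, 3), c(4, 5, 6), test = "mann_whitney")
  expect_equal(r2$p_value, 0.1)
  expect_error(compare_groups(numeric(0), x), "empty")
})

test_that("exact p from the normal approximation stays close at n = 10", {
  withr::with_seed(81, {
    for (rep in 1:5) {
      x <- rnorm(10); y <- rnorm(10, 0.5)
      p_exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
      p_norm <- stats::wilcox.test(x, y, exact = FALSE,
                                   correct = TRUE)$p.value
      expect_lt(abs(p_exact - p_norm), 0.02)
    }
  })
})

test_that("Fisher's exact test enumerates the hypergeometric tables", {
  r <- compare_groups(matrix(c(3, 0, 0, 3), 2, 2), test = "fisher")
  expect_equal(r$p_value, 0.1)
  expect_error(compare_groups(matrix(c(3, 2, 0, 0), 2, 2), test = "fisher"),
               "empty group|degenerate")
})

test_that("chi-squared warns about small expected counts", {
  tab <- matrix(c(3, 1, 2, 4), 2, 2)
  expect_warning(r <- compare_groups(tab, test = "chi2"), "Fisher")
  expect_true(r$note != "")
})

test_that("paired Wilcoxon detects a systematic within-pair shift", {
  withr::with_seed(82, {
    x <- rnorm(30, 250, 20)
    y <- x + rnorm(30, 15, 5)
    r <- compare_groups(x, y, test = "wilcoxon_paired")
    expect_lt(r$p_value, 1e-4)
  })
})

test_that("Spearman correlation matches the mid-rank oracle", {
  x <- 1:10
  expect_equal(spearman_corr(x, x)$rho, 1)
  expect_equal(spearman_corr(x, -x)$rho, -1)
  # fixed 10-point set with a tie: brute-force mid-rank computation
  xs <- c(1, 2, 3, 3, 5, 6, 7, 8, 9, 10)
  ys <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)
  manual_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      less <- sum(v < v[i]); eq <- sum(v == v[i])
      r[i] <- less + (eq + 1) / 2
    }
    r
  }
  rx <- manual_rank(xs); ry <- manual_rank(ys)
  rho_oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  got <- spearman_corr(xs, ys)
  expect_equal(got$rho, rho_oracle)
  # t-approximation p-value agrees with cor.test's asymptotic path
  ct <- stats::cor.test(xs, ys, method = "spearman", exact = FALSE)
  expect_equal(got$rho, unname(ct$estimate))
  # constant input is flagged, not an error
  flat <- spearman_corr(rep(1, 10), 1:10)
  expect_true(flat$undefined)
})

test_that("logistic fit recovers a known odds ratio at scale", {
  cfg <- cohort_sim_config(n_eyes = 5000, seed = 91)
  coh <- simulate_cohort(cfg)
  fit <- logistic_fit(coh, "recurrent",
                      c("dcp_c_mrt_um", "n_injections_total"),
                      mode = "multivariate")
  or_mrt <- fit$odds_ratio[fit$term == "dcp_c_mrt_um"]
  expect_gte(or_mrt, 1.02)
  expect_lte(or_mrt, 1.07)
  expect_true(all(fit$ci_low <= fit$odds_ratio &
                  fit$odds_ratio <= fit$ci_high))
  expect_equal(fit$odds_ratio, exp(fit$coef))
})

test_that("univariate mode fits each term alone and degenerate outcomes fail", {
  coh <- simulate_cohort(cohort_sim_config(n_eyes = 400, seed = 92))
  uni <- logistic_fit(coh, "recurrent",
                      c("dcp_c_mrt_um", "n_injections_total", "age_years"),
                      mode = "univariate")
  expect_equal(nrow(uni), 3)
  expect_true(all(uni$mode == "univariate"))
  coh$always <- TRUE
  expect_error(logistic_fit(coh, "always", "age_years"), "constant")
})

test_that("null-effect fits are calibrated (coefficients within 3 SE)", {
  withr::with_seed(93, {
    hits <- 0
    for (rep in 1:40) {
      n <- 300
      d <- tibble::tibble(x = rnorm(n),
                          y = rbinom(n, 1, 0.3) == 1)
      f <- logistic_fit(d, "y", "x", mode = "univariate")
      if (abs(f$coef) < 3 * f$se) hits <- hits + 1
    }
    expect_gte(hits / 40, 0.95)
  })
})

test_that("odds-ratio derivations match the printed arithmetic", {
  d <- or_derivations(1.044)
  expect_equal(d$pct_increase_per_unit, 4.4)
  expect_equal(d$doubling_units, 17L)
  expect_equal(or_derivations(2)$pct_increase_per_unit, 100)
  expect_equal(or_derivations(2)$doubling_units, 1L)
  expect_equal(or_derivations(1.5)$doubling_units, 2L)
  expect_error(or_derivations(1.0), "exceed 1")
  # monotone: a larger OR never needs more units to double the odds
  ors <- c(1.01, 1.044, 1.1, 1.5, 2, 5)
  ks <- vapply(ors, function(o) or_derivations(o)$doubling_units, integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("cohort accounting reproduces the screening arithmetic", {
  expect_equal(included_eyes(115, 39), 76)
  expect_equal(recurrence_rate_pct(22, 76), 100 * 22 / 76)
  expect_error(included_eyes(10, 20), "invalid")
  expect_error(recurrence_rate_pct(5, 0), "invalid")
})
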