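# Cohort-level statistics: the study's comparison layer (Mann-Whitney U,
# Wilcoxon signed-rank, Pearson chi-squared with Fisher's exact fallback,
# Spearman correlation), univariate/multivariate binary logistic regression
# with Wald CIs for recurrence risk factors, and the odds-ratio derivations
# (percent risk increase per unit; units needed to double the odds).
# Two-sided p-values throughout; no multiple-testing correction by default
# (a Holm option is provided), matching standard clinical reporting.

#' Snellen fraction to logMAR
#'
#' `-log10(numerator / denominator)`: 20/20 is 0.0, 20/200 is 1.0.
#'
#' @param numerator,denominator Snellen fraction parts (> 0); or give
#'   `fraction` as a string like `"20/32"`.
#' @param fraction optional character vector of fractions.
#' @export
snellen_to_logmar <- function(numerator, denominator, fraction = NULL) {
  if (!is.null(fraction)) {
    parts <- strsplit(fraction, "/")
    numerator <- as.numeric(vapply(parts, `[`, "", 1))
    denominator <- as.numeric(vapply(parts, `[`, "", 2))
  }
  if (any(numerator <= 0) || any(denominator <= 0))
    stop("Snellen fraction parts must be positive")
  -log10(numerator / denominator)
}

#' Two-group comparison
#'
#' Dispatches to the study's tests: Mann-Whitney U for independent numeric
#' data (exact enumeration when both groups have n <= 10 and no ties, else
#' the tie-corrected normal approximation), Wilcoxon signed-rank for paired
#' numeric data, Pearson chi-squared for categorical data (with a warning
#' echoing the usual fallback to Fisher when an expected count is below 5),
#' and Fisher's exact test. All p-values are two-sided.
#'
#' @param x,y the two samples (numeric), or for `chi2` / `fisher` either a
#'   2-way contingency table in `x` or two categorical vectors.
#' @param test one of `"mann_whitney"`, `"wilcoxon_paired"`, `"chi2"`,
#'   `"fisher"`.
#' @return tibble with test, statistic, p_value, n1, n2 and a note.
#' @export
compare_groups <- function(x, y = NULL,
                           test = c("mann_whitney", "wilcoxon_paired",
                                    "chi2", "fisher")) {
  test <- match.arg(test)
  note <- ""
  if (test %in% c("mann_whitney", "wilcoxon_paired")) {
    if (length(x) == 0 || length(y) == 0) stop("empty group")
    if (test == "mann_whitney") {
      exact <- length(x) <= 10 && length(y) <= 10 &&
        !any(duplicated(c(x, y)))
      # tie- and continuity-corrected normal approximation otherwise
      ht <- stats::wilcox.test(x, y, exact = exact, correct = !exact)
    } else {
      ht <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                               correct = TRUE)
    }
    stat <- unname(ht$statistic)
  } else {
    tab <- if (is.matrix(x) || is.table(x)) as.table(as.matrix(x))
           else table(x, y)
    if (any(dim(tab) < 2) || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      stop("degenerate contingency table (empty group)")
    if (test == "chi2") {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      if (any(ht$expected < 5)) {
        note <- "expected count < 5; consider Fisher's exact test"
        warning(note)
      }
      stat <- unname(ht$statistic)
    } else {
      ht <- stats::fisher.test(tab)
      stat <- NA_real_
    }
  }
  tibble::tibble(test = test, statistic = stat, p_value = ht$p.value,
                 n1 = if (is.null(y) || test %in% c("chi2", "fisher"))
                        NA_integer_ else length(x),
                 n2 = if (is.null(y) || test %in% c("chi2", "fisher"))
                        NA_integer_ else length(y),
                 note = note)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties) with a
#' t-approximation p-value. Constant input yields an NA result flagged
#' `undefined` rather than an error.
#'
#' @param x,y numeric vectors of equal length (n >= 4).
#' @return tibble with rho, p_value, n, undefined.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n,
                          undefined = TRUE))
  }
  rho <- stats::cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (abs(rho) >= 1) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
  tibble::tibble(rho = rho, p_value = p, n = n, undefined = FALSE)
}

#' Binary logistic regression with Wald odds-ratio intervals
#'
#' Maximum-likelihood fit (IRLS via [stats::glm]); per-term odds ratio,
#' Wald 95% CI `exp(coef +/- 1.96 SE)` and p-value. `mode = "univariate"`
#' fits each term alone; `"multivariate"` fits them jointly. Separation or
#' non-convergence is flagged on the affected rows, never silent.
#'
#' @param data data frame / tibble.
#' @param outcome name of the binary outcome column (logical or 0/1); both
#'   classes must be present.
#' @param terms character vector of predictor column names.
#' @param mode `"univariate"` or `"multivariate"`.
#' @return tibble with mode, term, coef, se, odds_ratio, ci_low, ci_high,
#'   p_value, converged, n.
#' @export
logistic_fit <- function(data, outcome, terms,
                         mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  yv <- data[[outcome]]
  if (is.logical(yv)) yv <- as.integer(yv)
  if (length(unique(yv[!is.na(yv)])) < 2)
    stop("outcome is constant: both classes must be present")
  fit_one <- function(tms) {
    fml <- stats::as.formula(paste("y_ ~", paste(tms, collapse = " + ")))
    d <- data[, tms, drop = FALSE]
    d$y_ <- yv
    fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                       data = d))
    s <- summary(fit)$coefficients
    rows <- rownames(s)[-1]
    separated <- !fit$converged | any(abs(s[-1, "Estimate"]) > 15) |
      any(s[-1, "Std. Error"] > 100)
    tibble::tibble(
      mode = mode, term = rows,
      coef = s[-1, "Estimate"], se = s[-1, "Std. Error"],
      odds_ratio = exp(s[-1, "Estimate"]),
      ci_low = exp(s[-1, "Estimate"] - 1.96 * s[-1, "Std. Error"]),
      ci_high = exp(s[-1, "Estimate"] + 1.96 * s[-1, "Std. Error"]),
      p_value = s[-1, "Pr(>|z|)"],
      converged = fit$converged & !separated,
      log_likelihood = as.numeric(stats::logLik(fit)),
      n = stats::nobs(fit))
  }
  if (mode == "univariate") {
    do.call(rbind, lapply(terms, fit_one))
  } else {
    fit_one(terms)
  }
}

#' Select multivariate terms by the univariate screen
#'
#' Terms entering the multivariate model are those univariately significant
#' at `alpha` — an explicit, logged rule (overridable by passing terms
#' directly to [logistic_fit]).
#'
#' @param univariate result tibble from `logistic_fit(mode = "univariate")`.
#' @param alpha screening level (default 0.05).
#' @export
select_multivariate_terms <- function(univariate, alpha = 0.05) {
  unique(univariate$term[univariate$p_value < alpha & univariate$converged])
}

#' Odds-ratio derivations
#'
#' From a per-unit odds ratio above 1: the percent risk increase per unit,
#' `(OR - 1) * 100`, and the smallest whole number of units whose combined
#' odds ratio reaches 2 (odds doubling), the smallest integer k with
#' `OR^k >= 2`. An OR of 1.044 per um gives 4.4% per um and a 17 um
#' doubling increment.
#'
#' @param or_per_unit odds ratio per unit (> 1).
#' @return named list with `pct_increase_per_unit` and `doubling_units`.
#' @export
or_derivations <- function(or_per_unit) {
  if (or_per_unit <= 1)
    stop("odds ratio must exceed 1 (no doubling exists otherwise)")
  k <- ceiling(log(2) / log(or_per_unit) - 1e-9)
  list(pct_increase_per_unit = (or_per_unit - 1) * 100,
       doubling_units = as.integer(k))
}

#' Holm adjustment helper (off by default everywhere)
#'
#' @param p numeric p-values.
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")

#' Study accounting helpers
#'
#' `included_eyes` is screened minus excluded; `recurrence_rate_pct` is the
#' recurrence percentage from counts.
#'
#' @param screened,excluded,recurred,included counts.
#' @export
included_eyes <- function(screened, excluded) {
  if (excluded > screened || screened < 0 || excluded < 0)
    stop("invalid counts")
  screened - excluded
}

#' @rdname included_eyes
#' @export
recurrence_rate_pct <- function(recurred, included) {
  if (recurred > included || included <= 0) stop("invalid counts")
  100 * recurred / included
}
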