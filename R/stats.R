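#' Two-sample Student's t-test from summary statistics
#'
#' Pooled-variance (equal-variance) t-test computed directly from group
#' means, SDs and sizes, so printed summary tables can be re-tested without
#' raw data. A Welch variant is available behind `var_equal = FALSE`.
#'
#' @param mean1,sd1,n1 Summary statistics of the first group.
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @param var_equal Pooled (Student) variance if `TRUE` (default), Welch
#'   otherwise.
#' @return A tibble with `t`, `df`, `p` (two-tailed), `mean1`, `mean2`,
#'   `sd1`, `sd2`, `n1`, `n2`.
#' @examples
#' pooled_t_from_summary(193.1, 12.5, 25, 206.1, 18.0, 26)
#' @export
pooled_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                  var_equal = TRUE) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative", call. = FALSE)
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0) {
    if (mean1 == mean2) {
      t <- 0
    } else {
      warning("zero pooled variance with unequal means; reporting signed infinite t",
              call. = FALSE)
      t <- sign(mean1 - mean2) * Inf
    }
  } else {
    t <- (mean1 - mean2) / se
  }
  p <- 2 * stats::pt(-abs(t), df)
  tibble::tibble(t = t, df = df, p = p, mean1 = mean1, mean2 = mean2,
                 sd1 = sd1, sd2 = sd2, n1 = n1, n2 = n2)
}

#' Two-sample Student's t-test from raw observations
#'
#' Computes the group summaries and routes through
#' [pooled_t_from_summary()], so the two entry points agree exactly.
#'
#' @param x,y Numeric samples (NAs dropped), each with n >= 2.
#' @inheritParams pooled_t_from_summary
#' @return As [pooled_t_from_summary()].
#' @export
pooled_t_from_raw <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2", call. = FALSE)
  pooled_t_from_summary(mean(x), stats::sd(x), length(x),
                        mean(y), stats::sd(y), length(y), var_equal)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Flags the rejections of the BH step-up procedure at level `q` and reports
#' the critical p-value: the largest p among the rejected tests (the family's
#' data-dependent significance cutoff often reported alongside FDR results).
#'
#' @param pvalues Vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return A list with `reject` (logical, in input order), `critical_p`
#'   (`NA` if nothing is rejected), and `p_adjusted` (BH-adjusted p-values).
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.30))
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0L) stop("bh_fdr: empty p-value list", call. = FALSE)
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("bh_fdr: p-values must lie in [0, 1]", call. = FALSE)
  }
  padj <- stats::p.adjust(pvalues, method = "BH")
  reject <- padj <= q
  critical_p <- if (any(reject)) max(pvalues[reject]) else NA_real_
  list(reject = reject, critical_p = critical_p, p_adjusted = padj)
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' Tests whether two Pearson correlations from independent samples differ:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-tailed normal p-value. Convention: `r1` is the first-named group.
#'
#' @param r1,n1 Correlation and sample size in the first group.
#' @param r2,n2 Correlation and sample size in the second group.
#' @return A tibble with `z` and `p`.
#' @examples
#' fisher_rz_compare(-0.486, 25, 0.480, 26)  # z ~ -3.53
#' @export
fisher_rz_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("fisher_rz_compare: |r| must be < 1", call. = FALSE)
  }
  if (n1 <= 3 || n2 <= 3) stop("fisher_rz_compare: each n must exceed 3", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Correlation screen of metabolite levels against performance measures
#'
#' Pearson correlations of every region x metabolite (including ratio
#' pseudo-metabolites) against each behavioral measure, within each group
#' separately, with pairwise deletion of missing (QC-failed) values.
#' Candidates for the follow-up regression are flagged at two-tailed
#' `p < alpha` (uncorrected, by design: the screen selects predictors, the
#' regression quantifies them).
#'
#' @param panel Corrected metabolite panel (with `corrected_concentration`),
#'   e.g. from [correct_panel()] + [panel_with_ratio()].
#' @param performance Performance table from [compute_performance_table()].
#' @param measures Behavioral measures to screen against.
#' @param alpha Screening significance level (default 0.05, two-tailed).
#' @param min_n Minimum complete pairs required (default 4); below it the
#'   correlation is reported missing.
#' @return A tibble `group`, `measure`, `region`, `metabolite`, `n`, `r`,
#'   `p`, `candidate`.
#' @export
pearson_screen <- function(panel, performance,
                           measures = c("go_rt", "proactive_slowing", "ssrt"),
                           alpha = 0.05, min_n = 4) {
  stopifnot(all(measures %in% names(performance)))
  merged <- dplyr::inner_join(
    panel[, c("subject_id", "group", "region", "metabolite",
              "corrected_concentration")],
    performance[, c("subject_id", measures)],
    by = "subject_id"
  )
  cells <- dplyr::distinct(merged[, c("group", "region", "metabolite")])
  rows <- vector("list", nrow(cells) * length(measures))
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    sub <- merged[merged$group == cells$group[i] &
                    merged$region == cells$region[i] &
                    merged$metabolite == cells$metabolite[i], , drop = FALSE]
    for (m in measures) {
      k <- k + 1L
      ok <- !is.na(sub$corrected_concentration) & !is.na(sub[[m]])
      x <- sub$corrected_concentration[ok]
      y <- sub[[m]][ok]
      n <- length(x)
      if (n < min_n || stats::sd(x) == 0 || stats::sd(y) == 0) {
        r <- p <- NA_real_
      } else {
        ct <- stats::cor.test(x, y, method = "pearson")
        r <- unname(ct$estimate)
        p <- ct$p.value
      }
      rows[[k]] <- tibble::tibble(
        group = cells$group[i], measure = m, region = cells$region[i],
        metabolite = cells$metabolite[i], n = n, r = r, p = p,
        candidate = !is.na(p) & p < alpha
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Ordinary least squares with standardized coefficients and variance
#' partitioning
#'
#' Fits `y ~ X` by OLS and reports the regression summary used for
#' metabolite-predictor tables: R-squared, adjusted R-squared, the overall F,
#' and per predictor the raw coefficient B (SE), the standardized coefficient
#' beta (SE; both response and predictors z-scored), the two-tailed p, and
#' the R-squared change - the amount by which R-squared drops when that
#' predictor is removed from the model (the squared semipartial correlation).
#'
#' @param data Data frame with complete cases for `response` and `predictors`
#'   (rows with missing values are dropped listwise).
#' @param response Name of the response column.
#' @param predictors Character vector of predictor columns.
#' @return An object of class `regression_summary`: a list with `n`, `r2`,
#'   `r2_adjusted`, `f`, `df1`, `df2`, `p_model` and a `coefficients` tibble
#'   (`term`, `b`, `b_se`, `beta`, `beta_se`, `p`, `r2_change`).
#' @export
fit_regression <- function(data, response, predictors) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  cols <- c(response, predictors)
  dat <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols, drop = FALSE]
  n <- nrow(dat)
  p <- length(predictors)
  if (n <= p + 1) {
    stop(sprintf("fit_regression: n = %d too small for %d predictors", n, p),
         call. = FALSE)
  }
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = dat)
  if (fit$rank < p + 1L) {
    dropped <- predictors[!predictors %in%
                            names(stats::coef(fit))[!is.na(stats::coef(fit))]]
    stop("fit_regression: rank-deficient design; offending predictor(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  coefs <- sm$coefficients
  sdy <- stats::sd(dat[[response]])
  sdx <- vapply(predictors, function(v) stats::sd(dat[[v]]), numeric(1))
  r2 <- sm$r.squared
  # standardized betas: coefficients of the model with y and X z-scored;
  # equivalently B * sd(x)/sd(y), with SEs rescaled the same way
  beta <- coefs[predictors, "Estimate"] * sdx / sdy
  beta_se <- coefs[predictors, "Std. Error"] * sdx / sdy
  r2_change <- vapply(predictors, function(j) {
    others <- setdiff(predictors, j)
    r2_reduced <- if (length(others) == 0L) 0 else {
      summary(stats::lm(stats::reformulate(others, response), data = dat))$r.squared
    }
    r2 - r2_reduced
  }, numeric(1))
  coef_tbl <- tibble::tibble(
    term = c("(Intercept)", predictors),
    b = unname(coefs[c("(Intercept)", predictors), "Estimate"]),
    b_se = unname(coefs[c("(Intercept)", predictors), "Std. Error"]),
    beta = c(NA_real_, unname(beta)),
    beta_se = c(NA_real_, unname(beta_se)),
    p = unname(coefs[c("(Intercept)", predictors), "Pr(>|t|)"]),
    r2_change = c(NA_real_, unname(r2_change))
  )
  structure(
    list(n = n, r2 = r2, r2_adjusted = sm$adj.r.squared,
         f = unname(sm$fstatistic["value"]),
         df1 = unname(sm$fstatistic["numdf"]),
         df2 = unname(sm$fstatistic["dendf"]),
         p_model = stats::pf(sm$fstatistic["value"], sm$fstatistic["numdf"],
                             sm$fstatistic["dendf"], lower.tail = FALSE),
         coefficients = coef_tbl,
         response = response, predictors = predictors),
    class = "regression_summary"
  )
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("OLS: %s ~ %s  (n = %d)\n", x$response,
              paste(x$predictors, collapse = " + "), x$n))
  cat(sprintf("  R2 = %.3f, adj. R2 = %.3f, F(%d, %d) = %.3f, p = %.4g\n",
              x$r2, x$r2_adjusted, x$df1, x$df2, x$f, x$p_model))
  print(x$coefficients)
  invisible(x)
}

#' R-squared change for a single predictor
#'
#' The amount by which the model R-squared is reduced when predictor `j` is
#' removed from the full model; equals the squared semipartial correlation of
#' `j` with the response.
#'
#' @inheritParams fit_regression
#' @param j Predictor to remove (must be among `predictors`).
#' @return The R-squared change (unitless).
#' @export
r2_change <- function(data, response, predictors, j) {
  stopifnot(j %in% predictors)
  fit <- fit_regression(data, response, predictors)
  fit$coefficients$r2_change[fit$coefficients$term == j]
}
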