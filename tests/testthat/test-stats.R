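test_that("pooled t from summaries reproduces printed group-comparison statistics", {
  # frozen from direct evaluation of the pooled-variance formula on the
  # printed means/SDs (n = 25 vs 26, df = 49)
  tt <- pooled_t_from_summary(193.1, 12.5, 25, 206.1, 18.0, 26)
  expect_equal(tt$t, -2.9844, tolerance = 1e-4)
  expect_equal(tt$df, 49)
  expect_lt(tt$p, 0.005)
  expect_equal(pooled_t_from_summary(10.26, 6.14, 25, 13.01, 16.77, 26)$t,
               -0.7715, tolerance = 1e-4)
  expect_equal(pooled_t_from_summary(616.5, 13.9, 25, 608.4, 24.5, 26)$t,
               1.4443, tolerance = 1e-4)
  expect_equal(pooled_t_from_summary(52.60, 1.02, 25, 52.50, 1.12, 26)$t,
               0.3330, tolerance = 1e-4)
})

test_that("summary and raw entry points agree exactly and match t.test", {
  set.seed(30)
  x <- rnorm(20, 5, 2)
  y <- rnorm(25, 6, 2.5)
  a <- pooled_t_from_summary(mean(x), sd(x), 20, mean(y), sd(y), 25)
  b <- pooled_t_from_raw(x, y)
  expect_identical(a$t, b$t)
  expect_identical(a$p, b$p)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(b$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(b$p, ref$p.value, tolerance = 1e-12)
  # Welch variant against t.test
  w <- pooled_t_from_raw(x, y, var_equal = FALSE)
  refw <- t.test(x, y)
  expect_equal(w$t, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(refw$parameter), tolerance = 1e-9)
})

test_that("degenerate t inputs are handled explicitly", {
  expect_equal(pooled_t_from_raw(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(pooled_t_from_summary(5, 1, 10, 5, 1, 10)$p, 1)
  expect_warning(tt <- pooled_t_from_raw(c(1, 1, 1), c(2, 2, 2)),
                 "infinite")
  expect_equal(tt$t, -Inf)
  expect_error(pooled_t_from_raw(1, c(1, 2)), "n >= 2")
})

test_that("pooled t keeps its type-I error rate under the null", {
  set.seed(31)
  reps <- 4000
  hits <- sum(replicate(reps, {
    pooled_t_from_raw(rnorm(12), rnorm(12))$p < 0.05
  }))
  expect_gt(hits / reps, 0.04)
  expect_lt(hits / reps, 0.06)
})

test_that("BH step-up matches hand thresholds and p.adjust", {
  out <- bh_fdr(c(0.01, 0.02, 0.30), q = 0.05)
  expect_equal(out$reject, c(TRUE, TRUE, FALSE))
  expect_equal(out$critical_p, 0.02)
  single <- bh_fdr(0.04)
  expect_true(single$reject)
  expect_equal(single$critical_p, 0.04)
  expect_equal(out$p_adjusted, p.adjust(c(0.01, 0.02, 0.30), "BH"))
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH rejection set equals the exhaustive step-up oracle on short lists", {
  set.seed(32)
  for (i in 1:100) {
    m <- sample(1:12, 1)
    p <- round(runif(m)^2, 3)  # skew toward small p so rejections happen
    expect_equal(bh_fdr(p, q = 0.05)$reject, bh_oracle(p, q = 0.05),
                 info = paste(p, collapse = ","))
  }
})

test_that("BH sits between Bonferroni and unadjusted testing", {
  set.seed(33)
  for (i in 1:50) {
    p <- runif(8)^1.5
    bh <- bh_fdr(p, q = 0.05)$reject
    bonf <- p <= 0.05 / length(p)
    raw <- p <= 0.05
    expect_true(all(bh[bonf]))   # everything Bonferroni rejects, BH rejects
    expect_true(all(raw[bh]))    # everything BH rejects is raw-significant
  }
})

test_that("Fisher r-to-z reproduces the printed cross-group contrast", {
  out <- fisher_rz_compare(-0.486, 25, 0.480, 26)
  expect_equal(out$z, -3.53, tolerance = 0.005)
  expect_lt(out$p, 0.001)
  expect_equal(fisher_rz_compare(0.4, 30, 0.4, 20)$z, 0)
  # closed-form cross-check computed term by term
  z_hand <- (atanh(-0.486) - atanh(0.480)) / sqrt(1 / 22 + 1 / 23)
  expect_equal(out$z, z_hand, tolerance = 1e-12)
  expect_error(fisher_rz_compare(1, 25, 0.5, 26), "< 1")
  expect_error(fisher_rz_compare(0.2, 3, 0.5, 26), "exceed 3")
})

test_that("OLS summary matches the normal-equations solution", {
  set.seed(34)
  n <- 40
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- 2 + 1.5 * d$x1 - 0.8 * d$x2 + rnorm(n, 0, 0.7)
  fit <- fit_regression(d, "y", c("x1", "x2", "x3"))
  # independent route: solve the normal equations directly
  X <- cbind(1, d$x1, d$x2, d$x3)
  beta_hat <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(fit$coefficients$b, as.numeric(beta_hat), tolerance = 1e-10)
  resid <- d$y - X %*% beta_hat
  r2_hand <- 1 - sum(resid^2) / sum((d$y - mean(d$y))^2)
  expect_equal(fit$r2, r2_hand, tolerance = 1e-12)
  expect_lte(fit$r2_adjusted, fit$r2)
  # standardized beta identity
  expect_equal(fit$coefficients$beta[-1],
               fit$coefficients$b[-1] *
                 sapply(d[c("x1", "x2", "x3")], sd) / sd(d$y),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("noise-free proportional response gives a perfect fit", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  fit <- suppressWarnings(fit_regression(d, "y", "x"))  # lm warns on exact fits
  expect_equal(fit$r2, 1)
  expect_equal(fit$coefficients$b[fit$coefficients$term == "x"], 2)
  expect_equal(fit$coefficients$beta[fit$coefficients$term == "x"], 1)
})

test_that("rank deficiency and tiny samples are rejected with clear errors", {
  d <- tibble::tibble(x1 = 1:10, x2 = 2 * (1:10), y = rnorm(10))
  expect_error(fit_regression(d, "y", c("x1", "x2")), "rank-deficient")
  expect_error(fit_regression(d[1:3, ], "y", c("x1", "x2")), "too small")
})

test_that("null predictors keep uniform p-values in the fitted model", {
  set.seed(35)
  reps <- 500
  pvals <- replicate(reps, {
    n <- 30
    d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), xnull = rnorm(n))
    d$y <- d$x1 - d$x2 + rnorm(n)
    fit <- fit_regression(d, "y", c("x1", "x2", "xnull"))
    fit$coefficients$p[fit$coefficients$term == "xnull"]
  })
  # calibration: roughly uniform -> KS distance small, 5% rate near nominal
  expect_gt(mean(pvals < 0.05), 0.02)
  expect_lt(mean(pvals < 0.05), 0.09)
  expect_lt(suppressWarnings(ks.test(pvals, "punif")$statistic), 0.08)
})

test_that("R-squared change equals the squared semipartial correlation", {
  set.seed(36)
  for (i in 1:100) {
    n <- 30
    z <- rnorm(n)
    d <- tibble::tibble(
      x1 = rnorm(n) + 0.5 * z, x2 = rnorm(n) + 0.5 * z, x3 = rnorm(n)
    )
    d$y <- 0.8 * d$x1 - 0.5 * d$x2 + 0.3 * d$x3 + rnorm(n)
    preds <- c("x1", "x2", "x3")
    j <- sample(preds, 1)
    # residualization oracle: correlate y with x_j purged of the others
    e_j <- resid(lm(reformulate(setdiff(preds, j), j), data = d))
    expect_equal(r2_change(d, "y", preds, j), cor(d$y, e_j)^2,
                 tolerance = 1e-10)
  }
})

test_that("R-squared changes sum to at most the model R-squared", {
  set.seed(37)
  for (i in 1:100) {
    n <- 25
    z <- rnorm(n)
    d <- tibble::tibble(x1 = rnorm(n) + z, x2 = rnorm(n) + z, x3 = rnorm(n) + 0.5 * z)
    d$y <- d$x1 + 0.5 * d$x2 + rnorm(n)
    fit <- fit_regression(d, "y", c("x1", "x2", "x3"))
    expect_lte(sum(fit$coefficients$r2_change[-1]), fit$r2 + 1e-12)
  }
})

test_that("orthogonal predictors give r2_change equal to squared zero-order r", {
  set.seed(38)
  n <- 64
  # columns orthogonal to each other and to the constant (mutually centered)
  x <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  d <- tibble::tibble(x1 = x[, 1], x2 = x[, 2], x3 = x[, 3])
  d$y <- 2 * d$x1 - d$x2 + 0.5 * d$x3 + rnorm(n, 0, 0.3)
  for (j in c("x1", "x2", "x3")) {
    expect_equal(r2_change(d, "y", c("x1", "x2", "x3"), j),
                 cor(d[[j]], d$y)^2, tolerance = 1e-10)
  }
})

test_that("correlation screen flags planted effects and counts its tests", {
  set.seed(39)
  sim <- simulate_cohort(cohort_spec(qc_fail_rate = 0), seed = 39)
  panel <- panel_with_ratio(correct_panel(sim$panel))
  screen <- pearson_screen(panel, sim$performance)
  # (5 metabolites x 7 regions + 7 ratio cells) x 3 measures x 2 groups
  expect_equal(nrow(screen), (35 + 7) * 3 * 2)
  planted <- screen[screen$group == "young" & screen$measure == "go_rt" &
                      screen$region == "LSTR" & screen$metabolite == "Glx", ]
  expect_true(planted$candidate)
  expect_equal(planted$r, -0.572, tolerance = 0.02)
  expect_equal(planted$n, 25)
  # a perfectly collinear pair gives r = 1
  panel2 <- panel[panel$region == "OCC" & panel$metabolite == "NAA", ]
  panel2$corrected_concentration <-
    sim$performance$go_rt[match(panel2$subject_id, sim$performance$subject_id)]
  s2 <- pearson_screen(panel2, sim$performance, measures = "go_rt")
  expect_equal(s2$r[s2$group == "young"], 1, tolerance = 1e-12)
  # zero variance is reported missing
  panel2$corrected_concentration <- 1
  s3 <- pearson_screen(panel2, sim$performance, measures = "go_rt")
  expect_true(all(is.na(s3$r)))
})
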