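test_that("go-trial filter keeps the 400-1280 ms window and preserves order", {
  tr <- go_rows(c(350, 800, 1300, NA))
  kept <- filter_go_trials(tr)
  expect_equal(kept$rt_ms, 800)
  expect_equal(nrow(filter_go_trials(go_rows(numeric(0)))), 0)
  # boundary values are inside the window
  expect_equal(filter_go_trials(go_rows(c(400, 1280, 399.9, 1280.1)))$rt_ms,
               c(400, 1280))
  expect_error(filter_go_trials(stop_rows(600, TRUE)), "go trials only")
})

test_that("go-trial filter agrees with the direct predicate on random RTs", {
  set.seed(8)
  rts <- runif(1000, 0, 1500)
  kept <- filter_go_trials(go_rows(rts))
  expect_equal(nrow(kept), sum(rts >= 400 & rts <= 1280))
  expect_equal(kept$rt_ms, rts[rts >= 400 & rts <= 1280])
})

test_that("integration SSRT follows the rank rule", {
  # constant distribution: any quantile is 800
  expect_equal(estimate_ssrt_integration(rep(800, 10), 600, 0.5), 200)
  # hand enumeration: N=4, p=0.5 -> n = round(2) = 2 -> sorted[2] = 750
  expect_equal(estimate_ssrt_integration(c(850, 700, 800, 750), 600, 0.5), 150)
  # round-half-up: N=5, p=0.5 -> 2.5 rounds to 3 -> sorted[3]
  expect_equal(estimate_ssrt_integration(c(700, 750, 800, 850, 900), 600, 0.5),
               800 - 600)
  # clamping at the top rank
  expect_equal(estimate_ssrt_integration(c(700, 800), 600, 0.99), 800 - 600)
  expect_error(estimate_ssrt_integration(numeric(0), 600, 0.5), "no go RTs")
  expect_error(estimate_ssrt_integration(c(700, 800), 600, 1), "p_inhibit")
  expect_error(estimate_ssrt_integration(c(700, 800), 600, 0), "p_inhibit")
})

test_that("integration SSRT shifts by exactly c when all go RTs shift by c", {
  set.seed(9)
  rts <- rnorm(200, 800, 50)
  for (p_inh in c(0.3, 0.5, 0.7)) {
    base <- estimate_ssrt_integration(rts, 610, p_inh)
    expect_equal(estimate_ssrt_integration(rts + 17, 610, p_inh), base + 17)
  }
})

test_that("integration SSRT recovers the true stop latency under the race model", {
  p <- race_params(800, 50, 200, proactive_delta_20 = 0, proactive_delta_40 = 0,
                   early_resp_rate = 0, omission_rate = 0)
  set.seed(10)
  go <- rnorm(5000, 800, 50)
  run <- staircase_run(p, n_trials = 2000, burn_in = 0)
  est <- estimate_ssrt_integration(go[go >= 400 & go <= 1280],
                                   mean(run$ssd), mean(run$success))
  expect_lt(abs(est - 200), 10)
})

test_that("subject performance averages sessions and reports every measure", {
  s1 <- toy_subject(session = 1)
  s2 <- toy_subject(session = 2)
  perf <- compute_subject_performance(dplyr::bind_rows(s1, s2))
  single <- compute_subject_performance(s1)
  # identical sessions: averaged measures equal single-session measures
  for (m in c("go_rt", "go_rt_20", "go_rt_40", "proactive_slowing",
              "ssrt", "mean_ssd", "p_inhibit", "rt_sf")) {
    expect_equal(perf[[m]], single[[m]], info = m)
  }
  expect_equal(perf$go_rt, 800)
  expect_equal(perf$p_inhibit, 0.5)
  expect_equal(perf$rt_sf, 780)
  expect_equal(perf$proactive_slowing, perf$go_rt_40 - perf$go_rt_20)
  # SSRT from the pooled 20/40 go RTs: sorted {800,820,830,840,850,860},
  # n = round(6 * 0.5) = 3 -> 830 - 600
  expect_equal(perf$ssrt, 230)
})

test_that("measures are invariant to trial order within a session", {
  set.seed(12)
  tr <- simulate_subject(race_params())
  shuffled <- dplyr::bind_rows(lapply(split(tr, tr$session),
                                      function(x) x[sample(nrow(x)), ]))
  expect_equal(compute_subject_performance(tr),
               compute_subject_performance(shuffled))
})

test_that("successful and failed stop counts partition the stop trials", {
  set.seed(13)
  tr <- simulate_subject(race_params())
  stp <- tr[tr$trial_type == "stop", ]
  perf <- compute_subject_performance(tr)
  expect_equal(sum(stp$stop_success) + sum(!stp$stop_success), perf$n_stop)
  expect_equal(perf$p_inhibit,
               mean(c(mean(stp$stop_success[stp$session == 1]),
                      mean(stp$stop_success[stp$session == 2]))))
})

test_that("a session without usable stop data drops out of the SSRT average", {
  s1 <- toy_subject(session = 1)
  # session 2: all stops succeed -> P(inhibit) = 1, SSRT undefined there
  s2 <- toy_subject(session = 2, success = c(TRUE, TRUE, TRUE, TRUE))
  expect_warning(perf <- compute_subject_performance(dplyr::bind_rows(s1, s2)),
                 "degenerate")
  expect_equal(perf$ssrt, compute_subject_performance(s1)$ssrt)
})

test_that("an injected proactive context shift is recovered from the go RTs", {
  # deltas 5 and 20 ms on a 800-ms planned lift: GoRT_40-20 = 15 ms
  set.seed(14)
  tr <- dplyr::bind_rows(
    go_rows(rnorm(1e4, 800, 50), ssp = 0),
    go_rows(rnorm(1e4, 805, 50), ssp = 20),
    go_rows(rnorm(1e4, 820, 50), ssp = 40)
  )
  perf <- compute_subject_performance(tr)
  expect_lt(abs(perf$proactive_slowing - 15), 2)
})

test_that("proactive slowing in the zero-noise limit equals the injected delta", {
  p <- race_params(planned_rt_sd = 1e-9, proactive_delta_20 = 10,
                   proactive_delta_40 = 25, early_resp_rate = 0,
                   omission_rate = 0)
  set.seed(15)
  tr <- simulate_subject(p)
  perf <- compute_subject_performance(tr)
  expect_equal(perf$proactive_slowing, 15, tolerance = 1e-6)
  # zero-noise SSRT is exact up to the staircase granularity
  expect_lt(abs(perf$ssrt - 200), 33 + 1e-6)
})

test_that("the two proactive-slowing orders agree on balanced sessions", {
  set.seed(16)
  tr <- simulate_subject(race_params())
  a <- compute_subject_performance(tr, proactive_by_session = FALSE)
  b <- compute_subject_performance(tr, proactive_by_session = TRUE)
  expect_equal(a$proactive_slowing, b$proactive_slowing, tolerance = 1e-9)
})

test_that("group summary reports sample SDs and matches a direct computation", {
  perf <- tibble::tibble(
    subject_id = sprintf("S%d", 1:6),
    group = rep(c("young", "older"), each = 3),
    go_rt = c(810, 820, 815, 830, 820, 825),
    proactive_slowing = c(10, 12, 8, 15, 13, 11),
    ssrt = c(190, 195, 200, 210, 205, 215),
    rt_sf = c(795, 790, 800, 780, 785, 790),
    mean_ssd = c(615, 610, 620, 605, 600, 610),
    p_inhibit = c(0.5, 0.52, 0.48, 0.51, 0.5, 0.49)
  )
  out <- summarize_group(perf)
  ya_ssrt <- out[out$measure == "ssrt" & out$group == "young", ]
  expect_equal(ya_ssrt$mean, mean(c(190, 195, 200)))
  expect_equal(ya_ssrt$sd, sd(c(190, 195, 200)))  # n-1 denominator
  expect_equal(nrow(out), 6 * 2)
  # two identical subjects -> SD 0
  twin <- perf[c(1, 1), ]
  twin$subject_id <- c("a", "b")
  out2 <- summarize_group(twin)
  expect_true(all(out2$sd == 0))
  expect_error(summarize_group(perf[c(1, 4, 5), ]), "at least 2")
})
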