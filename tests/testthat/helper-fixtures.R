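# Hand-built trial-table rows for behavior-module tests.

go_rows <- function(rts, ssp = 0, subject_id = "S01", group = "young",
                    session = 1) {
  tibble::tibble(
    subject_id = subject_id, group = group, session = session,
    ssp = ssp, trial_type = "go",
    ssd_ms = NA_real_, rt_ms = rts, stop_success = NA
  )
}

stop_rows <- function(ssd, success, rt = NULL, ssp = 20, subject_id = "S01",
                      group = "young", session = 1) {
  if (is.null(rt)) rt <- ifelse(success, NA_real_, 780)
  tibble::tibble(
    subject_id = subject_id, group = group, session = session,
    ssp = ssp, trial_type = "stop",
    ssd_ms = ssd, rt_ms = rt, stop_success = success
  )
}

# A minimal but complete subject: go trials in all three SSP conditions plus
# staircase-free stop trials with a fixed SSD.
toy_subject <- function(session = 1, go0 = c(790, 800, 810),
                        go20 = c(800, 820, 840, 860), go40 = c(830, 850),
                        ssd = 600, success = c(TRUE, FALSE, TRUE, FALSE),
                        subject_id = "S01", group = "young") {
  dplyr::bind_rows(
    go_rows(go0, ssp = 0, subject_id = subject_id, group = group, session = session),
    go_rows(go20, ssp = 20, subject_id = subject_id, group = group, session = session),
    go_rows(go40, ssp = 40, subject_id = subject_id, group = group, session = session),
    stop_rows(ssd, success, subject_id = subject_id, group = group, session = session)
  )
}

# Exhaustive step-up oracle for BH: the rejection set is the largest set of
# the form {p <= c}, c among the observed p-values, whose estimated false
# discovery proportion m * c / |{p <= c}| stays within q.
bh_oracle <- function(p, q = 0.05) {
  m <- length(p)
  best <- numeric(0)
  for (c in sort(unique(p))) {
    k <- sum(p <= c)
    if (m * c / k <= q && k > length(best)) best <- which(p <= c)
  }
  reject <- logical(m)
  reject[best] <- TRUE
  reject
}
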