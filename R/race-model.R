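#' Race-model parameters for an anticipated-response stop-signal subject
#'
#' Describes one simulated subject under the independent race model: a planned
#' finger-lift time drawn from a normal distribution (the "go" process, aimed
#' at a target crossing 800 ms after trial onset) races a stop process of fixed
#' latency `ssrt_true` triggered at the stop-signal delay (SSD). The stop wins
#' - the lift is cancelled - iff the planned lift time is at or after
#' SSD + SSRT. Proactive slowing in blocks with 20% or 40% stop-signal
#' probability (SSP) is an additive shift of the planned-lift mean.
#'
#' @param planned_rt_mean Mean planned lift time, ms from trial onset. The task
#'   rewards responses near the 800-ms target crossing.
#' @param planned_rt_sd Trial-to-trial SD of the planned lift time, ms (> 0).
#' @param ssrt_true Latency of the stop process, ms (> 0).
#' @param proactive_delta_20,proactive_delta_40 Additive slowing (ms) of the
#'   planned-lift mean in 20% and 40% SSP blocks. Their difference is the
#'   proactive-slowing construct GoRT_40-20.
#' @param early_resp_rate Probability that a go trial is replaced by an
#'   anticipatory early lift (< 400 ms).
#' @param omission_rate Probability that a go trial has no lift before the
#'   1280-ms display cutoff (recorded as missing RT).
#' @return An object of class `race_params` (a validated list).
#' @examples
#' p <- race_params(planned_rt_mean = 800, planned_rt_sd = 50, ssrt_true = 200)
#' @export
race_params <- function(planned_rt_mean = 800,
                        planned_rt_sd = 50,
                        ssrt_true = 200,
                        proactive_delta_20 = 10,
                        proactive_delta_40 = 20,
                        early_resp_rate = 0.01,
                        omission_rate = 0.01) {
  vals <- c(planned_rt_mean, planned_rt_sd, ssrt_true,
            proactive_delta_20, proactive_delta_40,
            early_resp_rate, omission_rate)
  if (!all(is.finite(vals))) {
    stop("race_params: all parameters must be finite numbers", call. = FALSE)
  }
  if (planned_rt_sd <= 0) stop("race_params: planned_rt_sd must be > 0", call. = FALSE)
  if (ssrt_true <= 0) stop("race_params: ssrt_true must be > 0", call. = FALSE)
  if (early_resp_rate < 0 || early_resp_rate > 1 ||
      omission_rate < 0 || omission_rate > 1) {
    stop("race_params: rates must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(planned_rt_mean = planned_rt_mean,
         planned_rt_sd = planned_rt_sd,
         ssrt_true = ssrt_true,
         proactive_delta_20 = proactive_delta_20,
         proactive_delta_40 = proactive_delta_40,
         early_resp_rate = early_resp_rate,
         omission_rate = omission_rate),
    class = "race_params"
  )
}

#' @export
print.race_params <- function(x, ...) {
  cat("Race-model subject parameters\n")
  cat(sprintf("  planned lift: Normal(%.1f, %.1f) ms; true SSRT: %.1f ms\n",
              x$planned_rt_mean, x$planned_rt_sd, x$ssrt_true))
  cat(sprintf("  proactive slowing: +%.1f ms (20%% SSP), +%.1f ms (40%% SSP)\n",
              x$proactive_delta_20, x$proactive_delta_40))
  cat(sprintf("  early-response rate %.3f, omission rate %.3f\n",
              x$early_resp_rate, x$omission_rate))
  invisible(x)
}

proactive_delta <- function(params, context) {
  switch(as.character(context),
         "0" = 0,
         "20" = params$proactive_delta_20,
         "40" = params$proactive_delta_40,
         stop("context must be one of 0, 20, 40", call. = FALSE))
}

#' One-up-one-down staircase state for the stop-signal delay
#'
#' The SSD staircase increases the delay by one step after a successful stop
#' and decreases it after a failed stop, so that the stop-success probability
#' converges to ~50%. The delay is clamped so the indicator always halts
#' before the 800-ms target crossing.
#'
#' @param current_ssd Current stop-signal delay, ms.
#' @param step Staircase step, ms (default 33).
#' @param lower_bound,upper_bound Clamp bounds for the SSD, ms.
#' @return An object of class `staircase_state`.
#' @export
staircase_state <- function(current_ssd = 550, step = 33,
                            lower_bound = 33, upper_bound = 767) {
  if (!all(is.finite(c(current_ssd, step, lower_bound, upper_bound)))) {
    stop("staircase_state: all fields must be finite", call. = FALSE)
  }
  if (step <= 0) stop("staircase_state: step must be > 0", call. = FALSE)
  if (lower_bound > upper_bound) {
    stop("staircase_state: lower_bound must not exceed upper_bound", call. = FALSE)
  }
  if (current_ssd < lower_bound || current_ssd > upper_bound) {
    stop("staircase_state: current_ssd must lie within the bounds", call. = FALSE)
  }
  structure(
    list(current_ssd = current_ssd, step = step,
         lower_bound = lower_bound, upper_bound = upper_bound),
    class = "staircase_state"
  )
}

#' Advance the SSD staircase after a stop trial
#'
#' @param state A [staircase_state()].
#' @param stop_success Logical; was the stop trial successful?
#' @return The updated `staircase_state`: SSD moves up one step after a
#'   success, down one step after a failure, clamped to the bounds.
#' @examples
#' s <- staircase_state(current_ssd = 550)
#' staircase_update(s, TRUE)$current_ssd  # 583
#' @export
staircase_update <- function(state, stop_success) {
  stopifnot(inherits(state, "staircase_state"), is.logical(stop_success),
            length(stop_success) == 1L, !is.na(stop_success))
  delta <- if (stop_success) state$step else -state$step
  state$current_ssd <- min(max(state$current_ssd + delta, state$lower_bound),
                           state$upper_bound)
  state
}

#' Simulate a single stop trial under the independent race model
#'
#' Draws a planned lift time T ~ Normal(mean + context delta, sd). The stop
#' succeeds iff T >= ssd + ssrt_true; on a failed stop the response escapes
#' and the observed RT is T (the failed-stop response time, RT_SF).
#'
#' @param params A [race_params()] object.
#' @param ssd Stop-signal delay, ms (>= 0).
#' @param context SSP condition of the block, 20 or 40.
#' @return A list with `stop_success` (logical) and `rt` (ms, `NA` when the
#'   stop succeeded).
#' @export
simulate_stop_trial <- function(params, ssd, context = 20) {
  stopifnot(inherits(params, "race_params"))
  if (!is.finite(ssd) || ssd < 0) stop("ssd must be finite and >= 0", call. = FALSE)
  if (!context %in% c(20, 40)) stop("context must be 20 or 40", call. = FALSE)
  t_go <- stats::rnorm(1L, params$planned_rt_mean + proactive_delta(params, context),
                       params$planned_rt_sd)
  success <- t_go >= ssd + params$ssrt_true
  list(stop_success = success, rt = if (success) NA_real_ else t_go)
}

#' Layout of one stop-signal session
#'
#' Default layout: a first block of 25 go trials at 0% SSP, then a second
#' block of 150 randomly interleaved trials - 80 go + 20 stop at 20% SSP and
#' 30 go + 20 stop at 40% SSP (175 trials per session; 350 over two sessions).
#'
#' @param n_go_0 Go trials in the 0% SSP block.
#' @param n_go_20,n_stop_20 Go and stop trials in the 20% SSP condition.
#' @param n_go_40,n_stop_40 Go and stop trials in the 40% SSP condition.
#' @return An object of class `session_design`.
#' @export
session_design <- function(n_go_0 = 25, n_go_20 = 80, n_stop_20 = 20,
                           n_go_40 = 30, n_stop_40 = 20) {
  counts <- c(n_go_0, n_go_20, n_stop_20, n_go_40, n_stop_40)
  if (!all(is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("session_design: counts must be non-negative integers", call. = FALSE)
  }
  if (n_go_0 <= 0) stop("session_design: the 0% SSP block needs at least one go trial",
                        call. = FALSE)
  structure(
    list(n_go_0 = n_go_0, n_go_20 = n_go_20, n_stop_20 = n_stop_20,
         n_go_40 = n_go_40, n_stop_40 = n_stop_40),
    class = "session_design"
  )
}

# Draw one go RT honoring the early-response / omission contamination rates.
# Early responses are anticipatory lifts uniform on [150, 400) ms; omissions
# are recorded as NA (no lift before the 1280-ms cutoff).
draw_go_rts <- function(params, n, context) {
  if (n == 0L) return(numeric(0))
  rt <- stats::rnorm(n, params$planned_rt_mean + proactive_delta(params, context),
                     params$planned_rt_sd)
  u <- stats::runif(n)
  early <- u < params$early_resp_rate
  omit <- !early & u < params$early_resp_rate + params$omission_rate
  rt[early] <- stats::runif(sum(early), 150, 400)
  rt[omit] <- NA_real_
  rt
}

#' Simulate one session of the anticipated-response stop-signal task
#'
#' Generates the 0% SSP go block followed by the interleaved 20%/40% block.
#' The SSD staircase is shared across the two stop conditions by default
#' (mirroring designs that report a single mean SSD) and is carried across
#' stop trials in presentation order; pass `per_condition_staircase = TRUE`
#' to track the two SSP conditions with separate staircases.
#'
#' @param params A [race_params()].
#' @param design A [session_design()].
#' @param staircase A [staircase_state()] giving the starting SSD, or a list
#'   of two states named `"20"` and `"40"` when `per_condition_staircase`.
#' @param per_condition_staircase Maintain separate staircases per SSP
#'   condition (default `FALSE`: one shared staircase).
#' @return A list with `trials` (a tibble with columns `ssp`, `trial_type`,
#'   `ssd_ms`, `rt_ms`, `stop_success`) and `staircase` (the final state(s),
#'   so it can be carried into the next session).
#' @export
simulate_session <- function(params,
                             design = session_design(),
                             staircase = staircase_state(),
                             per_condition_staircase = FALSE) {
  stopifnot(inherits(params, "race_params"), inherits(design, "session_design"))
  if (per_condition_staircase) {
    if (inherits(staircase, "staircase_state")) {
      staircase <- list(`20` = staircase, `40` = staircase)
    }
    stopifnot(all(c("20", "40") %in% names(staircase)))
  } else {
    stopifnot(inherits(staircase, "staircase_state"))
  }

  # block 1: pure go at 0% SSP; block 2: randomly interleaved 20% / 40%
  n1 <- design$n_go_0
  sched <- c(rep(20L, design$n_go_20), rep(-20L, design$n_stop_20),
             rep(40L, design$n_go_40), rep(-40L, design$n_stop_40))
  sched <- sample(sched)
  n2 <- length(sched)
  ssp <- c(rep(0L, n1), abs(sched))
  type <- c(rep("go", n1), ifelse(sched > 0L, "go", "stop"))
  ssd <- rep(NA_real_, n1 + n2)
  rt <- rep(NA_real_, n1 + n2)
  success <- rep(NA, n1 + n2)

  rt[seq_len(n1)] <- draw_go_rts(params, n1, 0)
  go20 <- which(type == "go" & ssp == 20L)
  go40 <- which(type == "go" & ssp == 40L)
  rt[go20] <- draw_go_rts(params, length(go20), 20)
  rt[go40] <- draw_go_rts(params, length(go40), 40)

  # stop trials run sequentially: each draws the current SSD and advances
  # its staircase one step by the one-up-one-down rule
  sd_go <- params$planned_rt_sd
  for (i in which(type == "stop")) {
    st <- if (per_condition_staircase) staircase[[as.character(ssp[i])]] else staircase
    ssd[i] <- st$current_ssd
    t_go <- stats::rnorm(1L, params$planned_rt_mean + proactive_delta(params, ssp[i]),
                         sd_go)
    success[i] <- t_go >= st$current_ssd + params$ssrt_true
    if (!success[i]) rt[i] <- t_go
    st <- staircase_update(st, success[i])
    if (per_condition_staircase) staircase[[as.character(ssp[i])]] <- st else staircase <- st
  }

  trials <- tibble::new_tibble(
    list(ssp = ssp, trial_type = type, ssd_ms = ssd, rt_ms = rt,
         stop_success = success),
    nrow = n1 + n2
  )
  list(trials = trials, staircase = staircase)
}

#' Simulate all sessions of one subject
#'
#' @param params A [race_params()].
#' @param subject_id Subject identifier.
#' @param group Group label (e.g. `"young"` or `"older"`).
#' @param n_sessions Number of behavioral assessment sessions (default 2).
#' @param design A [session_design()].
#' @param staircase Starting [staircase_state()].
#' @param reset_staircase If `TRUE` the staircase restarts from `staircase` at
#'   each session; default `FALSE` carries the adapted SSD across sessions.
#' @param per_condition_staircase See [simulate_session()].
#' @return A trial-table tibble with columns `subject_id`, `group`, `session`,
#'   `ssp`, `trial_type`, `ssd_ms`, `rt_ms`, `stop_success`.
#' @export
simulate_subject <- function(params, subject_id = "S01", group = "young",
                             n_sessions = 2, design = session_design(),
                             staircase = staircase_state(),
                             reset_staircase = FALSE,
                             per_condition_staircase = FALSE) {
  start <- staircase
  out <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    if (reset_staircase) staircase <- start
    ses <- simulate_session(params, design, staircase, per_condition_staircase)
    staircase <- ses$staircase
    tr <- ses$trials
    n <- nrow(tr)
    out[[s]] <- tibble::new_tibble(
      c(list(subject_id = rep(subject_id, n), group = rep(group, n),
             session = rep(s, n)), as.list(tr)),
      nrow = n
    )
  }
  dplyr::bind_rows(out)
}

#' Run the SSD staircase against a race-model subject and track convergence
#'
#' Simulates a long run of staircased stop trials for one subject and returns
#' the empirical stop-success fraction after burn-in. The one-up-one-down rule
#' converges to the 50% point of the inhibition function.
#'
#' @param params A [race_params()].
#' @param n_trials Number of stop trials to run.
#' @param burn_in Initial trials discarded before computing the success rate.
#' @param staircase Starting [staircase_state()].
#' @param context SSP condition used for the stop trials (20 or 40).
#' @return A list with `p_inhibit` (post-burn-in success fraction), `ssd`
#'   (vector of presented SSDs) and `success` (logical vector).
#' @export
staircase_run <- function(params, n_trials = 400, burn_in = 50,
                          staircase = staircase_state(), context = 20) {
  stopifnot(n_trials > burn_in)
  ssd <- numeric(n_trials)
  success <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    ssd[i] <- staircase$current_ssd
    out <- simulate_stop_trial(params, staircase$current_ssd, context)
    success[i] <- out$stop_success
    staircase <- staircase_update(staircase, out$stop_success)
  }
  keep <- (burn_in + 1L):n_trials
  list(p_inhibit = mean(success[keep]), ssd = ssd, success = success)
}
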