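#' Filter go trials on response-time validity
#'
#' Removes go trials with early responses (RT < 400 ms) or no response
#' (RT missing / beyond 1280 ms). The filter applies to go trials only;
#' failed-stop RTs are never filtered.
#'
#' @param trials A trial table containing go trials only (`trial_type == "go"`).
#' @param min_rt,max_rt Validity window in ms (defaults 400 and 1280).
#' @return The retained rows, original order preserved.
#' @export
filter_go_trials <- function(trials, min_rt = 400, max_rt = 1280) {
  if (nrow(trials) == 0L) return(trials)
  if (!all(trials$trial_type == "go")) {
    stop("filter_go_trials: input must contain go trials only", call. = FALSE)
  }
  keep <- !is.na(trials$rt_ms) & trials$rt_ms >= min_rt & trials$rt_ms <= max_rt
  trials[keep, , drop = FALSE]
}

#' Integration-method estimate of the stop-signal reaction time
#'
#' Rank-orders the go RTs and subtracts the mean SSD from the nth go RT,
#' where n = N x P(inhibit) (rounded half-up, clamped to `[1, N]`). Under the
#' independent race model this is a consistent estimator of the stop-process
#' latency.
#'
#' @param go_rts Valid (post-filter) go RTs in ms, from the stop-signal blocks.
#' @param mean_ssd Mean stop-signal delay over the stop trials, ms.
#' @param p_inhibit Proportion of stop trials successfully inhibited, strictly
#'   between 0 and 1.
#' @return SSRT estimate in ms.
#' @examples
#' estimate_ssrt_integration(c(700, 750, 800, 850), mean_ssd = 600, p_inhibit = 0.5)
#' @export
estimate_ssrt_integration <- function(go_rts, mean_ssd, p_inhibit) {
  go_rts <- go_rts[!is.na(go_rts)]
  n_go <- length(go_rts)
  if (n_go == 0L) stop("estimate_ssrt_integration: no go RTs supplied", call. = FALSE)
  if (!is.finite(p_inhibit) || p_inhibit <= 0 || p_inhibit >= 1) {
    stop("estimate_ssrt_integration: p_inhibit must lie strictly in (0, 1)",
         call. = FALSE)
  }
  if (!is.finite(mean_ssd)) stop("estimate_ssrt_integration: mean_ssd must be finite",
                                 call. = FALSE)
  # round half-up, then clamp to a valid 1-based rank
  n <- floor(n_go * p_inhibit + 0.5)
  n <- min(max(n, 1L), n_go)
  sort(go_rts)[n] - mean_ssd
}

# Measures for the trials of a single session (internal).
# SSRT pools the valid go RTs and all stop trials of the 20% and 40% blocks.
session_performance <- function(trials) {
  go <- trials[trials$trial_type == "go", , drop = FALSE]
  stopt <- trials[trials$trial_type == "stop", , drop = FALSE]

  mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
  go_valid <- filter_go_trials(go)
  go_rt <- mean_or_na(go_valid$rt_ms[go_valid$ssp == 0])
  go_rt_20 <- mean_or_na(go_valid$rt_ms[go_valid$ssp == 20])
  go_rt_40 <- mean_or_na(go_valid$rt_ms[go_valid$ssp == 40])

  n_stop <- nrow(stopt)
  if (n_stop > 0L) {
    mean_ssd <- mean(stopt$ssd_ms)
    p_inhibit <- mean(stopt$stop_success)
    # failed-stop RTs: no validity filter (stated only for go trials)
    rt_sf <- mean_or_na(stopt$rt_ms[!stopt$stop_success & !is.na(stopt$rt_ms)])
  } else {
    mean_ssd <- p_inhibit <- rt_sf <- NA_real_
  }

  pooled_go <- go_valid$rt_ms[go_valid$ssp %in% c(20, 40)]
  ssrt <- if (n_stop > 0L && length(pooled_go) > 0L &&
              is.finite(p_inhibit) && p_inhibit > 0 && p_inhibit < 1) {
    estimate_ssrt_integration(pooled_go, mean_ssd, p_inhibit)
  } else {
    if (n_stop > 0L) {
      warning("session has a degenerate P(inhibit) or no valid go RTs; SSRT set missing",
              call. = FALSE)
    }
    NA_real_
  }

  c(go_rt = go_rt, go_rt_20 = go_rt_20, go_rt_40 = go_rt_40,
    ssrt = ssrt, mean_ssd = mean_ssd, p_inhibit = p_inhibit, rt_sf = rt_sf,
    n_valid_go = nrow(go_valid), n_stop = n_stop)
}

#' Stop-signal performance measures for one subject
#'
#' Computes, per session, the mean go RT in the 0% SSP block (GoRT), the go
#' RTs in the 20% and 40% SSP conditions (GoRT_20, GoRT_40), the
#' integration-method SSRT pooled over the 20% + 40% blocks, the mean SSD,
#' P(inhibit) and the failed-stop RT (RT_SF); each measure is then averaged
#' across sessions. Proactive slowing (GoRT_40-20) is the difference of the
#' session-averaged GoRT_40 and GoRT_20 by default; with
#' `proactive_by_session = TRUE` it is differenced within each session and
#' the differences averaged (identical for balanced data).
#'
#' A session whose SSRT is undefined (no stop trials, or P(inhibit) of exactly
#' 0 or 1) is excluded from the SSRT average with a warning.
#'
#' @param trials Trial table for a single subject (one or more sessions).
#' @param proactive_by_session Difference GoRT_40 - GoRT_20 per session before
#'   averaging (default `FALSE`).
#' @return A one-row tibble with `go_rt`, `go_rt_20`, `go_rt_40`,
#'   `proactive_slowing`, `ssrt`, `mean_ssd`, `p_inhibit`, `rt_sf`,
#'   `n_valid_go`, `n_stop`.
#' @export
compute_subject_performance <- function(trials, proactive_by_session = FALSE) {
  if (nrow(trials) == 0L) stop("compute_subject_performance: empty trial table",
                               call. = FALSE)
  if (length(unique(trials$subject_id)) > 1L) {
    stop("compute_subject_performance: trials must come from a single subject",
         call. = FALSE)
  }
  df <- as.data.frame(trials)
  per_session <- do.call(rbind, lapply(split(df, df$session), session_performance))

  avg <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  m <- apply(per_session[, c("go_rt", "go_rt_20", "go_rt_40", "ssrt",
                             "mean_ssd", "p_inhibit", "rt_sf"), drop = FALSE],
             2, avg)
  proactive <- if (proactive_by_session) {
    avg(per_session[, "go_rt_40"] - per_session[, "go_rt_20"])
  } else {
    m[["go_rt_40"]] - m[["go_rt_20"]]
  }
  tibble::new_tibble(
    list(go_rt = m[["go_rt"]], go_rt_20 = m[["go_rt_20"]],
         go_rt_40 = m[["go_rt_40"]], proactive_slowing = proactive,
         ssrt = m[["ssrt"]], mean_ssd = m[["mean_ssd"]],
         p_inhibit = m[["p_inhibit"]], rt_sf = m[["rt_sf"]],
         n_valid_go = sum(per_session[, "n_valid_go"]),
         n_stop = sum(per_session[, "n_stop"])),
    nrow = 1L
  )
}

#' Per-subject performance table for a whole cohort
#'
#' Applies [compute_subject_performance()] to every subject in a trial table.
#'
#' @param trials Trial table (multiple subjects).
#' @param proactive_by_session See [compute_subject_performance()].
#' @return A tibble with one row per subject: `subject_id`, `group`, and the
#'   performance measures.
#' @export
compute_performance_table <- function(trials, proactive_by_session = FALSE) {
  pieces <- split(as.data.frame(trials), trials$subject_id)
  rows <- lapply(pieces, function(tr) {
    perf <- compute_subject_performance(tr, proactive_by_session)
    tibble::new_tibble(
      c(list(subject_id = tr$subject_id[1L], group = tr$group[1L]),
        as.list(perf)),
      nrow = 1L
    )
  })
  dplyr::bind_rows(rows)
}

#' Group means and SDs of the performance measures
#'
#' Summarises a performance table into per-group means and sample standard
#' deviations (n - 1 denominator) for each measure, the layout used to report
#' primary (GoRT, GoRT_40-20, SSRT) and secondary (RT_SF, SSD, P(inhibit))
#' stop-signal measures.
#'
#' @param perf Performance table from [compute_performance_table()].
#' @param measures Character vector of measure columns to summarise.
#' @return A tibble with columns `measure`, `group`, `n`, `mean`, `sd`.
#' @export
summarize_group <- function(perf,
                            measures = c("go_rt", "proactive_slowing", "ssrt",
                                         "rt_sf", "mean_ssd", "p_inhibit")) {
  stopifnot(all(measures %in% names(perf)), "group" %in% names(perf))
  counts <- table(perf$group)
  if (any(counts < 2L)) {
    stop("summarize_group: every group needs at least 2 subjects", call. = FALSE)
  }
  long <- tidyr::pivot_longer(perf[, c("group", measures)],
                              cols = dplyr::all_of(measures),
                              names_to = "measure", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$measure, .data$group),
    n = sum(!is.na(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
  out$measure <- factor(out$measure, levels = measures)
  dplyr::arrange(out, .data$measure, .data$group)
}
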