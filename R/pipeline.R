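#' Group comparisons of corrected metabolite levels with FDR control
#'
#' Runs a pooled (or Welch) t-test per region x metabolite (and ratio) cell
#' comparing the two groups on corrected concentrations, then applies
#' Benjamini-Hochberg FDR control across the whole family of comparisons and
#' reports the family's critical p-value.
#'
#' @param panel Corrected panel (after [correct_panel()], optionally
#'   [panel_with_ratio()]).
#' @param q FDR level.
#' @param var_equal Pooled variance (default) or Welch.
#' @param group_levels Which group is "group 1" in the contrast (default
#'   `c("young", "older")`).
#' @return A list with `tests` (tibble: `region`, `metabolite`, means/SDs/ns
#'   per group, `t`, `df`, `p`, `p_adjusted`, `significant`) and `critical_p`.
#' @export
metabolite_group_tests <- function(panel, q = 0.05, var_equal = TRUE,
                                   group_levels = c("young", "older")) {
  stopifnot("corrected_concentration" %in% names(panel))
  cells <- dplyr::distinct(panel[, c("region", "metabolite")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- panel[panel$region == cells$region[i] &
                   panel$metabolite == cells$metabolite[i], , drop = FALSE]
    x <- sub$corrected_concentration[sub$group == group_levels[1L]]
    y <- sub$corrected_concentration[sub$group == group_levels[2L]]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) return(NULL)
    tt <- pooled_t_from_raw(x, y, var_equal = var_equal)
    dplyr::mutate(tt, region = cells$region[i], metabolite = cells$metabolite[i],
                  .before = 1L)
  })
  tests <- dplyr::bind_rows(rows)
  fdr <- bh_fdr(tests$p, q = q)
  tests$p_adjusted <- fdr$p_adjusted
  tests$significant <- fdr$reject
  list(tests = tests, critical_p = fdr$critical_p)
}

# wide subject x predictor matrix of corrected concentrations for one group
predictor_matrix <- function(panel, group) {
  sub <- panel[panel$group == group, , drop = FALSE]
  sub$predictor <- paste(sub$region, gsub("/", "_", sub$metabolite, fixed = TRUE),
                         sep = ".")
  tidyr::pivot_wider(sub[, c("subject_id", "predictor", "corrected_concentration")],
                     names_from = "predictor",
                     values_from = "corrected_concentration")
}

#' Screen-then-regress: regression models per group and behavioral measure
#'
#' For each group and behavioral measure, takes the screen candidates
#' (uncorrected p < alpha from [pearson_screen()]), fits the full OLS model
#' on listwise-complete rows, and - when `two_step` - refits after dropping
#' predictors whose R-squared change falls below `drop_below` (near-null
#' contributors), reporting both models. When more candidates survive the
#' screen than the sample can support, the candidates with the largest |r|
#' are kept up to `n - 3` predictors.
#'
#' @param screen Output of [pearson_screen()].
#' @param panel Corrected panel (with ratios if screened).
#' @param performance Performance table.
#' @param drop_below R-squared-change threshold for the second step.
#' @param two_step Perform the documented drop-and-refit (default `TRUE`).
#' @return A tibble with one row per fitted model: `group`, `measure`,
#'   `step` (`"full"` or `"reduced"`), `n`, `r2`, `r2_adjusted`, `f`, `p`,
#'   and a list-column `fit` holding the `regression_summary`.
#' @export
regress_candidates <- function(screen, panel, performance,
                               drop_below = 0.01, two_step = TRUE) {
  combos <- dplyr::distinct(screen[screen$candidate, c("group", "measure")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    g <- combos$group[i]
    m <- combos$measure[i]
    cand <- screen[screen$candidate & screen$group == g & screen$measure == m, ,
                   drop = FALSE]
    cand$predictor <- paste(cand$region,
                            gsub("/", "_", cand$metabolite, fixed = TRUE),
                            sep = ".")
    wide <- predictor_matrix(panel, g)
    dat <- dplyr::inner_join(performance[performance$group == g,
                                         c("subject_id", m)],
                             wide, by = "subject_id")
    n_complete <- sum(stats::complete.cases(dat[, c(m, cand$predictor)]))
    keep <- cand$predictor
    if (length(keep) > n_complete - 3L) {
      keep <- cand$predictor[order(-abs(cand$r))][seq_len(max(1L, n_complete - 3L))]
    }
    fit_full <- fit_regression(dat, m, keep)
    out[[length(out) + 1L]] <- tibble::tibble(
      group = g, measure = m, step = "full", n = fit_full$n,
      r2 = fit_full$r2, r2_adjusted = fit_full$r2_adjusted,
      f = fit_full$f, p = fit_full$p_model, fit = list(fit_full)
    )
    if (two_step) {
      ct <- fit_full$coefficients
      strong <- ct$term[-1L][ct$r2_change[-1L] >= drop_below]
      if (length(strong) > 0L && length(strong) < length(keep)) {
        fit_red <- fit_regression(dat, m, strong)
        out[[length(out) + 1L]] <- tibble::tibble(
          group = g, measure = m, step = "reduced", n = fit_red$n,
          r2 = fit_red$r2, r2_adjusted = fit_red$r2_adjusted,
          f = fit_red$f, p = fit_red$p_model, fit = list(fit_red)
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

# flatten the regression list-column into a per-coefficient table for export
regression_table <- function(models) {
  if (nrow(models) == 0L) {
    return(tibble::tibble(group = character(), measure = character(),
                          step = character(), term = character()))
  }
  dplyr::bind_rows(lapply(seq_len(nrow(models)), function(i) {
    fit <- models$fit[[i]]
    dplyr::mutate(fit$coefficients,
                  group = models$group[i], measure = models$measure[i],
                  step = models$step[i], n = fit$n, r2 = fit$r2,
                  r2_adjusted = fit$r2_adjusted, f = fit$f, .before = 1L)
  }))
}

#' Run the full simulate-measure-correct-test pipeline
#'
#' Orchestrates the stages end to end: simulate a cohort (or load supplied
#' trial/panel tables), validate the inputs, compute behavioral performance
#' and the group summary, apply QC and tissue correction with the NAA/mIns
#' ratio appended, run the metabolite group comparisons with FDR control, the
#' per-group correlation screen and the screen-then-regress models, and write
#' every table plus a run manifest to `out_dir`. All randomness flows from
#' `config$seed` through named per-stage substreams.
#'
#' @param config Configuration list from [default_config()] / [load_config()].
#' @param out_dir Output directory (created if needed); `NULL` returns the
#'   results without writing.
#' @param trials,panel Optional user-supplied tables; when `NULL` (default)
#'   a cohort is simulated from the config.
#' @return Invisibly, a list with all stage outputs (`trials`, `panel`,
#'   `performance`, `group_summary`, `behavior_tests`, `corrected_panel`,
#'   `metabolite_tests`, `screen`, `models`, `validation`, `manifest`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         trials = NULL, panel = NULL) {
  validate_config(config)
  set.seed(as.integer(config$seed))
  # named per-stage substreams off the master seed
  stage_seeds <- stats::setNames(sample.int(.Machine$integer.max, 2L),
                                 c("cohort", "reserved"))

  simulated <- is.null(trials) && is.null(panel)
  if (simulated) {
    sim <- simulate_cohort(config_cohort_spec(config),
                           seed = stage_seeds[["cohort"]],
                           constants = config_constants(config),
                           design = config_design(config),
                           reset_staircase = config$staircase$reset_between_sessions)
    trials <- sim$trials
    panel <- sim$panel
  } else if (is.null(trials) || is.null(panel)) {
    stop("run_pipeline: supply both trials and panel, or neither", call. = FALSE)
  }

  validation <- validate_inputs(trials, panel)
  if (nrow(validation) > 0L) {
    stop(sprintf("run_pipeline: input validation failed with %d violation(s); first: %s (%s row %d)",
                 nrow(validation), validation$message[1L], validation$table[1L],
                 validation$row[1L]), call. = FALSE)
  }

  performance <- compute_performance_table(
    trials, proactive_by_session = config$behavior$proactive_by_session)
  group_summary <- summarize_group(performance)

  behavior_tests <- dplyr::bind_rows(lapply(
    c("go_rt", "proactive_slowing", "ssrt", "rt_sf", "mean_ssd", "p_inhibit"),
    function(m) {
      tt <- pooled_t_from_raw(performance[[m]][performance$group == "young"],
                              performance[[m]][performance$group == "older"],
                              var_equal = config$stats$var_equal)
      dplyr::mutate(tt, measure = m, .before = 1L)
    }))

  corrected <- correct_panel(panel, config_constants(config),
                             metabolite_attenuation = config$mrs$metabolite_attenuation,
                             snr_min = config$mrs$snr_min,
                             linewidth_max = config$mrs$linewidth_max)
  corrected <- panel_with_ratio(corrected)

  metabolite_tests <- metabolite_group_tests(corrected, q = config$stats$fdr_q,
                                             var_equal = config$stats$var_equal)
  screen <- pearson_screen(corrected, performance,
                           alpha = config$stats$screen_alpha)
  models <- regress_candidates(screen, corrected, performance,
                               drop_below = config$stats$r2_change_drop)

  n_go <- sum(trials$trial_type == "go")
  go_only <- trials[trials$trial_type == "go", , drop = FALSE]
  n_go_removed <- n_go - nrow(filter_go_trials(go_only, config$behavior$min_rt,
                                               config$behavior$max_rt))
  manifest <- list(
    package_version = as.character(utils::packageVersion("inhibmet")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    simulated_inputs = simulated,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    counts = list(
      n_subjects = length(unique(trials$subject_id)),
      n_trials = nrow(trials),
      n_go_trials = n_go,
      n_go_removed_by_filter = n_go_removed,
      n_stop_trials = sum(trials$trial_type == "stop"),
      n_spectra = nrow(panel),
      n_qc_excluded = sum(!corrected$qc_pass[!grepl("/", corrected$metabolite)]),
      n_screen_tests = nrow(screen),
      n_screen_candidates = sum(screen$candidate, na.rm = TRUE),
      n_regression_models = nrow(models)
    ),
    fdr_critical_p = metabolite_tests$critical_p
  )

  result <- list(trials = trials, panel = panel, performance = performance,
                 group_summary = group_summary, behavior_tests = behavior_tests,
                 corrected_panel = corrected, metabolite_tests = metabolite_tests,
                 screen = screen, models = models, validation = validation,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) {
      utils::write.table(x, file.path(out_dir, f), sep = "\t", na = "",
                         quote = FALSE, row.names = FALSE)
    }
    write_trial_table(trials, file.path(out_dir, "trials.tsv"))
    write_metabolite_panel(panel, file.path(out_dir, "panel.tsv"))
    wt(performance, "performance.tsv")
    wt(group_summary, "group_summary.tsv")
    wt(behavior_tests, "behavior_tests.tsv")
    wt(corrected[, setdiff(names(corrected), "level_raw")], "corrected_panel.tsv")
    wt(metabolite_tests$tests, "metabolite_tests.tsv")
    wt(screen, "correlation_screen.tsv")
    wt(regression_table(models), "regressions.tsv")
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  invisible(result)
}
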