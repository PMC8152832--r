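#' Default run configuration
#'
#' A nested list with every knob of the pipeline, shipped with the task and
#' correction constants as defaults so a bare `run_pipeline()` on simulator
#' output reproduces the standard procedural choices: 33-ms staircase from
#' 550 ms, go-RT validity window 400-1280 ms, QC at linewidth < 10 Hz and
#' SNR > 5, the 3 T water relaxation constants with TR 2 s / TE 68 ms,
#' FDR at q = 0.05 and correlation screening at alpha = 0.05.
#'
#' @return A named list (see the sections `cohort`, `design`, `staircase`,
#'   `behavior`, `mrs`, `stats`).
#' @export
default_config <- function() {
  list(
    seed = 20260101L,
    cohort = list(
      n_young = 25L, n_older = 26L,
      young = list(planned_rt_mean = 815, planned_rt_sd = 50, ssrt_true = 193,
                   proactive_delta_20 = 10, proactive_delta_40 = 20,
                   early_resp_rate = 0.01, omission_rate = 0.01),
      older = list(planned_rt_mean = 821, planned_rt_sd = 50, ssrt_true = 206,
                   proactive_delta_20 = 10, proactive_delta_40 = 23,
                   early_resp_rate = 0.01, omission_rate = 0.01),
      between_sd_rt_mean = list(young = 9, older = 20),
      between_sd_ssrt = list(young = 12, older = 17),
      qc_fail_rate = 0.04
    ),
    design = list(n_go_0 = 25L, n_go_20 = 80L, n_stop_20 = 20L,
                  n_go_40 = 30L, n_stop_40 = 20L),
    staircase = list(start_ssd = 550, step = 33, lower_bound = 33,
                     upper_bound = 767, reset_between_sessions = FALSE),
    behavior = list(min_rt = 400, max_rt = 1280, proactive_by_session = FALSE),
    mrs = list(
      t1_gm = 1331, t1_wm = 832, t1_csf = 3817,
      t2_gm = 110, t2_wm = 79, t2_csf = 503,
      tr = 2000, te = 68,
      water_content_gm = 0.78, water_content_wm = 0.65, water_content_csf = 0.97,
      pure_water_concentration = 55510,
      metabolite_attenuation = 1,
      snr_min = 5, linewidth_max = 10
    ),
    stats = list(fdr_q = 0.05, screen_alpha = 0.05, var_equal = TRUE,
                 r2_change_drop = 0.01)
  )
}

# recursive list merge: user values override defaults
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load a YAML run configuration
#'
#' Reads a YAML file and merges it over [default_config()], so a config file
#' only needs to state what it changes. Basic schema checks produce
#' actionable messages.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return A validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    known <- names(cfg)
    unknown <- setdiff(names(user), known)
    if (length(unknown) > 0L) {
      stop("unknown config section(s): ", paste(unknown, collapse = ", "),
           "; expected ", paste(known, collapse = ", "), call. = FALSE)
    }
    cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  fail <- function(...) stop("config: ", sprintf(...), call. = FALSE)
  if (!is.numeric(cfg$seed)) fail("seed must be an integer")
  if (cfg$staircase$step <= 0) fail("staircase$step must be > 0")
  if (cfg$mrs$snr_min <= 0 || cfg$mrs$linewidth_max <= 0) {
    fail("QC thresholds must be positive")
  }
  if (cfg$mrs$te >= cfg$mrs$tr) fail("mrs$te must be smaller than mrs$tr")
  if (cfg$behavior$min_rt >= cfg$behavior$max_rt) {
    fail("behavior$min_rt must be below behavior$max_rt")
  }
  if (cfg$stats$fdr_q <= 0 || cfg$stats$fdr_q >= 1) fail("stats$fdr_q must be in (0,1)")
  if (cfg$stats$screen_alpha <= 0 || cfg$stats$screen_alpha >= 1) {
    fail("stats$screen_alpha must be in (0,1)")
  }
  invisible(cfg)
}

# Constructors from a config list (internal glue)
config_race_params <- function(x) {
  race_params(planned_rt_mean = x$planned_rt_mean, planned_rt_sd = x$planned_rt_sd,
              ssrt_true = x$ssrt_true,
              proactive_delta_20 = x$proactive_delta_20,
              proactive_delta_40 = x$proactive_delta_40,
              early_resp_rate = x$early_resp_rate, omission_rate = x$omission_rate)
}

config_cohort_spec <- function(cfg) {
  co <- cfg$cohort
  cohort_spec(
    n_young = co$n_young, n_older = co$n_older,
    young = config_race_params(co$young), older = config_race_params(co$older),
    between_sd_rt_mean = c(young = co$between_sd_rt_mean$young,
                           older = co$between_sd_rt_mean$older),
    between_sd_ssrt = c(young = co$between_sd_ssrt$young,
                        older = co$between_sd_ssrt$older),
    qc_fail_rate = co$qc_fail_rate
  )
}

config_design <- function(cfg) {
  d <- cfg$design
  session_design(d$n_go_0, d$n_go_20, d$n_stop_20, d$n_go_40, d$n_stop_40)
}

config_constants <- function(cfg) {
  m <- cfg$mrs
  relaxation_constants(m$t1_gm, m$t1_wm, m$t1_csf, m$t2_gm, m$t2_wm, m$t2_csf,
                       m$tr, m$te, m$water_content_gm, m$water_content_wm,
                       m$water_content_csf, m$pure_water_concentration)
}
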