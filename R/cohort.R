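#' @keywords internal
mrs_regions <- function() c("LSM1", "RSM1", "preSMA", "RIFG", "LSTR", "RSTR", "OCC")

#' @keywords internal
mrs_metabolites <- function() c("NAA", "Glx", "Cr", "Cho", "mIns")

#' Reference concentrations for the metabolite generator
#'
#' Mean and SD (mM-equivalent institutional units) used to draw region-wise
#' metabolite levels in the synthetic cohort; values are in the range typical
#' of water-referenced 3 T quantification in cortical/striatal voxels.
#'
#' @return A tibble `metabolite`, `mean`, `sd`.
#' @export
default_metabolite_reference <- function() {
  tibble::tibble(
    metabolite = c("NAA", "Glx", "Cr", "Cho", "mIns"),
    mean = c(12.0, 10.0, 8.0, 2.0, 6.0),
    sd = c(1.0, 1.2, 0.8, 0.25, 0.7)
  )
}

#' Age-group shifts of the metabolite means
#'
#' Additive shifts (in within-group SD units) applied to the older group's
#' metabolite levels in every region, emulating the canonical aging pattern:
#' reduced NAA, elevated mIns and Cho, stable Glx and total Cr.
#'
#' @return A tibble `metabolite`, `shift_older_sd`.
#' @export
default_group_shifts <- function() {
  tibble::tibble(
    metabolite = c("NAA", "Glx", "Cr", "Cho", "mIns"),
    shift_older_sd = c(-0.6, 0, 0, 0.6, 0.7)
  )
}

#' Planted metabolite-behavior effects emulating an aging-cohort pattern
#'
#' The default effect set plants, within the young group, striatal Glx
#' correlations with GoRT of opposite sign in the left and right striatum and
#' a negative preSMA NAA/mIns association with SSRT; within the older group,
#' positive OCC mIns and RSM1 NAA associations with SSRT and a positive LSM1
#' NAA association with GoRT.
#'
#' @return A tibble `group`, `region`, `metabolite`, `measure`, `r`.
#' @export
default_metabolite_effects <- function() {
  tibble::tribble(
    ~group,  ~region,  ~metabolite, ~measure, ~r,
    "young", "LSTR",   "Glx",       "go_rt",  -0.572,
    "young", "RSTR",   "Glx",       "go_rt",   0.521,
    "young", "preSMA", "NAA/mIns",  "ssrt",   -0.474,
    "older", "OCC",    "mIns",      "ssrt",    0.584,
    "older", "RSM1",   "NAA",       "ssrt",    0.457,
    "older", "LSM1",   "NAA",       "go_rt",   0.510
  )
}

#' Specification of a synthetic two-group cohort
#'
#' Bundles everything [simulate_cohort()] needs: group sizes, per-group
#' race-model parameters, between-subject variability, the planted
#' metabolite-behavior effects, metabolite reference levels, and QC noise.
#' Defaults emulate a young/older aging cohort (n = 25/26): older adults have
#' a ~13 ms longer true SSRT and slightly later planned lifts.
#'
#' @param n_young,n_older Group sizes (each >= 4).
#' @param young,older [race_params()] for the group-level (mean) subject.
#' @param between_sd_rt_mean,between_sd_ssrt Between-subject SDs (ms) of the
#'   planned-lift mean and the true SSRT; either a single value or a named
#'   vector `c(young=, older=)`.
#' @param metabolite_effects Tibble `group`, `region`, `metabolite`,
#'   `measure`, `r` of planted sample correlations (|r| < 1). The metabolite
#'   may be a ratio (`"NAA/mIns"`), planted on the ratio with the numerator
#'   reconstructed from the denominator. At most one effect per
#'   group x region x metabolite cell.
#' @param metabolite_reference Tibble as [default_metabolite_reference()].
#' @param group_shifts Tibble as [default_group_shifts()]: additive older-group
#'   mean shifts per metabolite in SD units (`NULL` for none).
#' @param qc_fail_rate Fraction of spectra forced to violate a QC rule.
#' @param ratio_mean,ratio_sd Mean and SD of planted concentration ratios.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_young = 25, n_older = 26,
                        young = race_params(planned_rt_mean = 815,
                                            proactive_delta_20 = 10,
                                            proactive_delta_40 = 20,
                                            ssrt_true = 193),
                        older = race_params(planned_rt_mean = 821,
                                            proactive_delta_20 = 10,
                                            proactive_delta_40 = 23,
                                            ssrt_true = 206),
                        between_sd_rt_mean = c(young = 9, older = 20),
                        between_sd_ssrt = c(young = 12, older = 17),
                        metabolite_effects = default_metabolite_effects(),
                        metabolite_reference = default_metabolite_reference(),
                        group_shifts = default_group_shifts(),
                        qc_fail_rate = 0.04,
                        ratio_mean = 2.0, ratio_sd = 0.25) {
  if (n_young < 4 || n_older < 4) {
    stop("cohort_spec: each group needs n >= 4", call. = FALSE)
  }
  stopifnot(inherits(young, "race_params"), inherits(older, "race_params"))
  expand2 <- function(x) {
    if (length(x) == 1L) c(young = unname(x), older = unname(x))
    else c(young = unname(x[["young"]]), older = unname(x[["older"]]))
  }
  eff <- if (is.null(metabolite_effects)) {
    tibble::tibble(group = character(), region = character(),
                   metabolite = character(), measure = character(), r = numeric())
  } else {
    tibble::as_tibble(metabolite_effects)
  }
  if (nrow(eff) > 0L) {
    need <- c("group", "region", "metabolite", "measure", "r")
    if (!all(need %in% names(eff))) {
      stop("metabolite_effects needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (any(abs(eff$r) >= 1)) {
      stop("cohort_spec: planted |r| must be < 1", call. = FALSE)
    }
    key <- paste(eff$group, eff$region, eff$metabolite)
    if (anyDuplicated(key)) {
      stop("cohort_spec: at most one effect per group x region x metabolite cell",
           call. = FALSE)
    }
    # a ratio plant overwrites its numerator; forbid a competing direct plant
    ratio_rows <- grepl("/", eff$metabolite, fixed = TRUE)
    for (i in which(ratio_rows)) {
      parts <- strsplit(eff$metabolite[i], "/", fixed = TRUE)[[1L]]
      clash <- eff$group == eff$group[i] & eff$region == eff$region[i] &
        eff$metabolite %in% parts
      if (any(clash)) {
        stop("cohort_spec: ratio effect conflicts with a direct effect on its components",
             call. = FALSE)
      }
    }
  }
  structure(
    list(n_young = n_young, n_older = n_older,
         params = list(young = young, older = older),
         between_sd_rt_mean = expand2(between_sd_rt_mean),
         between_sd_ssrt = expand2(between_sd_ssrt),
         metabolite_effects = eff,
         metabolite_reference = tibble::as_tibble(metabolite_reference),
         group_shifts = if (is.null(group_shifts)) NULL
                        else tibble::as_tibble(group_shifts),
         qc_fail_rate = qc_fail_rate,
         ratio_mean = ratio_mean, ratio_sd = ratio_sd),
    class = "cohort_spec"
  )
}

# Draw a vector with EXACT sample correlation r against `behavior`:
# standardize the behavior, residualize fresh noise against it, standardize
# the residual, and mix with weights (r, sqrt(1 - r^2)).
plant_correlated <- function(behavior, r, mean, sd) {
  n <- length(behavior)
  zb <- as.numeric(scale(behavior))
  e <- stats::rnorm(n)
  e <- e - zb * sum(e * zb) / sum(zb * zb)
  ze <- as.numeric(scale(e))
  mean + sd * (r * zb + sqrt(1 - r^2) * ze)
}

# Dirichlet-ish voxel fractions around (gm, wm, csf) = (0.50, 0.40, 0.10)
draw_fractions <- function(n, conc = 300) {
  a <- c(0.50, 0.40, 0.10) * conc
  g <- cbind(stats::rgamma(n, a[1]), stats::rgamma(n, a[2]), stats::rgamma(n, a[3]))
  g / rowSums(g)
}

#' Simulate a two-group stop-signal + MRS cohort
#'
#' Generates, per subject, two sessions of anticipated-response stop-signal
#' trials (subject-level race parameters drawn around the group parameters),
#' computes the behavioral performance table, and draws a region x metabolite
#' panel in which each planted effect has its SAMPLE correlation with the
#' subject's measured behavioral statistic equal to the target r (computed
#' within the planted group). Metabolite levels are stored as water-referenced
#' signal ratios obtained by inverting the tissue correction at each voxel's
#' simulated fractions, so that [correct_panel()] with the shipped constants
#' returns the planted concentrations.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; all randomness in the cohort flows from it.
#' @param constants [relaxation_constants()] used to invert the correction.
#' @param design,reset_staircase Passed to [simulate_subject()].
#' @return A list with `trials` (trial table), `panel` (metabolite panel with
#'   columns `subject_id`, `group`, `region`, `metabolite`, `level`, `snr`,
#'   `linewidth_hz`, `f_gm`, `f_wm`, `f_csf`), `performance` (the behavioral
#'   table used for planting) and `truth` (per-subject true parameters).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L,
                            constants = relaxation_constants(),
                            design = session_design(),
                            reset_staircase = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  groups <- c(rep("young", spec$n_young), rep("older", spec$n_older))
  ids <- sprintf("S%03d", seq_along(groups))

  # subject-level race parameters around the group means
  truth <- tibble::tibble(subject_id = ids, group = groups)
  truth$planned_rt_mean <- vapply(seq_along(ids), function(i) {
    g <- groups[i]
    spec$params[[g]]$planned_rt_mean + stats::rnorm(1, 0, spec$between_sd_rt_mean[[g]])
  }, numeric(1))
  truth$ssrt_true <- vapply(seq_along(ids), function(i) {
    g <- groups[i]
    max(80, spec$params[[g]]$ssrt_true + stats::rnorm(1, 0, spec$between_sd_ssrt[[g]]))
  }, numeric(1))

  trials <- dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    g <- groups[i]
    base <- spec$params[[g]]
    p <- race_params(planned_rt_mean = truth$planned_rt_mean[i],
                     planned_rt_sd = base$planned_rt_sd,
                     ssrt_true = truth$ssrt_true[i],
                     proactive_delta_20 = base$proactive_delta_20,
                     proactive_delta_40 = base$proactive_delta_40,
                     early_resp_rate = base$early_resp_rate,
                     omission_rate = base$omission_rate)
    simulate_subject(p, subject_id = ids[i], group = g, design = design,
                     reset_staircase = reset_staircase)
  }))

  performance <- compute_performance_table(trials)
  performance <- performance[match(ids, performance$subject_id), , drop = FALSE]

  # concentrations: planted cells get an exact-sample-r draw against the
  # measured behavior within their group; everything else is independent noise
  ref <- spec$metabolite_reference
  eff <- spec$metabolite_effects
  n_sub <- length(ids)
  shifts <- spec$group_shifts
  conc_of <- function(region, metab) {
    m <- ref[ref$metabolite == metab, , drop = FALSE]
    conc <- stats::rnorm(n_sub, m$mean, m$sd)
    for (g in c("young", "older")) {
      hit <- which(eff$group == g & eff$region == region & eff$metabolite == metab)
      if (length(hit) == 1L) {
        rows <- which(groups == g)
        behavior <- performance[[eff$measure[hit]]][rows]
        conc[rows] <- plant_correlated(behavior, eff$r[hit], m$mean, m$sd)
      }
    }
    # aging shift: a within-group constant, so planted correlations survive
    if (!is.null(shifts) && metab %in% shifts$metabolite) {
      delta <- shifts$shift_older_sd[shifts$metabolite == metab] * m$sd
      conc[groups == "older"] <- conc[groups == "older"] + delta
    }
    conc
  }

  grid <- expand.grid(region = mrs_regions(), metabolite = mrs_metabolites(),
                      stringsAsFactors = FALSE)
  panel <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(k) {
    tibble::tibble(subject_id = ids, group = groups,
                   region = grid$region[k], metabolite = grid$metabolite[k],
                   conc = conc_of(grid$region[k], grid$metabolite[k]))
  }))

  # ratio plants: draw the target ratio with exact sample r, then rebuild the
  # numerator from the (independently drawn) denominator
  if (nrow(eff) > 0L) {
    for (i in which(grepl("/", eff$metabolite, fixed = TRUE))) {
      parts <- strsplit(eff$metabolite[i], "/", fixed = TRUE)[[1L]]
      rows <- which(groups == eff$group[i])
      behavior <- performance[[eff$measure[i]]][rows]
      ratio <- plant_correlated(behavior, eff$r[i], spec$ratio_mean, spec$ratio_sd)
      den_idx <- panel$region == eff$region[i] & panel$metabolite == parts[2L] &
        panel$group == eff$group[i]
      num_idx <- panel$region == eff$region[i] & panel$metabolite == parts[1L] &
        panel$group == eff$group[i]
      panel$conc[num_idx] <- ratio * panel$conc[den_idx]
    }
  }

  # voxel composition and QC fields; a configurable fraction of spectra is
  # forced to violate one QC rule
  frac <- draw_fractions(nrow(panel))
  panel$f_gm <- round(frac[, 1], 4)
  panel$f_wm <- round(frac[, 2], 4)
  panel$f_csf <- round(1 - panel$f_gm - panel$f_wm, 4)
  panel$snr <- pmax(stats::rnorm(nrow(panel), 15, 3), 6)
  panel$linewidth_hz <- pmin(pmax(stats::rnorm(nrow(panel), 7, 1), 3), 9.5)
  fail <- stats::runif(nrow(panel)) < spec$qc_fail_rate
  which_rule <- stats::runif(nrow(panel)) < 0.5
  panel$snr[fail & which_rule] <- stats::runif(sum(fail & which_rule), 2, 5)
  panel$linewidth_hz[fail & !which_rule] <- stats::runif(sum(fail & !which_rule), 10, 14)

  # store as water-referenced signal ratios: invert the tissue correction
  panel$level <- panel$conc /
    water_scaling(panel$f_gm / (panel$f_gm + panel$f_wm + panel$f_csf),
                  panel$f_wm / (panel$f_gm + panel$f_wm + panel$f_csf),
                  panel$f_csf / (panel$f_gm + panel$f_wm + panel$f_csf),
                  constants)
  panel$conc <- NULL
  panel <- panel[, c("subject_id", "group", "region", "metabolite", "level",
                     "snr", "linewidth_hz", "f_gm", "f_wm", "f_csf")]

  list(trials = trials, panel = panel, performance = performance, truth = truth)
}
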