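#' Water relaxation and sequence constants for tissue correction
#'
#' Bundles the compartment water T1/T2 relaxation times, sequence timing and
#' water-content parameters entering the partial-volume correction of
#' water-referenced metabolite signals. Shipped defaults are the constants
#' commonly used at 3 T for a PRESS-localized water reference (TE 68 ms,
#' TR 2 s): T1 of 1331/832/3817 ms and T2 of 110/79/503 ms for GM/WM/CSF,
#' relative water contents 0.78/0.65/0.97 and pure-water concentration
#' 55510 mM.
#'
#' @param t1_gm,t1_wm,t1_csf Compartment water T1, ms.
#' @param t2_gm,t2_wm,t2_csf Compartment water T2, ms.
#' @param tr,te Repetition and echo time of the water acquisition, ms.
#' @param water_content_gm,water_content_wm,water_content_csf Relative molar
#'   water density of each compartment (pure water = 1).
#' @param pure_water_concentration Molar concentration of pure water, mM.
#' @return An object of class `relaxation_constants`.
#' @export
relaxation_constants <- function(t1_gm = 1331, t1_wm = 832, t1_csf = 3817,
                                 t2_gm = 110, t2_wm = 79, t2_csf = 503,
                                 tr = 2000, te = 68,
                                 water_content_gm = 0.78,
                                 water_content_wm = 0.65,
                                 water_content_csf = 0.97,
                                 pure_water_concentration = 55510) {
  vals <- c(t1_gm, t1_wm, t1_csf, t2_gm, t2_wm, t2_csf, tr, te,
            water_content_gm, water_content_wm, water_content_csf,
            pure_water_concentration)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("relaxation_constants: all constants must be positive and finite",
         call. = FALSE)
  }
  if (te >= tr) stop("relaxation_constants: te must be smaller than tr", call. = FALSE)
  structure(
    list(t1 = c(gm = t1_gm, wm = t1_wm, csf = t1_csf),
         t2 = c(gm = t2_gm, wm = t2_wm, csf = t2_csf),
         tr = tr, te = te,
         water_content = c(gm = water_content_gm, wm = water_content_wm,
                           csf = water_content_csf),
         pure_water_concentration = pure_water_concentration),
    class = "relaxation_constants"
  )
}

#' Voxel tissue fractions
#'
#' Validates GM/WM/CSF partial-volume fractions from segmentation. Fractions
#' that mis-sum by more than `1e-6` but at most `tol` are renormalized with a
#' warning (segmentation outputs routinely mis-sum by rounding); larger
#' departures are errors.
#'
#' @param f_gm,f_wm,f_csf Volume fractions in `[0, 1]`.
#' @param tol Maximum tolerated departure of the sum from 1 before rejection.
#' @return A named numeric vector `c(gm=, wm=, csf=)` summing to 1.
#' @export
tissue_fractions <- function(f_gm, f_wm, f_csf, tol = 1e-3) {
  f <- c(gm = f_gm, wm = f_wm, csf = f_csf)
  if (!all(is.finite(f)) || any(f < 0) || any(f > 1)) {
    stop("tissue_fractions: fractions must lie in [0, 1]", call. = FALSE)
  }
  s <- sum(f)
  if (abs(s - 1) > tol) {
    stop(sprintf("tissue_fractions: fractions sum to %.4f (tolerance %g)", s, tol),
         call. = FALSE)
  }
  if (abs(s - 1) > 1e-6) {
    warning(sprintf("tissue fractions sum to %.4f; renormalizing", s), call. = FALSE)
  }
  f / s
}

#' Quality-control gate for MRS spectra
#'
#' A spectrum passes iff its linewidth is strictly below `linewidth_max`
#' (default 10 Hz) and its SNR is strictly above `snr_min` (default 5).
#' Vectorized; missing QC fields fail with reason `"missing-qc"`.
#'
#' @param snr Signal-to-noise ratio(s).
#' @param linewidth Linewidth(s), Hz.
#' @param snr_min,linewidth_max QC thresholds.
#' @return A tibble with logical `pass` and character `reason`
#'   (`NA` when passed; otherwise `"missing-qc"`, `"low-snr"`,
#'   `"broad-linewidth"`, or both rules comma-joined).
#' @examples
#' qc_filter(snr = c(12, 5, 8), linewidth = c(6, 6, 11))
#' @export
qc_filter <- function(snr, linewidth, snr_min = 5, linewidth_max = 10) {
  stopifnot(length(snr) == length(linewidth))
  n <- length(snr)
  reason <- character(n)
  missing <- is.na(snr) | is.na(linewidth)
  low_snr <- !missing & snr <= snr_min
  broad <- !missing & linewidth >= linewidth_max
  reason[missing] <- "missing-qc"
  both <- low_snr & broad
  reason[low_snr & !both] <- "low-snr"
  reason[broad & !both] <- "broad-linewidth"
  reason[both] <- "low-snr,broad-linewidth"
  pass <- !missing & !low_snr & !broad
  tibble::tibble(pass = pass, reason = ifelse(pass, NA_character_, reason))
}

#' Relaxation attenuation of a compartment water signal
#'
#' Steady-state attenuation `R = (1 - exp(-TR/T1)) * exp(-TE/T2)` of the
#' observable water signal from saturation (T1) and echo decay (T2).
#'
#' @param t1,t2 Relaxation times, ms.
#' @param tr,te Sequence repetition and echo time, ms.
#' @return Attenuation factor in `(0, 1)`.
#' @examples
#' compartment_attenuation(1331, 110, 2000, 68)  # ~0.419 for GM water
#' @export
compartment_attenuation <- function(t1, t2, tr, te) {
  if (any(!is.finite(c(t1, t2, tr, te))) || any(c(t1, t2, tr, te) <= 0)) {
    stop("compartment_attenuation: all inputs must be positive and finite",
         call. = FALSE)
  }
  (1 - exp(-tr / t1)) * exp(-te / t2)
}

# Water-side scaling of the tissue correction at given fractions (internal).
# Returns pure_water_conc * sum_k f'_k R_k / (1 - f'_csf) where f'_k are the
# water-content-weighted fractions. Vectorized over rows of a 3-col fraction
# matrix.
water_scaling <- function(f_gm, f_wm, f_csf, constants) {
  w <- constants$water_content
  rk <- c(gm = compartment_attenuation(constants$t1[["gm"]], constants$t2[["gm"]],
                                       constants$tr, constants$te),
          wm = compartment_attenuation(constants$t1[["wm"]], constants$t2[["wm"]],
                                       constants$tr, constants$te),
          csf = compartment_attenuation(constants$t1[["csf"]], constants$t2[["csf"]],
                                        constants$tr, constants$te))
  denom_w <- f_gm * w[["gm"]] + f_wm * w[["wm"]] + f_csf * w[["csf"]]
  fp_gm <- f_gm * w[["gm"]] / denom_w
  fp_wm <- f_wm * w[["wm"]] / denom_w
  fp_csf <- f_csf * w[["csf"]] / denom_w
  if (any(fp_csf >= 1)) {
    stop("correction undefined for a pure-CSF voxel (f_csf = 1)", call. = FALSE)
  }
  constants$pure_water_concentration *
    (fp_gm * rk[["gm"]] + fp_wm * rk[["wm"]] + fp_csf * rk[["csf"]]) / (1 - fp_csf)
}

#' Tissue- and relaxation-corrected metabolite concentration
#'
#' Converts a metabolite-to-water signal-amplitude ratio into a
#' CSF-corrected, water-scaled concentration:
#' \deqn{C = S \cdot C_{H_2O} \cdot \frac{\sum_k f'_k R_k}{(1 - f'_{CSF})\, A_{met}}}
#' where \eqn{f'_k} are water-content-weighted volume fractions, \eqn{R_k} the
#' compartment water relaxation attenuations (see
#' [compartment_attenuation()]), and \eqn{A_{met}} an optional metabolite
#' relaxation attenuation (default 1, i.e. no metabolite relaxation
#' correction).
#'
#' @param signal_ratio Metabolite-to-water signal amplitude ratio (unitless).
#' @param fractions Output of [tissue_fractions()] (named gm/wm/csf vector).
#' @param constants A [relaxation_constants()] object.
#' @param metabolite_attenuation Relaxation attenuation of the metabolite
#'   signal, in `(0, 1]`.
#' @return Corrected concentration in mM-equivalent institutional units.
#' @export
correct_concentration <- function(signal_ratio, fractions,
                                  constants = relaxation_constants(),
                                  metabolite_attenuation = 1) {
  stopifnot(inherits(constants, "relaxation_constants"))
  if (!is.finite(metabolite_attenuation) || metabolite_attenuation <= 0 ||
      metabolite_attenuation > 1) {
    stop("metabolite_attenuation must lie in (0, 1]", call. = FALSE)
  }
  signal_ratio * water_scaling(fractions[["gm"]], fractions[["wm"]],
                               fractions[["csf"]], constants) /
    metabolite_attenuation
}

#' Apply QC gating and tissue correction to a metabolite panel
#'
#' Takes the long-format metabolite panel (columns `subject_id`, `group`,
#' `region`, `metabolite`, `level` (= metabolite/water signal ratio), `snr`,
#' `linewidth_hz`, `f_gm`, `f_wm`, `f_csf`), applies [qc_filter()], and
#' appends `qc_pass`, `qc_reason` and `corrected_concentration` (present only
#' where QC passed).
#'
#' @param panel The metabolite panel tibble.
#' @param constants A [relaxation_constants()].
#' @param metabolite_attenuation Scalar metabolite attenuation, see
#'   [correct_concentration()].
#' @param snr_min,linewidth_max QC thresholds.
#' @return The panel with `qc_pass`, `qc_reason`, `corrected_concentration`
#'   columns appended.
#' @export
correct_panel <- function(panel, constants = relaxation_constants(),
                          metabolite_attenuation = 1,
                          snr_min = 5, linewidth_max = 10) {
  need <- c("subject_id", "region", "metabolite", "level", "snr",
            "linewidth_hz", "f_gm", "f_wm", "f_csf")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols) > 0L) {
    stop("correct_panel: panel lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  qc <- qc_filter(panel$snr, panel$linewidth_hz, snr_min, linewidth_max)
  fsum <- panel$f_gm + panel$f_wm + panel$f_csf
  bad <- which(abs(fsum - 1) > 1e-3)
  if (length(bad) > 0L) {
    stop("correct_panel: tissue fractions mis-sum beyond tolerance in rows ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(abs(fsum - 1) > 1e-6)) {
    warning("some tissue fractions mis-sum by rounding; renormalizing", call. = FALSE)
  }
  f_gm <- panel$f_gm / fsum
  f_wm <- panel$f_wm / fsum
  f_csf <- panel$f_csf / fsum
  conc <- panel$level * water_scaling(f_gm, f_wm, f_csf, constants) /
    metabolite_attenuation
  panel$qc_pass <- qc$pass
  panel$qc_reason <- qc$reason
  panel$corrected_concentration <- ifelse(qc$pass, conc, NA_real_)
  panel
}

#' Concentration ratio of two metabolites in a region
#'
#' Computes the per-subject ratio of corrected concentrations (e.g. NAA/mIns,
#' a composite neuronal-integrity marker) within one region. The ratio is
#' missing wherever either metabolite failed QC or the denominator is
#' non-positive (the latter with a warning).
#'
#' @param panel A corrected panel from [correct_panel()].
#' @param region Region to compute the ratio in.
#' @param numerator,denominator Metabolite names (defaults NAA and mIns).
#' @return A tibble `subject_id`, `group`, `region`, `metabolite`
#'   (e.g. `"NAA/mIns"`), `corrected_concentration`.
#' @export
compute_ratio <- function(panel, region, numerator = "NAA", denominator = "mIns") {
  stopifnot("corrected_concentration" %in% names(panel))
  sub <- panel[panel$region == region &
                 panel$metabolite %in% c(numerator, denominator), , drop = FALSE]
  wide <- tidyr::pivot_wider(
    sub[, c("subject_id", "group", "metabolite", "corrected_concentration")],
    names_from = "metabolite", values_from = "corrected_concentration"
  )
  for (m in c(numerator, denominator)) if (!m %in% names(wide)) wide[[m]] <- NA_real_
  den <- wide[[denominator]]
  bad_den <- !is.na(den) & den <= 0
  if (any(bad_den)) {
    warning(sprintf("non-positive %s denominator for %d subject(s) in %s; ratio set missing",
                    denominator, sum(bad_den), region), call. = FALSE)
    den[bad_den] <- NA_real_
  }
  tibble::tibble(
    subject_id = wide$subject_id, group = wide$group, region = region,
    metabolite = paste0(numerator, "/", denominator),
    corrected_concentration = wide[[numerator]] / den
  )
}

#' Append metabolite-ratio rows to a corrected panel
#'
#' Adds one pseudo-metabolite row (default `NAA/mIns`) per subject x region,
#' computed with [compute_ratio()], so ratios flow through the same screening
#' and regression machinery as single metabolites.
#'
#' @inheritParams compute_ratio
#' @return The panel with ratio rows appended (QC columns set from the
#'   availability of the ratio).
#' @export
panel_with_ratio <- function(panel, numerator = "NAA", denominator = "mIns") {
  ratios <- dplyr::bind_rows(lapply(unique(panel$region), function(rg) {
    compute_ratio(panel, rg, numerator, denominator)
  }))
  ratios$qc_pass <- !is.na(ratios$corrected_concentration)
  ratios$qc_reason <- ifelse(ratios$qc_pass, NA_character_, "component-missing")
  dplyr::bind_rows(panel, ratios)
}
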