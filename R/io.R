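#' Read and write the delimited trial-table and metabolite-panel formats
#'
#' Trial tables are tab-delimited with columns `subject_id`, `group`,
#' `session`, `ssp`, `trial_type`, `ssd_ms`, `rt_ms`, `stop_success`; empty
#' cells mark non-applicable fields (e.g. no SSD on go trials, no RT on
#' successful stops). Metabolite panels carry `subject_id`, `group`,
#' `region`, `metabolite`, `level`, `snr`, `linewidth_hz`, `f_gm`, `f_wm`,
#' `f_csf`.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return `write_*` return `path` invisibly; `read_*` return a tibble.
#' @name trial_io
NULL

trial_table_cols <- function() {
  c("subject_id", "group", "session", "ssp", "trial_type",
    "ssd_ms", "rt_ms", "stop_success")
}

panel_cols <- function() {
  c("subject_id", "group", "region", "metabolite", "level",
    "snr", "linewidth_hz", "f_gm", "f_wm", "f_csf")
}

#' @rdname trial_io
#' @export
write_trial_table <- function(x, path) {
  stopifnot(all(trial_table_cols() %in% names(x)))
  utils::write.table(x[, trial_table_cols()], path, sep = "\t", na = "",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname trial_io
#' @export
read_trial_table <- function(path) {
  x <- utils::read.delim(path, na.strings = "", stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_table_cols(), names(x))
  if (length(missing_cols) > 0L) {
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x$stop_success <- as.logical(x$stop_success)
  tibble::as_tibble(x)
}

#' @rdname trial_io
#' @export
write_metabolite_panel <- function(x, path) {
  stopifnot(all(panel_cols() %in% names(x)))
  utils::write.table(x[, panel_cols()], path, sep = "\t", na = "",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname trial_io
#' @export
read_metabolite_panel <- function(path) {
  x <- utils::read.delim(path, na.strings = "", stringsAsFactors = FALSE)
  missing_cols <- setdiff(panel_cols(), names(x))
  if (length(missing_cols) > 0L) {
    stop("metabolite panel lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Validate trial and panel tables against the format invariants
#'
#' Schema, range and consistency checks without mutating the data: go trials
#' must not carry an SSD or a stop outcome; successful stops must not carry
#' an RT; 0% SSP blocks contain only go trials; RTs and SSDs are
#' non-negative; tissue fractions lie in `[0, 1]` and sum to 1 within 1e-3;
#' SNR and linewidth are non-negative.
#'
#' @param trials Trial table (or `NULL` to skip).
#' @param panel Metabolite panel (or `NULL` to skip).
#' @return A tibble of violations with columns `table`, `row`, `rule`,
#'   `message`; zero rows when everything checks out.
#' @export
validate_inputs <- function(trials = NULL, panel = NULL) {
  out <- list()
  flag <- function(table, rows, rule, message) {
    if (length(rows) == 0L) return(NULL)
    tibble::tibble(table = table, row = rows, rule = rule, message = message)
  }
  if (!is.null(trials)) {
    go <- trials$trial_type == "go"
    stp <- trials$trial_type == "stop"
    out <- c(out, list(
      flag("trials", which(!trials$trial_type %in% c("go", "stop")),
           "trial-type", "trial_type must be 'go' or 'stop'"),
      flag("trials", which(!trials$ssp %in% c(0, 20, 40)),
           "ssp-level", "ssp must be 0, 20 or 40"),
      flag("trials", which(go & !is.na(trials$ssd_ms)),
           "go-has-ssd", "go trial carries an SSD"),
      flag("trials", which(go & !is.na(trials$stop_success)),
           "go-has-outcome", "go trial carries a stop outcome"),
      flag("trials", which(stp & is.na(trials$ssd_ms)),
           "stop-no-ssd", "stop trial lacks an SSD"),
      flag("trials", which(stp & is.na(trials$stop_success)),
           "stop-no-outcome", "stop trial lacks a stop outcome"),
      flag("trials", which(stp & !is.na(trials$stop_success) &
                             trials$stop_success & !is.na(trials$rt_ms)),
           "success-has-rt", "successful stop carries an RT"),
      flag("trials", which(stp & !is.na(trials$stop_success) &
                             !trials$stop_success & is.na(trials$rt_ms)),
           "failed-no-rt", "failed stop lacks an RT"),
      flag("trials", which(!is.na(trials$rt_ms) & trials$rt_ms < 0),
           "negative-rt", "negative RT"),
      flag("trials", which(!is.na(trials$ssd_ms) & trials$ssd_ms < 0),
           "negative-ssd", "negative SSD"),
      flag("trials", which(trials$ssp == 0 & stp),
           "stop-in-0ssp", "stop trial inside a 0% SSP block")
    ))
  }
  if (!is.null(panel)) {
    fsum <- panel$f_gm + panel$f_wm + panel$f_csf
    frac_bad <- panel$f_gm < 0 | panel$f_gm > 1 | panel$f_wm < 0 |
      panel$f_wm > 1 | panel$f_csf < 0 | panel$f_csf > 1
    key <- paste(panel$subject_id, panel$region, panel$metabolite)
    out <- c(out, list(
      flag("panel", which(frac_bad), "fraction-range",
           "tissue fraction outside [0, 1]"),
      flag("panel", which(!frac_bad & abs(fsum - 1) > 1e-3), "fraction-sum",
           "tissue fractions do not sum to 1"),
      flag("panel", which(!is.na(panel$snr) & panel$snr < 0), "negative-snr",
           "negative SNR"),
      flag("panel", which(!is.na(panel$linewidth_hz) & panel$linewidth_hz < 0),
           "negative-linewidth", "negative linewidth"),
      flag("panel", which(duplicated(key)), "duplicate-cell",
           "duplicated subject x region x metabolite row")
    ))
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(table = character(), row = integer(),
                          rule = character(), message = character())
  }
  res
}
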