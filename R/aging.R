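#' Accelerated-aging time-compression factor
#'
#' Soak testing at elevated temperature compresses time according to the
#' standard reaction-rate doubling rule: the factor is
#' `2^((t_device - t_ref) / 10)`, i.e. a doubling for every 10 degrees C
#' above the reference temperature. The default reference of 37 C is mouse
#' body temperature, so a device held at 87 C ages 32 times faster than
#' in vivo.
#'
#' @param t_device soak temperature, degrees C.
#' @param t_ref reference (body) temperature, degrees C.
#' @return dimensionless acceleration factor; a warning is issued when the
#'   device is colder than the reference (factor < 1, deceleration).
#' @export
aging_factor <- function(t_device, t_ref = 37) {
  stopifnot(is.finite(t_device), is.finite(t_ref))
  if (any(t_device < t_ref)) {
    warning("t_device below t_ref: factor < 1 (deceleration, not aging)")
  }
  2^((t_device - t_ref) / 10)
}

#' Equivalent in vivo lifetime of an aged device
#'
#' Converts time spent in an accelerated soak test to equivalent lifetime
#' at the reference temperature: `days * factor`, also expressed in years.
#' Years are reported both raw and rounded half-up to 2 decimals, the
#' precision used in lifetime summary tables.
#'
#' @param days_elapsed non-negative days at the soak temperature.
#' @param factor acceleration factor from [aging_factor()].
#' @param year_days days per year; 365.25 (Julian year) by default, and
#'   365 reproduces the same 2-decimal values for the durations used here.
#' @return list with `days`, `years_raw`, and `years` (2 d.p.).
#' @export
equivalent_lifetime <- function(days_elapsed, factor, year_days = 365.25) {
  if (any(!is.finite(days_elapsed)) || any(days_elapsed < 0)) {
    stop("'days_elapsed' must be non-negative", call. = FALSE)
  }
  check_positive(factor, "factor")
  days <- days_elapsed * factor
  years_raw <- days / year_days
  list(days = days, years_raw = years_raw,
       years = round_half_up(years_raw, 2))
}

AGING_MECHANISMS <- c("none", "minor_permeation", "crack_electrode", "crack_wire")

MECHANISM_LABELS <- c(none = "No failure",
                      minor_permeation = "Minor PBS permeation",
                      crack_electrode = "Cracks over electrode",
                      crack_wire = "Cracks over wire")

#' Validate a table of accelerated-aging array records
#'
#' One row per microelectrode array: `label`, `substrate` (`PET` or
#' `SU-8`), `days_elapsed` at the soak temperature, final `status`
#' (`working`/`failed`), and `failure_mechanism` (`none`,
#' `minor_permeation`, `crack_electrode`, `crack_wire`). A failed array
#' must name a destructive mechanism (cracks), since minor permeation by
#' itself does not break recording capability.
#'
#' @param records data.frame with the columns above.
#' @return the validated data.frame, invisibly classed `aging_records`.
#' @export
aging_records <- function(records) {
  need <- c("label", "substrate", "days_elapsed", "status", "failure_mechanism")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("records need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0) stop("empty records", call. = FALSE)
  if (!all(records$substrate %in% c("PET", "SU-8"))) {
    stop("substrate must be 'PET' or 'SU-8'", call. = FALSE)
  }
  if (!all(records$status %in% c("working", "failed"))) {
    stop("status must be 'working' or 'failed'", call. = FALSE)
  }
  if (!all(records$failure_mechanism %in% AGING_MECHANISMS)) {
    stop("unknown failure mechanism", call. = FALSE)
  }
  bad <- records$status == "failed" &
    records$failure_mechanism %in% c("none", "minor_permeation")
  if (any(bad)) {
    stop("failed arrays must have a destructive failure mechanism",
         call. = FALSE)
  }
  if (any(records$days_elapsed < 0)) stop("negative days_elapsed", call. = FALSE)
  class(records) <- c("aging_records", class(records))
  invisible(records)
}

#' Read aging records from CSV
#'
#' @param path CSV with columns `label`, `substrate`, `days_elapsed`,
#'   `status`, `failure_mechanism`. The packaged example (the eight-array
#'   PET/SU-8 soak-test cohort) is used when `path` is `NULL`.
#' @return validated records data.frame.
#' @export
read_aging_records <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aging_records.csv", package = "flexmea",
                        mustWork = TRUE)
  }
  aging_records(utils::read.csv(path, check.names = TRUE))
}

#' Lifetime summary table for an aging cohort
#'
#' One row per array, in input order: final status, days elapsed in the
#' soak, equivalent in vivo lifetime (days and years, 2 d.p.), and a
#' human-readable failure mechanism.
#'
#' @param records aging records (see [aging_records()]).
#' @param t_device,t_ref soak and reference temperatures, degrees C.
#' @param year_days days per year (see [equivalent_lifetime()]).
#' @return data.frame with columns `label`, `substrate`, `status`,
#'   `days_elapsed`, `equivalent_days`, `equivalent_years`,
#'   `failure_mechanism`.
#' @export
build_summary_table <- function(records, t_device = 87, t_ref = 37,
                                year_days = 365.25) {
  records <- aging_records(as.data.frame(records))
  f <- aging_factor(t_device, t_ref)
  lt <- equivalent_lifetime(records$days_elapsed, f, year_days)
  data.frame(
    label = records$label,
    substrate = records$substrate,
    status = ifelse(records$status == "working", "Working", "Failed"),
    days_elapsed = records$days_elapsed,
    equivalent_days = lt$days,
    equivalent_years = lt$years,
    failure_mechanism = unname(MECHANISM_LABELS[records$failure_mechanism]),
    stringsAsFactors = FALSE
  )
}
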