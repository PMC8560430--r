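# Longitudinal tracking of per-channel 1 kHz impedance during soak tests
# or chronic implants: working/nonworking classification against the
# acquisition-system threshold, array yield, per-day summaries over
# working channels, and detection of irreversible (open) channel failures.

#' Per-channel impedance timecourse
#'
#' @param channel_id identifier (any scalar).
#' @param days strictly increasing measurement days since start.
#' @param z_1khz impedance magnitude at 1 kHz per day, Ohm; `NA` marks a
#'   channel that could not be measured that day (open circuit).
#' @return object of class `channel_timecourse`.
#' @export
channel_timecourse <- function(channel_id, days, z_1khz) {
  stopifnot(length(days) == length(z_1khz), length(days) >= 1)
  if (is.unsorted(days, strictly = TRUE)) {
    stop("'days' must be strictly increasing", call. = FALSE)
  }
  ok <- !is.na(z_1khz)
  if (any(z_1khz[ok] <= 0)) stop("impedances must be positive", call. = FALSE)
  structure(list(channel_id = channel_id, days = days,
                 z_1khz = as.numeric(z_1khz)),
            class = "channel_timecourse")
}

#' Classify channels as working or nonworking
#'
#' A channel counts as working when its 1 kHz impedance is present and
#' strictly below the threshold; 2 MOhm is the acquisition-system limit
#' for a usable signal-to-noise ratio, so a channel at exactly the
#' threshold is nonworking. Unmeasurable channels (`NA`) are nonworking.
#'
#' @param z_1khz impedance magnitude(s) at 1 kHz, Ohm; `NA` allowed.
#' @param threshold working threshold, Ohm.
#' @return character vector, `"working"` or `"nonworking"`.
#' @seealso [is_working()] for the logical version.
#' @export
classify_channel <- function(z_1khz, threshold = 2e6) {
  ifelse(is_working(z_1khz, threshold), "working", "nonworking")
}

#' @rdname classify_channel
#' @export
is_working <- function(z_1khz, threshold = 2e6) {
  check_positive(threshold, "threshold")
  !is.na(z_1khz) & z_1khz < threshold
}

#' Fraction of working channels in an array
#'
#' @param values per-channel 1 kHz impedances, Ohm (`NA` = unmeasurable).
#' @param threshold working threshold, Ohm.
#' @return fraction in [0, 1].
#' @export
array_yield <- function(values, threshold = 2e6) {
  if (length(values) == 0) stop("empty channel list", call. = FALSE)
  mean(is_working(values, threshold))
}

#' First day of persistent channel failure
#'
#' Returns the first measurement day from which the channel is nonworking
#' at that day and every later day, or `NA` if the channel ends the record
#' working. A transient bad measurement followed by recovery is not a
#' failure: the failures of interest (opens from cracked wires or
#' electrodes) are irreversible, so persistence to the end of the record
#' is required. A channel that never worked fails on its first day.
#'
#' @param channel a [channel_timecourse()].
#' @param threshold working threshold, Ohm.
#' @return day of failure, or `NA` if none.
#' @export
detect_failure_day <- function(channel, threshold = 2e6) {
  stopifnot(inherits(channel, "channel_timecourse"))
  w <- is_working(channel$z_1khz, threshold)
  n <- length(w)
  if (w[n]) return(NA_real_)
  last_working <- max(c(0, which(w)))
  channel$days[last_working + 1]
}

#' Summarise an array's impedance timecourse
#'
#' Per-day mean and sample standard deviation of 1 kHz impedance over
#' working channels only (nonworking channels carry no measurable
#' impedance), yield (fraction of all channels working), and the array
#' failure day: the first day from which every channel is persistently
#' nonworking. Channels may be sampled on different day grids; the
#' summary is on the union of days, and a channel simply absent on a day
#' is ignored for that day (not counted in yield).
#'
#' @param channels list of [channel_timecourse()] objects.
#' @param threshold working threshold, Ohm.
#' @return object of class `array_summary`: a data.frame with columns
#'   `day`, `mean_ohm`, `sd_ohm` (`NA` when fewer than 2 working
#'   channels), `n_working`, `n_channels`, `yield`, plus attribute
#'   `failure_day`.
#' @export
summarize_timecourse <- function(channels, threshold = 2e6) {
  stopifnot(length(channels) >= 1,
            all(vapply(channels, inherits, TRUE, "channel_timecourse")))
  days <- sort(unique(unlist(lapply(channels, `[[`, "days"))))
  rows <- lapply(days, function(d) {
    vals <- unlist(lapply(channels, function(ch) {
      i <- match(d, ch$days)
      if (is.na(i)) NULL else ch$z_1khz[i]   # NA value kept, absent day dropped
    }))
    # channels measured (or attempted) on this day
    present <- vapply(channels, function(ch) d %in% ch$days, TRUE)
    w <- is_working(vals, threshold)
    work_vals <- vals[w]
    data.frame(
      day = d,
      mean_ohm = if (length(work_vals)) mean(work_vals) else NA_real_,
      sd_ohm = if (length(work_vals) >= 2) stats::sd(work_vals) else NA_real_,
      n_working = sum(w),
      n_channels = sum(present),
      yield = if (sum(present)) sum(w) / sum(present) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  per_channel_failures <- vapply(channels, detect_failure_day, 0,
                                 threshold = threshold)
  failure_day <- if (any(is.na(per_channel_failures))) NA_real_
                 else max(per_channel_failures)
  attr(out, "failure_day") <- failure_day
  class(out) <- c("array_summary", class(out))
  out
}

#' Pool per-day summaries across several arrays
#'
#' Two conventions are reported for the grand average: pooling all working
#' channels across arrays (`pooled_*`), and averaging the per-array means
#' (`of_means_*`). The two differ when arrays contribute different numbers
#' of working channels.
#'
#' @param array_channels named list; each element is a list of
#'   [channel_timecourse()] objects (one array).
#' @param threshold working threshold, Ohm.
#' @return data.frame with columns `day`, `pooled_mean_ohm`,
#'   `pooled_sd_ohm`, `mean_of_means_ohm`, `n_working`, `yield`.
#' @export
summarize_arrays <- function(array_channels, threshold = 2e6) {
  stopifnot(length(array_channels) >= 1)
  all_ch <- unlist(array_channels, recursive = FALSE)
  pooled <- summarize_timecourse(all_ch, threshold)
  per_array <- lapply(array_channels, summarize_timecourse, threshold = threshold)
  days <- pooled$day
  mom <- vapply(days, function(d) {
    m <- vapply(per_array, function(s) {
      i <- match(d, s$day)
      if (is.na(i)) NA_real_ else s$mean_ohm[i]
    }, 0)
    if (all(is.na(m))) NA_real_ else mean(m, na.rm = TRUE)
  }, 0)
  data.frame(day = days,
             pooled_mean_ohm = pooled$mean_ohm,
             pooled_sd_ohm = pooled$sd_ohm,
             mean_of_means_ohm = mom,
             n_working = pooled$n_working,
             yield = pooled$yield)
}

#' Read channel timecourses from a long-format CSV
#'
#' Columns: `array_id`, `channel_id`, `day`, `z_1khz_ohm`; an empty cell
#' in `z_1khz_ohm` marks an unmeasurable (open) channel on that day.
#'
#' @param path CSV file path.
#' @return named list (one element per array) of lists of
#'   [channel_timecourse()] objects.
#' @export
read_timecourse_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("array_id", "channel_id", "day", "z_1khz_ohm")
  if (!all(need %in% names(d))) {
    stop("timecourse CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(d, d$array_id), function(a) {
    lapply(split(a, a$channel_id), function(ch) {
      o <- order(ch$day)
      channel_timecourse(ch$channel_id[1], ch$day[o], ch$z_1khz_ohm[o])
    })
  })
}

#' Write channel timecourses to a long-format CSV
#'
#' @param array_channels named list of lists of [channel_timecourse()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(array_channels, path) {
  rows <- list()
  for (aid in names(array_channels)) {
    for (ch in array_channels[[aid]]) {
      rows[[length(rows) + 1]] <- data.frame(
        array_id = aid, channel_id = ch$channel_id,
        day = ch$days, z_1khz_ohm = ch$z_1khz)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
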