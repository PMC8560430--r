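# Quality metrics for chronic surface (ECoG) recordings: RMS noise,
# stimulus-locked epoch averaging with per-epoch baseline subtraction,
# onset-latency estimation against a baseline-noise criterion, and
# trial-averaged band-power spectrograms in dB relative to the
# pre-stimulus baseline.

#' Single-channel recording trace
#'
#' @param samples voltage samples, uV.
#' @param rate sampling rate, Hz.
#' @param start_time time of the first sample, s.
#' @return object of class `recording_trace`.
#' @export
recording_trace <- function(samples, rate, start_time = 0) {
  check_positive(rate, "rate")
  if (!all(is.finite(samples))) stop("non-finite samples", call. = FALSE)
  structure(list(samples = as.numeric(samples), rate = rate,
                 start_time = start_time),
            class = "recording_trace")
}

#' @export
print.recording_trace <- function(x, ...) {
  cat(sprintf("Recording: %d samples at %g Hz (%.1f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Visual-stimulation protocol
#'
#' Trials of a fixed-duration stimulus (default 4 s drifting grating, one
#' of 12 orientations 30 degrees apart) with onset-to-onset intervals in
#' a stated range (default 7-9 s).
#'
#' @param onsets increasing stimulus onset times, s.
#' @param duration stimulus duration per trial, s.
#' @param orientation optional orientation per trial, degrees.
#' @param isi_range nominal inter-stimulus-interval range, s.
#' @return object of class `stim_protocol`.
#' @export
stim_protocol <- function(onsets, duration = 4, orientation = NULL,
                          isi_range = c(7, 9)) {
  if (length(onsets) == 0) stop("no stimulus onsets", call. = FALSE)
  if (is.unsorted(onsets, strictly = TRUE)) {
    stop("'onsets' must be strictly increasing", call. = FALSE)
  }
  check_positive(duration, "duration")
  if (!is.null(orientation)) stopifnot(length(orientation) == length(onsets))
  structure(list(onsets = onsets, duration = duration,
                 orientation = orientation, isi_range = isi_range),
            class = "stim_protocol")
}

#' RMS noise of a recording window
#'
#' Square root of the mean squared mean-subtracted samples over the
#' window. Noise should be assessed on stimulus-free segments; the
#' default window is the whole trace.
#'
#' @param trace a [recording_trace()].
#' @param window `c(t0, t1)` in seconds relative to the trace start, or
#'   `NULL` for the full trace.
#' @return RMS amplitude, uV.
#' @export
rms_noise <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "recording_trace"))
  x <- trace$samples
  if (!is.null(window)) {
    i0 <- max(1L, floor(window[1] * trace$rate) + 1L)
    i1 <- min(length(x), ceiling(window[2] * trace$rate))
    if (i1 < i0) stop("empty window", call. = FALSE)
    x <- x[i0:i1]
  }
  if (length(x) == 0) stop("empty window", call. = FALSE)
  sqrt(mean((x - mean(x))^2))
}

# internal: extract complete epochs as a matrix (time x trial)
extract_epochs <- function(trace, protocol, window) {
  rate <- trace$rate
  pre_n <- round(window[1] * rate)
  post_n <- round(window[2] * rate)
  onset_idx <- round((protocol$onsets - trace$start_time) * rate) + 1L
  i0 <- onset_idx - pre_n
  i1 <- onset_idx + post_n - 1L
  complete <- i0 >= 1 & i1 <= length(trace$samples)
  ep <- vapply(which(complete), function(k) trace$samples[i0[k]:i1[k]],
               numeric(pre_n + post_n))
  list(epochs = matrix(ep, nrow = pre_n + post_n),
       n_dropped = sum(!complete), pre_n = pre_n,
       time = (seq_len(pre_n + post_n) - pre_n - 0.5) / rate)
}

#' Stimulus-locked trial average
#'
#' Cuts the trace into peri-stimulus epochs, subtracts each epoch's
#' pre-stimulus mean (per-epoch baseline), and averages across trials.
#' Epochs extending beyond the trace are dropped and counted.
#'
#' @param trace a [recording_trace()].
#' @param protocol a [stim_protocol()].
#' @param window `c(pre, post)`: seconds before and after onset.
#' @return object of class `evoked_result`: `time` (s, 0 = onset),
#'   `average` (uV), `n_trials`, `n_dropped`, `rate`.
#' @export
epoch_and_average <- function(trace, protocol, window = c(0.5, 1)) {
  stopifnot(inherits(trace, "recording_trace"),
            inherits(protocol, "stim_protocol"))
  ex <- extract_epochs(trace, protocol, window)
  if (ncol(ex$epochs) == 0) stop("no complete epochs", call. = FALSE)
  baselined <- apply(ex$epochs, 2, function(e) e - mean(e[seq_len(ex$pre_n)]))
  baselined <- matrix(baselined, nrow = nrow(ex$epochs))
  structure(list(time = ex$time, average = rowMeans(baselined),
                 n_trials = ncol(ex$epochs), n_dropped = ex$n_dropped,
                 rate = trace$rate),
            class = "evoked_result")
}

#' Onset latency of an evoked response
#'
#' First post-stimulus time at which the absolute trial-averaged response
#' exceeds `k` times the pre-stimulus baseline standard deviation and
#' stays above it for a sustained duration.
#'
#' @param evoked an `evoked_result` from [epoch_and_average()].
#' @param k threshold multiple of the baseline SD.
#' @param sustained_ms how long the response must stay above threshold, ms.
#' @return latency in ms, or `NA` if the criterion is never met (including
#'   a perfectly flat trace).
#' @export
onset_latency <- function(evoked, k = 3, sustained_ms = 20) {
  stopifnot(inherits(evoked, "evoked_result"))
  pre <- evoked$time < 0
  if (!any(pre)) stop("no pre-stimulus baseline present", call. = FALSE)
  sd_b <- stats::sd(evoked$average[pre])
  thresh <- k * sd_b
  post_idx <- which(evoked$time >= 0)
  above <- abs(evoked$average[post_idx]) > thresh
  if (thresh == 0) above <- abs(evoked$average[post_idx]) > 0
  need <- max(1L, round(sustained_ms / 1000 * evoked$rate))
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  hit <- which(run$values & run$lengths >= need)
  if (length(hit) == 0) return(NA_real_)
  evoked$time[post_idx[starts[hit[1]]]] * 1000
}

# internal: short-time PSD of one epoch. Hann window, one-sided density
# scaling |X|^2 * (2 except DC/Nyquist) / (fs * sum(w^2)); integrating the
# result over frequency recovers the windowed segment power (Parseval).
stft_psd <- function(x, rate, n_win, hop) {
  w <- signal::hanning(n_win)
  starts <- seq(1, length(x) - n_win + 1, by = hop)
  nf <- n_win %/% 2 + 1
  P <- vapply(starts, function(s) {
    X <- stats::fft(w * x[s:(s + n_win - 1)])[seq_len(nf)]
    p <- Mod(X)^2
    mult <- rep(2, nf); mult[1] <- 1
    if (n_win %% 2 == 0) mult[nf] <- 1
    p * mult / (rate * sum(w^2))
  }, numeric(nf))
  list(P = matrix(P, nrow = nf),
       freq = (seq_len(nf) - 1) * rate / n_win,
       centers = (starts + n_win / 2 - 0.5) / rate)
}

#' Trial-averaged band-power spectrogram
#'
#' Short-time power spectral density per epoch (Hann window, default
#' 256 ms with 75% overlap), averaged across trials and expressed in dB
#' relative to the per-frequency mean over pre-stimulus time bins. The
#' band-average time course averages linear power over frequency bins
#' whose centre lies inside the closed band (then converts to dB re the
#' band's baseline power), so narrowband increases are not diluted.
#'
#' @param trace a [recording_trace()].
#' @param protocol a [stim_protocol()].
#' @param band `c(lo, hi)` frequency band of interest, Hz; must lie below
#'   the Nyquist frequency.
#' @param window `c(pre, post)` epoch window, s.
#' @param win_s spectrogram window length, s.
#' @param overlap fractional window overlap in [0, 1).
#' @return object of class `evoked_spectrogram`: `time` (bin centres, s,
#'   0 = onset), `freq` (Hz), `db_map` (freq x time, dB re baseline),
#'   `power` (linear trial-averaged PSD, uV^2/Hz), `band_db` (band-average
#'   dB time course), `band`, `n_trials`.
#' @export
band_power_spectrogram <- function(trace, protocol, band = c(140, 200),
                                   window = c(0.5, 4), win_s = 0.256,
                                   overlap = 0.75) {
  stopifnot(inherits(trace, "recording_trace"),
            inherits(protocol, "stim_protocol"))
  if (band[2] >= trace$rate / 2) {
    stop("band extends to or beyond the Nyquist frequency", call. = FALSE)
  }
  ex <- extract_epochs(trace, protocol, window)
  if (ncol(ex$epochs) == 0) stop("no complete epochs", call. = FALSE)
  n_win <- round(win_s * trace$rate)
  hop <- max(1L, round(n_win * (1 - overlap)))
  acc <- NULL
  for (j in seq_len(ncol(ex$epochs))) {
    s <- stft_psd(ex$epochs[, j], trace$rate, n_win, hop)
    acc <- if (is.null(acc)) s$P else acc + s$P
  }
  P <- acc / ncol(ex$epochs)
  t_rel <- s$centers - window[1]
  base_bins <- t_rel < 0
  if (!any(base_bins)) stop("no pre-stimulus spectrogram bins; widen 'window'",
                            call. = FALSE)
  baseline <- rowMeans(P[, base_bins, drop = FALSE])
  db_map <- 10 * log10(sweep(P, 1, pmax(baseline, 1e-300), "/"))
  in_band <- s$freq >= band[1] & s$freq <= band[2]
  if (!any(in_band)) stop("no frequency bins inside the band", call. = FALSE)
  # band average on the linear power scale (then dB), so narrowband
  # increases are not diluted by averaging per-bin decibels
  band_lin <- colMeans(P[in_band, , drop = FALSE])
  band_base <- mean(baseline[in_band])
  structure(list(time = t_rel, freq = s$freq, db_map = db_map, power = P,
                 band_db = 10 * log10(band_lin / max(band_base, 1e-300)),
                 band = band, n_trials = ncol(ex$epochs)),
            class = "evoked_spectrogram")
}
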