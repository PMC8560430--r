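# Seeded synthetic-data generators emulating every input the analysis
# pipeline consumes: noisy impedance spectra drawn from the equivalent
# circuit, per-channel impedance timecourses with an initial drop, a
# plateau and injected open failures, permeation images with a lobe
# growing from the electrode-opening boundary, and ECoG-like traces with
# 1/f background, a stimulus-locked on-response and a high-band power
# increase during stimulation. Each generator is a pure function of its
# arguments: the same seed always yields bit-identical output, and every
# generator draws from its own sub-stream (see [substream_seed()]) so
# adding one never perturbs the others.

#' Synthetic noisy impedance spectrum
#'
#' Evaluates the equivalent circuit on the grid and applies independent
#' multiplicative Gaussian noise to the real and imaginary parts:
#' `Z * (1 + e_re + i e_im)`, `e ~ N(0, noise_frac)`, independent per
#' frequency and component.
#'
#' @param params a [circuit_params()] object.
#' @param grid frequency grid, Hz.
#' @param noise_frac relative noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return an [impedance_spectrum()].
#' @export
gen_eis_spectrum <- function(params, grid = freq_grid(), noise_frac = 0.01,
                             seed = 0) {
  stopifnot(noise_frac >= 0)
  z0 <- z_circuit(params, grid)
  if (noise_frac == 0) return(impedance_spectrum(grid, z0))
  withr::with_seed(substream_seed(seed, "eis"), {
    n <- length(grid)
    e_re <- stats::rnorm(n, 0, noise_frac)
    e_im <- stats::rnorm(n, 0, noise_frac)
    impedance_spectrum(grid, z0 * complex(real = 1 + e_re, imaginary = e_im))
  })
}

#' Synthetic per-channel impedance timecourses
#'
#' Emulates the typical soak/implant behaviour: an initial exponential
#' drop from `z0` to a plateau (`z(d) = z_plateau + (z0 - z_plateau)
#' exp(-d / tau_days)`), multiplicative lognormal variation between
#' channels and between measurements, and optional injected open failures
#' after which a channel is unmeasurable (`NA`) from the failure day on.
#'
#' @param n_channels number of channels.
#' @param days measurement days (strictly increasing).
#' @param profile list with `z0`, `z_plateau` (Ohm, `z0 >= z_plateau > 0`)
#'   and `tau_days` (time constant of the initial drop, days). Defaults
#'   emulate a working graphene array settling near 585 kOhm.
#' @param failures optional data.frame with columns `channel` and `day`.
#' @param noise list with `channel_sdlog` (per-channel lognormal spread)
#'   and `obs_sdlog` (per-measurement lognormal spread).
#' @param seed integer seed.
#' @return list of [channel_timecourse()] objects.
#' @export
gen_impedance_timecourse <- function(n_channels = 16, days = seq(0, 30, 3),
                                     profile = list(z0 = 1.1e6,
                                                    z_plateau = 5.85e5,
                                                    tau_days = 3),
                                     failures = NULL,
                                     noise = list(channel_sdlog = 0.1,
                                                  obs_sdlog = 0.05),
                                     seed = 0) {
  stopifnot(profile$z0 >= profile$z_plateau, profile$z_plateau > 0,
            n_channels >= 1)
  mean_curve <- profile$z_plateau +
    (profile$z0 - profile$z_plateau) * exp(-days / profile$tau_days)
  withr::with_seed(substream_seed(seed, "timecourse"), {
    lapply(seq_len(n_channels), function(ch) {
      ch_factor <- exp(stats::rnorm(1, 0, noise$channel_sdlog))
      obs <- exp(stats::rnorm(length(days), 0, noise$obs_sdlog))
      z <- mean_curve * ch_factor * obs
      if (!is.null(failures)) {
        hit <- failures$channel == ch
        if (any(hit)) z[days >= min(failures$day[hit])] <- NA_real_
      }
      channel_timecourse(ch, days, z)
    })
  })
}

#' Synthetic permeation microscopy image
#'
#' A grayscale image of one electrode opening edge: background texture
#' plus a bright permeated lobe grown from a vertical boundary (the
#' encapsulation edge at column `boundary_col`). The lobe's maximum
#' extent perpendicular to the boundary is exactly
#' `growth_um_per_day * day_index`, with a smooth angular modulation so
#' the front is not a perfect half-disk; at `day_index = 0` there is no
#' lobe.
#'
#' @param size image dimensions `c(nrow, ncol)`, pixels.
#' @param boundary_col column of the electrode-opening boundary.
#' @param day_index day in the growth schedule (>= 0).
#' @param growth_um_per_day radial growth rate, um/day.
#' @param pixel_size_um pixel size, um.
#' @param contrast intensity shift of the permeated lobe over background.
#' @param noise_sd Gaussian texture standard deviation.
#' @param seed integer seed.
#' @return a [microscopy_image()] with attributes `boundary` (n x 2
#'   matrix of boundary pixels) and `roi` (logical matrix covering the
#'   encapsulation side of the boundary).
#' @export
gen_permeation_image <- function(size = c(128, 128), boundary_col = 32,
                                 day_index = 0, growth_um_per_day = 2,
                                 pixel_size_um = 1, contrast = 0.4,
                                 noise_sd = 0.03, seed = 0) {
  stopifnot(growth_um_per_day >= 0, day_index >= 0)
  nr <- size[1]; nc <- size[2]
  center_row <- floor((nr + 1) / 2)   # a pixel centre, so the lobe apex
                                      # lands exactly on the grid
  withr::with_seed(substream_seed(seed, paste0("image", day_index)), {
    px <- matrix(0.3 + stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
    r_max <- growth_um_per_day * day_index / pixel_size_um
    if (r_max > 0) {
      dx <- matrix(rep(seq_len(nc) - boundary_col, each = nr), nr, nc)
      dy <- matrix(rep(seq_len(nr) - center_row, nc), nr, nc)
      rr <- sqrt(dx^2 + dy^2)
      theta <- atan2(dy, pmax(dx, 1e-9))
      lobe <- dx >= 0 & rr <= r_max * (0.7 + 0.3 * cos(2 * theta)) &
        abs(theta) <= pi / 2
      px[lobe] <- px[lobe] + contrast
    }
    px <- pmin(pmax(px, 0), 1)
    img <- microscopy_image(px, pixel_size_um)
    attr(img, "boundary") <- cbind(seq_len(nr), boundary_col)
    attr(img, "roi") <- matrix(rep(seq_len(nc) >= boundary_col, each = nr),
                               nr, nc)
    img
  })
}

# internal: 1/f-amplitude ("pink") noise by spectral shaping of white
# Gaussian noise over a fixed power-of-two FFT length, then truncation.
pink_noise <- function(n, rate) {
  nfft <- 2^ceiling(log2(max(n, 2)))
  white <- stats::rnorm(nfft)
  X <- stats::fft(white)
  f <- c(1, seq_len(nfft - 1))             # avoid the DC singularity
  f <- pmin(f, nfft - f + 1)               # symmetric shaping
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE)) / nfft
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

#' Synthetic ECoG trace with stimulus-locked responses
#'
#' Generates a 1/f ("pink") background, a visual-stimulation protocol
#' (onset-to-onset intervals drawn uniformly from `isi_range`, one of 12
#' orientations per trial), an evoked on-response injected at a fixed
#' latency after each onset, and a band-limited noise component whose
#' power is multiplied by `band_gain` while the stimulus is on.
#'
#' @param n_trials number of stimulus trials.
#' @param rate sampling rate, Hz; must exceed twice the band upper edge.
#' @param response list with `latency_ms`, `amplitude_uV` (peak of the
#'   on-response), `band` (`c(lo, hi)` Hz) and `band_gain` (power ratio
#'   stimulus vs baseline in the band).
#' @param noise list with `pink_scale_uV` (RMS of the 1/f background) and
#'   `band_floor_uV` (RMS of the always-on band-limited component).
#' @param isi_range onset-to-onset interval range, s.
#' @param stim_duration stimulus duration, s.
#' @param seed integer seed.
#' @return list with `trace` (a [recording_trace()]) and `protocol`
#'   (a [stim_protocol()]).
#' @export
gen_ecog <- function(n_trials = 40, rate = 1000,
                     response = list(latency_ms = 70, amplitude_uV = 150,
                                     band = c(140, 200), band_gain = 4),
                     noise = list(pink_scale_uV = 20, band_floor_uV = 8),
                     isi_range = c(7, 9), stim_duration = 4, seed = 0) {
  stopifnot(rate > 2 * response$band[2], n_trials >= 1)
  withr::with_seed(substream_seed(seed, "ecog"), {
    gaps <- stats::runif(n_trials, isi_range[1], isi_range[2])
    onsets <- 2 + cumsum(c(0, gaps[-n_trials]))
    n <- ceiling((max(onsets) + stim_duration + 3) * rate)
    x <- noise$pink_scale_uV * pink_noise(n, rate)

    # band-limited component, gain-switched during stimulation
    bf <- signal::butter(4, response$band / (rate / 2), type = "pass")
    bl <- signal::filtfilt(bf, stats::rnorm(n))
    bl <- bl / stats::sd(bl) * noise$band_floor_uV
    gain <- rep(1, n)
    for (t0 in onsets) {
      i <- (floor(t0 * rate) + 1):min(n, floor((t0 + stim_duration) * rate))
      gain[i] <- sqrt(response$band_gain)
    }
    x <- x + bl * gain

    # evoked on-response: fast rise, slow decay, injected at the latency
    shape_t <- seq(0, 0.5, by = 1 / rate)
    shape <- response$amplitude_uV *
      (1 - exp(-shape_t / 0.003)) * exp(-shape_t / 0.08)
    for (t0 in onsets) {
      i0 <- floor((t0 + response$latency_ms / 1000) * rate) + 1
      idx <- i0:min(n, i0 + length(shape) - 1)
      x[idx] <- x[idx] + shape[seq_along(idx)]
    }

    orientation <- (sample.int(12, n_trials, replace = TRUE) - 1) * 30
    list(trace = recording_trace(x, rate),
         protocol = stim_protocol(onsets, stim_duration, orientation,
                                  isi_range))
  })
}
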