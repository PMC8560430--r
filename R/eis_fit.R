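# Complex nonlinear least-squares fitting of impedance spectra to the
# equivalent circuit. Positive parameters are fitted on a log scale and the
# CPE exponent through a logistic transform, so positivity and the (0, 1)
# range hold without hard clipping. Levenberg-Marquardt via minpack.lm.

FIT_PAR_NAMES <- c("r_s", "c_dl_specific", "alpha", "c_q_specific",
                   "r_ct", "w_mag", "b")

#' Fitting configuration
#'
#' @param weighting residual weighting: `"modulus"` (default,
#'   `w_f = 1/|Z_meas|^2` on both components), `"unit"` (unweighted), or
#'   `"proportional"` (each component weighted by its own measured value,
#'   `1/Re(Z)^2` and `1/Im(Z)^2`).
#' @param fixed named list of parameters to hold fixed at the given
#'   values (any of `r_s`, `c_dl_specific`, `alpha`, `c_q_specific`,
#'   `r_ct`, `w_mag`, `b`).
#' @param lower,upper optional named numeric vectors of box bounds on the
#'   natural scale; defaults are wide positive intervals, and the `alpha`
#'   bound must lie within (0, 1].
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @param ftol relative objective-change convergence tolerance.
#' @param topology circuit wiring passed to [z_circuit()].
#' @return object of class `fit_config`.
#' @export
fit_config <- function(weighting = c("modulus", "unit", "proportional"),
                       fixed = list(), lower = NULL, upper = NULL,
                       max_iter = 1024, ftol = 1e-10,
                       topology = c("cq_inner", "cq_outer")) {
  weighting <- match.arg(weighting)
  topology <- match.arg(topology)
  if (length(fixed) && !all(names(fixed) %in% FIT_PAR_NAMES)) {
    stop("unknown fixed parameter(s): ",
         paste(setdiff(names(fixed), FIT_PAR_NAMES), collapse = ", "),
         call. = FALSE)
  }
  lo <- c(r_s = 1e-6, c_dl_specific = 1e-6, alpha = 0.01,
          c_q_specific = 1e-6, r_ct = 1e-3, w_mag = 1e-3, b = 1e-6)
  hi <- c(r_s = 1e12, c_dl_specific = 1e6, alpha = 1,
          c_q_specific = 1e6, r_ct = 1e15, w_mag = 1e15, b = 1e6)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(lo <= 0) || any(hi <= lo)) {
    stop("bounds must be positive intervals", call. = FALSE)
  }
  if (lo[["alpha"]] <= 0 || hi[["alpha"]] > 1) {
    stop("'alpha' bounds must lie within (0, 1]", call. = FALSE)
  }
  structure(list(weighting = weighting, fixed = fixed,
                 lower = lo, upper = hi, max_iter = max_iter,
                 ftol = ftol, topology = topology),
            class = "fit_config")
}

#' Graphene fitting protocol preset
#'
#' Convenience configuration mirroring the standard characterisation
#' workflow for graphene microelectrodes: the double-layer capacitance is
#' measured independently on gold electrodes and held fixed, while the
#' quantum capacitance and the remaining elements are fitted from the
#' spectrum.
#'
#' @param c_dl_specific measured double-layer capacitance, uF cm^-2.
#' @param ... further arguments passed to [fit_config()].
#' @return a [fit_config()] with `c_dl_specific` fixed.
#' @export
fit_config_graphene <- function(c_dl_specific, ...) {
  fit_config(fixed = list(c_dl_specific = c_dl_specific), ...)
}

# transforms between natural and unconstrained internal scale
to_internal <- function(v, names) {
  ifelse(names == "alpha", stats::qlogis(pmin(v, 1 - 1e-9)), log(v))
}
from_internal <- function(t, names) {
  ifelse(names == "alpha", stats::plogis(t), exp(t))
}

# residual weights for a measured spectrum
fit_weights <- function(z_meas, weighting) {
  switch(weighting,
    unit = list(re = rep(1, length(z_meas)), im = rep(1, length(z_meas))),
    modulus = {
      w <- 1 / Mod(z_meas)^2
      list(re = w, im = w)
    },
    proportional = list(re = 1 / pmax(Re(z_meas)^2, 1e-300),
                        im = 1 / pmax(Im(z_meas)^2, 1e-300))
  )
}

build_params <- function(values, area_cm2, roughness) {
  circuit_params(r_s = values[["r_s"]],
                 c_dl_specific = values[["c_dl_specific"]],
                 alpha = values[["alpha"]],
                 c_q_specific = values[["c_q_specific"]],
                 r_ct = values[["r_ct"]], w_mag = values[["w_mag"]],
                 b = values[["b"]],
                 area_cm2 = area_cm2, roughness = roughness)
}

#' Data-driven starting parameters for a circuit fit
#'
#' Heuristic initialisation requiring no prior knowledge of the electrode:
#' the series resistance from the real part at the highest frequency, the
#' interfacial capacitance from `1/(omega |Im Z|)` over the lowest decade
#' (used for both the CPE and the quantum capacitance, since only their
#' series combination is visible there), the CPE exponent from the median
#' local log-log slope of `|Z|`, and order-of-magnitude faradaic defaults
#' from the low-frequency real part.
#'
#' @param spectrum an [impedance_spectrum()] with at least 8 frequencies
#'   spanning at least 3 decades.
#' @param area_cm2,roughness geometry carried into the returned object
#'   (not estimated from the spectrum).
#' @return a [circuit_params()] object.
#' @export
initial_guess <- function(spectrum, area_cm2 = 1e-4, roughness = 1) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  f <- spectrum$frequencies
  z <- spectrum$z
  if (length(f) < 8 || log10(max(f) / min(f)) < 3) {
    stop("insufficient span: need >= 8 frequencies over >= 3 decades",
         call. = FALSE)
  }
  r_s <- max(Re(z)[which.max(f)], 1e-3)
  low <- f <= min(f) * 10
  c_tot <- stats::median(1 / (2 * pi * f[low] * pmax(Mod(Im(z[low])), 1e-300)))
  # keep the guess physical even for degenerate (e.g. purely resistive)
  # spectra where Im Z ~ 0 makes the capacitance estimate blow up
  c_tot <- min(max(c_tot, 1e-15), 1)
  spec_scale <- 1e-6 * area_cm2 * roughness
  slopes <- diff(log(Mod(z))) / diff(log(f))
  alpha <- min(max(-stats::median(slopes), 0.05), 1)
  re_low <- max(Re(z)[which.min(f)] - r_s, 1e-3)
  circuit_params(r_s = r_s,
                 c_dl_specific = c_tot / spec_scale,
                 alpha = alpha,
                 c_q_specific = c_tot / spec_scale,
                 r_ct = re_low / 2,
                 w_mag = re_low / 2,
                 b = 1,
                 area_cm2 = area_cm2, roughness = roughness)
}

#' Weighted complex least-squares objective
#'
#' The exact objective minimised by [fit_spectrum()]:
#' `sum_f w_f * |Z_meas(f) - Z_model(f)|^2`, with the real and imaginary
#' residuals weighted according to `weighting` (see [fit_config()]).
#' Zero if and only if the model reproduces the data exactly.
#'
#' @param spectrum an [impedance_spectrum()].
#' @param params a [circuit_params()] object.
#' @param weighting weighting scheme, as in [fit_config()].
#' @inheritParams z_circuit
#' @return non-negative chi-square value.
#' @export
goodness_of_fit <- function(spectrum, params,
                            weighting = c("modulus", "unit", "proportional"),
                            topology = c("cq_inner", "cq_outer")) {
  weighting <- match.arg(weighting)
  z_model <- z_circuit(params, spectrum$frequencies, match.arg(topology))
  w <- fit_weights(spectrum$z, weighting)
  sum(w$re * (Re(spectrum$z) - Re(z_model))^2 +
      w$im * (Im(spectrum$z) - Im(z_model))^2)
}

#' Fit an impedance spectrum to the equivalent circuit
#'
#' Complex nonlinear least squares: minimises the weighted sum of squared
#' real and imaginary residuals over the free parameters within bounds,
#' by Levenberg-Marquardt ([minpack.lm::nls.lm()]) on transformed
#' (log / logistic) parameters. Non-convergence is reported via the
#' `converged` flag, never silently; a rank-deficient Jacobian at the
#' solution sets `singular = TRUE` and drops the standard errors.
#'
#' Because the Warburg magnitude and time parameter trade off against the
#' charge-transfer resistance (the model is nearly linear in their product
#' over much of the frequency range), the objective has local minima. By
#' default the fit therefore runs from a small deterministic set of
#' starting points that vary the Warburg time parameter and the split of
#' the low-frequency resistance between the charge-transfer and diffusion
#' elements, and keeps the solution with the lowest objective.
#'
#' @param spectrum an [impedance_spectrum()].
#' @param config a [fit_config()].
#' @param init optional [circuit_params()] starting point; defaults to
#'   [initial_guess()]. Its `area_cm2` and `roughness` are held fixed.
#' @param multi_start run from the deterministic start grid in addition
#'   to `init` (default) or from `init` only.
#' @return object of class `eis_fit`: `params` (fitted
#'   [circuit_params()]), `se` (named standard errors on the natural
#'   scale, `NA` for fixed parameters), `chi_sq`, `n_freq`, `converged`,
#'   `singular`, `fixed` (names of held parameters), `niter`, `message`.
#' @export
fit_spectrum <- function(spectrum, config = fit_config(), init = NULL,
                         multi_start = TRUE) {
  stopifnot(inherits(spectrum, "impedance_spectrum"),
            inherits(config, "fit_config"))
  if (is.null(init)) init <- initial_guess(spectrum)
  stopifnot(inherits(init, "circuit_params"))

  values <- unlist(init[FIT_PAR_NAMES])
  for (nm in names(config$fixed)) values[[nm]] <- config$fixed[[nm]]
  fixed_names <- names(config$fixed)
  free_names <- setdiff(FIT_PAR_NAMES, fixed_names)
  if (length(free_names) == 0) stop("no free parameters", call. = FALSE)

  # starting points: init itself, plus (optionally) a grid varying the
  # Warburg time parameter b and the r_ct vs (w_mag * b) split of the
  # total faradaic resistance
  starts <- list(values)
  if (multi_start) {
    r_far <- values[["r_ct"]] + values[["w_mag"]] * values[["b"]]
    for (b0 in c(0.1, 0.3, 1)) {
      for (fr in c(0.5, 0.1, 0.01)) {
        v <- values
        v[["b"]] <- b0
        v[["r_ct"]] <- max(fr * r_far, 1e-3)
        v[["w_mag"]] <- max((1 - fr) * r_far / b0, 1e-3)
        starts[[length(starts) + 1]] <- v
      }
    }
  }

  lo <- config$lower[free_names]; hi <- config$upper[free_names]
  w <- fit_weights(spectrum$z, config$weighting)
  sw_re <- sqrt(w$re); sw_im <- sqrt(w$im)
  f <- spectrum$frequencies
  z_meas <- spectrum$z

  resid_fn <- function(theta) {
    v <- values
    v[free_names] <- from_internal(theta, free_names)
    p <- build_params(v, init$area_cm2, init$roughness)
    zm <- z_circuit(p, f, config$topology)
    c(sw_re * (Re(z_meas) - Re(zm)), sw_im * (Im(z_meas) - Im(zm)))
  }

  res <- NULL
  for (st in starts) {
    start <- pmin(pmax(st[free_names], lo * 1.000001), hi * 0.999999)
    # individual starts may stall in a local valley; only the retained
    # best solution's convergence status is reported
    r <- suppressWarnings(minpack.lm::nls.lm(
      par = to_internal(start, free_names), fn = resid_fn,
      lower = to_internal(lo, free_names),
      upper = to_internal(hi, free_names),
      control = minpack.lm::nls.lm.control(
        maxiter = min(config$max_iter, 1024), maxfev = 10000,
        ftol = config$ftol)))
    if (is.null(res) || r$deviance < res$deviance) res <- r
  }

  theta_hat <- res$par
  v_hat <- values
  v_hat[free_names] <- from_internal(theta_hat, free_names)
  params_hat <- build_params(v_hat, init$area_cm2, init$roughness)
  chi_sq <- sum(resid_fn(theta_hat)^2)

  # standard errors: s^2 (J'J)^-1 on the internal scale, delta method back;
  # J by central finite differences at the solution
  n_res <- 2 * length(f)
  p_free <- length(free_names)
  se <- stats::setNames(rep(NA_real_, length(FIT_PAR_NAMES)), FIT_PAR_NAMES)
  singular <- FALSE
  J <- matrix(0, n_res, p_free)
  for (k in seq_len(p_free)) {
    h <- 1e-6 * max(1, abs(theta_hat[k]))
    tp <- theta_hat; tp[k] <- tp[k] + h
    tm <- theta_hat; tm[k] <- tm[k] - h
    J[, k] <- (resid_fn(tp) - resid_fn(tm)) / (2 * h)
  }
  jtj <- crossprod(J)
  cov_t <- tryCatch(solve(jtj), error = function(e) NULL)
  if (is.null(cov_t) || any(!is.finite(diag(cov_t))) || any(diag(cov_t) < 0)) {
    singular <- TRUE
  } else {
    s2 <- chi_sq / max(n_res - p_free, 1)
    se_t <- sqrt(s2 * diag(cov_t))
    # d natural / d internal: value for log params, a(1-a) for logistic
    jac <- ifelse(free_names == "alpha",
                  v_hat[free_names] * (1 - v_hat[free_names]),
                  v_hat[free_names])
    se[free_names] <- se_t * abs(jac)
  }

  structure(list(params = params_hat, se = se, chi_sq = chi_sq,
                 n_freq = length(f),
                 converged = res$info %in% 1:3,
                 singular = singular,
                 fixed = fixed_names,
                 niter = res$niter,
                 message = res$message),
            class = "eis_fit")
}

#' @export
print.eis_fit <- function(x, ...) {
  cat(sprintf("Equivalent-circuit fit: %d frequencies, chi-sq %.4g, %s\n",
              x$n_freq, x$chi_sq,
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$fixed)) cat("  fixed:", paste(x$fixed, collapse = ", "), "\n")
  v <- unlist(x$params[FIT_PAR_NAMES])
  for (nm in FIT_PAR_NAMES) {
    cat(sprintf("  %-14s %12.5g  %s\n", nm, v[[nm]],
                if (is.na(x$se[[nm]])) "" else sprintf("+/- %.3g", x$se[[nm]])))
  }
  invisible(x)
}

#' Impedance magnitude at 1 kHz
#'
#' The standard single-frequency figure of merit for neural recording
#' electrodes: `|Z|` log-log interpolated at exactly 1000 Hz (exact if the
#' grid contains 1 kHz).
#'
#' @param spectrum an [impedance_spectrum()] whose grid spans 1 kHz.
#' @param at frequency of interest, Hz.
#' @return impedance magnitude, Ohm.
#' @export
impedance_at_1khz <- function(spectrum, at = 1000) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  f <- spectrum$frequencies
  if (at < min(f) || at > max(f)) {
    stop(sprintf("%g Hz is outside the measured grid [%g, %g] Hz",
                 at, min(f), max(f)), call. = FALSE)
  }
  exp(stats::approx(log(f), log(Mod(spectrum$z)), xout = log(at))$y)
}
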