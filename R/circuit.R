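#' Equivalent-circuit parameters for a graphene microelectrode
#'
#' Bundles the parameters of the interface model used throughout the
#' package: solution series resistance, a constant phase element (CPE)
#' for the Helmholtz double layer, graphene quantum capacitance in series
#' with the CPE, and a faradaic branch of charge-transfer resistance in
#' series with a bounded Warburg diffusion element.
#'
#' Capacitive magnitudes are given per geometric area (uF cm^-2); the
#' absolute values used in the impedance expressions are
#' `specific * 1e-6 * area_cm2 * roughness`, where `roughness` is the
#' effective/geometric surface-area ratio (>= 1) obtained e.g. from AFM
#' height maps via [effective_area_ratio()].
#'
#' @param r_s series (solution) resistance, Ohm.
#' @param c_dl_specific double-layer CPE magnitude per area, uF cm^-2.
#'   The absolute CPE magnitude has units F s^(alpha-1).
#' @param alpha CPE exponent, in (0, 1]; 1 is an ideal capacitor.
#' @param c_q_specific quantum capacitance per area, uF cm^-2.
#' @param r_ct charge-transfer resistance, Ohm.
#' @param w_mag bounded-Warburg magnitude, Ohm s^-1/2.
#' @param b bounded-Warburg time parameter, s^1/2; the dimensionless
#'   argument of the tanh is `b * sqrt(omega)`.
#' @param area_cm2 geometric electrode area, cm^2 (default 100 um pad).
#' @param roughness effective/geometric area ratio, >= 1.
#' @return object of class `circuit_params`.
#' @seealso [z_circuit()], [simulate_spectrum()], [reference_circuit_params()]
#' @export
circuit_params <- function(r_s, c_dl_specific, alpha, c_q_specific,
                           r_ct, w_mag, b,
                           area_cm2 = 1e-4, roughness = 1) {
  check_positive(r_s, "r_s")
  check_positive(c_dl_specific, "c_dl_specific")
  check_positive(c_q_specific, "c_q_specific")
  check_positive(r_ct, "r_ct")
  check_positive(w_mag, "w_mag")
  check_positive(b, "b")
  check_positive(area_cm2, "area_cm2")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(roughness) || roughness < 1) {
    stop("'roughness' must be >= 1", call. = FALSE)
  }
  structure(
    list(r_s = r_s, c_dl_specific = c_dl_specific, alpha = alpha,
         c_q_specific = c_q_specific, r_ct = r_ct, w_mag = w_mag, b = b,
         area_cm2 = area_cm2, roughness = roughness),
    class = "circuit_params"
  )
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Equivalent-circuit parameters\n")
  cat(sprintf("  R_s    %12.4g Ohm\n", x$r_s))
  cat(sprintf("  CPE    %12.4g uF/cm2 (alpha = %.3f)\n", x$c_dl_specific, x$alpha))
  cat(sprintf("  C_q    %12.4g uF/cm2\n", x$c_q_specific))
  cat(sprintf("  R_ct   %12.4g Ohm\n", x$r_ct))
  cat(sprintf("  W      %12.4g Ohm s^-1/2, B = %.4g s^1/2\n", x$w_mag, x$b))
  cat(sprintf("  area   %g cm2, roughness %.4g\n", x$area_cm2, x$roughness))
  invisible(x)
}

# internal: absolute CPE magnitude (F s^(alpha-1)) and capacitance (F)
abs_c_dl <- function(p) p$c_dl_specific * 1e-6 * p$area_cm2 * p$roughness
abs_c_q <- function(p) p$c_q_specific * 1e-6 * p$area_cm2 * p$roughness

#' Representative fitted circuit parameters for PET and SU-8 devices
#'
#' Loads the packaged representative parameter sets for monolayer-graphene
#' microelectrodes (100 um x 100 um openings) fabricated on PET and SU-8
#' substrates, including the AFM-derived surface roughness ratios
#' (1.5% and 7% above geometric area respectively).
#'
#' @param substrate `"PET"` or `"SU-8"`.
#' @return a [circuit_params()] object.
#' @export
reference_circuit_params <- function(substrate = c("PET", "SU-8")) {
  substrate <- match.arg(substrate)
  file <- if (substrate == "PET") "circuit_pet.json" else "circuit_su8.json"
  read_circuit_params(system.file("extdata", file, package = "flexmea",
                                  mustWork = TRUE))
}

#' Read/write circuit parameters as JSON
#'
#' The JSON schema uses explicit unit-suffixed keys: `r_s_ohm`,
#' `c_dl_uF_per_cm2`, `alpha`, `c_q_uF_per_cm2`, `r_ct_ohm`,
#' `w_mag_ohm_s_neg_half`, `b_s_half`, `area_cm2`, `roughness`.
#'
#' @param path file path.
#' @return `read_circuit_params()` returns a [circuit_params()] object;
#'   `write_circuit_params()` returns `path` invisibly.
#' @export
read_circuit_params <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("r_s_ohm", "c_dl_uF_per_cm2", "alpha", "c_q_uF_per_cm2",
            "r_ct_ohm", "w_mag_ohm_s_neg_half", "b_s_half",
            "area_cm2", "roughness")
  missing <- setdiff(need, names(j))
  if (length(missing)) {
    stop("parameter JSON missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  circuit_params(r_s = j$r_s_ohm, c_dl_specific = j$c_dl_uF_per_cm2,
                 alpha = j$alpha, c_q_specific = j$c_q_uF_per_cm2,
                 r_ct = j$r_ct_ohm, w_mag = j$w_mag_ohm_s_neg_half,
                 b = j$b_s_half, area_cm2 = j$area_cm2,
                 roughness = j$roughness)
}

#' @rdname read_circuit_params
#' @param params a [circuit_params()] object.
#' @export
write_circuit_params <- function(params, path) {
  stopifnot(inherits(params, "circuit_params"))
  j <- list(r_s_ohm = params$r_s, c_dl_uF_per_cm2 = params$c_dl_specific,
            alpha = params$alpha, c_q_uF_per_cm2 = params$c_q_specific,
            r_ct_ohm = params$r_ct, w_mag_ohm_s_neg_half = params$w_mag,
            b_s_half = params$b, area_cm2 = params$area_cm2,
            roughness = params$roughness)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Logarithmic frequency grid
#'
#' @param n number of points.
#' @param fmin,fmax frequency span, Hz. The default 1 Hz to 100 kHz is the
#'   standard span for electrode impedance spectroscopy.
#' @return strictly increasing numeric vector of frequencies, Hz.
#' @export
freq_grid <- function(n = 50, fmin = 1, fmax = 1e5) {
  stopifnot(n >= 1, fmin > 0, fmax > fmin || n == 1)
  10^seq(log10(fmin), log10(fmax), length.out = n)
}

#' Impedance spectrum container
#'
#' Pairs a frequency grid with complex impedance values for one electrode
#' at one timepoint.
#'
#' @param frequencies strictly increasing, strictly positive, Hz.
#' @param z complex impedance per frequency, Ohm.
#' @return object of class `impedance_spectrum` with elements
#'   `frequencies` and `z`.
#' @export
impedance_spectrum <- function(frequencies, z) {
  if (length(frequencies) == 0) stop("empty frequency grid", call. = FALSE)
  check_positive(frequencies, "frequencies")
  if (is.unsorted(frequencies, strictly = TRUE)) {
    stop("'frequencies' must be strictly increasing", call. = FALSE)
  }
  if (length(z) != length(frequencies)) {
    stop("'z' and 'frequencies' must have equal length", call. = FALSE)
  }
  z <- as.complex(z)
  if (any(!is.finite(Re(z)) | !is.finite(Im(z)))) {
    stop("non-finite impedance values", call. = FALSE)
  }
  structure(list(frequencies = frequencies, z = z),
            class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("Impedance spectrum: %d frequencies, %.3g-%.3g Hz, |Z| %.4g-%.4g Ohm\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              min(Mod(x$z)), max(Mod(x$z))))
  invisible(x)
}

#' @export
as.data.frame.impedance_spectrum <- function(x, ...) {
  data.frame(frequency_hz = x$frequencies,
             z_real_ohm = Re(x$z), z_imag_ohm = Im(x$z))
}

#' Read/write an impedance spectrum as CSV
#'
#' CSV columns are `frequency_hz`, `z_real_ohm`, `z_imag_ohm` with a
#' header row.
#'
#' @param path file path.
#' @return `read_spectrum_csv()` returns an [impedance_spectrum()];
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frequency_hz", "z_real_ohm", "z_imag_ohm")
  if (!all(need %in% names(d))) {
    stop("spectrum CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  o <- order(d$frequency_hz)
  impedance_spectrum(d$frequency_hz[o],
                     complex(real = d$z_real_ohm[o], imaginary = d$z_imag_ohm[o]))
}

#' @rdname read_spectrum_csv
#' @param spectrum an [impedance_spectrum()].
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(path)
}

#' Constant phase element impedance
#'
#' `Z = 1 / (Q (j 2 pi f)^alpha)`. At `alpha = 1` this is an ideal
#' capacitor of capacitance `Q`; the phase is `-alpha * 90` degrees at all
#' frequencies.
#'
#' @param q_abs absolute CPE magnitude, F s^(alpha-1).
#' @param alpha CPE exponent in (0, 1].
#' @param freq frequency, Hz (vectorised).
#' @return complex impedance, Ohm.
#' @export
z_cpe <- function(q_abs, alpha, freq) {
  check_positive(q_abs, "q_abs")
  check_positive(freq, "freq")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  }
  1 / (q_abs * (2i * pi * freq)^alpha)
}

#' Ideal capacitor impedance
#'
#' `Z = 1 / (j 2 pi f C)`: purely imaginary with negative imaginary part.
#'
#' @param c capacitance, F.
#' @param freq frequency, Hz (vectorised).
#' @return complex impedance, Ohm.
#' @export
z_capacitor <- function(c, freq) {
  check_positive(c, "c")
  check_positive(freq, "freq")
  1 / (2i * pi * freq * c)
}

#' Bounded (finite-length) Warburg impedance
#'
#' `Z = W tanh(B sqrt(j omega)) / sqrt(j omega)` with `omega = 2 pi f`,
#' using the principal complex square root. As `f -> 0` this tends to the
#' real limit `W * B`; for large `B sqrt(omega)` it approaches the
#' semi-infinite Warburg `W / sqrt(j omega)` with a -45 degree phase.
#' `tanh` is evaluated overflow-safely (its large-argument limit is 1).
#'
#' @param w_mag Warburg magnitude, Ohm s^-1/2.
#' @param b time parameter, s^1/2.
#' @param freq frequency, Hz (vectorised).
#' @return complex impedance, Ohm.
#' @export
z_bounded_warburg <- function(w_mag, b, freq) {
  check_positive(w_mag, "w_mag")
  check_positive(b, "b")
  check_positive(freq, "freq")
  s <- sqrt(2i * pi * freq)          # principal branch
  w_mag * tanh_safe(b * s) / s
}

# complex tanh that saturates instead of overflowing for large |Re(x)|
tanh_safe <- function(x) {
  out <- tanh(x)
  big <- Re(x) > 350
  if (any(big)) out[big] <- 1 + 0i
  small <- Re(x) < -350
  if (any(small)) out[small] <- -1 + 0i
  out
}

#' Full equivalent-circuit impedance
#'
#' Composes the interface model: series resistance `R_s` in series with
#' two parallel branches, a capacitive branch (double-layer CPE in series
#' with the quantum capacitance) and a faradaic branch (`R_ct` in series
#' with the bounded Warburg element):
#'
#' `Z(f) = R_s + ( (Z_CPE + Z_Cq)^-1 + (R_ct + Z_W)^-1 )^-1`
#'
#' The alternative topology `"cq_outer"` places the quantum capacitance in
#' series with the whole parallel network instead, for sensitivity checks
#' against the default wiring.
#'
#' @param params a [circuit_params()] object.
#' @param freq frequency, Hz (vectorised).
#' @param topology `"cq_inner"` (default, quantum capacitance inside the
#'   capacitive branch) or `"cq_outer"`.
#' @return complex impedance, Ohm.
#' @export
z_circuit <- function(params, freq, topology = c("cq_inner", "cq_outer")) {
  stopifnot(inherits(params, "circuit_params"))
  topology <- match.arg(topology)
  z_dl <- z_cpe(abs_c_dl(params), params$alpha, freq)
  z_q <- z_capacitor(abs_c_q(params), freq)
  z_far <- params$r_ct + z_bounded_warburg(params$w_mag, params$b, freq)
  if (topology == "cq_inner") {
    params$r_s + 1 / (1 / (z_dl + z_q) + 1 / z_far)
  } else {
    params$r_s + z_q + 1 / (1 / z_dl + 1 / z_far)
  }
}

#' Simulate a noiseless impedance spectrum
#'
#' Deterministic element-wise evaluation of [z_circuit()] on a frequency
#' grid. For noisy synthetic spectra see [gen_eis_spectrum()].
#'
#' @param params a [circuit_params()] object.
#' @param grid numeric frequency vector, Hz (default [freq_grid()]).
#' @inheritParams z_circuit
#' @return an [impedance_spectrum()].
#' @export
simulate_spectrum <- function(params, grid = freq_grid(),
                              topology = c("cq_inner", "cq_outer")) {
  if (length(grid) == 0) stop("empty frequency grid", call. = FALSE)
  impedance_spectrum(grid, z_circuit(params, grid, match.arg(topology)))
}

#' Effective/geometric surface-area ratio from a height map
#'
#' Triangulates the sampled surface (two triangles per pixel cell, split
#' along a fixed diagonal) and returns total 3-D facet area divided by
#' projected (geometric) area. A flat map gives exactly 1; a plane tilted
#' by angle theta gives `1/cos(theta)`. The ratio feeds the `roughness`
#' field of [circuit_params()].
#'
#' @param heights numeric matrix of surface heights, um; at least 2 x 2.
#' @param pixel_x,pixel_y lateral sample spacing along columns and rows, um.
#' @return dimensionless ratio >= 1.
#' @export
effective_area_ratio <- function(heights, pixel_x, pixel_y) {
  if (!is.matrix(heights) || nrow(heights) < 2 || ncol(heights) < 2) {
    stop("height map must be a matrix of at least 2 x 2", call. = FALSE)
  }
  if (!all(is.finite(heights))) stop("non-finite heights", call. = FALSE)
  check_positive(pixel_x, "pixel_x")
  check_positive(pixel_y, "pixel_y")
  nr <- nrow(heights); nc <- ncol(heights)
  h00 <- heights[-nr, -nc]   # (i, j)
  h10 <- heights[-1, -nc]    # (i+1, j)
  h01 <- heights[-nr, -1]    # (i, j+1)
  h11 <- heights[-1, -1]     # (i+1, j+1)
  # triangle (00, 10, 11): edges u = (0, dy, h10-h00), v = (dx, dy, h11-h00)
  a1 <- tri_area(0, pixel_y, h10 - h00, pixel_x, pixel_y, h11 - h00)
  # triangle (00, 01, 11): edges u = (dx, 0, h01-h00), v = (dx, dy, h11-h00)
  a2 <- tri_area(pixel_x, 0, h01 - h00, pixel_x, pixel_y, h11 - h00)
  sum(a1 + a2) / ((nr - 1) * pixel_y * (nc - 1) * pixel_x)
}

# half-magnitude of cross product of edge vectors (ux,uy,uz) x (vx,vy,vz)
tri_area <- function(ux, uy, uz, vx, vy, vz) {
  cx <- uy * vz - uz * vy
  cy <- uz * vx - ux * vz
  cz <- ux * vy - uy * vx
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}
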