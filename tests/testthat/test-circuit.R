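# Forward model of the electrode-interface equivalent circuit.

test_that("CPE reduces to an ideal capacitor at alpha = 1", {
  f <- c(0.5, 1 / (2 * pi), 10, 1234, 9.9e4)
  expect_equal(z_cpe(2.2e-6, 1, f), z_capacitor(2.2e-6, f))
  # omega = 1 rad/s, unit capacitance: exactly -1i
  expect_equal(z_cpe(1, 1, 1 / (2 * pi)), 0 - 1i)
  expect_equal(z_capacitor(1, 1 / (2 * pi)), 0 - 1i)
})

test_that("element impedances match the high-precision reference values", {
  # frozen from a 50-digit arbitrary-precision evaluation of the closed forms
  expect_equal(z_cpe(1e-6, 0.924, 1000),
               complex(real = 36.845394206284379,
                       imaginary = -307.17064065000339),
               tolerance = 1e-13)
  expect_equal(z_capacitor(1.45e-6 * 1e-4 * 1.015, 1000),
               complex(real = 0, imaginary = -1081399.3075719065),
               tolerance = 1e-13)
  expect_equal(z_bounded_warburg(178e6, 0.565, 1),
               complex(real = 68057658.681948469,
                       imaginary = -40866281.279296834),
               tolerance = 1e-13)
  p <- reference_circuit_params("PET")
  expect_equal(z_circuit(p, 1000),
               complex(real = 85823.456578866382,
                       imaginary = -1506226.4990911753),
               tolerance = 1e-13)
})

test_that("capacitor and CPE phase/scaling behaviour", {
  z1 <- z_capacitor(3.3e-9, 500)
  z2 <- z_capacitor(3.3e-9, 1000)
  expect_equal(Re(z1), 0)
  expect_lt(Im(z1), 0)
  expect_equal(Mod(z2), Mod(z1) / 2)     # |Z| halves when f doubles
  # CPE phase is -alpha * 90 degrees at any frequency
  for (alpha in c(0.3, 0.7, 0.924)) {
    ph <- Arg(z_cpe(1e-7, alpha, c(1, 1e3, 1e5))) * 180 / pi
    expect_equal(ph, rep(-alpha * 90, 3), tolerance = 1e-10)
  }
})

test_that("bounded Warburg limits: resistive at DC, -45 degrees when deep", {
  w <- 178e6; b <- 0.565
  z_dc <- z_bounded_warburg(w, b, 1e-12)
  expect_equal(Re(z_dc), w * b, tolerance = 1e-6)
  expect_lt(abs(Im(z_dc)) / (w * b), 1e-9)
  # large b*sqrt(omega): semi-infinite behaviour
  z <- z_bounded_warburg(w, b, 1e5)
  expect_equal(Arg(z) * 180 / pi, -45, tolerance = 1e-6)
  expect_equal(Mod(z), w / sqrt(2 * pi * 1e5), tolerance = 1e-6)
  # overflow-safe at extreme frequency
  expect_true(is.finite(Mod(z_bounded_warburg(w, b, 1e18))))
})

test_that("non-positive element arguments are rejected", {
  expect_error(z_cpe(-1, 0.9, 10), "positive")
  expect_error(z_cpe(1e-6, 0, 10), "alpha")
  expect_error(z_cpe(1e-6, 1.2, 10), "alpha")
  expect_error(z_capacitor(0, 10), "positive")
  expect_error(z_bounded_warburg(1, -2, 10), "positive")
  expect_error(z_bounded_warburg(1, 1, 0), "positive")
})

test_that("circuit parameter invariants are enforced", {
  expect_error(circuit_params(1e3, 7, 1.1, 1.4, 1e6, 1e8, 0.5), "alpha")
  expect_error(circuit_params(1e3, 7, 0.9, 1.4, 1e6, 1e8, 0.5,
                              roughness = 0.9), "roughness")
  expect_error(circuit_params(-5, 7, 0.9, 1.4, 1e6, 1e8, 0.5), "positive")
})

test_that("full circuit approaches r_s at high frequency (both substrates)", {
  for (sub in c("PET", "SU-8")) {
    p <- reference_circuit_params(sub)
    z <- z_circuit(p, 1e9)
    expect_lt(Mod(z - p$r_s) / p$r_s, 0.001)
  }
})

test_that("full circuit DC limit is r_s + r_ct + w*b (both substrates)", {
  for (sub in c("PET", "SU-8")) {
    p <- reference_circuit_params(sub)
    z <- z_circuit(p, 1e-6)
    expect_equal(Re(z), p$r_s + p$r_ct + p$w_mag * p$b, tolerance = 0.01)
  }
})

test_that("alternative topology differs but shares the r_s limit", {
  p <- reference_circuit_params("PET")
  z_in <- z_circuit(p, 100)
  z_out <- z_circuit(p, 100, topology = "cq_outer")
  expect_false(isTRUE(all.equal(z_in, z_out)))
  expect_lt(Mod(z_circuit(p, 1e12, topology = "cq_outer") - p$r_s) / p$r_s,
            0.001)
})

test_that("simulate_spectrum is element-wise z_circuit and |Z| decreases", {
  p <- reference_circuit_params("PET")
  s1 <- simulate_spectrum(p, grid = 1234)
  expect_equal(s1$z, z_circuit(p, 1234))
  expect_error(simulate_spectrum(p, grid = numeric(0)), "empty")
  for (sub in c("PET", "SU-8")) {
    s <- simulate_spectrum(reference_circuit_params(sub))
    expect_true(all(diff(Mod(s$z)) <= 0))
  }
})

test_that("spectrum container validates and round-trips through CSV", {
  expect_error(impedance_spectrum(c(10, 1), c(1 + 0i, 2 + 0i)), "increasing")
  expect_error(impedance_spectrum(c(1, 10), c(1 + 0i, NaN + 0i)), "finite")
  expect_error(impedance_spectrum(c(-1, 10), c(1 + 0i, 1 + 0i)), "positive")
  s <- simulate_spectrum(reference_circuit_params("SU-8"), freq_grid(12))
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(s, path)
  s2 <- read_spectrum_csv(path)
  expect_equal(s2$frequencies, s$frequencies, tolerance = 1e-12)
  expect_equal(s2$z, s$z, tolerance = 1e-12)
})

test_that("parameter JSON round-trips and validates keys", {
  p <- reference_circuit_params("PET")
  path <- tempfile(fileext = ".json")
  write_circuit_params(p, path)
  p2 <- read_circuit_params(path)
  expect_equal(unclass(p2), unclass(p), tolerance = 1e-12)
  jsonlite::write_json(list(r_s_ohm = 1), path, auto_unbox = TRUE)
  expect_error(read_circuit_params(path), "missing keys")
})

test_that("effective area ratio: flat = 1, tilted plane = 1/cos(theta)", {
  flat <- matrix(2.5, 8, 9)
  expect_equal(effective_area_ratio(flat, 0.5, 0.5), 1)
  # plane rising along columns at slope tan(theta)
  theta <- 25 * pi / 180
  px <- 0.4
  plane <- matrix(rep((0:9) * px * tan(theta), each = 7), 7, 10)
  expect_equal(effective_area_ratio(plane, px, 0.3), 1 / cos(theta),
               tolerance = 1e-12)
})

test_that("effective area ratio matches direct triangulation on rough maps", {
  h <- withr::with_seed(11, matrix(rnorm(9 * 7, sd = 0.3), 9, 7))
  got <- effective_area_ratio(h, 0.8, 1.1)
  expect_equal(got, oracle_area_ratio(h, 0.8, 1.1), tolerance = 1e-12)
  expect_gte(got, 1)
  # invariant under uniform rescaling of all three dimensions
  expect_equal(effective_area_ratio(3 * h, 3 * 0.8, 3 * 1.1), got,
               tolerance = 1e-12)
  expect_error(effective_area_ratio(matrix(1, 1, 5), 1, 1), "2 x 2")
})
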