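# Seeded generators: determinism, calibration, and round trips through
# the consuming modules.

test_that("all generators are pure functions of their seed", {
  p <- reference_circuit_params("PET")
  expect_identical(gen_eis_spectrum(p, seed = 5), gen_eis_spectrum(p, seed = 5))
  expect_false(identical(gen_eis_spectrum(p, seed = 5)$z,
                         gen_eis_spectrum(p, seed = 6)$z))
  a <- gen_impedance_timecourse(seed = 2)
  b <- gen_impedance_timecourse(seed = 2)
  expect_identical(a, b)
  expect_identical(gen_permeation_image(day_index = 4, seed = 3),
                   gen_permeation_image(day_index = 4, seed = 3))
  e1 <- gen_ecog(n_trials = 3, seed = 4)
  e2 <- gen_ecog(n_trials = 3, seed = 4)
  expect_identical(e1$trace$samples, e2$trace$samples)
  expect_identical(e1$protocol$onsets, e2$protocol$onsets)
  # generators draw from distinct substreams of one top-level seed
  expect_false(substream_seed(1, "eis") == substream_seed(1, "ecog"))
})

test_that("zero-noise spectrum equals the deterministic forward model", {
  p <- reference_circuit_params("SU-8")
  expect_identical(gen_eis_spectrum(p, noise_frac = 0, seed = 1)$z,
                   simulate_spectrum(p)$z)
})

test_that("spectrum noise is calibrated to the requested fraction", {
  p <- reference_circuit_params("PET")
  grid <- freq_grid(10)
  z0 <- Mod(z_circuit(p, grid))
  reps <- vapply(1:200, function(sd)
    Re(gen_eis_spectrum(p, grid, noise_frac = 0.01, seed = sd)$z),
    numeric(10))
  emp <- apply(reps, 1, sd) / z0
  # sd(Re Z) = noise_frac * |Z| under the multiplicative complex model
  expect_true(all(abs(emp / 0.01 - 1) < 0.15))
})

test_that("impedance timecourse follows the drop-then-plateau profile", {
  prof <- list(z0 = 1.1e6, z_plateau = 5.85e5, tau_days = 3)
  days <- seq(0, 30, 3)
  # tau -> infinity: flat at z0 (noise off)
  flat <- gen_impedance_timecourse(4, days,
                                   profile = list(z0 = 1e6, z_plateau = 9.99e5,
                                                  tau_days = 1e12),
                                   noise = list(channel_sdlog = 0,
                                                obs_sdlog = 0), seed = 0)
  expect_equal(flat[[1]]$z_1khz, rep(1e6, length(days)), tolerance = 1e-5)
  # 64-channel mean tracks the noiseless profile within 3%
  chs <- gen_impedance_timecourse(64, days, profile = prof, seed = 0)
  m <- sapply(seq_along(days), function(i)
    mean(vapply(chs, function(ch) ch$z_1khz[i], 0)))
  truth <- prof$z_plateau + (prof$z0 - prof$z_plateau) * exp(-days / prof$tau_days)
  expect_true(all(abs(m / truth - 1) < 0.03))
  # the mean impedance drops early then stabilises
  expect_gt(m[1], m[4])
  expect_lt(abs(m[9] / m[11] - 1), 0.1)
})

test_that("injected failures round-trip through failure-day detection", {
  chs <- gen_impedance_timecourse(6, days = 1:14,
                                  failures = data.frame(channel = c(2, 5),
                                                        day = c(8, 3)),
                                  seed = 1)
  expect_equal(detect_failure_day(chs[[2]]), 8)
  expect_equal(detect_failure_day(chs[[5]]), 3)
  expect_true(is.na(detect_failure_day(chs[[1]])))
  expect_true(all(is.na(chs[[2]]$z_1khz[chs[[2]]$days >= 8])))
})

test_that("permeation images grow as scheduled and start clean", {
  img0 <- gen_permeation_image(day_index = 0, seed = 0)
  res0 <- analyze_permeation(img0, attr(img0, "boundary"), attr(img0, "roi"),
                             method = "fixed", threshold = 0.5)
  expect_equal(res0$area_percent, 0)
  expect_equal(res0$max_distance_um, 0)
  # 9 days at 2 um/day reaches 18 um within a pixel
  img9 <- gen_permeation_image(day_index = 9, growth_um_per_day = 2, seed = 0)
  res9 <- analyze_permeation(img9, attr(img9, "boundary"), attr(img9, "roi"),
                             method = "fixed", threshold = 0.5)
  expect_equal(res9$max_distance_um, 18, tolerance = 1 / 18)
  # non-decreasing area and distance across the schedule
  days <- seq(0, 30, 5)
  dist <- area <- numeric(length(days))
  for (k in seq_along(days)) {
    im <- gen_permeation_image(day_index = days[k], seed = 0)
    r <- analyze_permeation(im, attr(im, "boundary"), attr(im, "roi"),
                            method = "fixed", threshold = 0.5)
    dist[k] <- r$max_distance_um
    area[k] <- r$area_percent
  }
  expect_true(all(diff(dist) >= 0))
  expect_true(all(diff(area) >= 0))
})

test_that("ECoG generator: protocol structure and null response", {
  sim <- gen_ecog(n_trials = 12, seed = 2)
  gaps <- diff(sim$protocol$onsets)
  expect_true(all(gaps >= 7 & gaps <= 9))
  expect_true(all(sim$protocol$orientation %in% seq(0, 330, 30)))
  # amplitude 0, gain 1: the stimulus-locked average tends to zero
  null <- gen_ecog(n_trials = 100,
                   response = list(latency_ms = 70, amplitude_uV = 0,
                                   band = c(140, 200), band_gain = 1),
                   seed = 0)
  ev <- epoch_and_average(null$trace, null$protocol, window = c(0.5, 1))
  floor_rms <- rms_noise(null$trace) / sqrt(100)
  expect_lt(rms_noise(recording_trace(ev$average, 1000)), 3 * floor_rms)
})

test_that("injected latency and band gain are recovered downstream", {
  sim <- gen_ecog(n_trials = 40, seed = 0)
  ev <- epoch_and_average(sim$trace, sim$protocol, window = c(0.5, 1))
  expect_identical(ev$n_trials, 40L)
  lat <- onset_latency(ev)
  expect_lt(abs(lat - 70), 2)
  sp <- band_power_spectrogram(sim$trace, sim$protocol, band = c(140, 200))
  expect_gt(mean(sp$band_db[sp$time > 0.5 & sp$time < 3.5]), 3)
  expect_lt(abs(mean(sp$band_db[sp$time < 0])), 1)
})
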