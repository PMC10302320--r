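test_that("stratum corneum capacitance matches hand-evaluated values", {
  # frozen values computed by direct evaluation of the coaxial-capacitor
  # formula 2*pi*eps0*eps_r*l / log((d + d_sc)/d)
  g1 <- electrode_geometry(d_sc = 800e-6, eps_r = 1e3)
  expect_equal(stratum_corneum_capacitance(g1), 3.56597e-8,
               tolerance = 1e-4)
  g2 <- electrode_geometry(d_sc = 100e-6, eps_r = 1e4)
  expect_equal(stratum_corneum_capacitance(g2), 2.76631e-6,
               tolerance = 1e-4)

  # linear in eps_r and l_elec
  g3 <- electrode_geometry(d_sc = 800e-6, eps_r = 2e3)
  expect_equal(stratum_corneum_capacitance(g3) /
                 stratum_corneum_capacitance(g1), 2)
  g4 <- electrode_geometry(d_sc = 800e-6, eps_r = 1e3, l_elec = 0.090)
  expect_equal(stratum_corneum_capacitance(g4) /
                 stratum_corneum_capacitance(g1), 2)
})

test_that("capacitance is strictly decreasing in SC thickness", {
  d_grid <- seq(10e-6, 800e-6, length.out = 50)
  caps <- vapply(d_grid, function(d)
    stratum_corneum_capacitance(electrode_geometry(d_sc = d)), numeric(1))
  expect_true(all(diff(caps) < 0))
  expect_true(all(caps > 0))
})

test_that("invalid geometry and circuit parameters are rejected", {
  expect_error(electrode_geometry(d_sc = -1e-6), "positive")
  expect_error(electrode_geometry(d_sc = 0.02), "smaller")
  expect_error(electrode_geometry(eps_r = 0.5), "positive|>= 1")
  expect_error(circuit_params(C_cpl = 0), "positive")
  expect_error(circuit_params(R_in = Inf), "finite")
})

test_that("high-pass cutoff reproduces the device operating points", {
  expect_equal(highpass_cutoff(circuit_params(C_cpl = 0.3e-12)),
               10.61, tolerance = 1e-3)
  expect_equal(highpass_cutoff(circuit_params(C_cpl = 100e-12)),
               0.0318, tolerance = 1e-2)
  expect_equal(highpass_cutoff(circuit_params(C_cpl = 0.1e-12)),
               31.83, tolerance = 1e-3)
  # unit normalization
  expect_equal(highpass_cutoff(circuit_params(R_in = 1 / (2 * pi),
                                              C_cpl = 1)), 1)
})

test_that("transfer function has the right limits", {
  p <- circuit_params(C_cpl = 0.3e-12)
  expect_identical(transfer_function(p, 0), 0 + 0i)
  expect_equal(Mod(transfer_function(p, 1e4)), 1, tolerance = 0.01)
  expect_error(transfer_function(p, -1), "non-negative")
})

test_that("with negligible skin impedance the response is one-pole", {
  p <- circuit_params(R_sc = 1e-3, C_sc = 1e-15, C_cpl = 0.3e-12)
  fc <- highpass_cutoff(p)
  f <- 10^seq(log10(0.01), log10(100), length.out = 200)
  h <- Mod(transfer_function(p, f))
  expect_equal(h, f / sqrt(f^2 + fc^2), tolerance = 1e-6)
})

test_that("simulated measurement kills DC and passes the -3 dB point", {
  fs <- 200
  # constant input decays to zero
  sim <- simulate_measurement(rep(1, 10 * fs), fs, circuit_params())
  expect_lt(abs(sim$output_signal[10 * fs]), 1e-3)
  expect_lt(abs(mean(sim$output_signal)), 0.01 * 1)

  # sinusoid at the cutoff: amplitude ratio ~ 1/sqrt(2)
  p <- circuit_params(R_sc = 1e-3, C_sc = 1e-15, C_cpl = 0.3e-12)
  fc <- highpass_cutoff(p)
  t <- (0:(20 * fs)) / fs
  sine <- sin(2 * pi * fc * t)
  out <- simulate_measurement(sine, fs, p)$output_signal
  ss <- out[(10 * fs):(20 * fs)]          # steady state
  expect_equal(max(abs(ss)), 1 / sqrt(2), tolerance = 0.02)

  expect_error(simulate_measurement(numeric(0), fs, p), "empty")
})

test_that("output power never exceeds input power (passive network)", {
  fs <- 200
  x <- template_train(duration_s = 20)
  for (cc in c(0.1e-12, 1e-12, 100e-12)) {
    out <- simulate_measurement(x, fs, circuit_params(C_cpl = cc))
    expect_lte(mean(out$output_signal^2), mean(x^2) * (1 + 1e-9))
  }
})

test_that("strong coupling distortion flips the post-T lobe negative", {
  fs <- 200
  x <- template_train(duration_s = 30, hr = 60)
  out <- simulate_measurement(x, fs, circuit_params(C_cpl = 0.3e-12))
  # post-T phase window of a mid-recording beat (beat 10, cycle 1 s): the
  # input holds a positive T lobe, the filtered output dips clearly below it
  idx <- (10 * fs + round(0.60 * fs)):(10 * fs + round(0.75 * fs))
  expect_gt(max(x[idx]), 0.25)
  expect_gt(min(x[idx]), -0.05)                  # input: no negative lobe
  expect_lt(min(out$output_signal[idx]), -0.05)  # output turns negative
  expect_lt(max(out$output_signal[idx]), 0.1)    # T lobe largely removed
})

test_that("simulation is deterministic", {
  x <- template_train(duration_s = 15)
  s1 <- simulate_measurement(x, 200, circuit_params())
  s2 <- simulate_measurement(x, 200, circuit_params())
  expect_identical(s1$output_signal, s2$output_signal)
})

test_that("morphology sweep approaches the clean template as C_cpl grows", {
  fs <- 200
  x <- template_train(duration_s = 40, hr = 60)
  grid <- c(0.1e-12, 0.5e-12, 2e-12, 10e-12, 100e-12)
  sw <- morphology_sweep(x, fs, grid)
  expect_length(sw, length(grid))
  expect_true(all(!vapply(sw, `[[`, logical(1), "failed")))

  pk <- detect_r_peaks(x, fs)
  clean_cycle <- average_morphology(segment_beats(x, pk$indices))$cycle
  cors <- vapply(sw, function(s) stats::cor(s$cycle, clean_cycle),
                 numeric(1))
  expect_true(all(diff(cors) > 0))        # monotone in C_cpl
  expect_gt(cors[length(cors)], 0.99)     # near-identity filter

  # single grid point equals simulate + average of that signal
  one <- morphology_sweep(x, fs, 2e-12)[[1]]
  sim <- simulate_measurement(x, fs, circuit_params(C_cpl = 2e-12))
  pk2 <- detect_r_peaks(sim$output_signal, fs)
  ref <- average_morphology(segment_beats(sim$output_signal, pk2$indices))
  expect_equal(one$cycle, ref$cycle)
})
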