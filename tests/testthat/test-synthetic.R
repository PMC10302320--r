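test_that("heart-cycle template has its maximum at the R phase", {
  tmpl <- generate_template()
  phase <- seq(0, 1 - 1 / 200, length.out = 200)
  expect_equal(phase[which.max(tmpl)], attr(tmpl, "r_phase"))
  expect_equal(mean(tmpl), 0, tolerance = 1e-12)
  expect_identical(generate_template(), generate_template())
  expect_error(generate_template(qrs_amp = 0), "positive")
})

test_that("suppressing the P wave leaves its phase window flat", {
  t0 <- generate_template(p_amp = 0)
  t1 <- generate_template(p_amp = 0.15)
  p_window <- 30:55                        # phase 0.145-0.27
  expect_lt(diff(range(t0[p_window])), 1e-4)
  expect_gt(diff(range(t1[p_window])), 0.05)
  # no-P template stays below 5% of the R amplitude in the P window
  expect_lt(max(abs(t0[p_window] - stats::median(t0))), 0.05 * max(t0))
})

test_that("RR series: NSR regularity, AF irregularity, determinism", {
  rr0 <- generate_rr_series("NSR", mean_hr = 75, variability = 0,
                            duration_s = 60, seed = 4)
  expect_true(all(rr0 == 60 / 75))
  expect_gte(sum(rr0), 60)

  # coefficients of variation on long series
  rr_nsr <- generate_rr_series("NSR", 70, duration_s = 5000, seed = 8)
  rr_af <- generate_rr_series("AF", 70, duration_s = 5000, seed = 8)
  cv <- function(x) stats::sd(x) / mean(x)
  expect_gt(cv(rr_af), 3 * cv(rr_nsr))
  expect_gt(cv(rr_af), 0.15)
  # AF draws are serially uncorrelated; NSR modulation is correlated
  expect_lt(abs(stats::cor(rr_af[-1], rr_af[-length(rr_af)])), 0.05)
  expect_gt(stats::cor(rr_nsr[-1], rr_nsr[-length(rr_nsr)]), 0.5)

  expect_identical(generate_rr_series("AF", 70, duration_s = 60, seed = 3),
                   generate_rr_series("AF", 70, duration_s = 60, seed = 3))
  expect_error(generate_rr_series("NSR", mean_hr = 250), "\\[30, 200\\]")
})

test_that("quality label rule is monotone in corruption", {
  expect_identical(quality_label_rule(Inf, 0), 0L)
  expect_identical(quality_label_rule(15, 0), 1L)
  expect_identical(quality_label_rule(8, 0), 2L)
  expect_identical(quality_label_rule(3, 0), 3L)
  expect_identical(quality_label_rule(30, 0.5), 3L)
  # lowering snr never lowers the label, at any artifact fraction
  for (af in c(0, 0.05, 0.2, 0.5)) {
    labs <- vapply(seq(30, 0, by = -1), quality_label_rule,
                   integer(1), artifact_frac = af)
    expect_true(all(diff(labs) >= 0))
  }
})

test_that("synthesized recordings honour their configuration", {
  out <- synthesize_recording(synthetic_config(seed = 5, snr_db = Inf,
                                               powerline_amp = 0))
  expect_identical(out$truth$quality_label, 0L)
  expect_s3_class(out$recording, "ecg_recording")
  expect_length(out$recording$samples, 60 * 200)
  expect_true(all(diff(out$truth$r_peaks) > 0))

  # leading 3 s artifact: ground-truth window covers exactly the first 3 s
  out2 <- synthesize_recording(synthetic_config(
    seed = 5, snr_db = 25,
    artifact_spec = data.frame(start_s = 0, dur_s = 3, kind = "burst")))
  expect_equal(out2$truth$artifact_windows$start, 0)
  expect_equal(out2$truth$artifact_windows$end, 600)
  expect_identical(out2$truth$quality_label, 1L)  # 5% artifact samples

  # overlapping artifact windows are merged with a warning
  expect_warning(
    synthesize_recording(synthetic_config(
      seed = 5, snr_db = 25,
      artifact_spec = data.frame(start_s = c(1, 3), dur_s = c(3, 3),
                                 kind = "burst"))),
    "merged")
})

test_that("inverted recordings violate the alignment inequality", {
  flips <- vapply(1:30, function(s) {
    x <- synthesize_recording(synthetic_config(seed = s, snr_db = 25,
                                               inverted = TRUE))
    mean(x$recording$samples) > stats::median(x$recording$samples)
  }, logical(1))
  expect_gte(mean(flips), 0.95)
  uprights <- vapply(1:30, function(s) {
    x <- synthesize_recording(synthetic_config(seed = s, snr_db = 25))
    mean(x$recording$samples) < stats::median(x$recording$samples)
  }, logical(1))
  expect_gte(mean(uprights), 0.95)
})

test_that("generation is fully deterministic under seed", {
  a <- synthesize_recording(synthetic_config(seed = 77, snr_db = 15,
                                             rhythm = "AF"))
  b <- synthesize_recording(synthetic_config(seed = 77, snr_db = 15,
                                             rhythm = "AF"))
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth, b$truth)
})

test_that("generated datasets follow the requested label mix", {
  ds0 <- generate_dataset(20, label_mix = c(1, 0, 0, 0), seed = 2)
  expect_true(all(vapply(ds0, function(d) d$truth$quality_label,
                         integer(1)) == 0L))

  ds <- generate_dataset(400, seed = 3)
  labs <- vapply(ds, function(d) d$truth$quality_label, integer(1))
  freq <- tabulate(labs + 1L, 4) / 400
  target <- c(0.1183, 0.6797, 0.1910, 0.0110)
  # binomial 3-sigma bounds at n = 400
  expect_true(all(abs(freq - target) <=
                    3 * sqrt(target * (1 - target) / 400) + 1e-9))

  d1 <- generate_dataset(5, seed = 9)
  d2 <- generate_dataset(5, seed = 9)
  expect_identical(lapply(d1, function(d) d$recording$samples),
                   lapply(d2, function(d) d$recording$samples))
})

test_that("device decision stand-in reacts to RR dispersion", {
  expect_identical(simulate_device_decision(rep(0.8, 60)), "normal")
  expect_error(simulate_device_decision(rep(0.8, 5)), "undecided")

  af_hits <- vapply(1:1000, function(s)
    simulate_device_decision(
      generate_rr_series("AF", 75, duration_s = 60, seed = s)) == "AF",
    logical(1))
  expect_gte(mean(af_hits), 0.95)

  nsr_hits <- vapply(1:200, function(s)
    simulate_device_decision(
      generate_rr_series("NSR", 75, duration_s = 60, seed = s)) == "normal",
    logical(1))
  expect_gte(mean(nsr_hits), 0.95)

  expect_identical(simulate_device_decision(
    generate_rr_series("AF", 75, duration_s = 60, seed = 1),
    threshold = Inf), "normal")
})
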