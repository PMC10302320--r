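test_that("windowing arithmetic drops the trailing remainder", {
  fs <- 200
  expect_length(window_signal(numeric(60 * fs), fs), 12)
  expect_length(window_signal(numeric(59 * fs), fs), 11)
  expect_length(window_signal(numeric(60 * fs), fs)[[1]], 1000)
  expect_error(window_signal(numeric(7 * fs), fs), "too short")
})

test_that("window eCDF is a valid CDF on the shared grid", {
  w <- rnorm(500)
  grid <- seq(min(w), max(w), length.out = 50)
  e <- window_ecdf(w, grid)
  expect_true(all(diff(e) >= 0))
  expect_gte(e[1], 0)
  expect_equal(e[50], 1)                       # grid covers the max
  expect_identical(window_ecdf(rev(w), grid), e)  # amplitude-only statistic
  # constant window: step function at that value
  ec <- window_ecdf(rep(0.5, 100), grid)
  expect_true(all(ec[grid < 0.5] == 0) && all(ec[grid >= 0.5] == 1))
})

test_that("CCmax equals its brute-force definition", {
  set.seed(42)
  base <- rnorm(80)
  vecs <- c(replicate(5, base, simplify = FALSE), list(rnorm(80)))
  cc <- max_correlation(vecs, N = 5)

  # direct enumeration over all pairs
  brute <- vapply(1:6, function(i) {
    cors <- vapply(setdiff(1:6, i), function(j)
      stats::cor(vecs[[i]], vecs[[j]]), numeric(1))
    mean(sort(cors, decreasing = TRUE)[1:5])
  }, numeric(1))
  expect_equal(cc, brute, tolerance = 1e-12)

  # the 5 identical windows: 4 perfect correlations + the noise one
  rho_noise <- stats::cor(base, vecs[[6]])
  expect_equal(cc[1], (4 + rho_noise) / 5, tolerance = 1e-12)

  # permutation equivariance
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(max_correlation(vecs[perm], N = 5), cc[perm])

  expect_error(max_correlation(vecs[1:4], N = 5), "at least")
  expect_warning(max_correlation(c(vecs, list(rep(1, 80))), N = 5),
                 "zero-variance")
})

test_that("clean recordings produce no artifact flags", {
  for (s in 1:5) {
    a <- detect_artifacts(clean_fixture(seed = s)$recording)
    expect_identical(sum(a$mask), 0L)
  }
  # irregular rhythm is not mistaken for motion artifact
  for (s in 1:5) {
    a <- detect_artifacts(clean_fixture(seed = s, rhythm = "AF",
                                        snr_db = 25)$recording)
    expect_identical(sum(a$mask), 0L)
  }
  expect_error(detect_artifacts(numeric(20 * 200), fs = 200), "30 s")
})

test_that("a leading motion artifact flags exactly its window", {
  out <- synthesize_recording(synthetic_config(
    seed = 3, snr_db = 25,
    artifact_spec = data.frame(start_s = 0, dur_s = 3, kind = "burst")))
  a <- detect_artifacts(out$recording)
  expect_identical(which(a$mask), 1L)
})

test_that("longest valid segment respects the 30 s guideline rule", {
  fs <- 200
  seg <- longest_valid_segment(rep(FALSE, 12), fs)
  expect_equal(seg$T_seg, 60)
  expect_identical(seg$start, 1L)

  seg2 <- longest_valid_segment(c(TRUE, rep(FALSE, 11)), fs)
  expect_equal(seg2$T_seg, 55)
  expect_identical(seg2$start, 1000L + 1L)

  expect_error(longest_valid_segment(rep(c(TRUE, FALSE), 6), fs),
               "excluded")
  expect_error(longest_valid_segment(c(rep(FALSE, 5), rep(TRUE, 7)), fs),
               "excluded")
  # earliest maximal run wins ties
  seg3 <- longest_valid_segment(
    c(rep(FALSE, 6), TRUE, rep(FALSE, 6)), fs, min_duration_s = 30)
  expect_identical(seg3$start, 1L)
})

test_that("inversion correction follows the amplitude-distribution rule", {
  up <- clean_fixture(seed = 2)$recording$samples
  r1 <- correct_inversion(up)
  expect_false(r1$inverted)
  expect_identical(r1$samples, up)

  r2 <- correct_inversion(-up)
  expect_true(r2$inverted)
  expect_identical(r2$samples, up)

  # idempotence on R-dominated ECG: a second application changes nothing
  r3 <- correct_inversion(r2$samples)
  expect_false(r3$inverted)

  # tie mean == median resolves to inverted
  expect_true(correct_inversion(rep(1, 100))$inverted)
})

test_that("R-peak detection finds the planted beats", {
  out <- clean_fixture(seed = 6, mean_hr = 60)
  pp <- preprocess_recording(out$recording)
  expect_true(pp$valid)
  det <- pp$peaks$indices + pp$segment$start - 1L
  tru <- out$truth$r_peaks
  expect_equal(length(det), length(tru))
  # every true beat matched within 40 ms
  expect_true(all(vapply(tru, function(p) min(abs(det - p)) <= 8,
                         logical(1))))
  expect_error(detect_r_peaks(numeric(15 * 200), 200), "failed")
  expect_error(detect_r_peaks(numeric(200), 200), "10 s")
})

test_that("peak detection is invariant to amplitude scaling", {
  x <- clean_fixture(seed = 7)$recording$samples
  p1 <- detect_r_peaks(x, 200)
  p2 <- detect_r_peaks(10 * x, 200)
  expect_identical(p1$indices, p2$indices)
})

test_that("heart-rate gate accepts only physiological rates", {
  mk <- function(rr_s) {
    idx <- cumsum(c(1, rep(round(rr_s * 200), 30)))
    structure(list(indices = idx, rr_ms = diff(idx) * 5,
                   median_hr = 60000 / stats::median(diff(idx) * 5)),
              class = "peak_list")
  }
  expect_true(validate_heart_rate(mk(1.0)))    # 60 bpm
  expect_false(validate_heart_rate(mk(0.3)))   # 200 bpm
  expect_false(validate_heart_rate(mk(1.6)))   # 37.5 bpm
  expect_false(validate_heart_rate(structure(list(indices = 1),
                                             class = "peak_list")))
})

test_that("preprocessing reports reason codes instead of raising", {
  # heavy artifacts split the recording below 30 s of clean tracing
  art <- data.frame(start_s = 27, dur_s = 6, kind = "burst")
  out <- synthesize_recording(synthetic_config(seed = 4, snr_db = 25,
                                               artifact_spec = art))
  pp <- preprocess_recording(out$recording)
  expect_false(pp$valid)
  expect_identical(pp$reason, "too_short_segment")

  ok <- preprocess_recording(clean_fixture(seed = 4)$recording)
  expect_true(ok$valid)
  expect_identical(ok$reason, "ok")
})

test_that("artifact masks recover the planted window across seeds", {
  hits <- vapply(1:25, function(s) {
    start <- 5 * (s %% 10)                 # window-aligned burst
    out <- synthesize_recording(synthetic_config(
      seed = s, snr_db = 25,
      artifact_spec = data.frame(start_s = start, dur_s = 5,
                                 kind = "burst")))
    a <- detect_artifacts(out$recording)
    identical(which(a$mask), as.integer(s %% 10 + 1))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
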