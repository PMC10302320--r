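# The 22-entry multi-domain feature vector: statistical, time-domain,
# frequency-domain and morphology-related descriptors of one preprocessed
# recording.

#' Names of the 22 features, in canonical order
#' @export
aisqa_feature_names <- c(
  "mean", "median", "std", "skewness", "kurtosis",
  "mean_hr", "sdnn", "coverage", "ecdf_consistency", "signal_consistency",
  "fft_consistency", "bas_sqi", "qrs_sqi", "pli_sqi", "snr", "mean_sqi",
  "r_amp", "template_std", "eucl_dist", "cityblock_dist", "dtw_dist",
  "proto_cc")

# Feature-subgroup column indices, in the canonical order above.
aisqa_feature_groups <- list(
  statistical = 1:5, time = 6:10, frequency = 11:16, morphology = 17:22)

#' Statistical amplitude features
#'
#' Mean, median, sample standard deviation, bias-corrected skewness and raw
#' kurtosis (fourth standardized moment; 3 for a normal distribution) of the
#' valid segment. For a constant segment skewness and kurtosis are defined
#' as 0.
#'
#' @param segment Numeric signal (the valid, inversion-corrected segment).
#' @return Named numeric vector of length 5.
#' @export
statistical_features <- function(segment) {
  n <- length(segment)
  s <- stats::sd(segment)
  if (s == 0) {
    skew <- 0; kurt <- 0
  } else {
    m <- segment - mean(segment)
    m2 <- mean(m^2)
    g1 <- mean(m^3) / m2^1.5
    skew <- g1 * sqrt(n * (n - 1)) / (n - 2)  # bias-corrected (type 2)
    kurt <- mean(m^4) / m2^2                   # raw 4th moment; normal -> 3
  }
  c(mean = mean(segment), median = stats::median(segment), std = s,
    skewness = skew, kurtosis = kurt)
}

#' Time-domain features
#'
#' Mean heart rate and SDNN from the RR series, valid-segment coverage, the
#' mean eCDF window-consistency correlation, and the DTW distance between
#' the averaged morphologies of the segment's first and second halves
#' (signal consistency).
#'
#' @param segment Numeric valid segment.
#' @param fs Sampling rate (Hz).
#' @param peaks `peak_list` for the segment.
#' @param analysis `artifact_analysis` of the recording.
#' @param t_seg Valid-segment duration (s).
#' @param n_points Cycle grid length for the half-segment morphologies.
#' @return Named numeric vector of length 5.
#' @export
time_domain_features <- function(segment, fs, peaks, analysis, t_seg,
                                 n_points = 200) {
  rr_s <- peaks$rr_ms / 1000
  if (length(rr_s) < 2) stop("need at least 2 RR intervals", call. = FALSE)
  half <- length(segment) %/% 2
  half_morph <- function(x) {
    pk <- detect_r_peaks(x, fs)
    average_morphology(segment_beats(x, pk$indices), n_points)$cycle
  }
  # if either half defeats peak detection, compare the raw halves on a
  # common grid instead (still a DTW self-consistency measure)
  sig_cons <- tryCatch(
    dtw_distance(half_morph(segment[1:half]),
                 half_morph(segment[(half + 1):length(segment)])),
    error = function(e)
      dtw_distance(resample_to_cycle(segment[1:half], n_points),
                   resample_to_cycle(segment[(half + 1):length(segment)],
                                     n_points)))
  c(mean_hr = 60 / mean(rr_s),
    sdnn = stats::sd(peaks$rr_ms),
    coverage = t_seg,
    ecdf_consistency = mean(analysis$cc_ecdf),
    signal_consistency = sig_cons)
}

#' Welch power spectral density
#'
#' Hann-windowed averaged periodogram (4 s windows, 50\% overlap by
#' default); the frequency resolution of 0.25 Hz resolves the 0-1 Hz
#' baseline-wander band.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param window_s Window length (s).
#' @param overlap Fractional overlap.
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, window_s = 4, overlap = 0.5) {
  nw <- min(length(x), round(window_s * fs))
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))  # Hann
  u <- sum(w^2)
  acc <- numeric(floor(nw / 2) + 1L)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2
    acc <- acc + p[seq_along(acc)]
  }
  psd <- acc / (length(starts) * u * fs)
  # one-sided scaling (double all but DC and Nyquist)
  if (length(psd) > 2) psd[2:(length(psd) - 1L)] <- 2 * psd[2:(length(psd) - 1L)]
  list(freq = seq(0, fs / 2, length.out = length(psd)), psd = psd)
}

# Integrated band power [f1, f2] from a welch_psd result.
band_power <- function(pw, f1, f2) {
  sel <- pw$freq >= f1 & pw$freq <= f2
  sum(pw$psd[sel])
}

#' Frequency-domain features
#'
#' Spectral signal-quality indices from Welch band powers `P(f1, f2)`:
#' baseline SQI `1 - P(0,1)/P(0,40)`, QRS SQI `P(5,15)/P(5,40)`, power-line
#' SQI `1 - P(49,51)/P(1,60)` (50 Hz mains), in-band/out-of-band SNR
#' `10 log10(P(5,40)/P(40,100))` dB, the mean FFT window-consistency
#' correlation and the mean of the three SQIs.
#'
#' @param segment Numeric valid segment.
#' @param fs Sampling rate (Hz).
#' @param analysis `artifact_analysis` of the recording.
#' @return Named numeric vector of length 6.
#' @export
frequency_domain_features <- function(segment, fs, analysis) {
  pw <- welch_psd(segment, fs)
  nyq <- fs / 2
  bas <- 1 - band_power(pw, 0, 1) / band_power(pw, 0, 40)
  qrs <- band_power(pw, 5, 15) / band_power(pw, 5, 40)
  pli <- 1 - band_power(pw, 49, 51) / band_power(pw, 1, 60)
  snr <- 10 * log10(band_power(pw, 5, 40) / band_power(pw, 40, nyq))
  c(fft_consistency = mean(analysis$cc_fft),
    bas_sqi = bas, qrs_sqi = qrs, pli_sqi = pli, snr = snr,
    mean_sqi = (bas + qrs + pli) / 3)
}

#' Morphology-related features
#'
#' Mean R-peak amplitude (the only amplitude-carrying morphology feature),
#' mean pointwise standard deviation of the averaged morphology, and four
#' similarity measures between the amplitude-normalized (unit R amplitude)
#' mean morphology and its best-matching ideal prototype: Euclidean
#' distance, cityblock (L1) distance, DTW distance and Pearson correlation.
#' The best match is the prototype with the smallest DTW distance.
#'
#' @param morph `beat_morphology` of the valid segment.
#' @param peaks `peak_list` (for R amplitudes).
#' @param segment Numeric valid segment (inversion-corrected, mV).
#' @param prototypes List of normalized prototype cycles.
#' @return Named numeric vector of length 6.
#' @export
morphology_features <- function(morph, peaks, segment, prototypes) {
  stopifnot(length(prototypes) >= 1)
  r_amp <- mean(segment[peaks$indices])
  cyc <- morph$cycle
  cyc_n <- cyc / max(abs(cyc))
  d_dtw <- vapply(prototypes, function(p) dtw_distance(cyc_n, p), numeric(1))
  best <- prototypes[[which.min(d_dtw)]]
  c(r_amp = r_amp,
    template_std = mean(morph$std_curve),
    eucl_dist = sqrt(sum((cyc_n - best)^2)),
    cityblock_dist = sum(abs(cyc_n - best)),
    dtw_dist = min(d_dtw),
    proto_cc = stats::cor(cyc_n, best))
}

#' Extract the 22-feature vector of one recording
#'
#' Runs preprocessing (unless a `preprocessed_ecg` is supplied) and computes
#' the four feature families in the canonical order of
#' [aisqa_feature_names]. Recordings failing preprocessing raise an error
#' carrying the failure reason; they never yield a vector of NaNs.
#'
#' @param recording An [ecg_recording()] or a `preprocessed_ecg`.
#' @param prototypes List of normalized prototype cycles (e.g. from
#'   [build_prototypes()] `$prototypes` or [read_prototypes()]).
#' @param n_points Cycle grid length.
#' @return Named numeric vector of length 22.
#' @export
extract_features <- function(recording, prototypes, n_points = 200) {
  pp <- if (inherits(recording, "preprocessed_ecg")) recording
        else preprocess_recording(recording)
  if (!pp$valid)
    stop(sprintf("recording failed preprocessing: %s", pp$reason),
         call. = FALSE)
  fs <- pp$recording$fs
  seg <- pp$samples
  beats <- segment_beats(seg, pp$peaks$indices)
  morph <- average_morphology(beats, n_points)
  v <- c(statistical_features(seg),
         time_domain_features(seg, fs, pp$peaks, pp$analysis,
                              pp$segment$T_seg, n_points),
         frequency_domain_features(seg, fs, pp$analysis),
         morphology_features(morph, pp$peaks, seg, prototypes))
  names(v) <- aisqa_feature_names
  if (!all(is.finite(v)))
    stop(sprintf("non-finite features: %s",
                 paste(aisqa_feature_names[!is.finite(v)], collapse = ", ")),
         call. = FALSE)
  v
}

#' Extract features for a whole dataset
#'
#' @param dataset List of `(recording, truth)` pairs or of
#'   [ecg_recording()]s.
#' @param prototypes Normalized prototype cycles.
#' @return A data frame with `id`, `label` (if available), the 22 feature
#'   columns, and attribute `failures` (data frame of id/reason for
#'   recordings that failed preprocessing).
#' @export
extract_features_dataset <- function(dataset, prototypes) {
  rows <- list(); fails <- list()
  for (item in dataset) {
    rec <- if (inherits(item, "ecg_recording")) item else item$recording
    lab <- if (!is.null(rec$expert_label)) rec$expert_label
           else if (!is.null(item$truth)) item$truth$quality_label
           else NA
    v <- tryCatch(extract_features(rec, prototypes), error = function(e) e)
    if (inherits(v, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(id = rec$id, reason = conditionMessage(v))
    } else {
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(id = rec$id, label = lab),
              as.data.frame(as.list(v)))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), label = numeric(0))
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(id = character(0), reason = character(0))
  out
}
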