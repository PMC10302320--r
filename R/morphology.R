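# Heart-cycle morphology: beat segmentation, cycle-percentage resampling,
# averaged morphology, DTW distances and prototype clustering/selection.

#' Segment a signal into beats at R peaks
#'
#' Beat *i* spans the half-open sample range from R peak *i* to R peak
#' *i + 1*; the partial cycles before the first and after the last peak are
#' dropped.
#'
#' @param samples Numeric signal.
#' @param peaks R-peak sample indices (strictly increasing, at least 4).
#' @return List of numeric beats (length `length(peaks) - 1`).
#' @export
segment_beats <- function(samples, peaks) {
  if (length(peaks) < 4) stop("too few beats: need at least 4 R peaks",
                              call. = FALSE)
  stopifnot(all(diff(peaks) > 0), peaks[length(peaks)] <= length(samples))
  lapply(seq_len(length(peaks) - 1L),
         function(i) samples[peaks[i]:(peaks[i + 1L] - 1L)])
}

#' Resample a beat onto the heart-cycle-percentage grid
#'
#' Linear interpolation of one beat onto `n_points` uniformly spaced cycle
#' percentages in `[0, 100)`, making morphologies comparable independently
#' of the instantaneous heart rate.
#'
#' @param beat Numeric vector (>= 4 samples).
#' @param n_points Cycle grid length (default 200).
#' @return Numeric vector of length `n_points`.
#' @export
resample_to_cycle <- function(beat, n_points = 200) {
  if (length(beat) < 4) stop("beat too short", call. = FALSE)
  stats::approx(x = seq(0, 1, length.out = length(beat) + 1L)[-(length(beat) + 1L)],
                y = beat,
                xout = seq(0, 1 - 1 / n_points, length.out = n_points),
                rule = 2)$y
}

#' Average beat morphology on the cycle grid
#'
#' @param beats List of beats (from [segment_beats()]), at least 3.
#' @param n_points Cycle grid length.
#' @return A `beat_morphology`: `cycle` (pointwise mean), `std_curve`
#'   (pointwise standard deviation), `n_beats`.
#' @export
average_morphology <- function(beats, n_points = 200) {
  if (length(beats) < 3) stop("too few beats: need at least 3", call. = FALSE)
  m <- vapply(beats, resample_to_cycle, numeric(n_points),
              n_points = n_points)
  structure(list(cycle = rowMeans(m),
                 std_curve = apply(m, 1, stats::sd),
                 n_beats = length(beats)),
            class = "beat_morphology")
}

#' Dynamic time warping distance
#'
#' Classic dynamic-programming alignment cost between two sequences with
#' absolute-difference local cost, unit steps (match, insertion, deletion)
#' and an optional Sakoe-Chiba band restricting warping. The distance is
#' symmetric and zero iff the sequences are identical; like all DTW costs it
#' is not a metric (no triangle inequality).
#'
#' @param a,b Numeric sequences.
#' @param band Band half-width as a fraction of the longer length
#'   (default 0.1); `band >= 1` removes the constraint.
#' @return Non-negative alignment cost.
#' @export
dtw_distance <- function(a, b, band = 0.1) {
  .dtw_cost(as.numeric(a), as.numeric(b), band)
}

# Pairwise DTW distance matrix for a list of equal-role sequences.
dtw_distance_matrix <- function(seqs, band = 0.1) {
  n <- length(seqs)
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- dtw_distance(seqs[[i]], seqs[[j]], band)
  }
  d
}

#' Cluster averaged morphologies into prototype groups
#'
#' Partitions a set of mean-beat morphologies by their pairwise DTW
#' distances using k-medoids (PAM) on the precomputed distance matrix, then
#' summarises each cluster by the pointwise average and standard deviation
#' of its members and by its membership fraction. PAM's build/swap search is
#' deterministic, so the partition is reproducible by construction.
#'
#' @param morphologies List of numeric cycle vectors (equal length, >= k).
#' @param k Number of clusters (default 4).
#' @param band DTW band fraction.
#' @param seed Retained for interface stability; the partition does not
#'   depend on it.
#' @return A `prototype_set`: `clusters` (list of `mean`, `std`, `fraction`,
#'   `members`), `assignment`, `k`, `selected` (initially `NULL`).
#' @export
cluster_prototypes <- function(morphologies, k = 4, band = 0.1, seed = 1) {
  n <- length(morphologies)
  if (n < k) stop("need at least k morphologies", call. = FALSE)
  d <- dtw_distance_matrix(morphologies, band)
  if (all(d == 0)) {
    assignment <- rep(1L, n)
    warning("all morphologies identical: single effective cluster",
            call. = FALSE)
  } else {
    assignment <- cluster::pam(stats::as.dist(d), k = k,
                               diss = TRUE, cluster.only = TRUE)
  }
  mat <- do.call(cbind, morphologies)
  clusters <- lapply(seq_len(k), function(ci) {
    mem <- which(assignment == ci)
    if (length(mem) == 0)
      return(list(mean = NULL, std = NULL, fraction = 0,
                  members = integer(0), empty = TRUE))
    sub <- mat[, mem, drop = FALSE]
    list(mean = rowMeans(sub),
         std = if (length(mem) > 1) apply(sub, 1, stats::sd)
               else rep(0, nrow(sub)),
         fraction = length(mem) / n,
         members = mem, empty = FALSE)
  })
  structure(list(clusters = clusters, assignment = assignment, k = k,
                 selected = NULL),
            class = "prototype_set")
}

#' Select the ideal prototype clusters
#'
#' Encodes the prototype-selection criteria (high membership coverage,
#' minimum morphology variance) as a greedy rule: clusters are added in
#' increasing order of their mean pointwise standard deviation until the
#' cumulative membership fraction reaches `coverage_target`. The selected
#' cluster means become the ideal prototypes against which morphology
#' similarity features are computed (downstream features use the best match
#' over the selected prototypes).
#'
#' @param prototype_set A `prototype_set` from [cluster_prototypes()].
#' @param coverage_target Required cumulative membership (default 0.90).
#' @return The `prototype_set` with `selected` (cluster indices, in
#'   selection order) filled in.
#' @export
select_prototypes <- function(prototype_set, coverage_target = 0.90) {
  stopifnot(inherits(prototype_set, "prototype_set"))
  cl <- prototype_set$clusters
  nonempty <- which(vapply(cl, function(c) !isTRUE(c$empty), logical(1)))
  mean_std <- vapply(nonempty, function(i) mean(cl[[i]]$std), numeric(1))
  ord <- nonempty[order(mean_std)]
  cum <- 0
  sel <- integer(0)
  for (i in ord) {
    sel <- c(sel, i)
    cum <- cum + cl[[i]]$fraction
    if (cum >= coverage_target) break
  }
  prototype_set$selected <- sel
  prototype_set
}

#' Build ideal prototypes from a synthetic dataset
#'
#' Reproduces the reference-prototype construction: take the recordings
#' rated *excellent* (label 0) with normal sinus rhythm, preprocess each,
#' average its beats on the cycle grid, cluster the averaged morphologies by
#' DTW distance and select the low-variance clusters covering ~90% of the
#' members.
#'
#' @param dataset List of `(recording, truth)` pairs from
#'   [generate_dataset()] (or any list of [ecg_recording()]s with
#'   `expert_label`/rhythm available).
#' @param k,coverage_target,band See [cluster_prototypes()] and
#'   [select_prototypes()].
#' @param n_points Cycle grid length.
#' @return A selected `prototype_set` with an extra `prototypes` element:
#'   list of normalized (unit R amplitude) prototype cycles.
#' @export
build_prototypes <- function(dataset, k = 4, coverage_target = 0.90,
                             band = 0.1, n_points = 200) {
  morphs <- list()
  for (item in dataset) {
    rec <- item$recording
    lab <- if (!is.null(rec$expert_label)) rec$expert_label else
      item$truth$quality_label
    rhy <- if (!is.null(item$truth$rhythm)) item$truth$rhythm else "NSR"
    if (!identical(lab, 0L) && !identical(lab, 0)) next
    if (!identical(rhy, "NSR")) next
    pp <- preprocess_recording(rec)
    if (!pp$valid) next
    beats <- tryCatch(segment_beats(pp$samples, pp$peaks$indices),
                      error = function(e) NULL)
    if (is.null(beats)) next
    morphs[[length(morphs) + 1L]] <-
      average_morphology(beats, n_points)$cycle
  }
  if (length(morphs) < k)
    stop("not enough excellent NSR recordings to build prototypes",
         call. = FALSE)
  ps <- select_prototypes(cluster_prototypes(morphs, k = k, band = band),
                          coverage_target)
  ps$prototypes <- lapply(ps$selected, function(i) {
    m <- ps$clusters[[i]]$mean
    m / max(abs(m))                       # unit R amplitude
  })
  ps
}

#' Write / read prototype sets as plain text
#'
#' Prototypes are persisted as a CSV (`cycle_pct, cluster, mean, std`) plus a
#' JSON manifest (`k`, `coverage`, `selected`).
#'
#' @param ps A selected `prototype_set` from [build_prototypes()].
#' @param csv_path,json_path Output paths.
#' @return `write_prototypes`: invisibly, the CSV path. `read_prototypes`:
#'   a list with `prototypes` (normalized cycles) and `manifest`.
#' @export
write_prototypes <- function(ps, csv_path, json_path = sub("\\.csv$", ".json",
                                                           csv_path)) {
  stopifnot(!is.null(ps$selected))
  rows <- do.call(rbind, lapply(ps$selected, function(i) {
    cl <- ps$clusters[[i]]
    n <- length(cl$mean)
    data.frame(cycle_pct = seq(0, 100 - 100 / n, length.out = n),
               cluster = i, mean = cl$mean, std = cl$std)
  }))
  utils::write.csv(rows, csv_path, row.names = FALSE)
  manifest <- list(k = ps$k, selected = ps$selected,
                   coverage = sum(vapply(ps$selected,
                     function(i) ps$clusters[[i]]$fraction, numeric(1))))
  jsonlite::write_json(manifest, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_prototypes
#' @export
read_prototypes <- function(csv_path, json_path = sub("\\.csv$", ".json",
                                                      csv_path)) {
  rows <- utils::read.csv(csv_path)
  manifest <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  protos <- lapply(split(rows, rows$cluster),
                   function(d) d$mean[order(d$cycle_pct)] /
                     max(abs(d$mean)))
  list(prototypes = unname(protos), manifest = manifest)
}
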