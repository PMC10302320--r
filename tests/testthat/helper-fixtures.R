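# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Shipped synthetic prototype set (normalized cycles).
get_prototypes <- function() {
  if (is.null(.fixtures$protos)) {
    path <- system.file("extdata", "prototypes_synthetic.csv",
                        package = "aisqa")
    .fixtures$protos <- read_prototypes(path)$prototypes
  }
  .fixtures$protos
}

# A clean 60 s NSR recording plus its ground truth.
clean_fixture <- function(seed = 1, snr_db = 30, ...) {
  synthesize_recording(synthetic_config(seed = seed, snr_db = snr_db, ...))
}

# Small mixed-grade dataset reused by feature/model tests.
get_small_dataset <- function() {
  if (is.null(.fixtures$small_ds))
    .fixtures$small_ds <- generate_dataset(
      40, label_mix = c(0.3, 0.3, 0.3, 0.1), seed = 101)
  .fixtures$small_ds
}

get_small_features <- function() {
  if (is.null(.fixtures$small_ft))
    .fixtures$small_ft <- extract_features_dataset(get_small_dataset(),
                                                   get_prototypes())
  .fixtures$small_ft
}

# Independent DTW oracle: shortest path on the alignment DAG (igraph),
# same local cost and band definition, different algorithm.
dtw_oracle <- function(a, b, band = 1) {
  n <- length(a); m <- length(b)
  w <- if (band >= 1) max(n, m) else
    max(ceiling(band * max(n, m)), abs(n - m))
  id <- function(i, j) (i - 1) * m + j
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (i in 1:n) for (j in max(1, i - w):min(m, i + w)) {
    for (d in list(c(1, 0), c(0, 1), c(1, 1))) {
      i2 <- i + d[1]; j2 <- j + d[2]
      if (i2 <= n && j2 <= m && abs(i2 - j2) <= w) {
        from <- c(from, id(i, j)); to <- c(to, id(i2, j2))
        wt <- c(wt, abs(a[i2] - b[j2]))
      }
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to))
  igraph::E(g)$weight <- wt
  abs(a[1] - b[1]) +
    igraph::distances(g, v = id(1, 1), to = id(n, m), mode = "out")[1, 1]
}

# Clean template-train signal (no noise, no distortion) at a given HR.
template_train <- function(duration_s = 60, fs = 200, hr = 60,
                           p_amp = 0.15) {
  tmpl <- generate_template(p_amp = p_amp)
  rr <- rep(60 / hr, ceiling(duration_s * hr / 60) + 2)
  n <- duration_s * fs
  beat_start <- c(0, cumsum(rr))
  t <- (seq_len(n) - 1) / fs
  k <- findInterval(t, beat_start)
  ph <- pmin((t - beat_start[k]) / rr[pmin(k, length(rr))], 1 - 1e-9)
  stats::approx(seq(0, 1 - 1 / 200, length.out = 200), tmpl, xout = ph,
                rule = 2)$y
}
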