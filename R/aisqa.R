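# Gaussian process regression of the 22-feature description onto the
# continuous signal quality index on [0, 3] ("AISQA"). This file holds the
# package's central model-fitting function and its S3 methods.

# ---- kernels ---------------------------------------------------------------

# Kernel value on a Euclidean distance matrix r. pars: list(l, sf2, alpha).
kernel_eval <- function(kernel, r, pars) {
  l <- pars$l; sf2 <- pars$sf2
  switch(kernel,
    exponential = sf2 * exp(-r / l),
    matern52 = {
      s <- sqrt(5) * r / l
      sf2 * (1 + s + s^2 / 3) * exp(-s)
    },
    rational_quadratic = {
      a <- pars$alpha
      sf2 * (1 + r^2 / (2 * a * l^2))^(-a)
    },
    stop("unknown kernel: ", kernel, call. = FALSE))
}

n_kernel_pars <- function(kernel)
  if (kernel == "rational_quadratic") 4L else 3L

# theta = log(l, sf, sn[, alpha]); returns pars list
unpack_theta <- function(kernel, theta) {
  pars <- list(l = exp(theta[1]), sf2 = exp(2 * theta[2]),
               sn2 = exp(2 * theta[3]))
  if (kernel == "rational_quadratic") pars$alpha <- exp(theta[4])
  pars
}

# Negative log marginal likelihood of the centred targets.
gp_nll <- function(theta, kernel, r, y) {
  pars <- unpack_theta(kernel, theta)
  K <- kernel_eval(kernel, r, pars)
  diag(K) <- diag(K) + pars$sn2 + 1e-8
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  as.numeric(0.5 * crossprod(y, alpha) + sum(log(diag(L))) +
               length(y) / 2 * log(2 * pi))
}

gp_fit_kernel <- function(kernel, r, y, seed, restarts = 3) {
  d_med <- stats::median(r[upper.tri(r)])
  if (!is.finite(d_med) || d_med <= 0) d_med <- 1
  sy <- stats::sd(y); if (sy == 0) sy <- 1e-3
  base <- c(log(d_med), log(sy), log(0.3 * sy))
  if (kernel == "rational_quadratic") base <- c(base, log(1))
  starts <- with_seed(seed, {
    lapply(seq_len(restarts), function(i) {
      if (i == 1) base else base + stats::rnorm(length(base), sd = 0.7)
    })
  })
  fits <- lapply(starts, function(th0) {
    tryCatch(stats::optim(th0, gp_nll, kernel = kernel, r = r, y = y,
                          method = "L-BFGS-B",
                          lower = base - 8, upper = base + 8,
                          control = list(maxit = 200)),
             error = function(e) list(value = Inf))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  list(theta = best$par, nll = best$value)
}

# ---- data plumbing ---------------------------------------------------------

resolve_xy <- function(features, labels) {
  if (is.data.frame(features)) {
    if (is.null(labels) && "label" %in% names(features))
      labels <- features$label
    x <- as.matrix(features[, intersect(aisqa_feature_names,
                                        names(features)), drop = FALSE])
  } else x <- as.matrix(features)
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (!all(is.finite(labels)) || any(labels < 0 | labels > 3))
    stop("labels must be finite and within [0, 3]", call. = FALSE)
  if (nrow(x) != length(labels)) stop("feature/label length mismatch",
                                      call. = FALSE)
  list(x = x, y = as.numeric(labels))
}

#' Stratified holdout split
#'
#' Splits a feature table into disjoint, exhaustive train and test sets with
#' a fixed holdout fraction, stratified by the quality label so all grades
#' appear in both sets where possible; reproducible under `seed`.
#'
#' @param features Data frame (e.g. from [extract_features_dataset()]); the
#'   stratification uses its `label` column when present.
#' @param holdout_fraction Fraction held out for testing (default 0.2).
#' @param seed Integer seed.
#' @param stratify Logical; stratify by label when available.
#' @return List with `train` and `test` data frames and integer attribute
#'   vectors `train_idx`, `test_idx`.
#' @export
split_holdout <- function(features, holdout_fraction = 0.2, seed = 1,
                          stratify = TRUE) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 1)
  n <- nrow(features)
  if (n < 25) stop("need at least 25 records to split", call. = FALSE)
  lab <- if (stratify && "label" %in% names(features))
    round(features$label) else rep(0L, n)
  test_idx <- with_seed(seed, {
    unlist(lapply(unique(lab), function(l) {
      idx <- which(lab == l)
      k <- round(length(idx) * holdout_fraction)
      if (k == 0 || k == length(idx)) k <- max(1L, min(length(idx) - 1L, k))
      sample(idx, k)
    }))
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  miss <- setdiff(unique(lab), unique(lab[train_idx]))
  if (length(miss))
    warning("quality class absent from training split: ",
            paste(miss, collapse = ", "), call. = FALSE)
  out <- list(train = features[train_idx, , drop = FALSE],
              test = features[test_idx, , drop = FALSE])
  attr(out, "train_idx") <- train_idx
  attr(out, "test_idx") <- test_idx
  out
}

# ---- the model -------------------------------------------------------------

#' Fit the AISQA quality-index model
#'
#' Gaussian process regression from the 22-feature signal description onto
#' the continuous quality index on `[0, 3]`. Features are standardized on
#' the training statistics; kernel hyperparameters (length-scale, signal
#' variance, homoscedastic noise variance and, for the rational quadratic
#' kernel, the shape parameter) are fitted by marginal-likelihood
#' maximization with seeded multi-start L-BFGS. Out-of-fold predictions
#' from a label-stratified k-fold cross-validation are stored for model
#' selection reporting. Length-scales are isotropic.
#'
#' @param features Feature matrix or data frame (22 canonical columns; a
#'   `label` column, when present, supplies `labels`).
#' @param labels Numeric quality labels in `[0, 3]` (may be continuous).
#' @param kernel One of `"exponential"` (absolute-exponential, Matern 1/2),
#'   `"matern52"`, `"rational_quadratic"`.
#' @param cv_folds Folds for out-of-fold reporting (default 5; 0 disables).
#' @param seed Integer seed for restarts and fold assignment.
#' @param restarts Optimizer restarts (default 3).
#' @return An object of class `aisqa`.
#' @examples
#' \donttest{
#' set.seed(1)
#' x <- matrix(rnorm(60 * 4), 60)
#' y <- pmin(3, pmax(0, 1.5 + x[, 1] + 0.2 * rnorm(60)))
#' fit <- aisqa(x, y, kernel = "exponential", cv_folds = 0)
#' predict(fit, x[1:3, , drop = FALSE])
#' }
#' @export
aisqa <- function(features, labels = NULL,
                  kernel = c("exponential", "matern52",
                             "rational_quadratic"),
                  cv_folds = 5, seed = 1, restarts = 3) {
  kernel <- match.arg(kernel)
  xy <- resolve_xy(features, labels)
  x <- xy$x; y <- xy$y
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  mu <- mean(y)
  r <- as.matrix(stats::dist(xs))
  fit <- gp_fit_kernel(kernel, r, y - mu, seed, restarts)
  pars <- unpack_theta(kernel, fit$theta)
  K <- kernel_eval(kernel, r, pars)
  diag(K) <- diag(K) + pars$sn2 + 1e-8
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y - mu))

  obj <- structure(list(
    kernel = kernel, theta = fit$theta, pars = pars, nll = fit$nll,
    x_train = xs, y_train = y, y_mean = mu, center = ctr, scale = scl,
    alpha = alpha, chol_K = L, seed = seed,
    n = length(y), cv_folds = cv_folds,
    feature_names = colnames(x), call = match.call()),
    class = "aisqa")

  if (cv_folds >= 2) {
    folds <- with_seed(seed + 1L, {
      f <- integer(length(y))
      for (l in unique(round(y))) {
        idx <- which(round(y) == l)
        f[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
      }
      f
    })
    cv_pred <- numeric(length(y))
    for (k in seq_len(cv_folds)) {
      tr <- folds != k
      rk <- r[tr, tr, drop = FALSE]
      muk <- mean(y[tr])
      fitk <- gp_fit_kernel(kernel, rk, y[tr] - muk, seed + k, restarts = 1)
      pk <- unpack_theta(kernel, fitk$theta)
      Kk <- kernel_eval(kernel, rk, pk)
      diag(Kk) <- diag(Kk) + pk$sn2 + 1e-8
      Lk <- chol(Kk)
      ak <- backsolve(Lk, forwardsolve(t(Lk), y[tr] - muk))
      ks <- kernel_eval(kernel, r[!tr, tr, drop = FALSE], pk)
      cv_pred[!tr] <- pmin(3, pmax(0, muk + as.numeric(ks %*% ak)))
    }
    obj$cv <- list(folds = folds, pred = cv_pred,
                   rmse = sqrt(mean((cv_pred - y)^2)),
                   mae = mean(abs(cv_pred - y)),
                   rho = if (stats::sd(cv_pred) > 0 && stats::sd(y) > 0)
                     stats::cor(cv_pred, y) else NA_real_)
  }
  obj
}

#' Predict the quality index for new recordings
#'
#' Posterior mean of the Gaussian process, clipped to `[0, 3]`; optionally
#' the posterior standard deviation of the latent quality function.
#'
#' @param object An `aisqa` fit.
#' @param newdata Feature matrix/data frame (canonical 22 columns) or a
#'   single feature vector.
#' @param se.fit Return posterior standard deviations as well.
#' @param ... Unused.
#' @return Numeric predictions in `[0, 3]`, or a list `fit`/`se.fit`.
#' @export
predict.aisqa <- function(object, newdata, se.fit = FALSE, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (is.data.frame(newdata))
    newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  if (ncol(newdata) != length(object$center))
    stop(sprintf("expected %d features, got %d", length(object$center),
                 ncol(newdata)), call. = FALSE)
  if (!all(is.finite(newdata))) stop("non-finite features", call. = FALSE)
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  r <- cross_dist(xs, object$x_train)
  ks <- kernel_eval(object$kernel, r, object$pars)
  mu <- object$y_mean + as.numeric(ks %*% object$alpha)
  fit <- pmin(3, pmax(0, mu))
  if (!se.fit) return(fit)
  v <- backsolve(object$chol_K, t(ks), transpose = TRUE)
  var_f <- pmax(0, object$pars$sf2 - colSums(v^2))
  list(fit = fit, se.fit = sqrt(var_f))
}

# Euclidean cross-distance matrix (rows of a) x (rows of b).
cross_dist <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' @export
print.aisqa <- function(x, ...) {
  cat("AISQA Gaussian process regression\n")
  cat(sprintf("  kernel: %s   n = %d   features = %d\n",
              x$kernel, x$n, length(x$center)))
  cat(sprintf("  length-scale %.3g, signal sd %.3g, noise sd %.3g%s\n",
              x$pars$l, sqrt(x$pars$sf2), sqrt(x$pars$sn2),
              if (!is.null(x$pars$alpha))
                sprintf(", alpha %.3g", x$pars$alpha) else ""))
  if (!is.null(x$cv))
    cat(sprintf("  %d-fold CV: RMSE %.3f, MAE %.3f, rho %.3f\n",
                x$cv_folds, x$cv$rmse, x$cv$mae, x$cv$rho))
  invisible(x)
}

#' @export
coef.aisqa <- function(object, ...) {
  out <- c(length_scale = object$pars$l,
           signal_sd = sqrt(object$pars$sf2),
           noise_sd = sqrt(object$pars$sn2))
  if (!is.null(object$pars$alpha)) out <- c(out, alpha = object$pars$alpha)
  out
}

#' @export
fitted.aisqa <- function(object, ...)
  predict(object, unscale_features(object))

#' @export
residuals.aisqa <- function(object, ...)
  object$y_train - fitted(object)

unscale_features <- function(object)
  sweep(sweep(object$x_train, 2, object$scale, "*"), 2, object$center)

#' @export
summary.aisqa <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object, residuals = res,
                 train_rmse = sqrt(mean(res^2)),
                 train_mae = mean(abs(res)), cv = object$cv),
            class = "summary.aisqa")
}

#' @export
print.summary.aisqa <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  in-sample: RMSE %.3f, MAE %.3f\n", x$train_rmse,
              x$train_mae))
  cat("  residual quartiles:\n")
  print(stats::quantile(x$residuals))
  invisible(x)
}

#' Plot out-of-fold predictions against labels
#'
#' @param x An `aisqa` fit (with cross-validation results).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.aisqa <- function(x, ...) {
  pred <- if (!is.null(x$cv)) x$cv$pred else fitted(x)
  graphics::plot(x$y_train + stats::runif(x$n, -0.05, 0.05), pred,
                 xlab = "reference quality label",
                 ylab = if (!is.null(x$cv)) "out-of-fold AISQA"
                        else "fitted AISQA",
                 ylim = c(0, 3), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate from the model's posterior
#'
#' Draws from the Gaussian process posterior of the latent quality function
#' at the training inputs (clipped to `[0, 3]`).
#'
#' @param object An `aisqa` fit.
#' @param nsim Number of draws.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Matrix `n x nsim`.
#' @export
simulate.aisqa <- function(object, nsim = 1, seed = 1, ...) {
  r <- as.matrix(stats::dist(object$x_train))
  K <- kernel_eval(object$kernel, r, object$pars)
  v <- backsolve(object$chol_K, K, transpose = TRUE)
  post_cov <- K - crossprod(v)
  post_mean <- object$y_mean + as.numeric(K %*% object$alpha)
  ev <- eigen(post_cov, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  with_seed(seed, {
    z <- matrix(stats::rnorm(object$n * nsim), object$n)
    draws <- post_mean + rt %*% z
    matrix(pmin(3, pmax(0, draws)), object$n, nsim)
  })
}
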