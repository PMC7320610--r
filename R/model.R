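## The single-kernel classifier: feature groups concatenated into one kernel,
## train-only standardization, a regularized kernel machine (kernel ridge on
## the +/-1 labels), and a monotone sigmoid (Platt) calibration mapping
## decision values to scores in [0,1]. Labels are "+" iff score >= 0.5.

#' Kernel classifier configuration
#'
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param bandwidth RBF bandwidth sigma: a positive number or
#'   `"median-heuristic"` (median pairwise training distance, data-adaptive
#'   and deterministic).
#' @param regularization ridge penalty lambda (> 0, default 1).
#' @param standardize standardize columns using training means/SDs
#'   (population convention) before the kernel (default TRUE).
#' @param calibration `"sigmoid-fit"` (Platt scaling, default) or `"none"`
#'   (a fixed logistic squashing of the decision value).
#' @param seed integer recorded in training metadata (the fit itself is
#'   deterministic and draws no random numbers).
#' @return list of class `model_config`.
#' @export
model_config <- function(kernel = c("rbf", "linear"),
                         bandwidth = "median-heuristic",
                         regularization = 1.0, standardize = TRUE,
                         calibration = c("sigmoid-fit", "none"), seed = 1L) {
  kernel <- match.arg(kernel)
  calibration <- match.arg(calibration)
  if (is.numeric(bandwidth) && bandwidth <= 0) stop_config("bandwidth must be > 0")
  if (!is.numeric(regularization) || regularization <= 0) {
    stop_config("regularization must be > 0")
  }
  structure(list(kernel = kernel, bandwidth = bandwidth,
                 regularization = regularization,
                 standardize = isTRUE(standardize),
                 calibration = calibration, seed = as.integer(seed)),
            class = "model_config")
}

#' Column standardization statistics
#'
#' Column means and standard deviations (population convention: divisor `n`)
#' from training rows. Zero-SD (constant) columns get SD 1 with a warning, so
#' they standardize to all-zero rather than dividing by zero.
#'
#' @param x numeric training matrix (non-empty, finite).
#' @return list with `mean` and `sd` vectors.
#' @export
standardize_fit <- function(x) {
  if (!is.matrix(x) || nrow(x) == 0L) stop_config("x must be a non-empty matrix")
  if (any(!is.finite(x))) stop_config("x must be finite (impute first)")
  m <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2, m)^2))
  if (any(sd_pop == 0)) {
    warning("constant column(s); SD stored as 1", call. = FALSE)
    sd_pop[sd_pop == 0] <- 1
  }
  list(mean = m, sd = sd_pop)
}

#' Apply standardization statistics
#'
#' @param x matrix.
#' @param stats list from [standardize_fit()].
#' @return standardized matrix.
#' @export
standardize_apply <- function(x, stats) {
  sweep(sweep(x, 2, stats$mean), 2, stats$sd, "/")
}

## Squared Euclidean cross-distances.
sqdist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

## Median pairwise distance; deterministic stride subsample above 1500 rows.
median_heuristic <- function(x) {
  n <- nrow(x)
  if (n > 1500L) x <- x[unique(round(seq(1L, n, length.out = 1500L))), , drop = FALSE]
  d <- sqrt(sqdist(x, x)[upper.tri(diag(nrow(x)))])
  s <- stats::median(d)
  if (!is.finite(s) || s <= 0) 1 else s
}

kernel_matrix <- function(a, b, kernel, sigma) {
  if (kernel == "rbf") exp(-sqdist(a, b) / (2 * sigma^2)) else tcrossprod(a, b)
}

## Platt's sigmoid fit: p = 1 / (1 + exp(A f + B)), fitted by Newton descent
## on the cross-entropy against regularized targets (N+1)/(N+2) and 1/(N+2).
## Deterministic; robust to separable decision values.
platt_fit <- function(f, y) {
  n_pos <- sum(y == 1)
  n_neg <- sum(y == -1)
  t <- ifelse(y == 1, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  A <- 0
  B <- log((n_neg + 1) / (n_pos + 1))
  for (it in 1:200) {
    z <- A * f + B
    p <- 1 / (1 + exp(z))
    ## gradient of sum(-t*log(p) - (1-t)*log(1-p)) wrt (A, B)
    d <- p - t
    g <- c(sum(-d * f), sum(-d))
    wt <- p * (1 - p)
    H <- matrix(c(sum(wt * f^2), sum(wt * f), sum(wt * f), sum(wt)), 2, 2)
    H <- H + diag(1e-10, 2)
    step <- solve(H, g)
    A <- A - step[1]
    B <- B - step[2]
    if (max(abs(step)) < 1e-10) break
  }
  c(A = A, B = B)
}

#' Fit the single-kernel classifier
#'
#' Fits a regularized kernel machine on concatenated (imputed) feature
#' columns with labels in \{-1, +1\}: after optional train-only
#' standardization, the dual coefficients solve
#' `(K + lambda I) alpha = y`, and decision values are mapped to `[0, 1]`
#' scores by a monotone sigmoid calibration fitted on the training decision
#' values. The fit is deterministic for fixed inputs and configuration.
#'
#' @param x numeric feature matrix (finite; impute first).
#' @param y labels in \{-1, +1\} (one of each class required).
#' @param config a [model_config()].
#' @return object of class `kernel_classifier` with `predict`, `print`,
#'   `summary`, `coef` and `residuals` methods.
#' @export
fit_kernel_classifier <- function(x, y, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop_config("x must be finite (impute first)")
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop_config("y must be coded -1 / +1")
  if (length(unique(y)) < 2L) stop_config("both classes must be present in y")
  if (length(y) != nrow(x)) stop_config("length(y) must equal nrow(x)")

  std <- if (config$standardize) standardize_fit(x) else NULL
  xs <- if (is.null(std)) x else standardize_apply(x, std)
  sigma <- if (config$kernel == "rbf") {
    if (identical(config$bandwidth, "median-heuristic")) median_heuristic(xs)
    else as.numeric(config$bandwidth)
  } else NA_real_
  K <- kernel_matrix(xs, xs, config$kernel, sigma)
  alpha <- solve(K + diag(config$regularization, nrow(K)), y)
  f_train <- as.numeric(K %*% alpha)
  platt <- if (config$calibration == "sigmoid-fit") platt_fit(f_train, y) else NULL

  structure(list(
    x_train = xs, alpha = alpha, sigma = sigma, std = std, platt = platt,
    config = config, colnames = colnames(x), n = nrow(x), y = y,
    n_pos = sum(y == 1), n_neg = sum(y == -1),
    fitted_decision = f_train
  ), class = "kernel_classifier")
}

decision_to_score <- function(model, f) {
  if (!is.null(model$platt)) {
    s <- 1 / (1 + exp(model$platt["A"] * f + model$platt["B"]))
  } else {
    s <- stats::plogis(f)
  }
  pmin(1, pmax(0, as.numeric(s)))
}

#' Predict calibrated scores from a fitted kernel classifier
#'
#' @param object a `kernel_classifier`.
#' @param newdata feature matrix, column-compatible with training.
#' @param type `"score"` (calibrated, in `[0,1]`), `"label"` (+1/-1 with
#'   positive at score >= 0.5) or `"decision"` (raw kernel-machine value).
#' @param ... unused.
#' @return numeric vector, one value per row of `newdata`.
#' @export
predict.kernel_classifier <- function(object, newdata,
                                      type = c("score", "label", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x_train)) {
    stop_config("newdata has ", ncol(newdata), " columns; model expects ",
                ncol(object$x_train))
  }
  if (!is.null(object$colnames) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$colnames)) {
    stop_config("newdata column names do not match training columns")
  }
  if (any(!is.finite(newdata))) stop_config("newdata must be finite (impute first)")
  xs <- if (is.null(object$std)) newdata else standardize_apply(newdata, object$std)
  f <- as.numeric(kernel_matrix(xs, object$x_train, object$config$kernel,
                                object$sigma) %*% object$alpha)
  switch(type,
         decision = f,
         score = decision_to_score(object, f),
         label = ifelse(decision_to_score(object, f) >= 0.5, 1, -1))
}

#' @export
print.kernel_classifier <- function(x, ...) {
  cat("kernel_classifier (", x$config$kernel, " kernel)\n", sep = "")
  cat("  training examples:", x$n, "(", x$n_pos, "positive /", x$n_neg, "negative )\n")
  cat("  features:", ncol(x$x_train),
      if (x$config$standardize) " (standardized)" else "", "\n", sep = "")
  if (x$config$kernel == "rbf") cat("  bandwidth sigma:", signif(x$sigma, 4), "\n")
  cat("  regularization lambda:", x$config$regularization, "\n")
  cat("  calibration:", x$config$calibration, "\n")
  invisible(x)
}

#' @export
summary.kernel_classifier <- function(object, ...) {
  s <- decision_to_score(object, object$fitted_decision)
  pred <- ifelse(s >= 0.5, 1, -1)
  sens <- mean(pred[object$y == 1] == 1)
  spec <- mean(pred[object$y == -1] == -1)
  structure(list(model = object,
                 score_quartiles = stats::quantile(s, c(0, .25, .5, .75, 1)),
                 train_sensitivity = sens, train_specificity = spec,
                 train_balanced_accuracy = (sens + spec) / 2),
            class = "summary.kernel_classifier")
}

#' @export
print.summary.kernel_classifier <- function(x, ...) {
  print(x$model)
  cat("  fitted score quartiles:",
      paste(signif(x$score_quartiles, 3), collapse = " "), "\n")
  cat("  training balanced accuracy:",
      signif(x$train_balanced_accuracy, 4), "\n")
  invisible(x)
}

#' @export
coef.kernel_classifier <- function(object, ...) object$alpha

#' @export
residuals.kernel_classifier <- function(object, ...) {
  ## residuals on the score scale against 0/1 targets
  (object$y + 1) / 2 - fitted(object)
}

#' @export
fitted.kernel_classifier <- function(object, ...) {
  decision_to_score(object, object$fitted_decision)
}
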