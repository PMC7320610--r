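## Evaluation: confusion metrics, ROC AUC, cautious classification, LOCO-CV
## orchestration, recurrence-threshold sweeps and class-conditional
## distribution tests.

#' Confusion counts from true and predicted labels
#'
#' @param truth,pred label vectors in \{-1, +1\}.
#' @return list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  list(TP = sum(truth == 1 & pred == 1),
       FP = sum(truth == -1 & pred == 1),
       TN = sum(truth == -1 & pred == -1),
       FN = sum(truth == 1 & pred == -1))
}

#' Classification metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), balanced accuracy
#' (sensitivity+specificity)/2, PPV TP/(TP+FP) and the Matthews correlation
#' coefficient. Metrics with a zero denominator are reported as `NA`, never
#' as 0.
#'
#' @param cc list with `TP`, `FP`, `TN`, `FN` (not all zero).
#' @return list of metrics.
#' @export
compute_metrics <- function(cc) {
  tp <- cc$TP; fp <- cc$FP; tn <- cc$TN; fn <- cc$FN
  total <- tp + fp + tn + fn
  if (total == 0) stop_config("all confusion counts are zero")
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  list(
    sensitivity = sens,
    specificity = spec,
    balanced_accuracy = if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2,
    ppv = div(tp, tp + fp),
    mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den,
    accuracy = (tp + tn) / total
  )
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen positive
#' outscores a uniformly chosen negative, with ties counted 1/2.
#'
#' @param scores numeric scores.
#' @param labels labels in \{-1, +1\}; both classes required.
#' @return AUC in `[0,1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == -1)
  if (n1 == 0 || n0 == 0) stop_config("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cautious classification at confidence cutoff tau
#'
#' Confidence is the score's distance from the 0.5 decision point: an example
#' is predicted with high confidence iff its score is at least `tau` or at
#' most `1 - tau`. Coverage is the fraction of high-confidence examples;
#' cautious metrics are computed over those examples only.
#'
#' @param scores scores in `[0,1]`.
#' @param tau confidence cutoff, `0.5 < tau <= 1`.
#' @return list with `labels` (+1/-1, positive at score >= 0.5), logical
#'   `confident`, and `coverage`.
#' @export
cautious_apply <- function(scores, tau) {
  if (!is.numeric(tau) || tau <= 0.5 || tau > 1) {
    stop_config("tau must satisfy 0.5 < tau <= 1")
  }
  if (length(scores) && (any(scores < 0) || any(scores > 1))) {
    stop_config("scores must lie in [0,1]")
  }
  confident <- scores >= tau | scores <= 1 - tau
  list(labels = ifelse(scores >= 0.5, 1, -1),
       confident = confident,
       coverage = if (length(scores)) mean(confident) else NA_real_)
}

#' Leave-one-chromosome-out evaluation
#'
#' For each autosome present in the dataset: subsample the training side to a
#' balanced set (test side keeps all examples), assemble the selected feature
#' groups with train-only imputation, fit the kernel classifier with
#' train-only standardization, and score the held-out chromosome. Pooled
#' predictions over folds are primary; a per-fold breakdown is included.
#'
#' @param ds `labeled_dataset` (or any data.frame with `chrom` and `label`).
#' @param groups named list of row-aligned feature matrices.
#' @param selected feature groups to use (default all).
#' @param model_cfg a [model_config()].
#' @param n_per_class balanced training subsample size per class
#'   (`NULL` = use all training examples).
#' @param tau cautious-classification cutoff (default 0.9).
#' @param impute imputation policy (see [assemble_features()]).
#' @param seed integer seed driving the per-fold subsampling streams.
#' @return object of class `loco_eval`: pooled metrics (default and
#'   cautious), AUC, coverage, per-fold table, pooled scores aligned to `ds`
#'   rows (`NA` for rows in skipped folds or off-autosome).
#' @export
run_loco <- function(ds, groups, selected = names(groups),
                     model_cfg = model_config(), n_per_class = NULL,
                     tau = 0.9, impute = c("train_mean", "zero"), seed = 1L) {
  impute <- match.arg(impute)
  folds <- make_loco_folds(ds)
  n <- nrow(ds)
  scores <- rep(NA_real_, n)
  per_fold <- list()
  skipped <- character(0)
  for (k in seq_along(folds)) {
    fold <- folds[[k]]
    tr <- fold$train_idx
    if (length(tr) == 0L || length(unique(ds$label[tr])) < 2L) {
      warning("skipping degenerate fold ", fold$test_chrom, call. = FALSE)
      skipped <- c(skipped, fold$test_chrom)
      next
    }
    if (!is.null(n_per_class)) {
      sub <- balanced_subsample(ds[tr, , drop = FALSE], n_per_class,
                                seed = seed + k)
      tr <- tr[sub]
    }
    x <- assemble_features(groups, selected, train_idx = tr, impute = impute)
    fit <- fit_kernel_classifier(x[tr, , drop = FALSE], ds$label[tr], model_cfg)
    te <- fold$test_idx
    scores[te] <- predict(fit, x[te, , drop = FALSE], type = "score")
    fm <- if (length(unique(ds$label[te])) == 2L) {
      compute_metrics(confusion_counts(ds$label[te],
                                       ifelse(scores[te] >= 0.5, 1, -1)))
    } else {
      list(sensitivity = NA_real_, specificity = NA_real_,
           balanced_accuracy = NA_real_, ppv = NA_real_, mcc = NA_real_,
           accuracy = NA_real_)
    }
    per_fold[[length(per_fold) + 1L]] <- data.frame(
      test_chrom = fold$test_chrom, n_train = length(tr), n_test = length(te),
      balanced_accuracy = fm$balanced_accuracy, sensitivity = fm$sensitivity,
      specificity = fm$specificity, stringsAsFactors = FALSE)
  }
  scored <- which(!is.na(scores))
  if (length(scored) == 0L) stop_config("no fold produced predictions")
  truth <- ds$label[scored]
  pred <- ifelse(scores[scored] >= 0.5, 1, -1)
  cc <- confusion_counts(truth, pred)
  metrics <- compute_metrics(cc)
  auc <- if (length(unique(truth)) == 2L) roc_auc(scores[scored], truth) else NA_real_
  caut <- cautious_apply(scores[scored], tau)
  ci <- which(caut$confident)
  cautious_metrics <- if (length(ci) && length(unique(truth[ci])) == 2L) {
    compute_metrics(confusion_counts(truth[ci], caut$labels[ci]))
  } else NULL
  structure(list(
    metrics = metrics, auc = auc, counts = cc,
    cautious = list(tau = tau, coverage = caut$coverage,
                    metrics = cautious_metrics),
    per_fold = do.call(rbind, per_fold),
    scores = scores, n_scored = length(scored),
    selected = selected, tau = tau, seed = seed,
    n_per_class = n_per_class, skipped_folds = skipped
  ), class = "loco_eval")
}

#' @export
print.loco_eval <- function(x, ...) {
  m <- x$metrics
  cat("Leave-one-chromosome-out evaluation (", nrow(x$per_fold), " folds, ",
      x$n_scored, " pooled predictions)\n", sep = "")
  cat(sprintf("  balanced accuracy %.3f | sensitivity %.3f | specificity %.3f\n",
              m$balanced_accuracy, m$sensitivity, m$specificity))
  cat(sprintf("  AUC %.3f | MCC %.3f | PPV %.3f\n", x$auc, m$mcc, m$ppv))
  if (!is.null(x$cautious$metrics)) {
    cat(sprintf("  cautious (tau=%.2f): balanced accuracy %.3f at coverage %.3f\n",
                x$cautious$tau, x$cautious$metrics$balanced_accuracy,
                x$cautious$coverage))
  }
  invisible(x)
}

#' @export
summary.loco_eval <- function(object, ...) {
  print(object)
  cat("\nPer-fold breakdown:\n")
  print(object$per_fold, row.names = FALSE)
  invisible(object)
}

#' ROC curve for a LOCO evaluation
#'
#' @param x a `loco_eval`.
#' @param ds the dataset the evaluation was run on (for labels).
#' @param ... passed to [graphics::plot()].
#' @export
plot.loco_eval <- function(x, ds, ...) {
  scored <- which(!is.na(x$scores))
  truth <- ds$label[scored]
  s <- x$scores[scored]
  thr <- sort(unique(c(0, s, 1)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(s[truth == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s[truth == -1] >= t), numeric(1))
  graphics::plot(fpr, tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("LOCO ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(data.frame(fpr = fpr, tpr = tpr))
}

#' Balanced accuracy across recurrence thresholds
#'
#' Re-labels the catalog at each threshold rho (positives `r >= rho`,
#' negatives `r = 1` window-matched at `w`), rebuilds LOCO folds and runs the
#' full evaluation, reusing the cached feature matrices (only labels,
#' matching and folds are recomputed). Thresholds leaving fewer than two
#' examples in either class are reported as `NA`.
#'
#' @param variants full catalog `data.frame` (`chrom`, `pos`, `ref`, `alt`,
#'   `r`).
#' @param groups feature-group matrices row-aligned to `variants`.
#' @param rho_values ascending integer thresholds (>= 2).
#' @param w matching window.
#' @param selected,model_cfg,n_per_class,tau,seed passed to [run_loco()].
#' @return `data.frame` of class `recurrence_sweep` with columns `rho`,
#'   `balanced_accuracy`, `auc`, `n_pos`, `n_neg`.
#' @export
recurrence_sweep <- function(variants, groups, rho_values, w,
                             selected = names(groups),
                             model_cfg = model_config(), n_per_class = NULL,
                             tau = 0.9, seed = 1L) {
  if (any(rho_values < 2) || is.unsorted(rho_values)) {
    stop_config("rho_values must be ascending and >= 2")
  }
  rows <- lapply(rho_values, function(rho) {
    parts <- assign_labels(variants, rho)
    negs <- window_match(parts$negatives, parts$positives, w)
    ## rebuild by row index to keep feature alignment
    pos_idx <- which(variants$r >= rho)
    neg_idx <- match(paste(negs$chrom, negs$pos, negs$ref, negs$alt),
                     paste(variants$chrom, variants$pos, variants$ref, variants$alt))
    take <- c(pos_idx, neg_idx)
    if (length(pos_idx) < 2L || length(neg_idx) < 2L) {
      return(data.frame(rho = rho, balanced_accuracy = NA_real_, auc = NA_real_,
                        n_pos = length(pos_idx), n_neg = length(neg_idx)))
    }
    ds <- variants[take, , drop = FALSE]
    ds$label <- rep(c(1L, -1L), c(length(pos_idx), length(neg_idx)))
    sub_groups <- lapply(groups, function(m) m[take, , drop = FALSE])
    ev <- tryCatch(
      suppressWarnings(run_loco(ds, sub_groups, selected, model_cfg,
                                n_per_class = n_per_class, tau = tau,
                                seed = seed)),
      error = function(e) NULL)
    data.frame(rho = rho,
               balanced_accuracy = if (is.null(ev)) NA_real_
                                   else ev$metrics$balanced_accuracy,
               auc = if (is.null(ev)) NA_real_ else ev$auc,
               n_pos = length(pos_idx), n_neg = length(neg_idx))
  })
  structure(do.call(rbind, rows), class = c("recurrence_sweep", "data.frame"))
}

#' Two-sample distribution test
#'
#' Kolmogorov-Smirnov by default (Mann-Whitney/Wilcoxon by option). When the
#' p-value underflows double precision it is reported as an analytic upper
#' bound (`p_label` like `"< 1e-120"`, with `log10_p_bound` carrying the
#' numeric exponent), never as 0.
#'
#' @param a,b numeric samples (non-empty).
#' @param method `"ks"` or `"wilcoxon"`.
#' @return list with `statistic`, `p_value`, `log10_p_bound`, `p_label`.
#' @export
distribution_test <- function(a, b, method = c("ks", "wilcoxon")) {
  method <- match.arg(method)
  if (length(a) == 0L || length(b) == 0L) stop_config("samples must be non-empty")
  if (method == "ks") {
    ht <- suppressWarnings(stats::ks.test(a, b))
    stat <- unname(ht$statistic)
    p <- ht$p.value
    neff <- length(a) * length(b) / (length(a) + length(b))
    ## asymptotic two-sample tail bound: p <= 2 exp(-2 neff D^2)
    log10_bound <- (log(2) - 2 * neff * stat^2) / log(10)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b))
    stat <- unname(ht$statistic)
    p <- ht$p.value
    ## normal-approximation bound on the standardized U statistic
    n1 <- length(a); n2 <- length(b)
    mu <- n1 * n2 / 2
    sdv <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    z <- abs(stat - mu) / sdv
    log10_bound <- (log(2) + stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)) / log(10)
  }
  if (is.na(p) || p > 0) {
    log10_p <- max(log10(max(p, .Machine$double.xmin)), log10_bound)
  } else {
    log10_p <- log10_bound
  }
  label <- if (!is.na(p) && p > 0) sprintf("%.3g", p)
           else sprintf("< 1e%d", ceiling(log10_p))
  list(statistic = stat, p_value = p, log10_p_bound = log10_p, p_label = label)
}
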