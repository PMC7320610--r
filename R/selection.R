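## Greedy forward selection over feature groups: rank singleton groups by
## cross-validated balanced accuracy, then grow the best combination until no
## addition yields a significant improvement. All candidates within a round
## share the fold partition and per-fold subsampling seeds, so the stop rule
## operates on paired per-fold differences.

## Per-fold balanced accuracies for one group set, reusing run_loco's
## orchestration conventions (train-only subsampling/imputation/standardization).
cv_perfold_ba <- function(groups, ds, selected, model_cfg, folds,
                          n_per_class = NULL, seed = 1L,
                          impute = "train_mean") {
  ba <- rep(NA_real_, length(folds))
  for (k in seq_along(folds)) {
    fold <- folds[[k]]
    tr <- fold$train_idx
    if (length(tr) == 0L || length(unique(ds$label[tr])) < 2L) {
      warning("skipping fold ", fold$test_chrom,
              " (degenerate training data)", call. = FALSE)
      next
    }
    if (!is.null(n_per_class)) {
      tr <- tr[balanced_subsample(ds[tr, , drop = FALSE], n_per_class,
                                  seed = seed + k)]
    }
    x <- assemble_features(groups, selected, train_idx = tr, impute = impute)
    te <- fold$test_idx
    if (length(unique(ds$label[te])) < 2L) next
    fit <- tryCatch(
      fit_kernel_classifier(x[tr, , drop = FALSE], ds$label[tr], model_cfg),
      error = function(e) NULL)
    if (is.null(fit)) next
    s <- predict(fit, x[te, , drop = FALSE], type = "score")
    m <- compute_metrics(confusion_counts(ds$label[te], ifelse(s >= 0.5, 1, -1)))
    ba[k] <- m$balanced_accuracy
  }
  ba
}

#' Rank singleton feature groups by cross-validated balanced accuracy
#'
#' @param groups named list of row-aligned feature matrices.
#' @param ds `labeled_dataset`.
#' @param model_cfg a [model_config()].
#' @param folds LOCO folds from [make_loco_folds()] (default: built from
#'   `ds`).
#' @param n_per_class balanced training subsample per fold (`NULL` = all).
#' @param seed seed for the per-fold subsampling streams (shared across
#'   groups so comparisons are paired).
#' @return `data.frame` sorted by descending mean balanced accuracy (ties
#'   broken by the declared group order in `names(groups)`; all-missing
#'   groups rank last), with the per-fold accuracies as a list column.
#' @export
rank_singletons <- function(groups, ds, model_cfg = model_config(),
                            folds = NULL, n_per_class = NULL, seed = 1L) {
  if (length(groups) == 0L) stop_config("at least one feature group required")
  if (is.null(folds)) folds <- make_loco_folds(ds)
  perfold <- lapply(names(groups), function(g) {
    cv_perfold_ba(groups, ds, g, model_cfg, folds, n_per_class, seed)
  })
  mean_ba <- vapply(perfold, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  ## descending accuracy; NA (all-missing) last; ties keep declared order
  ord <- order(-ifelse(is.na(mean_ba), -Inf, mean_ba), seq_along(mean_ba))
  out <- data.frame(group = names(groups)[ord],
                    mean_balanced_accuracy = mean_ba[ord],
                    stringsAsFactors = FALSE)
  out$per_fold <- perfold[ord]
  out
}

#' Greedy forward selection of feature groups
#'
#' Starts from the top-ranked singleton group. Each round evaluates adding
#' every remaining group to the current set as one concatenated kernel,
#' takes the best addition by mean cross-validated balanced accuracy, and
#' accepts it only if the improvement over the current set is significant
#' under `stop_rule`; otherwise selection stops.
#'
#' The published procedure's significance criterion is not printed in the
#' available text; two conventional paired criteria are provided:
#' `"stderr"` (mean per-fold paired improvement exceeds one standard error
#' of the differences) and `"permutation"` (paired sign-flip test at
#' `alpha`).
#'
#' @inheritParams rank_singletons
#' @param stop_rule `"stderr"` or `"permutation"`.
#' @param alpha significance level for the permutation rule.
#' @param n_perm sign-flip permutations (exact enumeration is used when
#'   there are at most 12 folds).
#' @return list with `selected` (character vector of group names) and
#'   `trace` (class `selection_trace`): ranking, one step per round with
#'   per-fold accuracies and accepted flag, and a single stopping reason.
#' @export
forward_select <- function(groups, ds, model_cfg = model_config(),
                           folds = NULL, stop_rule = c("stderr", "permutation"),
                           alpha = 0.05, n_perm = 1000L,
                           n_per_class = NULL, seed = 1L) {
  stop_rule <- match.arg(stop_rule)
  if (is.null(folds)) folds <- make_loco_folds(ds)
  ranking <- rank_singletons(groups, ds, model_cfg, folds, n_per_class, seed)
  current <- ranking$group[1]
  current_perfold <- ranking$per_fold[[1]]
  steps <- list(list(added = current,
                     set = current,
                     per_fold = current_perfold,
                     mean_ba = ranking$mean_balanced_accuracy[1],
                     accepted = TRUE,
                     reason = "top-ranked singleton"))
  remaining <- setdiff(names(groups), current)
  stop_reason <- "groups exhausted"
  while (length(remaining)) {
    cand_perfold <- lapply(remaining, function(g) {
      cv_perfold_ba(groups, ds, c(current, g), model_cfg, folds,
                    n_per_class, seed)
    })
    cand_mean <- vapply(cand_perfold, function(v) {
      if (all(is.na(v))) -Inf else mean(v, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(cand_mean)
    d <- cand_perfold[[best]] - current_perfold
    d <- d[!is.na(d)]
    verdict <- improvement_significant(d, stop_rule, alpha, n_perm,
                                       n_candidates = length(remaining))
    steps[[length(steps) + 1L]] <- list(
      added = remaining[best],
      set = c(current, remaining[best]),
      per_fold = cand_perfold[[best]],
      mean_ba = cand_mean[best],
      accepted = verdict$accept,
      reason = verdict$reason)
    if (!verdict$accept) {
      stop_reason <- paste0("no significant improvement (", verdict$reason, ")")
      break
    }
    current <- c(current, remaining[best])
    current_perfold <- cand_perfold[[best]]
    remaining <- setdiff(remaining, remaining[best])
    if (length(remaining) == 0L) stop_reason <- "groups exhausted"
  }
  trace <- structure(list(ranking = ranking, steps = steps,
                          stop_reason = stop_reason, stop_rule = stop_rule,
                          seed = seed),
                     class = "selection_trace")
  list(selected = current, trace = trace)
}

## Decide whether the best candidate's paired per-fold improvement d is
## significant. The permutation rule Bonferroni-corrects alpha by the number
## of candidates examined in the round, since the tested difference is the
## best of several (otherwise the best-of-m selection inflates the
## false-acceptance rate well above alpha).
improvement_significant <- function(d, stop_rule, alpha, n_perm,
                                    n_candidates = 1L) {
  if (length(d) == 0L) return(list(accept = FALSE, reason = "no comparable folds"))
  md <- mean(d)
  if (md <= 0) return(list(accept = FALSE, reason = "no mean improvement"))
  if (length(d) == 1L) {
    return(list(accept = md > 0, reason = "single fold; sign of difference"))
  }
  if (stop_rule == "stderr") {
    se <- stats::sd(d) / sqrt(length(d))
    if (se == 0) return(list(accept = TRUE, reason = "uniform positive improvement"))
    list(accept = md > se, reason = sprintf("mean %.4f vs SE %.4f", md, se))
  } else {
    n <- length(d)
    if (n <= 12L) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      stat <- as.numeric(signs %*% d) / n
      p <- mean(stat >= md)
    } else {
      stat <- local_seed(7L, replicate(n_perm, mean(sample(c(-1, 1), n,
                                                           replace = TRUE) * d)))
      p <- (sum(stat >= md) + 1) / (n_perm + 1)
    }
    thr <- alpha / max(1L, n_candidates)
    list(accept = p < thr,
         reason = sprintf("sign-flip p = %.4f vs %.4f", p, thr))
  }
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Forward selection trace (", x$stop_rule, " rule)\n", sep = "")
  for (s in x$steps) {
    cat(sprintf("  %s %-18s mean BA %.3f  (%s)\n",
                if (s$accepted) "+" else "x", s$added, s$mean_ba, s$reason))
  }
  cat("  stop:", x$stop_reason, "\n")
  invisible(x)
}
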