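test_that("confusion metrics follow their closed forms", {
  ## sensitivity 0.96, specificity 0.88 -> balanced accuracy 0.92
  m <- compute_metrics(list(TP = 96, FN = 4, TN = 88, FP = 12))
  expect_equal(m$sensitivity, 0.96, tolerance = 1e-12)
  expect_equal(m$specificity, 0.88, tolerance = 1e-12)
  expect_equal(m$balanced_accuracy, 0.92, tolerance = 1e-12)
  expect_equal(m$mcc, 8400 / sqrt(108 * 92 * 100 * 100), tolerance = 1e-12)
  expect_equal(m$ppv, 96 / 108, tolerance = 1e-12)

  perfect <- compute_metrics(list(TP = 100, FN = 0, TN = 100, FP = 0))
  expect_true(all(unlist(perfect) == 1))

  ## zero denominators are missing, never zero
  nopos <- compute_metrics(list(TP = 0, FN = 0, TN = 5, FP = 5))
  expect_true(is.na(nopos$sensitivity))
  expect_true(is.na(nopos$balanced_accuracy))
  expect_true(is.na(nopos$mcc))
  expect_error(compute_metrics(list(TP = 0, FN = 0, TN = 0, FP = 0)), "zero")

  cc <- confusion_counts(c(1, 1, -1, -1), c(1, -1, -1, 1))
  expect_equal(cc, list(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
})

test_that("AUC matches the pairwise-comparison definition", {
  expect_equal(roc_auc(c(.9, .8, .2, .1), c(1, 1, -1, -1)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(1, -1), 5)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")

  set.seed(19)
  s <- round(stats::runif(200), 1)  # heavy ties
  y <- sample(c(1, -1), 200, replace = TRUE)
  pos <- s[y == 1]; neg <- s[y == -1]
  bf <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(roc_auc(s, y), bf)
  ## invariance under strictly monotone transforms
  expect_equal(roc_auc(stats::qlogis(pmin(pmax(s, .01), .99)), y),
               roc_auc(s, y))
})

test_that("cautious classification thresholds confidence symmetrically", {
  out <- cautious_apply(c(0.95, 0.60, 0.05, 0.12), tau = 0.91)
  expect_equal(out$labels, c(1, 1, -1, -1))
  expect_equal(out$confident, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$coverage, 0.5)
  expect_error(cautious_apply(0.5, tau = 0.5), "tau")
  ## extreme scores give full coverage for any tau just above 1/2
  expect_equal(cautious_apply(rep(c(0, 1), 5), tau = 0.501)$coverage, 1)
  ## coverage is non-increasing in tau for arbitrary score sets
  set.seed(37)
  for (i in 1:20) {
    s <- stats::runif(50)
    taus <- sort(stats::runif(8, 0.51, 1))
    cov <- vapply(taus, function(t) cautious_apply(s, t)$coverage, numeric(1))
    expect_true(all(diff(cov) <= 0))
  }
})

test_that("KS distribution test matches the ECDF-gap oracle and bounds p", {
  same <- distribution_test(1:10, 1:10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(43)
  for (i in 1:10) {
    a <- stats::rnorm(30)
    b <- stats::rnorm(25, mean = 0.5)
    got <- distribution_test(a, b)
    grid <- c(a, b)
    bf <- max(abs(vapply(grid, function(x) mean(a <= x) - mean(b <= x),
                         numeric(1))))
    expect_equal(got$statistic, bf)
  }
  expect_error(distribution_test(numeric(0), 1:3), "non-empty")

  big <- distribution_test(stats::rnorm(5000), stats::rnorm(5000, 2))
  expect_lte(big$log10_p_bound, -18)
  expect_match(big$p_label, "^< 1e-")

  mw <- distribution_test(stats::rnorm(100), stats::rnorm(100, 1),
                          method = "wilcoxon")
  expect_lt(mw$p_value, 0.01)
})

test_that("LOCO evaluation recovers planted signal and is reproducible", {
  ds <- tiny_dataset()
  groups <- tiny_groups()
  sel <- c("Conservation", "Uniqueness", "GC")
  ev <- suppressWarnings(run_loco(ds, groups, selected = sel, n_per_class = 50,
                                  tau = 0.9, seed = 2))
  expect_gt(ev$metrics$balanced_accuracy, 0.85)
  expect_gt(ev$auc, 0.9)
  ## pooled counts sum to the number of scored examples
  expect_equal(with(ev$counts, TP + FP + TN + FN), ev$n_scored)
  expect_equal(ev$n_scored, sum(!is.na(ev$scores)))

  ev2 <- suppressWarnings(run_loco(ds, groups, selected = sel, n_per_class = 50,
                                   tau = 0.9, seed = 2))
  expect_identical(ev$scores, ev2$scores)
  expect_identical(ev$metrics, ev2$metrics)
  expect_output(print(ev), "balanced accuracy")
  expect_output(summary(ev), "Per-fold")
  pdf(NULL); on.exit(dev.off())
  roc <- plot(ev, ds)
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("permuted labels drive LOCO accuracy to chance", {
  ds <- tiny_dataset()
  set.seed(77)
  ds$label <- sample(ds$label)
  ev <- suppressWarnings(run_loco(ds, tiny_groups(),
                                  selected = c("Conservation", "Uniqueness", "GC"),
                                  n_per_class = 50, seed = 3))
  expect_gt(ev$metrics$balanced_accuracy, 0.35)
  expect_lt(ev$metrics$balanced_accuracy, 0.65)
})

test_that("single-threshold recurrence sweep is consistent with run_loco", {
  s <- tiny_study()
  cat <- s$catalog
  groups_all <- compute_feature_groups(cat, s$genome, s$annotation, s$tracks,
                                       s$elements, catalog = cat)
  sw <- suppressWarnings(recurrence_sweep(cat, groups_all, rho_values = 7,
                                          w = 1000,
                                          selected = c("Conservation", "Uniqueness"),
                                          n_per_class = 50, seed = 2))
  expect_equal(nrow(sw), 1L)
  ## same labeled rows, same seed: must match a direct run
  ds <- build_dataset(cat, dataset_config("noncoding", rho = 7, window = 1000))
  idx <- match(paste(ds$chrom, ds$pos, ds$alt), paste(cat$chrom, cat$pos, cat$alt))
  groups_ds <- lapply(groups_all, function(m) m[idx, , drop = FALSE])
  ev <- suppressWarnings(run_loco(ds, groups_ds,
                                  selected = c("Conservation", "Uniqueness"),
                                  n_per_class = 50, seed = 2))
  expect_equal(sw$balanced_accuracy, ev$metrics$balanced_accuracy)
  ## a threshold beyond the maximum recurrence is reported missing
  sw2 <- suppressWarnings(recurrence_sweep(cat, groups_all,
                                           rho_values = c(7, 50), w = 1000,
                                           selected = "Conservation",
                                           n_per_class = 50, seed = 2))
  expect_true(is.na(sw2$balanced_accuracy[2]))
  expect_error(recurrence_sweep(cat, groups_all, c(5, 3), 1000), "ascending")
})
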