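## Dataset construction: recurrence-threshold labeling, window-matched
## negative selection, LOCO-CV folds, and balanced training subsamples.

#' Dataset construction configuration
#'
#' Bundles the recurrence threshold rho, the matching window w, the region
#' mode, the per-class training subsample size, and the seed. Defaults follow
#' the published operating points: rho = 7 with w = 10000 in coding regions,
#' rho = 8 with w = 1000 in non-coding regions.
#'
#' @param region_mode `"coding"` or `"noncoding"`.
#' @param rho positive-class recurrence threshold (integer >= 2). Variants
#'   with `r >= rho` become positives (putative drivers); `r = 1` variants are
#'   candidate negatives (putative passengers); intermediate recurrence is
#'   excluded from training.
#' @param window matching window in nucleotides: a candidate negative is
#'   retained only if it lies within `window` of a positive on the same
#'   chromosome.
#' @param n_per_class balanced training subsample size per class.
#' @param seed integer seed for subsampling.
#' @return a list of class `dataset_config`.
#' @export
dataset_config <- function(region_mode = c("coding", "noncoding"),
                           rho = NULL, window = NULL,
                           n_per_class = 4000L, seed = 1L) {
  region_mode <- match.arg(region_mode)
  if (is.null(rho)) rho <- if (region_mode == "coding") 7L else 8L
  if (is.null(window)) window <- if (region_mode == "coding") 10000L else 1000L
  rho <- as.integer(rho)
  if (is.na(rho) || rho < 2L) stop_config("rho must be an integer >= 2")
  if (window < 1L) stop_config("window must be >= 1")
  structure(list(region_mode = region_mode, rho = rho, window = as.integer(window),
                 n_per_class = as.integer(n_per_class), seed = as.integer(seed)),
            class = "dataset_config")
}

#' Classify variants as coding or non-coding
#'
#' A variant is coding iff its position overlaps any CDS interval of the
#' annotation; anything else is non-coding. Chromosomes absent from the
#' annotation are treated as having no CDS, with a warning.
#'
#' @param variants variant `data.frame` (columns `chrom`, `pos`).
#' @param annotation interval [GenomicRanges::GRanges] with a `kind` column.
#' @return character vector `"coding"`/`"noncoding"` aligned to `variants`.
#' @export
classify_region <- function(variants, annotation) {
  cds <- annotation[annotation$kind == "CDS"]
  ann_chroms <- unique(as.character(GenomicRanges::seqnames(annotation)))
  missing <- setdiff(unique(variants$chrom), ann_chroms)
  if (length(missing)) {
    warning("chromosome(s) absent from annotation (treated as no CDS): ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(variants) == 0L) return(character(0))
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(variant_granges(variants), cds)
  )
  ifelse(hits > 0L, "coding", "noncoding")
}

#' Partition a catalog by recurrence level
#'
#' @param variants variant `data.frame` with column `r`.
#' @param rho recurrence threshold (integer >= 2).
#' @return list with `positives` (`r >= rho`), `negatives` (`r = 1`) and
#'   `excluded` (`1 < r < rho`); the three partition the input.
#' @export
assign_labels <- function(variants, rho) {
  rho <- as.integer(rho)
  if (is.na(rho) || rho < 2L) stop_config("rho must be an integer >= 2")
  list(
    positives = variants[variants$r >= rho, , drop = FALSE],
    negatives = variants[variants$r == 1L, , drop = FALSE],
    excluded = variants[variants$r > 1L & variants$r < rho, , drop = FALSE]
  )
}

#' Retain negatives within a window of a positive
#'
#' Keeps exactly those candidate negatives whose position lies within `w`
#' nucleotides (inclusive) of at least one positive on the same chromosome,
#' preserving input order. Matching is per-chromosome; uses sorted positive
#' positions for an O((N+M) log M) scan.
#'
#' @param negatives,positives variant `data.frame`s.
#' @param w window in nucleotides (>= 1).
#' @return the retained subset of `negatives`.
#' @export
window_match <- function(negatives, positives, w) {
  if (w < 1L) stop_config("w must be >= 1")
  if (nrow(negatives) == 0L || nrow(positives) == 0L) {
    return(negatives[integer(0), , drop = FALSE])
  }
  keep <- logical(nrow(negatives))
  for (ch in unique(negatives$chrom)) {
    p <- sort(positives$pos[positives$chrom == ch])
    if (length(p) == 0L) next
    i <- which(negatives$chrom == ch)
    x <- negatives$pos[i]
    lo <- findInterval(x, p)                  # index of largest p <= x
    d_left <- ifelse(lo >= 1L, x - p[pmax(lo, 1L)], Inf)
    hi <- lo + 1L
    d_right <- ifelse(hi <= length(p), p[pmin(hi, length(p))] - x, Inf)
    keep[i] <- pmin(d_left, d_right) <= w
  }
  negatives[keep, , drop = FALSE]
}

#' Build a labeled driver/passenger dataset
#'
#' Applies recurrence labeling at `cfg$rho`, retains window-matched negatives
#' at `cfg$window`, and returns the labeled dataset (+1 recurrent / -1 rare)
#' with the per-variant fold key (chromosome). Intermediate-recurrence
#' variants are kept in the `"excluded"` attribute so recurrence sweeps can
#' relabel without re-reading inputs.
#'
#' @param variants variant catalog `data.frame` (`chrom`, `pos`, `ref`,
#'   `alt`, `r`, optionally `region`).
#' @param cfg a [dataset_config()].
#' @param annotation optional annotation `GRanges`; when given and `variants`
#'   has no `region` column, regions are classified and the catalog is
#'   filtered to `cfg$region_mode`.
#' @return a `data.frame` of class `labeled_dataset` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `r`, `region`, `label`.
#' @export
build_dataset <- function(variants, cfg, annotation = NULL) {
  stopifnot(inherits(cfg, "dataset_config"))
  if (!"region" %in% names(variants)) {
    variants$region <- if (is.null(annotation)) "unassigned"
                       else classify_region(variants, annotation)
  }
  if (!is.null(annotation) || any(variants$region %in% c("coding", "noncoding"))) {
    variants <- variants[variants$region %in% c(cfg$region_mode, "unassigned"), ,
                         drop = FALSE]
  }
  parts <- assign_labels(variants, cfg$rho)
  negs <- window_match(parts$negatives, parts$positives, cfg$window)
  pos <- parts$positives
  pos$label <- if (nrow(pos)) 1L else integer(0)
  negs$label <- if (nrow(negs)) -1L else integer(0)
  ds <- rbind(pos, negs)
  rownames(ds) <- NULL
  structure(ds, excluded = parts$excluded, config = cfg,
            class = c("labeled_dataset", "data.frame"))
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", nrow(x), "variants (",
      sum(x$label == 1L), "positive /", sum(x$label == -1L), "negative ) on",
      length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Leave-one-chromosome-out cross-validation folds
#'
#' One fold per autosome present in the data: the fold's test set is every
#' example on that chromosome and its training set is every example on the
#' other autosomes. Examples on X, Y or the mitochondrial chromosome never
#' appear in any fold.
#'
#' @param ds a `labeled_dataset` (any `data.frame` with a `chrom` column).
#' @return list of folds, each `list(test_chrom, train_idx, test_idx,
#'   degenerate)`; indices refer to rows of `ds`.
#' @export
make_loco_folds <- function(ds) {
  chrom <- normalize_chrom(ds$chrom)
  auto <- which(is_autosome(chrom))
  if (length(auto) == 0L) stop_config("dataset has no autosomal examples")
  present <- intersect(AUTOSOMES, unique(chrom[auto]))
  folds <- lapply(present, function(ch) {
    test_idx <- auto[chrom[auto] == ch]
    train_idx <- auto[chrom[auto] != ch]
    list(test_chrom = ch, train_idx = train_idx, test_idx = test_idx,
         degenerate = length(train_idx) == 0L)
  })
  if (any(vapply(folds, `[[`, logical(1), "degenerate"))) {
    warning("fold(s) with empty training set (single autosome present)",
            call. = FALSE)
  }
  folds
}

#' Balanced subsample of a labeled dataset
#'
#' Uniformly samples up to `n_per_class` examples per class without
#' replacement, under a dedicated seeded generator isolated from the global
#' random state. If a class has fewer than `n_per_class` examples, the whole
#' class is kept (with a warning when both are short).
#'
#' @param ds `labeled_dataset`.
#' @param n_per_class target size per class.
#' @param seed integer seed.
#' @return row indices into `ds` (sorted), so callers can subset both the
#'   dataset and any row-aligned feature matrix.
#' @export
balanced_subsample <- function(ds, n_per_class, seed) {
  pos <- which(ds$label == 1L)
  neg <- which(ds$label == -1L)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop_config("both classes must be present for balanced subsampling")
  }
  if (length(pos) < n_per_class && length(neg) < n_per_class) {
    warning("n_per_class exceeds both class sizes; returning full dataset",
            call. = FALSE)
  }
  local_seed(seed, {
    take_pos <- if (length(pos) > n_per_class) sample(pos, n_per_class) else pos
    take_neg <- if (length(neg) > n_per_class) sample(neg, n_per_class) else neg
    sort(c(take_pos, take_neg))
  })
}
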