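## Feature extraction: the seven feature groups computed for each variant and
## assembled into row-aligned matrices. Every extractor is a pure function of
## (inputs, config); missing values are NA until imputation in
## assemble_features().

FEATURE_GROUPS <- c("Conservation", "GC", "Uniqueness", "LocalMutFreq",
                    "GeneProximity", "Spectrum", "FunctionalElements")

#' Feature extraction configuration
#'
#' @param gc_window width in bases of the window centered on the variant used
#'   for GC content (default 100).
#' @param spectrum_k k-mer length for the sequence spectrum (1..5, default 3).
#' @param spectrum_window window width for the spectrum (default 100).
#' @param mutfreq_window total width of the local-mutation-frequency region
#'   (default 1000, i.e. +/- 500 around the variant).
#' @param proximity_kinds gene-feature kinds for proximity features.
#' @param log_distance log1p-transform proximity distances (default TRUE).
#' @param impute imputation policy for missing feature values:
#'   `"train_mean"` (training-row column means) or `"zero"`.
#' @param conservation_tracks,uniqueness_tracks names of score tracks feeding
#'   the Conservation and Uniqueness groups.
#' @param element_classes functional-element classes to encode as indicators;
#'   `NULL` means all classes present in the element set.
#' @return a list of class `feature_config`.
#' @export
feature_config <- function(gc_window = 100L, spectrum_k = 3L,
                           spectrum_window = 100L, mutfreq_window = 1000L,
                           proximity_kinds = c("TSS", "splice_site", "TFBS", "CDS"),
                           log_distance = TRUE,
                           impute = c("train_mean", "zero"),
                           conservation_tracks = c("phastcons_like", "phylop_like"),
                           uniqueness_tracks = "uniqueness_like",
                           element_classes = NULL) {
  impute <- match.arg(impute)
  if (gc_window < 1L || spectrum_window < 1L || mutfreq_window < 1L) {
    stop_config("windows must be >= 1")
  }
  if (spectrum_k < 1L || spectrum_k > 5L) stop_config("spectrum_k must be in [1,5]")
  if (spectrum_window < spectrum_k) stop_config("spectrum window must be >= k")
  structure(list(gc_window = as.integer(gc_window),
                 spectrum_k = as.integer(spectrum_k),
                 spectrum_window = as.integer(spectrum_window),
                 mutfreq_window = as.integer(mutfreq_window),
                 proximity_kinds = proximity_kinds,
                 log_distance = isTRUE(log_distance),
                 impute = impute,
                 conservation_tracks = conservation_tracks,
                 uniqueness_tracks = uniqueness_tracks,
                 element_classes = element_classes),
            class = "feature_config")
}

## Window of `window` bases centered on pos: [pos - floor(w/2), start + w - 1],
## clipped at the chromosome ends. Frozen convention, shared by GC and
## spectrum features.
window_bounds <- function(pos, window) {
  start <- pos - window %/% 2L
  list(start = start, end = start + window - 1L)
}

#' GC content around variants
#'
#' Fraction of G/C among non-N bases in a window of `window` bases centered on
#' each variant (clipped at chromosome ends); all-N windows give `NA`.
#'
#' @param genome a `DNAStringSet` from [read_genome()].
#' @param variants variant `data.frame` (`chrom`, `pos`).
#' @param window window width in bases.
#' @return numeric vector in `[0,1]` (or `NA`), aligned to `variants`.
#' @export
gc_content <- function(genome, variants, window = 100L) {
  if (window < 1L) stop_config("window must be >= 1")
  out <- rep(NA_real_, nrow(variants))
  b <- window_bounds(variants$pos, as.integer(window))
  for (ch in unique(variants$chrom)) {
    i <- which(variants$chrom == ch)
    len <- length(genome[[ch]])
    if (is.null(genome[[ch]])) stop("chromosome '", ch, "' not in genome", call. = FALSE)
    if (any(variants$pos[i] < 1L | variants$pos[i] > len)) {
      stop("variant position outside chromosome ", ch, call. = FALSE)
    }
    v <- Biostrings::Views(genome[[ch]],
                           start = pmax(1L, b$start[i]),
                           end = pmin(len, b$end[i]))
    counts <- Biostrings::letterFrequency(v, c("G", "C", "A", "T"))
    gc <- counts[, "G"] + counts[, "C"]
    tot <- rowSums(counts)
    out[i] <- ifelse(tot > 0, gc / tot, NA_real_)
  }
  out
}

#' Local mutation frequency
#'
#' Number of catalog variants on the same chromosome within `window/2`
#' positions of each query variant, excluding the query variant itself (a
#' catalog entry with identical chrom/pos/ref/alt).
#'
#' @param variants query variants.
#' @param catalog the full somatic catalog (all recurrence levels).
#' @param window total region width (default 1000, i.e. +/- 500).
#' @return non-negative integer vector aligned to `variants`.
#' @export
local_mutation_frequency <- function(variants, catalog, window = 1000L) {
  half <- as.integer(window) %/% 2L
  out <- integer(nrow(variants))
  if (nrow(catalog) == 0L || nrow(variants) == 0L) return(out)
  cat_key <- paste(catalog$chrom, catalog$pos, catalog$ref, catalog$alt)
  var_key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  for (ch in unique(variants$chrom)) {
    i <- which(variants$chrom == ch)
    p <- sort(catalog$pos[catalog$chrom == ch])
    if (length(p) == 0L) next
    x <- variants$pos[i]
    out[i] <- findInterval(x + half, p) - findInterval(x - half - 1L, p)
  }
  out - as.integer(var_key %in% cat_key)
}

#' k-mer spectrum around variants
#'
#' Normalized k-mer frequency vector over the reference window centered on
#' each variant. k-mers containing N are skipped; when no valid k-mer exists
#' the whole row is `NA`.
#'
#' @param genome a `DNAStringSet`.
#' @param variants variant `data.frame`.
#' @param k k-mer length.
#' @param window window width (must be >= k).
#' @return matrix of `4^k` columns, rows aligned to `variants`; defined rows
#'   sum to 1.
#' @export
kmer_spectrum <- function(genome, variants, k = 3L, window = 100L) {
  k <- as.integer(k)
  if (window < k) stop_config("window must be >= k")
  dimers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  out <- matrix(NA_real_, nrow(variants), length(dimers),
                dimnames = list(NULL, paste0("kmer_", dimers)))
  b <- window_bounds(variants$pos, as.integer(window))
  for (ch in unique(variants$chrom)) {
    i <- which(variants$chrom == ch)
    len <- length(genome[[ch]])
    v <- Biostrings::Views(genome[[ch]],
                           start = pmax(1L, b$start[i]),
                           end = pmin(len, b$end[i]))
    counts <- Biostrings::oligonucleotideFrequency(v, width = k)
    tot <- rowSums(counts)
    ok <- tot > 0
    counts[ok, ] <- counts[ok, , drop = FALSE] / tot[ok]
    counts[!ok, ] <- NA_real_
    out[i, ] <- counts
  }
  out
}

#' Distance to the nearest gene feature of each kind
#'
#' For each requested kind, the nucleotide distance from the variant position
#' to the nearest interval of that kind on the same chromosome (0 when
#' overlapping, `|pos - boundary|` otherwise), optionally log1p-transformed.
#' `NA` where the chromosome carries no interval of that kind.
#'
#' @param variants variant `data.frame`.
#' @param annotation `GRanges` with a `kind` column.
#' @param kinds feature kinds to measure against.
#' @param log_distance apply `log1p` to distances.
#' @return matrix with one column per kind, rows aligned to `variants`.
#' @export
proximity_features <- function(variants, annotation,
                               kinds = c("TSS", "splice_site", "TFBS", "CDS"),
                               log_distance = TRUE) {
  unknown <- setdiff(kinds, unique(c(INTERVAL_KINDS, annotation$kind)))
  if (length(unknown)) stop_config("unknown feature kind(s): ",
                                   paste(unknown, collapse = ", "))
  out <- matrix(NA_real_, nrow(variants), length(kinds),
                dimnames = list(NULL, paste0("dist_", kinds)))
  if (nrow(variants) == 0L) return(out)
  q <- variant_granges(variants)
  for (j in seq_along(kinds)) {
    sub <- annotation[annotation$kind == kinds[j]]
    if (length(sub) == 0L) next
    hits <- suppressWarnings(GenomicRanges::distanceToNearest(q, sub))
    qi <- S4Vectors::queryHits(hits)
    gap <- S4Vectors::mcols(hits)$distance
    ## GRanges distance is the gap (adjacent = 0); nucleotide distance to the
    ## boundary is gap + 1 for disjoint ranges and 0 when overlapping.
    ov <- suppressWarnings(GenomicRanges::countOverlaps(q[qi], sub)) > 0L
    d <- ifelse(ov, 0, gap + 1)
    out[qi, j] <- if (log_distance) log1p(d) else d
  }
  out
}

#' Score-track values at variant positions
#'
#' @param variants variant `data.frame`.
#' @param tracks named list of `score_track` objects.
#' @return matrix with one column per track (`NA` where a track has no value).
#' @export
track_features <- function(variants, tracks) {
  stopifnot(length(names(tracks)) == length(tracks))
  out <- vapply(tracks, function(tr) track_values(tr, variants$chrom, variants$pos),
                numeric(nrow(variants)))
  out <- matrix(out, nrow = nrow(variants), dimnames = list(NULL, names(tracks)))
  out
}

#' Functional-element overlap indicators
#'
#' One 0/1 indicator per element class: 1 iff the variant position overlaps
#' any element of that class.
#'
#' @param variants variant `data.frame`.
#' @param elements `GRanges` whose `kind` column carries element classes.
#' @param classes element classes to encode (default: all classes present,
#'   sorted).
#' @return 0/1 matrix with one column per class.
#' @export
functional_element_features <- function(variants, elements, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(elements$kind))
  out <- matrix(0, nrow(variants), length(classes),
                dimnames = list(NULL, paste0("elem_", classes)))
  if (nrow(variants) == 0L || length(elements) == 0L) return(out)
  q <- variant_granges(variants)
  for (j in seq_along(classes)) {
    sub <- elements[elements$kind == classes[j]]
    out[, j] <- as.integer(
      suppressWarnings(GenomicRanges::countOverlaps(q, sub)) > 0L
    )
  }
  out
}

#' Compute all feature groups for a variant set
#'
#' Builds the named list of row-aligned feature-group matrices used throughout
#' the pipeline: Conservation and Uniqueness from score tracks, GC and
#' Spectrum from the reference sequence, LocalMutFreq from the full catalog,
#' GeneProximity from the annotation and FunctionalElements from element
#' intervals.
#'
#' @param variants variant `data.frame` (rows define the alignment).
#' @param genome `DNAStringSet`.
#' @param annotation gene-feature `GRanges`.
#' @param tracks named list of `score_track`s (names matched against
#'   `config$conservation_tracks` / `config$uniqueness_tracks`).
#' @param elements functional-element `GRanges` (kind = class).
#' @param catalog full somatic catalog for mutation density (defaults to
#'   `variants`).
#' @param config a [feature_config()].
#' @return named list of matrices (one per feature group).
#' @export
compute_feature_groups <- function(variants, genome, annotation, tracks,
                                   elements, catalog = variants,
                                   config = feature_config()) {
  stopifnot(inherits(config, "feature_config"))
  cons <- tracks[intersect(config$conservation_tracks, names(tracks))]
  uniq <- tracks[intersect(config$uniqueness_tracks, names(tracks))]
  list(
    Conservation = track_features(variants, cons),
    GC = matrix(gc_content(genome, variants, config$gc_window),
                ncol = 1, dimnames = list(NULL, "gc_content")),
    Uniqueness = track_features(variants, uniq),
    LocalMutFreq = matrix(as.numeric(
      local_mutation_frequency(variants, catalog, config$mutfreq_window)),
      ncol = 1, dimnames = list(NULL, "local_mut_freq")),
    GeneProximity = proximity_features(variants, annotation,
                                       config$proximity_kinds,
                                       config$log_distance),
    Spectrum = kmer_spectrum(genome, variants, config$spectrum_k,
                             config$spectrum_window),
    FunctionalElements = functional_element_features(variants, elements,
                                                     config$element_classes)
  )
}

#' Assemble selected feature groups into one matrix
#'
#' Column-wise concatenation of the selected groups in stable order (group
#' order, then column order within a group), with missing values imputed using
#' statistics computed from the training rows only. Held-out rows never
#' contribute to imputation.
#'
#' @param groups named list of row-aligned feature matrices.
#' @param selected group names to concatenate (default all, in list order).
#' @param train_idx row indices whose values drive imputation statistics
#'   (default: all rows).
#' @param impute `"train_mean"` or `"zero"`.
#' @return numeric matrix over all rows with an `"impute_means"` attribute;
#'   all values finite.
#' @export
assemble_features <- function(groups, selected = names(groups),
                              train_idx = NULL, impute = c("train_mean", "zero")) {
  impute <- match.arg(impute)
  missing_groups <- setdiff(selected, names(groups))
  if (length(missing_groups)) {
    stop_config("unknown feature group(s): ", paste(missing_groups, collapse = ", "))
  }
  mats <- groups[selected]
  n <- unique(vapply(mats, nrow, integer(1)))
  if (length(n) != 1L) stop_config("feature groups are not row-aligned")
  x <- do.call(cbind, mats)
  if (is.null(train_idx)) train_idx <- seq_len(n)
  means <- colMeans(x[train_idx, , drop = FALSE], na.rm = TRUE)
  means[!is.finite(means)] <- 0        # all-missing column in training rows
  fill <- if (impute == "train_mean") means else rep(0, ncol(x))
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- fill[j]
  }
  attr(x, "impute_means") <- fill
  x
}
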