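test_that("GC content matches hand counts and the naive oracle", {
  g <- Biostrings::DNAStringSet(c(chr1 = "GGCCATAT"))
  v <- data.frame(chrom = "chr1", pos = c(3L, 7L))
  expect_equal(gc_content(g, v, window = 4), c(1, 0))
  expect_error(gc_content(g, data.frame(chrom = "chr1", pos = 99L), 4),
               "outside")
  ## all-N window is missing, partial N windows use non-N denominator
  gn <- Biostrings::DNAStringSet(c(chr1 = "NNNNGCNN"))
  vn <- data.frame(chrom = "chr1", pos = c(2L, 5L))
  expect_equal(gc_content(gn, vn, window = 2), c(NA, 1))

  set.seed(3)
  seqstr <- paste(sample(c("A", "C", "G", "T", "N"), 500, replace = TRUE,
                         prob = c(.24, .24, .24, .24, .04)), collapse = "")
  g2 <- Biostrings::DNAStringSet(c(chr1 = seqstr))
  v2 <- data.frame(chrom = "chr1", pos = sample(500, 100))
  w <- 21
  expect_equal(gc_content(g2, v2, w),
               vapply(v2$pos, naive_gc, numeric(1), seqstr = seqstr, window = w))
})

test_that("k-mer spectra normalize correctly and match naive counting", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGAT"))
  v <- data.frame(chrom = "chr1", pos = 3L)
  sp <- kmer_spectrum(g, v, k = 2, window = 4)
  expect_equal(sum(sp), 1)
  expect_equal(unname(sp[1, c("kmer_AC", "kmer_CG", "kmer_GA")]),
               rep(1 / 3, 3))
  ghom <- Biostrings::DNAStringSet(c(chr1 = "AAAAA"))
  sph <- kmer_spectrum(ghom, v, k = 2, window = 4)
  expect_equal(unname(sph[1, "kmer_AA"]), 1)
  expect_equal(sum(sph), 1)
  expect_error(kmer_spectrum(g, v, k = 5, window = 4), ">= k")

  set.seed(13)
  seqstr <- paste(sample(c("A", "C", "G", "T", "N"), 400, replace = TRUE,
                         prob = c(.24, .24, .24, .24, .04)), collapse = "")
  g2 <- Biostrings::DNAStringSet(c(chr1 = seqstr))
  pos <- sample(400, 50)
  got <- kmer_spectrum(g2, data.frame(chrom = "chr1", pos = pos), k = 3,
                       window = 30)
  for (i in seq_along(pos)) {
    expect_equal(unname(got[i, ]),
                 naive_spectrum(seqstr, pos[i], 3, 30))
  }
})

test_that("local mutation frequency excludes self and matches brute force", {
  cat <- data.frame(chrom = "chr1", pos = c(600L, 1000L, 1450L),
                    ref = c("A", "C", "G"), alt = c("C", "T", "A"))
  q <- cat[2, ]
  expect_equal(local_mutation_frequency(q, cat, window = 1000), 2L)
  expect_equal(local_mutation_frequency(q, cat[0, ], window = 1000), 0L)

  set.seed(29)
  cat2 <- rand_variants(1000, maxpos = 20000L)
  cat2 <- cat2[!duplicated(cat2[c("chrom", "pos")]), ]
  q2 <- rbind(cat2[sample(nrow(cat2), 25), ], rand_variants(25, maxpos = 20000L))
  w <- 800
  got <- local_mutation_frequency(q2, cat2, w)
  want <- vapply(seq_len(nrow(q2)), function(i) {
    inwin <- sum(cat2$chrom == q2$chrom[i] & abs(cat2$pos - q2$pos[i]) <= w %/% 2)
    self <- any(cat2$chrom == q2$chrom[i] & cat2$pos == q2$pos[i] &
                  cat2$ref == q2$ref[i] & cat2$alt == q2$alt[i])
    as.integer(inwin - self)
  }, integer(1))
  expect_equal(got, want)
  ## monotone non-decreasing in window width
  expect_true(all(local_mutation_frequency(q2, cat2, 2000) >= got))
})

test_that("proximity features match brute force and reflect symmetrically", {
  ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(200L, 700L), c(210L, 790L)),
                                kind = c("TSS", "TSS"))
  v <- data.frame(chrom = "chr1", pos = c(100L, 205L, 500L))
  d <- proximity_features(v, ann, kinds = "TSS", log_distance = FALSE)
  expect_equal(unname(d[, 1]), c(100, 0, 200))
  expect_equal(unname(proximity_features(v, ann, "TSS", TRUE)[, 1]),
               log1p(c(100, 0, 200)))
  expect_error(proximity_features(v, ann, kinds = "promoter_zone"), "unknown")
  ## no interval of the kind on the chromosome: missing
  expect_true(all(is.na(proximity_features(v, ann, kinds = "CDS")[, 1])))

  set.seed(53)
  L <- 10000L
  starts <- sample(L - 60L, 80)
  ends <- starts + sample(0:60, 80, replace = TRUE)
  ann2 <- GenomicRanges::GRanges(sample(c("chr1", "chr2"), 80, replace = TRUE),
                                 IRanges::IRanges(starts, ends),
                                 kind = sample(c("TSS", "TFBS"), 80, replace = TRUE))
  v2 <- rand_variants(200, maxpos = L)
  got <- proximity_features(v2, ann2, c("TSS", "TFBS"), log_distance = FALSE)
  chroms <- as.character(GenomicRanges::seqnames(ann2))
  for (kk in c("TSS", "TFBS")) {
    want <- vapply(seq_len(nrow(v2)), function(i) {
      sel <- ann2$kind == kk & chroms == v2$chrom[i]
      if (!any(sel)) return(NA_real_)
      s <- GenomicRanges::start(ann2)[sel]; e <- GenomicRanges::end(ann2)[sel]
      min(ifelse(v2$pos[i] >= s & v2$pos[i] <= e, 0,
                 pmin(abs(v2$pos[i] - s), abs(v2$pos[i] - e))))
    }, numeric(1))
    expect_equal(unname(got[, paste0("dist_", kk)]), want)
  }
  ## reflection symmetry: distances invariant under coordinate reflection
  refl_v <- transform(v2, pos = L + 1L - pos)
  refl_ann <- GenomicRanges::GRanges(chroms,
                                     IRanges::IRanges(L + 1L - GenomicRanges::end(ann2),
                                                      L + 1L - GenomicRanges::start(ann2)),
                                     kind = ann2$kind)
  expect_equal(proximity_features(refl_v, refl_ann, c("TSS", "TFBS"), FALSE),
               got)
})

test_that("track and element features read values and overlap indicators", {
  tr <- score_track(GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 120),
                                           score = 0.9))
  v <- data.frame(chrom = "chr1", pos = c(110L, 500L))
  tf <- track_features(v, list(cons = tr))
  expect_equal(unname(tf[, "cons"]), c(0.9, NA))

  el <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(100L, 105L, 300L), width = 20L),
                               kind = c("enhancer_like", "promoter_like",
                                        "enhancer_like"))
  fe <- functional_element_features(v, el)
  expect_equal(unname(fe[1, ]), c(1, 1))   # overlaps both classes
  expect_equal(unname(fe[2, ]), c(0, 0))

  set.seed(61)
  v3 <- rand_variants(300, maxpos = 5000L)
  el3 <- GenomicRanges::GRanges(sample(c("chr1", "chr2"), 60, TRUE),
                                IRanges::IRanges(sample(4900L, 60), width = 80L),
                                kind = sample(c("a", "b"), 60, TRUE))
  got <- functional_element_features(v3, el3, classes = c("a", "b"))
  chroms <- as.character(GenomicRanges::seqnames(el3))
  for (cl in c("a", "b")) {
    want <- vapply(seq_len(nrow(v3)), function(i) {
      as.integer(any(el3$kind == cl & chroms == v3$chrom[i] &
                       GenomicRanges::start(el3) <= v3$pos[i] &
                       GenomicRanges::end(el3) >= v3$pos[i]))
    }, integer(1))
    expect_equal(unname(got[, paste0("elem_", cl)]), want)
  }
})

test_that("assembly concatenates stably and imputes from training rows only", {
  set.seed(71)
  g <- list(A = matrix(stats::rnorm(30), 10, 3,
                       dimnames = list(NULL, paste0("a", 1:3))),
            B = matrix(stats::rnorm(50), 10, 5,
                       dimnames = list(NULL, paste0("b", 1:5))))
  x <- assemble_features(g)
  expect_equal(ncol(x), 8L)
  expect_equal(colnames(x), c(paste0("a", 1:3), paste0("b", 1:5)))

  g$A[3, 2] <- NA; g$A[9, 2] <- NA
  train <- 1:6
  x2 <- assemble_features(g, train_idx = train)
  m_indep <- mean(g$A[intersect(train, which(!is.na(g$A[, 2]))), 2])
  expect_equal(unname(x2[3, "a2"]), m_indep)
  expect_equal(unname(x2[9, "a2"]), m_indep)
  expect_true(all(is.finite(x2)))

  ## leakage: perturbing held-out rows never changes imputation statistics
  g_pert <- g
  g_pert$A[7:10, ] <- g_pert$A[7:10, , drop = FALSE] + 100
  g_pert$A[9, 2] <- NA
  x3 <- assemble_features(g_pert, train_idx = train)
  expect_identical(attr(x2, "impute_means"), attr(x3, "impute_means"))
  expect_identical(x2[train, ], x3[train, ])
  ## single selected group equals that group's matrix post-imputation
  one <- assemble_features(g, selected = "B")
  expect_equal(unname(one[, ]), unname(g$B), ignore_attr = TRUE)
  expect_error(assemble_features(g, selected = "Z"), "unknown")
  expect_error(assemble_features(list(A = g$A, B = g$B[1:5, ])), "row-aligned")
})
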