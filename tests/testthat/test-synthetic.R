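test_that("catalog counts and recurrence structure follow the configuration", {
  cfg <- sim_config(n_chroms = 2, chrom_length = 50000, n_drivers = 20,
                    n_passengers = 200, seed = 8)
  s <- simulate_study(cfg)
  expect_equal(nrow(s$catalog), 220L)
  expect_equal(sum(s$catalog$r >= cfg$rho_sim), 20L)
  expect_true(all(s$catalog$r[s$truth != "driver"] == 1L))
  expect_true(all(s$catalog$r <= cfg$r_max))
  ## variants are unique and lie on the simulated chromosomes
  expect_false(any(duplicated(s$catalog[c("chrom", "pos")])))
  expect_true(all(s$catalog$pos >= 1 & s$catalog$pos <= cfg$chrom_length))
  expect_true(all(s$catalog$ref != s$catalog$alt))
  ## reference alleles match the genome
  idx <- sample(nrow(s$catalog), 25)
  refs <- vapply(idx, function(i) {
    as.character(Biostrings::subseq(s$genome[[s$catalog$chrom[i]]],
                                    s$catalog$pos[i], s$catalog$pos[i]))
  }, character(1))
  expect_equal(refs, s$catalog$ref[idx])
  ## near/far passenger mix: both present
  expect_true(all(c("near", "far") %in% s$truth))
})

test_that("generation is deterministic under the seed and varies across seeds", {
  cfg <- sim_config(n_chroms = 2, chrom_length = 20000, n_drivers = 10,
                    n_passengers = 80, seed = 3)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$catalog, b$catalog)
  expect_identical(a$tracks$phastcons_like$ranges$score,
                   b$tracks$phastcons_like$ranges$score)
  cfg2 <- sim_config(n_chroms = 2, chrom_length = 20000, n_drivers = 10,
                     n_passengers = 80, seed = 4)
  c <- simulate_study(cfg2)
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
  expect_false(identical(a$catalog, c$catalog))
})

test_that("planted track effects have the configured magnitude", {
  cfg <- sim_config(n_chroms = 4, chrom_length = 50000, n_drivers = 60,
                    n_passengers = 60, effect_sizes = c(Conservation = 2),
                    seed = 15)
  s <- simulate_genome(cfg)
  vals_at <- function(df) track_values(s$tracks$phastcons_like, df$chrom, df$pos)
  core <- vals_at(s$hotspots)
  set.seed(1)
  bg <- data.frame(chrom = sample(paste0("chr", 1:4), 4000, replace = TRUE),
                   pos = sample(50000L, 4000, replace = TRUE))
  far <- bg[vapply(seq_len(nrow(bg)), function(i) {
    hp <- s$hotspots$pos[s$hotspots$chrom == bg$chrom[i]]
    length(hp) == 0L || min(abs(hp - bg$pos[i])) > cfg$bump_radius + 100L
  }, logical(1)), ]
  shift <- mean(core) - mean(vals_at(far))
  expect_gt(shift, 1.5)   # configured 2 SD, Monte-Carlo tolerance
  expect_lt(shift, 2.5)
  ## uniqueness track was not shifted
  uniq_core <- track_values(s$tracks$uniqueness_like, s$hotspots$chrom,
                            s$hotspots$pos)
  expect_lt(abs(mean(uniq_core)), 0.75)
})

test_that("all synthetic outputs re-parse through the format readers", {
  outdir <- withr::local_tempdir()
  cfg <- sim_config(n_chroms = 2, chrom_length = 20000, n_drivers = 12,
                    n_passengers = 100, germline_mode = TRUE,
                    n_germline = 50, seed = 6)
  s <- simulate_study(cfg, outdir = outdir)
  ## FASTA
  g <- read_genome(file.path(outdir, "ref.fa"))
  expect_identical(as.character(g), as.character(s$genome))
  ## VCF, including recurrence counts
  v <- read_variants(file.path(outdir, "somatic.vcf"))
  ord <- order(s$catalog$chrom, s$catalog$pos, s$catalog$alt)
  expect_equal(v[, c("chrom", "pos", "ref", "alt", "r")],
               `rownames<-`(s$catalog[ord, c("chrom", "pos", "ref", "alt", "r")],
                            NULL))
  gl <- read_variants(file.path(outdir, "germline.vcf"))
  expect_equal(nrow(gl), 50L)
  ## GFF3 annotation
  ann <- read_intervals(file.path(outdir, "genes.gff3"), format = "gff3")
  expect_equal(length(ann), length(s$annotation))
  expect_setequal(unique(ann$kind), unique(s$annotation$kind))
  ## BED elements
  el <- read_intervals(file.path(outdir, "elements.bed"), format = "bed",
                       kinds = NULL)
  expect_equal(length(el), length(s$elements))
  expect_equal(sort(GenomicRanges::start(el)),
               sort(GenomicRanges::start(s$elements)))
  ## bedGraph tracks: spot-check values at variant positions
  tr <- read_score_track(file.path(outdir, "tracks", "phastcons_like.bedgraph"))
  q <- s$catalog[1:20, ]
  expect_equal(track_values(tr, q$chrom, q$pos),
               track_values(s$tracks$phastcons_like, q$chrom, q$pos),
               tolerance = 1e-6)
  ## manifest records the ground truth
  mf <- jsonlite::read_json(file.path(outdir, "manifest.json"),
                            simplifyVector = TRUE)
  expect_equal(nrow(mf$truth), nrow(s$catalog))
  expect_equal(mf$config$seed, 6)
})

test_that("germline mode plants detectable somatic-vs-germline shifts", {
  cfg <- sim_config(n_chroms = 4, chrom_length = 50000, n_drivers = 40,
                    n_passengers = 400, germline_mode = TRUE,
                    n_germline = 400, germline_contrast = 1.5, seed = 9)
  s <- simulate_study(cfg)
  pass <- s$catalog[s$truth == "near", ]
  cons_pass <- track_values(s$tracks$phylop_like, pass$chrom, pass$pos)
  cons_germ <- track_values(s$tracks$phylop_like, s$germline$chrom,
                            s$germline$pos)
  dt <- distribution_test(cons_pass, cons_germ)
  expect_lt(dt$log10_p_bound, -5)
  expect_gt(mean(cons_pass), mean(cons_germ))
  ## rare somatic variants also sit in denser mutation neighbourhoods
  dens_pass <- local_mutation_frequency(pass, s$catalog)
  dens_germ <- local_mutation_frequency(s$germline, s$catalog)
  expect_gt(mean(dens_pass), mean(dens_germ))
})
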