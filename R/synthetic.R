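## Seeded synthetic-data generator: random genomes, planted gene-feature
## annotations, per-position score tracks and recurrence-structured somatic
## catalogs with controllable class-conditional effects, so every pipeline
## stage is testable without external downloads. All outputs are synthetic
## stand-ins for the corresponding public resources.

#' Synthetic study configuration
#'
#' Defaults define a small driver/passenger study: a handful of autosomes,
#' hotspots hosting highly recurrent (driver-like) variants with recurrence
#' drawn from a truncated geometric distribution, and singleton (`r = 1`)
#' passengers placed both within the matching window of a hotspot and far
#' from any hotspot, so window matching has true positives and true negatives
#' to filter. Per-group effect sizes are expressed in SD units of the
#' baseline feature distribution.
#'
#' @param n_chroms number of autosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length length of each chromosome in bases.
#' @param n_drivers number of hotspot driver variants (`r >= rho_sim`).
#' @param n_passengers number of singleton (`r = 1`) variants.
#' @param near_frac fraction of passengers placed within `window` of a
#'   hotspot (the rest are placed beyond it).
#' @param window matching window emulated by placement (nucleotides).
#' @param rho_sim minimum driver recurrence.
#' @param r_max maximum recurrence.
#' @param r_geom_p geometric decay parameter of the recurrence distribution.
#' @param effect_sizes named numeric vector of per-group class-conditional
#'   shifts, in SD units, over
#'   `Conservation, GC, Uniqueness, LocalMutFreq, GeneProximity, Spectrum,
#'   FunctionalElements` (missing names default to 0).
#' @param effect_by_r scale each hotspot's planted effect linearly with its
#'   recurrence level (and widen the recurrence support down to `r = 2`), for
#'   threshold-sweep experiments.
#' @param effect_split make the Conservation and Uniqueness track effects
#'   complementary: each hotspot is randomly assigned one of the two, so
#'   either group alone explains only part of the drivers and their
#'   combination is required for full separation (a feature-group-selection
#'   test bed).
#' @param germline_mode also generate a germline-like cohort placed away from
#'   hotspot neighbourhoods, with somatic-variant neighbourhoods shifted by
#'   `germline_contrast` SD so somatic-vs-germline distribution comparisons
#'   have a planted signal.
#' @param n_germline germline-like cohort size.
#' @param germline_contrast SD shift of track values in hotspot
#'   neighbourhoods (radius `window`) relative to germline territory.
#' @param bump_radius radius in bases of the hotspot core where per-group
#'   effects are planted.
#' @param track_bin score-track bin width in bases.
#' @param seed integer seed; identical configuration and seed give
#'   byte-identical outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 4L, chrom_length = 100000L,
                       n_drivers = 60L, n_passengers = 600L,
                       near_frac = 0.7, window = 1000L,
                       rho_sim = 7L, r_max = 20L, r_geom_p = 0.4,
                       effect_sizes = NULL, effect_by_r = FALSE,
                       effect_split = FALSE,
                       germline_mode = FALSE, n_germline = 1000L,
                       germline_contrast = 1,
                       bump_radius = 150L, track_bin = 25L, seed = 1L) {
  base <- stats::setNames(rep(0, length(FEATURE_GROUPS)), FEATURE_GROUPS)
  if (!is.null(effect_sizes)) {
    unknown <- setdiff(names(effect_sizes), FEATURE_GROUPS)
    if (length(unknown)) stop_config("unknown effect group(s): ",
                                     paste(unknown, collapse = ", "))
    base[names(effect_sizes)] <- effect_sizes
  }
  if (!all(is.finite(base))) stop_config("effect sizes must be finite")
  if (n_chroms < 1L || chrom_length < 1000L || n_drivers < 1L || n_passengers < 1L) {
    stop_config("counts and lengths must be positive (chromosomes >= 1 kb)")
  }
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_drivers = as.integer(n_drivers),
                 n_passengers = as.integer(n_passengers),
                 near_frac = near_frac, window = as.integer(window),
                 rho_sim = as.integer(rho_sim), r_max = as.integer(r_max),
                 r_geom_p = r_geom_p,
                 effect_sizes = base, effect_by_r = isTRUE(effect_by_r),
                 effect_split = isTRUE(effect_split),
                 germline_mode = isTRUE(germline_mode),
                 n_germline = as.integer(n_germline),
                 germline_contrast = germline_contrast,
                 bump_radius = as.integer(bump_radius),
                 track_bin = as.integer(track_bin),
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Truncated geometric recurrence levels on [lo, hi].
sample_recurrence <- function(n, lo, hi, p) {
  support <- lo:hi
  probs <- p * (1 - p)^(seq_along(support) - 1)
  sample(support, n, replace = TRUE, prob = probs / sum(probs))
}

## Random non-overlapping interval starts on [margin, len - width - margin].
random_starts <- function(n, len, width, margin = 100L) {
  lo <- margin
  hi <- max(lo + 1L, len - width - margin)
  sort(sample(lo:hi, n, replace = FALSE))
}

#' Simulate a genome with annotation, elements and score tracks
#'
#' Generates a uniform-composition genome, plants CDS/TSS/splice-site/TFBS
#' intervals and functional elements, places driver hotspots (with assigned
#' recurrence levels), and draws conservation-like and uniqueness-like score
#' tracks from a standard-normal baseline, elevated in hotspot cores by the
#' configured effect sizes. GC/Spectrum effects reshape the hotspot-core
#' sequence composition; GeneProximity and FunctionalElements effects plant
#' intervals near a fraction of hotspots.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_genome`: `genome` (`DNAStringSet`),
#'   `annotation` and `elements` (`GRanges` with `kind`), `tracks` (named
#'   `score_track` list), `hotspots` (`data.frame` with `chrom`, `pos`, `r`,
#'   `scale`), and `cfg`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(cfg$seed, {
    chroms <- paste0("chr", seq_len(cfg$n_chroms))
    len <- cfg$chrom_length
    eff <- cfg$effect_sizes

    ## hotspots: spread across chromosomes, preferring a 3-window spacing but
    ## relaxing it (down to disjoint cores) when the chromosome is crowded,
    ## so the requested count is always placed when physically possible
    per_chrom <- diff(round(seq(0, cfg$n_drivers, length.out = cfg$n_chroms + 1)))
    min_gap <- 2L * cfg$bump_radius + 50L
    hotspots <- do.call(rbind, lapply(seq_along(chroms), function(i) {
      k <- per_chrom[i]
      if (k == 0L) return(NULL)
      gap <- max(3L * cfg$window, min_gap)
      pos <- integer(0)
      tries <- 0L
      while (length(pos) < k) {
        cand <- sample(seq(2L * cfg$window, len - 2L * cfg$window), k - length(pos))
        for (p in cand) if (all(abs(p - pos) >= gap)) pos <- c(pos, p)
        tries <- tries + 1L
        if (tries %% 50L == 0L) {
          if (gap <= min_gap) break
          gap <- max(gap %/% 2L, min_gap)
        }
      }
      data.frame(chrom = chroms[i], pos = sort(pos), stringsAsFactors = FALSE)
    }))
    r_lo <- if (cfg$effect_by_r) 2L else cfg$rho_sim
    hotspots$r <- sample_recurrence(nrow(hotspots), r_lo, cfg$r_max, cfg$r_geom_p)
    hotspots$scale <- if (cfg$effect_by_r) {
      (hotspots$r - 1) / (cfg$r_max - 1)
    } else rep(1, nrow(hotspots))
    ## complementary-effect assignment: half the hotspots carry the
    ## Conservation shift, the other half the Uniqueness shift
    hotspots$eff_group <- if (cfg$effect_split) {
      sample(rep(c("conservation", "uniqueness"),
                 length.out = nrow(hotspots)))
    } else rep("both", nrow(hotspots))

    ## genome sequence, with composition effects planted in hotspot cores
    bases <- c("A", "C", "G", "T")
    seqs <- lapply(chroms, function(ch) sample(bases, len, replace = TRUE))
    names(seqs) <- chroms
    for (i in seq_len(nrow(hotspots))) {
      h <- hotspots[i, ]
      core <- max(1L, h$pos - cfg$bump_radius):min(len, h$pos + cfg$bump_radius)
      if (eff[["GC"]] != 0) {
        ## gc_content over a 100 bp window has baseline SD ~ 0.05
        p_gc <- min(0.95, max(0.05, 0.5 + 0.05 * eff[["GC"]] * h$scale))
        seqs[[h$chrom]][core] <- sample(bases, length(core), replace = TRUE,
                                        prob = c((1 - p_gc) / 2, p_gc / 2,
                                                 p_gc / 2, (1 - p_gc) / 2))
      }
      if (eff[["Spectrum"]] != 0) {
        n_motif <- max(0L, round(3 * eff[["Spectrum"]] * h$scale))
        if (n_motif > 0L && length(core) > 6L) {
          starts <- sample(core[seq_len(length(core) - 3L)], n_motif, replace = TRUE)
          for (s in starts) seqs[[h$chrom]][s:(s + 2L)] <- c("A", "C", "G")
        }
      }
    }
    genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                              collapse = ""))
    names(genome) <- chroms

    ## gene-feature annotation
    ann <- list()
    widths <- c(CDS = 300L, TSS = 10L, splice_site = 2L, TFBS = 12L)
    counts <- c(CDS = 40L, TSS = 40L, splice_site = 60L, TFBS = 60L)
    for (ch in chroms) {
      for (kind in names(widths)) {
        st <- random_starts(counts[[kind]], len, widths[[kind]])
        ann[[length(ann) + 1L]] <- GenomicRanges::GRanges(
          ch, IRanges::IRanges(st, width = widths[[kind]]), kind = kind)
      }
    }
    ## proximity effect: plant a TSS close to a fraction of hotspots
    if (eff[["GeneProximity"]] != 0) {
      frac <- min(1, 0.25 * abs(eff[["GeneProximity"]]))
      take <- which(stats::runif(nrow(hotspots)) < frac * hotspots$scale)
      if (length(take)) {
        st <- pmin(len - 10L, hotspots$pos[take] + sample(50:200, length(take),
                                                          replace = TRUE))
        ann[[length(ann) + 1L]] <- GenomicRanges::GRanges(
          hotspots$chrom[take], IRanges::IRanges(st, width = 10L), kind = "TSS")
      }
    }
    annotation <- sort(suppressWarnings(do.call(c, ann)))

    ## functional elements in two classes
    el <- list()
    for (ch in chroms) {
      st <- random_starts(30L, len, 200L)
      el[[length(el) + 1L]] <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(st, width = 200L),
        kind = sample(c("enhancer_like", "promoter_like"), 30L, replace = TRUE))
    }
    if (eff[["FunctionalElements"]] != 0) {
      frac <- min(1, 0.3 * abs(eff[["FunctionalElements"]]))
      take <- which(stats::runif(nrow(hotspots)) < frac * hotspots$scale)
      if (length(take)) {
        st <- pmax(1L, hotspots$pos[take] - 100L)
        el[[length(el) + 1L]] <- GenomicRanges::GRanges(
          hotspots$chrom[take], IRanges::IRanges(st, width = 200L),
          kind = "enhancer_like")
      }
    }
    elements <- sort(suppressWarnings(do.call(c, el)))

    ## score tracks: standard-normal bins, elevated in hotspot cores; the
    ## wider hotspot neighbourhood is shifted by germline_contrast so somatic
    ## cohorts (placed near hotspots) differ from germline-like ones
    track_names <- c("phastcons_like", "phylop_like", "uniqueness_like")
    track_eff <- c(phastcons_like = eff[["Conservation"]],
                   phylop_like = eff[["Conservation"]],
                   uniqueness_like = eff[["Uniqueness"]])
    nbins <- ceiling(len / cfg$track_bin)
    starts <- (seq_len(nbins) - 1L) * cfg$track_bin + 1L
    ends <- pmin(len, starts + cfg$track_bin - 1L)
    tracks <- lapply(track_names, function(tn) {
      grl <- lapply(chroms, function(ch) {
        val <- stats::rnorm(nbins)
        h <- hotspots[hotspots$chrom == ch, , drop = FALSE]
        for (i in seq_len(nrow(h))) {
          if (cfg$germline_mode && cfg$germline_contrast != 0) {
            nb <- which(ends >= h$pos[i] - cfg$window & starts <= h$pos[i] + cfg$window)
            val[nb] <- val[nb] + cfg$germline_contrast
          }
          applies <- h$eff_group[i] == "both" ||
            (h$eff_group[i] == "conservation" && tn != "uniqueness_like") ||
            (h$eff_group[i] == "uniqueness" && tn == "uniqueness_like")
          if (track_eff[[tn]] != 0 && applies) {
            core <- which(ends >= h$pos[i] - cfg$bump_radius &
                            starts <= h$pos[i] + cfg$bump_radius)
            val[core] <- val[core] + track_eff[[tn]] * h$scale[i]
          }
        }
        GenomicRanges::GRanges(ch, IRanges::IRanges(starts, ends), score = val)
      })
      score_track(suppressWarnings(do.call(c, grl)))
    })
    names(tracks) <- track_names

    structure(list(genome = genome, annotation = annotation,
                   elements = elements, tracks = tracks,
                   hotspots = hotspots, cfg = cfg),
              class = "sim_genome")
  })
}

alt_base <- function(ref) {
  vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
         character(1), USE.NAMES = FALSE)
}

#' Simulate a recurrence-structured somatic catalog
#'
#' Places one driver variant at each hotspot with its assigned recurrence,
#' and singleton passengers both within the matching window of a hotspot
#' (`near_frac`) and beyond it. With `germline_mode`, also generates a
#' germline-like cohort placed away from hotspot neighbourhoods.
#'
#' @param cfg a [sim_config()].
#' @param sim a `sim_genome` from [simulate_genome()].
#' @return list of class `sim_catalog`: `catalog` (`data.frame` with `chrom`,
#'   `pos`, `ref`, `alt`, `r`), `truth` (`origin` per catalog row:
#'   driver/near/far), and optionally `germline`.
#' @export
simulate_catalog <- function(cfg, sim) {
  stopifnot(inherits(cfg, "sim_config"), inherits(sim, "sim_genome"))
  local_seed(cfg$seed + 1L, {
    len <- cfg$chrom_length
    hs <- sim$hotspots
    used <- paste(hs$chrom, hs$pos)

    draw_positions <- function(n, placer) {
      out_ch <- character(0); out_pos <- integer(0)
      tries <- 0L
      while (length(out_pos) < n && tries < 500L) {
        cand <- placer(n - length(out_pos))
        key <- paste(cand$chrom, cand$pos)
        ok <- !(key %in% used) & !duplicated(key) &
          cand$pos >= 1L & cand$pos <= len
        used <<- c(used, key[ok])
        out_ch <- c(out_ch, cand$chrom[ok])
        out_pos <- c(out_pos, cand$pos[ok])
        tries <- tries + 1L
      }
      data.frame(chrom = out_ch, pos = out_pos, stringsAsFactors = FALSE)
    }

    near_min <- cfg$bump_radius + 50L
    place_near <- function(k) {
      i <- sample(nrow(hs), k, replace = TRUE)
      off <- sample(near_min:cfg$window, k, replace = TRUE) *
        sample(c(-1L, 1L), k, replace = TRUE)
      data.frame(chrom = hs$chrom[i], pos = hs$pos[i] + off,
                 stringsAsFactors = FALSE)
    }
    place_far <- function(k) {
      ch <- sample(paste0("chr", seq_len(cfg$n_chroms)), k, replace = TRUE)
      ## same chromosome-end margin as hotspot placement, so passenger and
      ## driver feature windows are clipped identically (no edge confound)
      pos <- sample(seq(2L * cfg$window, len - 2L * cfg$window), k,
                    replace = TRUE)
      d <- data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
      ## reject positions within the window of any hotspot
      ok <- vapply(seq_len(k), function(j) {
        hp <- hs$pos[hs$chrom == d$chrom[j]]
        length(hp) == 0L || min(abs(hp - d$pos[j])) > cfg$window
      }, logical(1))
      d[ok, , drop = FALSE]
    }

    n_near <- round(cfg$near_frac * cfg$n_passengers)
    near <- draw_positions(n_near, place_near)
    far <- draw_positions(cfg$n_passengers - n_near, place_far)

    ref_at <- function(chrom, pos) {
      vapply(seq_along(pos), function(j) {
        as.character(Biostrings::subseq(sim$genome[[chrom[j]]], pos[j], pos[j]))
      }, character(1))
    }
    mk <- function(d, r, origin) {
      if (nrow(d) == 0L) {
        return(cbind(d, data.frame(ref = character(0), alt = character(0),
                                   r = integer(0), origin = character(0))))
      }
      d$ref <- ref_at(d$chrom, d$pos)
      d$alt <- alt_base(d$ref)
      d$r <- r
      d$origin <- origin
      d
    }
    drivers <- mk(hs[, c("chrom", "pos")], hs$r, "driver")
    near <- mk(near, 1L, "near")
    far <- mk(far, 1L, "far")
    catalog <- rbind(drivers, near, far)
    rownames(catalog) <- NULL
    truth <- catalog$origin
    catalog$origin <- NULL

    germline <- NULL
    if (cfg$germline_mode) {
      g <- draw_positions(cfg$n_germline, place_far)
      germline <- mk(g, 1L, "germline")
      germline$origin <- NULL
    }
    structure(list(catalog = catalog, truth = truth, germline = germline),
              class = "sim_catalog")
  })
}

#' Simulate a complete study, optionally writing files
#'
#' Runs [simulate_genome()] and [simulate_catalog()] and, when `outdir` is
#' given, writes `ref.fa`, `genes.gff3`, `elements.bed`,
#' `tracks/<name>.bedgraph`, `somatic.vcf` (recurrence in INFO `CNT`),
#' optionally `germline.vcf`, and `manifest.json` recording the ground truth.
#'
#' @param cfg a [sim_config()].
#' @param outdir optional output directory.
#' @return list of class `sim_study` combining the genome-simulation and
#'   catalog objects (plus `paths` when files were written).
#' @export
simulate_study <- function(cfg, outdir = NULL) {
  sim <- simulate_genome(cfg)
  cat <- simulate_catalog(cfg, sim)
  out <- structure(c(sim, cat), class = "sim_study")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(outdir, "tracks"), showWarnings = FALSE)
    paths <- list(
      genome = file.path(outdir, "ref.fa"),
      annotation = file.path(outdir, "genes.gff3"),
      elements = file.path(outdir, "elements.bed"),
      somatic = file.path(outdir, "somatic.vcf"),
      manifest = file.path(outdir, "manifest.json")
    )
    Biostrings::writeXStringSet(sim$genome, paths$genome)
    ann <- sim$annotation
    ann$type <- ann$kind
    ann$source <- "sim"
    ann$phase <- ifelse(ann$kind == "CDS", 0L, NA_integer_)
    rtracklayer::export(ann, paths$annotation, format = "gff3")
    el <- sim$elements
    el$name <- el$kind
    rtracklayer::export(el, paths$elements, format = "bed")
    for (tn in names(sim$tracks)) {
      p <- file.path(outdir, "tracks", paste0(tn, ".bedgraph"))
      rtracklayer::export(sim$tracks[[tn]]$ranges, p, format = "bedGraph")
      paths[[paste0("track_", tn)]] <- p
    }
    write_vcf(cat$catalog, paths$somatic)
    if (!is.null(cat$germline)) {
      paths$germline <- file.path(outdir, "germline.vcf")
      write_vcf(cat$germline, paths$germline)
    }
    manifest <- list(
      config = unclass(cfg),
      hotspots = sim$hotspots,
      truth = data.frame(chrom = cat$catalog$chrom, pos = cat$catalog$pos,
                         origin = cat$truth),
      effect_sizes = as.list(cfg$effect_sizes)
    )
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  out
}

#' @export
print.sim_study <- function(x, ...) {
  cat("sim_study:", length(x$genome), "chromosomes of",
      x$cfg$chrom_length, "bp;", nrow(x$catalog), "somatic variants (",
      sum(x$truth == "driver"), "drivers )\n")
  invisible(x)
}
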