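## Readers and writers for the standard genomic formats the pipeline touches.
## All format dialects are converted at this boundary: internally every
## interval is a 1-based closed GRanges and every variant position is 1-based,
## matching VCF.

INTERVAL_KINDS <- c("CDS", "splice_site", "TSS", "TFBS", "functional_element")

#' Read a genome from FASTA
#'
#' @param path path to a (plain-text) FASTA file.
#' @return a [Biostrings::DNAStringSet] with normalized chromosome names.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  ## FASTA headers may carry descriptions; keep the first token only.
  names(g) <- normalize_chrom(sub("\\s.*$", "", names(g)))
  g
}

genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

## Extract a window [start, end] from a chromosome, clipping at the ends.
## The anchor position itself must lie within the chromosome.
genome_window <- function(genome, chrom, pos, start, end) {
  if (!chrom %in% names(genome)) {
    stop("chromosome '", chrom, "' not present in genome", call. = FALSE)
  }
  len <- length(genome[[chrom]])
  if (pos < 1L || pos > len) {
    stop("position ", pos, " outside [1, ", len, "] on ", chrom, call. = FALSE)
  }
  Biostrings::subseq(genome[[chrom]], start = max(1L, start), end = min(len, end))
}

#' Read somatic SNVs from a VCF file
#'
#' Parses a VCF 4.x file and returns single-nucleotide substitutions with a
#' recurrence count taken from an INFO key (COSMIC-style `CNT`). Multi-allelic
#' records are split into one candidate per ALT allele; alleles that are not
#' single-nucleotide substitutions are dropped and counted. Positions are
#' 1-based as in VCF.
#'
#' @param path path to a VCF file.
#' @param recurrence_key INFO key carrying the recurrence count (default
#'   `"CNT"`). The source databases do not share a fixed key, so it is a
#'   parameter rather than a constant.
#' @param on_missing_r what to do with records lacking the key:
#'   `"error"` (default) or `"skip"` (dropped and counted).
#' @return a `data.frame` with columns `chrom`, `pos`, `ref`, `alt`, `r` and a
#'   `"skip_report"` attribute (raw, retained and per-reason dropped counts;
#'   dropped + retained always equals the number of candidate alleles).
#' @export
read_variants <- function(path, recurrence_key = "CNT",
                          on_missing_r = c("error", "skip")) {
  on_missing_r <- match.arg(on_missing_r)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), r = integer(), stringsAsFactors = FALSE)
    attr(out, "skip_report") <- list(n_records = 0L, n_alleles = 0L,
                                     n_retained = 0L, n_non_snv = 0L,
                                     n_missing_r = 0L)
    return(out)
  }
  info <- fix[, "INFO"]
  r_raw <- vapply(info, function(s) {
    fields <- strsplit(s, ";", fixed = TRUE)[[1]]
    hit <- grep(paste0("^", recurrence_key, "="), fields, value = TRUE)
    if (length(hit) == 0L) NA_real_ else suppressWarnings(as.numeric(sub("^[^=]*=", "", hit[1])))
  }, numeric(1), USE.NAMES = FALSE)

  ## split multi-allelic ALT into one candidate allele per record
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  nalt <- lengths(alts)
  idx <- rep.int(seq_len(nrow(fix)), nalt)
  cand <- data.frame(
    chrom = normalize_chrom(fix[idx, "CHROM"]),
    pos = as.integer(fix[idx, "POS"]),
    ref = toupper(fix[idx, "REF"]),
    alt = toupper(unlist(alts)),
    r = r_raw[idx],
    stringsAsFactors = FALSE
  )
  is_snv <- nchar(cand$ref) == 1L & nchar(cand$alt) == 1L &
    cand$ref %in% c("A", "C", "G", "T") & cand$alt %in% c("A", "C", "G", "T") &
    cand$ref != cand$alt
  missing_r <- is.na(cand$r)
  if (any(missing_r & is_snv) && on_missing_r == "error") {
    stop_config("INFO key '", recurrence_key, "' missing for ",
                sum(missing_r & is_snv), " record(s); pass on_missing_r = \"skip\" to drop them")
  }
  keep <- is_snv & !missing_r
  out <- cand[keep, , drop = FALSE]
  out$r <- as.integer(out$r)
  if (any(out$r < 1L)) stop("recurrence counts must be >= 1", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "skip_report") <- list(
    n_records = nrow(fix),
    n_alleles = nrow(cand),
    n_retained = nrow(out),
    n_non_snv = sum(!is_snv),
    n_missing_r = sum(missing_r & is_snv)
  )
  out
}

#' Read a per-position score track from bedGraph
#'
#' The bedGraph intervals are stored run-length (one range per line), never
#' expanded to a dense array. Overlapping intervals are resolved last-wins at
#' query time, with a warning at read time.
#'
#' @param path path to a 4-column bedGraph file.
#' @return an object of class `score_track`.
#' @export
read_score_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  score_track(gr)
}

#' Construct a score track from a GRanges with a `score` column
#'
#' @param gr a [GenomicRanges::GRanges] carrying a numeric `score`.
#' @return an object of class `score_track`. Queries outside any interval
#'   return `NA` (the missing-value marker; scores themselves may be negative).
#' @export
score_track <- function(gr) {
  if (!"score" %in% names(S4Vectors::mcols(gr))) {
    if (length(gr) == 0L) {
      gr$score <- numeric(0)      # empty track: every query misses
    } else {
      stop("score track ranges must carry a 'score' column", call. = FALSE)
    }
  }
  if (length(gr) && any(!is.finite(gr$score))) {
    stop("score track values must be finite", call. = FALSE)
  }
  GenomeInfoDb::seqlevels(gr) <- normalize_chrom(GenomeInfoDb::seqlevels(gr))
  if (length(gr) > 1L) {
    self <- GenomicRanges::countOverlaps(gr, gr)
    if (any(self > 1L)) {
      warning("score track has overlapping intervals; queries resolve last-wins",
              call. = FALSE)
    }
  }
  structure(list(ranges = gr), class = "score_track")
}

#' Look up score-track values at positions
#'
#' @param track a `score_track`.
#' @param chrom,pos equal-length chromosome / 1-based position vectors.
#' @return numeric vector; `NA` where the track has no value.
#' @export
track_values <- function(track, chrom, pos) {
  stopifnot(inherits(track, "score_track"), length(chrom) == length(pos))
  n <- length(pos)
  out <- rep(NA_real_, n)
  if (n == 0L || length(track$ranges) == 0L) return(out)
  q <- GenomicRanges::GRanges(normalize_chrom(chrom), IRanges::IRanges(pos, pos))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, track$ranges))
  if (length(hits)) {
    ## last interval in file order wins on overlap
    best <- tapply(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits), max)
    out[as.integer(names(best))] <- track$ranges$score[as.integer(best)]
  }
  out
}

#' @export
print.score_track <- function(x, ...) {
  cat("score_track:", length(x$ranges), "intervals on",
      length(unique(as.character(GenomicRanges::seqnames(x$ranges)))), "chromosome(s)\n")
  invisible(x)
}

#' Read typed genomic intervals from BED or GFF3
#'
#' BED (0-based half-open) and GFF3 (1-based closed) are both normalized to
#' the internal 1-based closed convention (a BED line `chr1 10 20` and a GFF3
#' line with `start=11 end=20` yield the same interval). The feature kind is
#' taken from the BED name column or the GFF3 type column and mapped through
#' `kind_map`.
#'
#' @param path input file.
#' @param format `"bed"` or `"gff3"`; declared explicitly by the caller.
#' @param kind_map optional named character vector mapping raw kinds to the
#'   internal vocabulary; unnamed kinds pass through unchanged.
#' @param kinds allowed kind vocabulary (defaults to the pipeline's gene
#'   feature kinds). Pass other vocabularies for, e.g., functional-element
#'   classes, or `NULL` to accept every kind.
#' @param strict if `TRUE`, an unknown kind is an error; otherwise unknown
#'   kinds are dropped and counted in the `"dropped"` attribute.
#' @return a [GenomicRanges::GRanges] with a `kind` metadata column.
#' @export
read_intervals <- function(path, format = c("bed", "gff3"), kind_map = NULL,
                           kinds = INTERVAL_KINDS, strict = FALSE) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = if (format == "bed") "bed" else "gff3")
  raw_kind <- if (format == "bed") {
    as.character(gr$name)
  } else {
    as.character(gr$type)
  }
  if (!is.null(kind_map)) {
    mapped <- unname(kind_map[raw_kind])
    raw_kind <- ifelse(is.na(mapped), raw_kind, mapped)
  }
  known <- if (is.null(kinds)) rep(TRUE, length(raw_kind)) else raw_kind %in% kinds
  if (any(!known)) {
    if (strict) {
      stop_config("unknown feature kind(s): ",
                  paste(unique(raw_kind[!known]), collapse = ", "))
    }
  }
  out <- GenomicRanges::GRanges(
    normalize_chrom(as.character(GenomicRanges::seqnames(gr)[known])),
    IRanges::ranges(gr)[known],
    strand = GenomicRanges::strand(gr)[known],
    kind = raw_kind[known]
  )
  attr(out, "dropped") <- sum(!known)
  out
}

#' Write variant predictions to TSV
#'
#' One row per variant with the calibrated score, the hard label (`+` for
#' score at or above the decision threshold, `-` below it) and a
#' high-confidence flag. Rows are ordered deterministically by
#' (chrom, pos, alt).
#'
#' @param records `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `score` in `[0,1]`, and logical/0-1 `high_confidence`.
#' @param path output path.
#' @param threshold decision threshold (default 0.5; scores below it are
#'   labeled negative).
#' @param digits fixed number of decimal places written for scores.
#' @return invisibly, the written `data.frame`.
#' @export
write_predictions <- function(records, path, threshold = 0.5, digits = 6) {
  need <- c("chrom", "pos", "ref", "alt", "score", "high_confidence")
  if (!all(need %in% names(records))) {
    stop_config("records must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(records) && (any(records$score < 0) || any(records$score > 1))) {
    stop_config("scores must lie in [0,1]")
  }
  ord <- order(records$chrom, records$pos, records$alt)
  out <- records[ord, , drop = FALSE]
  out <- data.frame(
    chrom = out$chrom, pos = out$pos, ref = out$ref, alt = out$alt,
    score = sprintf(paste0("%.", digits, "f"), out$score),
    label = ifelse(out$score >= threshold, "+", "-"),
    high_confidence = as.integer(out$high_confidence),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read back a predictions TSV written by [write_predictions()]
#'
#' @param path file written by [write_predictions()].
#' @return `data.frame` with typed columns.
#' @export
read_predictions <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "character",
                                   "character", "numeric", "character", "integer"))
}

## Minimal VCF writer used by the synthetic generator (plain SNVs with a
## recurrence INFO key). General VCF annotation writing is out of scope.
write_vcf <- function(variants, path, recurrence_key = "CNT") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Recurrence count\">",
            recurrence_key),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(variants)) {
    ord <- order(variants$chrom, variants$pos, variants$alt)
    v <- variants[ord, , drop = FALSE]
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s=%d",
                       v$chrom, v$pos, v$ref, v$alt, recurrence_key, v$r), con)
  }
  invisible(path)
}
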