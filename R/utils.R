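#' @keywords internal
"_PACKAGE"

## Canonical chromosome vocabulary: "chr1".."chr22", "chrX", "chrY", "chrM".
AUTOSOMES <- paste0("chr", 1:22)

#' Normalize chromosome names
#'
#' Maps mixed-source chromosome names onto a single vocabulary:
#' a `chr` prefix is added where missing, and mitochondrial aliases
#' (`MT`, `M`) collapse to `chrM`. `"1"` and `"chr1"` are therefore
#' equivalent at ingest.
#'
#' @param x character vector of chromosome names.
#' @return character vector of normalized names.
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  x <- sub("^chr", "", x)
  x[x %in% c("MT", "M", "m")] <- "M"
  x[x == "x"] <- "X"
  x[x == "y"] <- "Y"
  paste0("chr", x)
}

is_autosome <- function(x) x %in% AUTOSOMES

## Run code under a private RNG stream, restoring any global state afterwards,
## so seeded operations are reproducible regardless of call order.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Point-query GRanges for a variant table.
variant_granges <- function(variants) {
  GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, end = variants$pos)
  )
}

stop_config <- function(...) stop(..., call. = FALSE)
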