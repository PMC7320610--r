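## Shared fixtures, built once per session and memoized. All synthetic.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

## Small study with strong track signal: fast enough for per-module tests.
tiny_study <- function() {
  memo("study", simulate_study(sim_config(
    n_chroms = 4L, chrom_length = 40000L, n_drivers = 60L,
    n_passengers = 500L,
    effect_sizes = c(Conservation = 2, Uniqueness = 2), seed = 42L)))
}

tiny_dataset <- function() {
  memo("dataset", build_dataset(
    tiny_study()$catalog,
    dataset_config("noncoding", rho = 7, window = 1000, seed = 1)))
}

tiny_groups <- function() {
  memo("groups", {
    s <- tiny_study()
    compute_feature_groups(tiny_dataset(), s$genome, s$annotation, s$tracks,
                           s$elements, catalog = s$catalog)
  })
}

rand_variants <- function(n, chroms = c("chr1", "chr2"), maxpos = 10000L,
                          r = NULL) {
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample(maxpos, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = "X",  # placeholder; fixed up below so ref != alt
    r = r %||% sample(20L, n, replace = TRUE),
    stringsAsFactors = FALSE
  ) |> (function(d) {
    d$alt <- vapply(d$ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                    "", USE.NAMES = FALSE)
    d
  })()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Naive single-variant sequence-feature oracles (character-level counting),
## independent of the Biostrings-based implementations.
naive_gc <- function(seqstr, pos, window) {
  len <- nchar(seqstr)
  ## centered window [pos - floor(w/2), pos + ceil(w/2) - 1], endpoints
  ## clipped independently (the window shrinks at chromosome edges)
  end <- min(len, pos - window %/% 2 + window - 1)
  start <- max(1, pos - window %/% 2)
  chars <- strsplit(substr(seqstr, start, end), "")[[1]]
  chars <- chars[chars != "N"]
  if (length(chars) == 0) return(NA_real_)
  mean(chars %in% c("G", "C"))
}

naive_spectrum <- function(seqstr, pos, k, window) {
  len <- nchar(seqstr)
  end <- min(len, pos - window %/% 2 + window - 1)
  start <- max(1, pos - window %/% 2)
  win <- substr(seqstr, start, end)
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  counts <- stats::setNames(numeric(length(kmers)), kmers)
  if (nchar(win) >= k) {
    for (i in 1:(nchar(win) - k + 1)) {
      km <- substr(win, i, i + k - 1)
      if (!grepl("N", km, fixed = TRUE)) counts[km] <- counts[km] + 1
    }
  }
  if (sum(counts) == 0) rep(NA_real_, length(kmers)) else unname(counts / sum(counts))
}
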