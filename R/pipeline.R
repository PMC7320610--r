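## End-to-end orchestration: named model profiles binding the published
## defaults, a single-call pipeline runner, and a run manifest that makes
## every run reproducible and auditable.

#' Named model profiles
#'
#' Pre-binds the published operating points. The `noncoding` profile uses the
#' five-group model (Conservation, LocalMutFreq, GeneProximity, GC,
#' Uniqueness) at rho = 8, w = 1000; the `coding` profile adds
#' FunctionalElements and Spectrum at rho = 7, w = 10000.
#'
#' @param region_mode `"coding"` or `"noncoding"`.
#' @return list with `region_mode`, `groups`, `rho`, `window`.
#' @export
model_profile <- function(region_mode = c("coding", "noncoding")) {
  region_mode <- match.arg(region_mode)
  base_groups <- c("Conservation", "LocalMutFreq", "GeneProximity", "GC",
                   "Uniqueness")
  if (region_mode == "coding") {
    list(region_mode = "coding",
         groups = c(base_groups, "FunctionalElements", "Spectrum"),
         rho = 7L, window = 10000L)
  } else {
    list(region_mode = "noncoding", groups = base_groups,
         rho = 8L, window = 1000L)
  }
}

#' Pipeline configuration
#'
#' Resolves user choices against the profile defaults. Every decided default
#' is recorded in the run manifest.
#'
#' @param region_mode `"coding"` or `"noncoding"`.
#' @param rho,window recurrence threshold and matching window (default from
#'   the profile).
#' @param groups feature groups (default from the profile).
#' @param n_per_class balanced training subsample per class (default 4000).
#' @param tau cautious-classification cutoff (default 0.9).
#' @param select run forward feature-group selection before evaluation.
#' @param sim a [sim_config()] to generate inputs, or `NULL` to read files.
#' @param inputs named list of file paths (`variants`, `genome`,
#'   `annotation`, `elements`, `tracks` = named bedGraph paths) when `sim`
#'   is `NULL`.
#' @param feature_cfg a [feature_config()].
#' @param model_cfg a [model_config()].
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(region_mode = c("noncoding", "coding"),
                            rho = NULL, window = NULL, groups = NULL,
                            n_per_class = 4000L, tau = 0.9, select = FALSE,
                            sim = sim_config(), inputs = NULL,
                            feature_cfg = feature_config(),
                            model_cfg = model_config(), seed = 1L) {
  region_mode <- match.arg(region_mode)
  prof <- model_profile(region_mode)
  structure(list(region_mode = region_mode,
                 rho = as.integer(rho %||% prof$rho),
                 window = as.integer(window %||% prof$window),
                 groups = groups %||% prof$groups,
                 n_per_class = as.integer(n_per_class), tau = tau,
                 select = isTRUE(select), sim = sim, inputs = inputs,
                 feature_cfg = feature_cfg, model_cfg = model_cfg,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, timings, code) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(code), error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  list(result = res, timings = timings)
}

#' Run the pipeline end to end
#'
#' Executes simulate (or load) -> build-dataset -> extract-features ->
#' (select-groups) -> evaluate-loco -> predict, writing `predictions.tsv`,
#' `report.json` and `manifest.json` to `outdir`. Any stage failure aborts
#' with the stage name and leaves a `.failed` marker in `outdir`.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return list with the `loco_eval` report, the selected groups, and the
#'   output paths; re-running with an identical config and inputs reproduces
#'   the report's metric values.
#' @export
run_end_to_end <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(outdir, ".failed")
  if (file.exists(failed_marker)) unlink(failed_marker)
  timings <- list()
  on.exit(if (!file.exists(file.path(outdir, "manifest.json")))
            file.create(failed_marker), add = TRUE)

  input_digests <- list()
  if (!is.null(config$sim)) {
    st <- stage("simulate", timings, simulate_study(config$sim))
    timings <- st$timings
    study <- st$result
    variants <- study$catalog
    genome <- study$genome
    annotation <- study$annotation
    elements <- study$elements
    tracks <- study$tracks
    input_digests$simulated <- list(seed = config$sim$seed,
                                    n_variants = nrow(variants))
  } else {
    st <- stage("load-inputs", timings, {
      list(variants = read_variants(config$inputs$variants),
           genome = read_genome(config$inputs$genome),
           annotation = read_intervals(config$inputs$annotation, format = "gff3"),
           elements = read_intervals(config$inputs$elements, format = "bed",
                                     kinds = NULL),
           tracks = lapply(config$inputs$tracks, read_score_track))
    })
    timings <- st$timings
    variants <- st$result$variants
    genome <- st$result$genome
    annotation <- st$result$annotation
    elements <- st$result$elements
    tracks <- st$result$tracks
    input_digests <- lapply(
      c(config$inputs[c("variants", "genome", "annotation", "elements")],
        config$inputs$tracks),
      function(p) unname(tools::md5sum(p)))
  }

  dcfg <- dataset_config(config$region_mode, rho = config$rho,
                         window = config$window,
                         n_per_class = config$n_per_class, seed = config$seed)
  st <- stage("build-dataset", timings,
              build_dataset(variants, dcfg, annotation = annotation))
  timings <- st$timings
  ds <- st$result
  if (nrow(ds) == 0L) stop("stage 'build-dataset' failed: empty dataset",
                           call. = FALSE)

  st <- stage("extract-features", timings,
              compute_feature_groups(ds, genome, annotation, tracks, elements,
                                     catalog = variants,
                                     config = config$feature_cfg))
  timings <- st$timings
  groups <- st$result

  selected <- config$groups
  sel_trace <- NULL
  if (config$select) {
    st <- stage("select-groups", timings,
                forward_select(groups[selected], ds,
                               model_cfg = config$model_cfg,
                               n_per_class = config$n_per_class,
                               seed = config$seed))
    timings <- st$timings
    selected <- st$result$selected
    sel_trace <- st$result$trace
  }

  st <- stage("evaluate-loco", timings,
              run_loco(ds, groups, selected = selected,
                       model_cfg = config$model_cfg,
                       n_per_class = config$n_per_class,
                       tau = config$tau, seed = config$seed))
  timings <- st$timings
  ev <- st$result

  st <- stage("predict", timings, {
    scored <- which(!is.na(ev$scores))
    caut <- cautious_apply(ev$scores[scored], config$tau)
    data.frame(chrom = ds$chrom[scored], pos = ds$pos[scored],
               ref = ds$ref[scored], alt = ds$alt[scored],
               score = ev$scores[scored],
               high_confidence = caut$confident, stringsAsFactors = FALSE)
  })
  timings <- st$timings
  preds <- st$result

  pred_path <- file.path(outdir, "predictions.tsv")
  write_predictions(preds, pred_path)

  report <- list(
    version = as.character(utils::packageVersion("driverpass")),
    config = list(region_mode = config$region_mode, rho = config$rho,
                  window = config$window, groups = selected,
                  n_per_class = config$n_per_class, tau = config$tau,
                  seed = config$seed,
                  kernel = config$model_cfg$kernel,
                  regularization = config$model_cfg$regularization,
                  standardize = config$model_cfg$standardize),
    n_examples = nrow(ds),
    metrics = ev$metrics,
    auc = ev$auc,
    cautious = list(tau = ev$cautious$tau, coverage = ev$cautious$coverage,
                    metrics = ev$cautious$metrics),
    per_fold = ev$per_fold,
    skipped_folds = ev$skipped_folds
  )
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  manifest <- list(
    tool = "driverpass",
    version = report$version,
    seed = config$seed,
    config = report$config,
    resolved_defaults = list(rho = config$rho, window = config$window,
                             tau = config$tau,
                             gc_window = config$feature_cfg$gc_window,
                             spectrum_k = config$feature_cfg$spectrum_k,
                             mutfreq_window = config$feature_cfg$mutfreq_window),
    inputs = input_digests,
    timings_sec = timings,
    outputs = list(predictions = pred_path, report = report_path)
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  list(report = ev, selection = sel_trace, dataset = ds,
       paths = list(predictions = pred_path, report = report_path,
                    manifest = manifest_path))
}
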