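## Orchestration: simulate -> process -> quantify -> covariates -> fit ->
## summarize under a single validated config, with deterministic seeding
## and a reproducibility manifest.

.PIPELINE_KEYS <- c("cohort", "filters", "model", "alpha", "seed",
                    "inputs", "annotation", "fiber_scale", "center_scope")
.FILTER_KEYS <- c("peptide_fdr", "protein_fdr")
.MODEL_KEYS <- c("batch", "reml", "df", "use_fiber_ratio")
.INPUT_KEYS <- c("psm", "samples", "purity")

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list. Recognized keys: `cohort`
#' (arguments of [cohortConfig()]; used when no input tables are given),
#' `inputs` (`psm`, `samples`, optional `purity` TSV paths), `filters`
#' (`peptide_fdr`, `protein_fdr`), `model` (arguments of [modelSpec()]),
#' `alpha`, `seed`, `annotation` (TSV path), `fiber_scale`, `center_scope`
#' (within-protein centering scope, `"global"` or `"set"`). Unknown keys
#' are rejected before any stage runs.
#'
#' @param config path to a YAML file or a named list.
#' @return the validated config as a list with defaults filled in.
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  checkKeys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
      stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "))
  }
  checkKeys(config, .PIPELINE_KEYS, "config")
  checkKeys(config$filters, .FILTER_KEYS, "filters")
  checkKeys(config$model, .MODEL_KEYS, "model")
  checkKeys(config$inputs, .INPUT_KEYS, "inputs")
  checkKeys(config$cohort, setdiff(names(formals(cohortConfig)), "seed"),
            "cohort")
  if (!is.null(config$inputs)) {
    if (is.null(config$inputs$psm) || is.null(config$inputs$samples))
      stop("inputs must provide both 'psm' and 'samples' paths")
    for (p in unlist(config$inputs))
      if (!file.exists(p)) stop("input file not found: ", p)
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$alpha <- config$alpha %||% 0.05
  config$fiber_scale <- config$fiber_scale %||% "linear"
  config$center_scope <- match.arg(config$center_scope %||% "global",
                                   c("global", "set"))
  config$filters$peptide_fdr <- config$filters$peptide_fdr %||% 0.001
  config$filters$protein_fdr <- config$filters$protein_fdr %||% 0.01
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Runs every stage in order and writes all intermediate and final tables
#' plus a JSON manifest (file checksums, row counts, seed, model formula)
#' to `out_dir`. Outputs are pure functions of (inputs, config, seed), so
#' two runs with the same config produce identical files and manifests.
#'
#' @param config a [pipelineConfig()] list or YAML path.
#' @param out_dir output directory (created if needed).
#' @param verbose log per-stage progress to stderr.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = list(), out_dir, verbose = FALSE) {
  config <- pipelineConfig(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  note <- function(...) if (verbose) message("[tmtpa] ", ...)
  written <- character()
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    writeTsv(x, p)
    written <<- c(written, p)
    p
  }

  ## stage 1: simulate or load
  if (is.null(config$inputs)) {
    note("simulate: seeded synthetic cohort")
    cfg <- do.call(cohortConfig, c(config$cohort %||% list(),
                                   list(seed = config$seed)))
    cohort <- simulateCohort(cfg)
    psm <- cohort$psm
    samples <- cohort$samples
    purity <- cfg@purity_matrix
    emit(psm, "psm.tsv"); emit(samples, "samples.tsv")
    emit(cohort$truth$protein_effects, "truth.tsv")
    emit(cohort$truth$loading_offsets, "truth_loading.tsv")
  } else {
    note("load: ", config$inputs$psm)
    psm <- readPsmTable(config$inputs$psm)
    samples <- readSampleTable(config$inputs$samples)
    purity <- if (!is.null(config$inputs$purity))
      readPurityMatrix(config$inputs$purity) else diag(6)
    cohort <- NULL
  }

  ## stage 2: purity correction + retention rules
  note("process: purity correction and retention rules")
  psm <- applyPurityCorrection(psm, purity)
  flt <- filterPSM(psm, samples,
                   peptide_fdr = config$filters$peptide_fdr,
                   protein_fdr = config$filters$protein_fdr)
  emit(flt$psm, "psm.filtered.tsv")
  emit(reportTable(flt$report), "filter_report.tsv")

  ## stage 3: quantification
  note("quantify: log2, centering, roll-up, loading correction")
  pqm <- quantifyProteins(flt$psm, samples,
                          center_scope = config$center_scope)
  qm <- quantMatrix(pqm)
  emit(data.frame(accession = rownames(qm), qm, check.names = FALSE),
       "protein_matrix.tsv")
  prov <- data.frame(
    accession = rownames(qm),
    n_spectra = as.integer(table(flt$psm$protein_accessions)[rownames(qm)]),
    n_peptides = as.integer(tapply(flt$psm$peptide_seq,
                                   flt$psm$protein_accessions,
                                   function(p) length(unique(p)))[rownames(qm)]))
  emit(prov, "provenance.tsv")

  ## stage 4: covariates
  note("covariates: questionnaire scoring and fiber-type ratio")
  has_myh <- all(c("MYH7", "MYH1", "MYH2", "MYH4") %in% rownames(qm))
  covs <- buildCovariates(samples, if (has_myh) pqm else NULL,
                          fiber_scale = config$fiber_scale)
  emit(covs, "covariates.tsv")

  ## stage 5: per-protein models
  note("fit: per-protein mixed models")
  spec <- do.call(modelSpec, c(config$model %||% list(),
                               list(alpha = config$alpha)))
  if (!has_myh) spec@use_fiber_ratio <- FALSE
  results <- fitAllProteins(pqm, covs, spec, verbose = verbose)
  emit(as.data.frame(results), "results.tsv")
  meta <- list(
    formula = paste("log2_abundance ~", .fixedFormula(spec),
                    if (spec@batch == "random") "+ (1 | tmt_set)"
                    else "+ tmt_set"),
    race_reference = names(which.max(table(covs$race))),
    estimation = if (spec@reml) "REML" else "ML",
    df_method = spec@df, alpha = spec@alpha, seed = config$seed,
    lme4_version = as.character(utils::packageVersion("lme4")),
    lmerTest_version = as.character(utils::packageVersion("lmerTest")))
  jsonlite::write_json(meta, file.path(out_dir, "model_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, file.path(out_dir, "model_metadata.json"))

  ## stage 6: category summary
  note("summarize: annotation-category counts")
  annot <- if (!is.null(config$annotation)) readAnnotation(config$annotation)
           else NULL
  summ <- summarizeCategories(results, annot, alpha = config$alpha)
  emit(summ, "category_summary.tsv")

  manifest <- list(
    seed = config$seed,
    stages = c("simulate/load", "process", "quantify", "covariates",
               "fit", "summarize"),
    files = lapply(setNames(written, basename(written)), function(p)
      list(md5 = unname(tools::md5sum(p)),
           rows = length(readLines(p)) - 1L)),
    n_proteins = nrow(results),
    n_significant = sum(results$p_value < config$alpha, na.rm = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
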