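#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats median rnorm runif rbinom setNames p.adjust qnorm sd
#' @importFrom utils read.delim write.table head
NULL

## Reporter intensity columns for a TMT 6-plex, in mass order.
TMT_CHANNELS <- c("i126", "i127", "i128", "i129", "i130", "i131")

## ---------------------------------------------------------------------------
## CohortConfig
## ---------------------------------------------------------------------------

#' Configuration of a synthetic TMT cohort
#'
#' Holds every knob of the synthetic-cohort generator: the TMT-set design
#' (five donors plus one reference channel per 6-plex set), the per-protein
#' effect structure (activity, age, BMI slopes on the log2 scale), the
#' variance components (spectrum noise, per-set batch intercepts, per-channel
#' loading offsets, peptide ionization offsets), the nuisance-record rates
#' (decoys, contaminants, shared spectra, missing channels, peptides with
#' incomplete sample coverage), the reporter isotopic-purity (crosstalk)
#' matrix, and the seed.
#'
#' @slot n_donors number of donors in the cohort.
#' @slot donors_per_set donors per TMT set (the sixth channel is the
#'   pooled reference).
#' @slot n_proteins number of proteins, including the four myosin heavy
#'   chains (MYH7, MYH1, MYH2, MYH4) always present so the fiber-type ratio
#'   covariate is computable.
#' @slot peptides_per_protein integer range (min, max) of peptides per protein.
#' @slot spectra_per_peptide integer range (min, max) of spectra per peptide
#'   per TMT set.
#' @slot frac_nonnull proportion of proteins with a nonzero activity slope.
#' @slot beta_range magnitude range (log2 units per activity point) of
#'   nonzero activity slopes.
#' @slot frac_beta_negative probability a nonzero activity slope is negative.
#' @slot beta_age_sd,beta_bmi_sd SDs of per-protein age and BMI slopes
#'   (log2 units per year, per kg/m2).
#' @slot sigma_spectrum spectrum-level noise SD (log2 units).
#' @slot tau_batch per-set random-intercept SD (log2 units).
#' @slot loading_sd per-channel loading-offset SD (log2 units).
#' @slot peptide_offset_sd peptide ionization-offset SD (log2 units).
#' @slot frac_decoy,frac_contaminant,frac_shared,frac_missing_channel,frac_incomplete_peptide
#'   nuisance-record rates, all proportions in \[0, 1\].
#' @slot purity_matrix 6x6 reporter crosstalk matrix; entry (i, j) is the
#'   fraction of channel j's true signal observed in channel i.
#' @slot seed integer seed driving the single RNG stream of the generator.
#'
#' @seealso [cohortConfig()] for the user-facing constructor with defaults,
#'   [simulateCohort()].
#' @export
setClass("CohortConfig",
  representation(
    n_donors = "integer",
    donors_per_set = "integer",
    n_proteins = "integer",
    peptides_per_protein = "integer",
    spectra_per_peptide = "integer",
    frac_nonnull = "numeric",
    beta_range = "numeric",
    frac_beta_negative = "numeric",
    beta_age_sd = "numeric",
    beta_bmi_sd = "numeric",
    sigma_spectrum = "numeric",
    tau_batch = "numeric",
    loading_sd = "numeric",
    peptide_offset_sd = "numeric",
    frac_decoy = "numeric",
    frac_contaminant = "numeric",
    frac_shared = "numeric",
    frac_missing_channel = "numeric",
    frac_incomplete_peptide = "numeric",
    purity_matrix = "matrix",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  fracs <- c(
    frac_nonnull = object@frac_nonnull,
    frac_beta_negative = object@frac_beta_negative,
    frac_decoy = object@frac_decoy,
    frac_contaminant = object@frac_contaminant,
    frac_shared = object@frac_shared,
    frac_missing_channel = object@frac_missing_channel,
    frac_incomplete_peptide = object@frac_incomplete_peptide
  )
  bad <- fracs < 0 | fracs > 1 | !is.finite(fracs)
  if (any(bad))
    msg <- c(msg, paste0("proportions outside [0,1]: ",
                         paste(names(fracs)[bad], collapse = ", ")))
  if (object@n_donors < 1L) msg <- c(msg, "n_donors must be >= 1")
  if (object@donors_per_set < 1L || object@donors_per_set > 5L)
    msg <- c(msg, "donors_per_set must be in 1..5 (channel 6 is the reference)")
  n_sets <- ceiling(object@n_donors / object@donors_per_set)
  if (object@donors_per_set * n_sets < object@n_donors)
    msg <- c(msg, "donors_per_set * n_sets must cover n_donors")
  if (object@n_proteins < 4L)
    msg <- c(msg, "n_proteins must be >= 4 (the four MYH proteins)")
  rng_ok <- function(r) length(r) == 2L && all(r >= 1L) && r[1] <= r[2]
  if (!rng_ok(object@peptides_per_protein))
    msg <- c(msg, "peptides_per_protein must be an increasing range >= 1")
  if (!rng_ok(object@spectra_per_peptide))
    msg <- c(msg, "spectra_per_peptide must be an increasing range >= 1")
  if (length(object@beta_range) != 2L || any(object@beta_range < 0) ||
      object@beta_range[1] > object@beta_range[2])
    msg <- c(msg, "beta_range must be a nonnegative increasing magnitude range")
  if (any(c(object@sigma_spectrum, object@tau_batch, object@loading_sd,
            object@peptide_offset_sd, object@beta_age_sd, object@beta_bmi_sd) < 0))
    msg <- c(msg, "variance components must be nonnegative")
  P <- object@purity_matrix
  if (!is.numeric(P) || !identical(dim(P), c(6L, 6L))) {
    msg <- c(msg, "purity_matrix must be a numeric 6x6 matrix")
  } else {
    if (any(P < 0)) msg <- c(msg, "purity_matrix entries must be >= 0")
    offdiag <- P; diag(offdiag) <- 0
    if (any(diag(P) <= apply(offdiag, 1L, max)))
      msg <- c(msg, "purity_matrix diagonal must dominate its row")
  }
  if (length(msg)) msg else TRUE
})

#' Number of TMT sets implied by a cohort configuration
#' @param config a [CohortConfig-class] object.
#' @return integer count of 6-plex sets.
#' @export
nSets <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  as.integer(ceiling(config@n_donors / config@donors_per_set))
}

#' @export
setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@n_donors, "donors in", nSets(object),
      "TMT 6-plex sets (", object@donors_per_set, "+ reference/set )\n")
  cat("  proteins:", object@n_proteins,
      " peptides/protein:", paste(object@peptides_per_protein, collapse = "-"),
      " spectra/peptide/set:", paste(object@spectra_per_peptide, collapse = "-"), "\n")
  cat("  activity effects: ", round(100 * object@frac_nonnull), "% nonnull, |beta| in [",
      object@beta_range[1], ", ", object@beta_range[2], "] log2/point\n", sep = "")
  cat("  noise: sigma_spectrum =", object@sigma_spectrum,
      " tau_batch =", object@tau_batch,
      " loading_sd =", object@loading_sd,
      " peptide_offset_sd =", object@peptide_offset_sd, "\n")
  cat("  nuisance: decoy", object@frac_decoy, "contaminant", object@frac_contaminant,
      "shared", object@frac_shared, "missing-channel", object@frac_missing_channel,
      "incomplete-peptide", object@frac_incomplete_peptide, "\n")
  cat("  seed:", object@seed, "\n")
  invisible(object)
})

## ---------------------------------------------------------------------------
## FilterReport
## ---------------------------------------------------------------------------

#' Per-rule accounting of PSM retention
#'
#' One row per retention rule, in the order applied, with the number of
#' records entering, removed, and leaving; counts telescope (the records
#' leaving rule k enter rule k+1). Protein counts before and after the full
#' cascade are carried alongside.
#'
#' @slot rules data.frame with columns `rule`, `n_in`, `n_removed`, `n_out`.
#' @slot proteins_before,proteins_after distinct protein accessions before
#'   and after filtering (decoys/contaminants excluded from the "before"
#'   count's target-protein tally is not attempted; the raw accession count
#'   is reported).
#' @export
setClass("FilterReport",
  representation(
    rules = "data.frame",
    proteins_before = "integer",
    proteins_after = "integer"
  )
)

setValidity("FilterReport", function(object) {
  r <- object@rules
  need <- c("rule", "n_in", "n_removed", "n_out")
  if (!all(need %in% names(r)))
    return("rules must have columns rule, n_in, n_removed, n_out")
  if (nrow(r)) {
    if (any(r$n_in - r$n_removed != r$n_out))
      return("per-rule counts must satisfy n_in - n_removed = n_out")
    if (nrow(r) > 1L && any(r$n_out[-nrow(r)] != r$n_in[-1L]))
      return("counts must telescope across rules")
  }
  TRUE
})

#' @describeIn FilterReport-class the per-rule count table.
#' @param report a `FilterReport`.
#' @export
reportTable <- function(report) {
  stopifnot(is(report, "FilterReport"))
  report@rules
}

#' @export
setMethod("show", "FilterReport", function(object) {
  r <- object@rules
  cat("FilterReport:", if (nrow(r)) r$n_in[1] else 0L, "records in,",
      if (nrow(r)) r$n_out[nrow(r)] else 0L, "retained\n")
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-28s -%6d  (%d -> %d)\n",
                r$rule[i], r$n_removed[i], r$n_in[i], r$n_out[i]))
  cat("  proteins:", object@proteins_before, "->", object@proteins_after, "\n")
  invisible(object)
})

## ---------------------------------------------------------------------------
## ProteinQuantMatrix
## ---------------------------------------------------------------------------

#' Protein-by-sample log2 relative abundance matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] with assay
#' `"log2ratio"` (proteins x non-reference samples, log2 relative abundance
#' after within-protein median centering and spectrum roll-up), plus
#' provenance assays `"n_spectra"` and `"n_peptides"` giving the evidence
#' behind each cell. `colData` carries the sample metadata; metadata flag
#' `loading_corrected` records whether [medianPolishLoading()] has run.
#'
#' @seealso [rollupProtein()], [medianPolishLoading()], [quantMatrix()].
#' @export
setClass("ProteinQuantMatrix", contains = "SummarizedExperiment")

setValidity("ProteinQuantMatrix", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!"log2ratio" %in% an)
    return("assay 'log2ratio' is required")
  if (anyNA(SummarizedExperiment::assay(object, "log2ratio")))
    return("log2ratio must be complete (no absent cells)")
  TRUE
})

#' Extract the log2 abundance matrix
#' @param x a [ProteinQuantMatrix-class].
#' @return numeric matrix, proteins x samples.
#' @export
quantMatrix <- function(x) {
  stopifnot(is(x, "ProteinQuantMatrix"))
  SummarizedExperiment::assay(x, "log2ratio")
}

#' Has sample-loading correction been applied?
#' @param x a [ProteinQuantMatrix-class].
#' @return logical flag.
#' @export
isLoadingCorrected <- function(x) {
  isTRUE(S4Vectors::metadata(x)$loading_corrected)
}

#' @export
setMethod("show", "ProteinQuantMatrix", function(object) {
  cat("ProteinQuantMatrix:", nrow(object), "proteins x", ncol(object),
      "samples;", if (isLoadingCorrected(object)) "loading-corrected"
      else "pre loading correction", "\n")
  callNextMethod()
})

## ---------------------------------------------------------------------------
## ModelSpec
## ---------------------------------------------------------------------------

#' Specification of the per-protein regression model
#'
#' Fixed effects are the ordinal activity code (numeric 0-3, a single
#' slope), age, race (dummy-coded against the most frequent level), BMI and
#' the myosin fiber-type ratio; the TMT set enters as a random intercept
#' (default) or a fixed factor. Estimation is REML with Satterthwaite
#' degrees of freedom by default, mirroring lme4 + lmerTest.
#'
#' @slot batch `"random"` or `"fixed"` handling of the TMT set.
#' @slot reml logical, REML (TRUE) or ML estimation.
#' @slot df `"Satterthwaite"` or `"residual"` degrees of freedom.
#' @slot alpha significance level for direction calls.
#' @slot use_fiber_ratio logical; include the fiber-type ratio covariate.
#' @seealso [modelSpec()], [fitAllProteins()].
#' @export
setClass("ModelSpec",
  representation(
    batch = "character",
    reml = "logical",
    df = "character",
    alpha = "numeric",
    use_fiber_ratio = "logical"
  )
)

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!object@batch %in% c("random", "fixed"))
    msg <- c(msg, "batch must be 'random' or 'fixed'")
  if (!object@df %in% c("Satterthwaite", "residual"))
    msg <- c(msg, "df must be 'Satterthwaite' or 'residual'")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec: abundance ~ pa_code + age + race + bmi",
      if (object@use_fiber_ratio) "+ fiber_ratio" else "",
      if (object@batch == "random") "+ (1 | tmt_set)" else "+ factor(tmt_set)",
      "\n  estimation:", if (object@reml) "REML" else "ML",
      " df:", object@df, " alpha:", object@alpha, "\n")
  invisible(object)
})
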