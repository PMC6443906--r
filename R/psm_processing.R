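## Reporter isotopic-purity correction and the PSM/peptide/protein
## retention rules, with an auditable per-rule filter report.

#' Correct reporter intensities for isotopic impurity
#'
#' The tags' isotopic impurities mix a known fraction of each channel's
#' signal into its mass neighbors, so the observed reporter vector is
#' `P %*% true`. Correction solves that linear system and clamps any
#' (small, noise-induced) negative components to zero. Vectors with absent
#' channels cannot be corrected and are returned unchanged with attribute
#' `purity_corrected = FALSE`.
#'
#' @param intensities numeric reporter vector (linear scale).
#' @param purity_matrix square crosstalk matrix matching the vector length;
#'   entry (i, j) is the fraction of channel j observed in channel i.
#' @param cond_threshold condition-number threshold above which a warning
#'   is issued.
#' @return corrected vector, with attribute `purity_corrected`.
#' @examples
#' correctIsotopicPurity(c(9, 11), matrix(c(.9, .1, .1, .9), 2))
#' @export
correctIsotopicPurity <- function(intensities, purity_matrix,
                                  cond_threshold = 1e6) {
  n <- length(intensities)
  if (!is.matrix(purity_matrix) || !all(dim(purity_matrix) == n))
    stop("purity_matrix must be ", n, "x", n)
  if (anyNA(intensities)) {
    attr(intensities, "purity_corrected") <- FALSE
    return(intensities)
  }
  if (any(intensities < 0))
    stop("reporter intensities must be nonnegative")
  k <- kappa(purity_matrix, exact = TRUE)
  if (!is.finite(k) || abs(det(purity_matrix)) < .Machine$double.eps)
    stop("purity matrix is singular; check the crosstalk configuration")
  if (k > cond_threshold)
    warning("purity matrix is ill-conditioned (condition number ",
            format(k, digits = 3), ")")
  x <- as.numeric(solve(purity_matrix, intensities))
  x[x < 0] <- 0
  attr(x, "purity_corrected") <- TRUE
  x
}

#' Apply purity correction to every complete PSM record
#'
#' Rows with all six reporter channels present are corrected by solving the
#' crosstalk system (negatives clamped to zero); rows with any absent
#' channel are passed through unchanged and flagged. Correction runs before
#' the retention rules, so channel completeness is judged on raw presence.
#'
#' @param psm PSM table (see [readPsmTable()]).
#' @param purity_matrix 6x6 crosstalk matrix.
#' @return the PSM table with corrected intensities and a logical column
#'   `purity_corrected`.
#' @export
applyPurityCorrection <- function(psm, purity_matrix) {
  stopifnot(all(TMT_CHANNELS %in% names(psm)))
  if (!is.matrix(purity_matrix) || !all(dim(purity_matrix) == 6L))
    stop("purity_matrix must be 6x6")
  if (abs(det(purity_matrix)) < .Machine$double.eps)
    stop("purity matrix is singular; check the crosstalk configuration")
  if (kappa(purity_matrix, exact = TRUE) > 1e6)
    warning("purity matrix is ill-conditioned")
  M <- as.matrix(psm[, TMT_CHANNELS])
  complete <- !apply(is.na(M), 1L, any)
  if (any(complete)) {
    X <- t(solve(purity_matrix, t(M[complete, , drop = FALSE])))
    X[X < 0] <- 0
    M[complete, ] <- X
  }
  psm[, TMT_CHANNELS] <- M
  psm$purity_corrected <- complete
  psm
}

## first accession of a possibly ';'-joined accession field
.firstAccession <- function(acc) sub(";.*$", "", acc)

#' Filter a PSM table by the study's retention rules
#'
#' Applies, in order: (1) drop decoy records; (2) drop contaminants;
#' (3) peptide FDR <= `peptide_fdr`; (4) protein FDR <= `protein_fdr`;
#' (5) drop spectra shared between more than one protein; (6) keep only
#' spectra identified in all six channels of their set (an absent or
#' literal-zero reporter fails); (7) keep only peptides detected in every
#' non-reference sample; (8) drop proteins whose entire surviving evidence
#' is a single peptide never confirmed by more than one search engine.
#' Every rule's in/removed/out counts are reported and telescope.
#'
#' @param psm PSM table.
#' @param samples sample metadata table defining the full set roster, so
#'   "every non-reference sample" is well-defined.
#' @param peptide_fdr,protein_fdr retention thresholds (defaults 0.001 and
#'   0.01, i.e. 0.1% peptide and 1% protein FDR).
#' @return list with elements `psm` (retained records) and `report`
#'   (a [FilterReport-class]).
#' @export
filterPSM <- function(psm, samples, peptide_fdr = 0.001, protein_fdr = 0.01) {
  stopifnot(all(TMT_CHANNELS %in% names(psm)),
            all(c("tmt_set", "is_reference") %in% names(samples)))
  acc_all <- unique(unlist(strsplit(psm$protein_accessions, ";", fixed = TRUE)))
  proteins_before <- length(acc_all)

  rules <- list(
    decoy = function(x) !x$is_decoy,
    contaminant = function(x) !x$is_contaminant,
    peptide_fdr = function(x) x$peptide_fdr <= peptide_fdr,
    protein_fdr = function(x) x$protein_fdr <= protein_fdr,
    shared_protein = function(x) !grepl(";", x$protein_accessions, fixed = TRUE),
    incomplete_channels = function(x) {
      M <- as.matrix(x[, TMT_CHANNELS])
      !apply(is.na(M) | M == 0, 1L, any)
    },
    peptide_coverage = function(x) {
      sets_needed <- sort(unique(samples$tmt_set[!samples$is_reference]))
      cov <- tapply(x$tmt_set, x$peptide_seq,
                    function(s) all(sets_needed %in% s))
      as.logical(cov[x$peptide_seq])
    },
    single_peptide_unconfirmed = function(x) {
      acc <- .firstAccession(x$protein_accessions)
      npep <- tapply(x$peptide_seq, acc, function(p) length(unique(p)))
      conf <- tapply(x$engines_confirming, acc, max)
      ok <- npep > 1L | conf >= 2L
      as.logical(ok[acc])
    }
  )

  counts <- data.frame(rule = names(rules), n_in = NA_integer_,
                       n_removed = NA_integer_, n_out = NA_integer_,
                       stringsAsFactors = FALSE)
  x <- psm
  for (i in seq_along(rules)) {
    n_in <- nrow(x)
    keep <- rules[[i]](x)
    x <- x[keep, , drop = FALSE]
    counts$n_in[i] <- n_in
    counts$n_removed[i] <- n_in - nrow(x)
    counts$n_out[i] <- nrow(x)
    if (nrow(x) == 0L)
      stop("no quantifiable proteins: rule '", names(rules)[i],
           "' removed every remaining record")
  }
  report <- new("FilterReport", rules = counts,
                proteins_before = proteins_before,
                proteins_after = length(unique(x$protein_accessions)))
  list(psm = x, report = report)
}
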