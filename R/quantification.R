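## Normalization arithmetic: log2 transform, within-protein median
## centering per TMT set, median roll-up to protein x sample, and the
## sample-loading (median-polish) correction.

#' Log2-transform reporter intensities
#'
#' @param psm filtered PSM table with strictly positive, complete reporter
#'   intensities.
#' @return the table with each reporter intensity replaced by its base-2
#'   logarithm.
#' @export
log2Transform <- function(psm) {
  stopifnot(all(TMT_CHANNELS %in% names(psm)))
  M <- as.matrix(psm[, TMT_CHANNELS])
  bad <- which(is.na(M) | M <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("nonpositive or absent intensity in record ",
         psm$spectrum_id[bad[1, 1]], ", channel ", TMT_CHANNELS[bad[1, 2]],
         "; filter before transforming")
  psm[, TMT_CHANNELS] <- log2(M)
  psm
}

#' Center log2 intensities within each protein
#'
#' Subtracts, from every spectrum-channel log2 value of a protein, the
#' median over all reporter values belonging to that protein (the
#' reference channels participate in the median), putting each protein on
#' a relative log2 scale. With `scope = "global"` (the default) one median
#' is taken across all channels of all TMT sets, which preserves
#' between-set abundance contrasts and leaves set-to-set batch offsets to
#' the model's random intercept; with `scope = "set"` the median is taken
#' per (protein, TMT set), making every per-(protein, set) median exactly
#' zero but also absorbing part of any covariate signal that varies
#' between sets (see the methods vignette). The per-group median of the
#' output is exactly zero and centering is idempotent in both scopes.
#'
#' @param psm log2-transformed PSM table (see [log2Transform()]).
#' @param scope `"global"` (one median per protein) or `"set"` (one
#'   median per protein and TMT set).
#' @return the table with centered log2 intensities.
#' @export
normalizeWithinProtein <- function(psm, scope = c("global", "set")) {
  scope <- match.arg(scope)
  stopifnot(all(c("protein_accessions", "tmt_set") %in% names(psm)))
  M <- as.matrix(psm[, TMT_CHANNELS])
  if (anyNA(M)) stop("centering requires complete channel values")
  g <- if (scope == "set")
    paste(psm$protein_accessions, psm$tmt_set, sep = "\r")
  else psm$protein_accessions
  idx <- split(seq_len(nrow(M)), g)
  for (rows in idx) {
    med <- median(M[rows, ])
    M[rows, ] <- M[rows, ] - med
  }
  psm[, TMT_CHANNELS] <- M
  psm
}

#' Roll spectra up to a protein-by-sample abundance matrix
#'
#' The relative abundance of protein p in a sample is the median over all
#' retained spectra of all of p's peptides in that sample's channel,
#' pooling spectrum-level values ("median of all peptides combined
#' together"; even counts use the mean of the two middle values). Reference
#' channels are excluded from the output columns. Provenance assays record
#' the number of spectra and distinct peptides behind each cell.
#'
#' @param psm centered log2 PSM table (see [normalizeWithinProtein()]).
#' @param samples sample metadata table; columns of the result are its
#'   non-reference samples ordered by set then channel.
#' @param method `"pooled"` (default; one median over all spectrum-level
#'   values, weighting peptides by their spectral support) or
#'   `"peptide_median"` (median of per-peptide medians, weighting peptides
#'   equally).
#' @return a [ProteinQuantMatrix-class].
#' @export
rollupProtein <- function(psm, samples,
                          method = c("pooled", "peptide_median")) {
  method <- match.arg(method)
  stopifnot(all(c("sample_id", "tmt_set", "channel", "is_reference")
                %in% names(samples)))
  s <- samples[!samples$is_reference, , drop = FALSE]
  s <- s[order(s$tmt_set, s$channel), , drop = FALSE]
  prots <- sort(unique(psm$protein_accessions))
  m <- matrix(NA_real_, length(prots), nrow(s),
              dimnames = list(prots, s$sample_id))
  nsp <- npep <- matrix(0L, length(prots), nrow(s),
                        dimnames = dimnames(m))
  M <- as.matrix(psm[, TMT_CHANNELS])
  byps <- split(seq_len(nrow(psm)),
                paste(psm$protein_accessions, psm$tmt_set, sep = "\r"))
  keys <- strsplit(names(byps), "\r", fixed = TRUE)
  key_prot <- vapply(keys, `[`, character(1), 1L)
  key_set <- vapply(keys, `[`, character(1), 2L)
  for (k in seq_along(byps)) {
    rows <- byps[[k]]
    cols <- which(s$tmt_set == as.integer(key_set[k]))
    for (jc in cols) {
      v <- M[rows, s$channel[jc]]
      m[key_prot[k], jc] <- if (method == "pooled") median(v)
        else median(tapply(v, psm$peptide_seq[rows], median))
      nsp[key_prot[k], jc] <- length(v)
      npep[key_prot[k], jc] <- length(unique(psm$peptide_seq[rows]))
    }
  }
  if (anyNA(m))
    stop("roll-up produced absent cells; the peptide-coverage filter ",
         "must run first")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2ratio = m, n_spectra = nsp, n_peptides = npep),
    colData = S4Vectors::DataFrame(s, row.names = s$sample_id),
    rowData = S4Vectors::DataFrame(accession = prots, row.names = prots),
    metadata = list(loading_corrected = FALSE))
  new("ProteinQuantMatrix", se)
}

#' Correct sample-loading differences by median polishing
#'
#' Subtracts from every sample column the median of that column across
#' proteins, so every sample has zero median log2 relative abundance. This
#' is the single-pass channel-median centering that defines the loading
#' correction here (not an iterative row/column polish); it removes any
#' per-sample additive offset (pipetting/labeling load differences)
#' exactly.
#'
#' @param x a [ProteinQuantMatrix-class].
#' @return the corrected matrix; the removed per-sample offsets are stored
#'   in `metadata(x)$loading_offsets`.
#' @export
medianPolishLoading <- function(x) {
  stopifnot(is(x, "ProteinQuantMatrix"))
  m <- quantMatrix(x)
  offsets <- apply(m, 2L, median)
  m <- sweep(m, 2L, offsets)
  SummarizedExperiment::assay(x, "log2ratio") <- m
  S4Vectors::metadata(x)$loading_corrected <- TRUE
  S4Vectors::metadata(x)$loading_offsets <- offsets
  stopifnot(all(abs(apply(m, 2L, median)) < 1e-9))
  x
}

#' Run the full quantification chain
#'
#' Convenience wrapper: [log2Transform()], [normalizeWithinProtein()],
#' [rollupProtein()], [medianPolishLoading()].
#'
#' @inheritParams rollupProtein
#' @param center_scope passed to [normalizeWithinProtein()].
#' @return a loading-corrected [ProteinQuantMatrix-class].
#' @export
quantifyProteins <- function(psm, samples,
                             center_scope = c("global", "set")) {
  center_scope <- match.arg(center_scope)
  medianPolishLoading(
    rollupProtein(normalizeWithinProtein(log2Transform(psm),
                                         scope = center_scope),
                  samples))
}
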