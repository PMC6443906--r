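## Plain-TSV readers/writers. All tables are tab-separated with a header
## row, UTF-8, '.' decimal; absent intensity channels are empty fields.

#' Write a table as TSV
#' @param x data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a PSM-level quantification table
#'
#' Reads a TSV of one row per quantified spectrum. Empty reporter fields
#' and literal zero intensities are both treated as absent (a detected
#' reporter ion is never truly zero).
#'
#' @param path TSV file with columns `spectrum_id`, `tmt_set`,
#'   `peptide_seq`, `protein_accessions`, the six reporter columns
#'   `i126`..`i131`, `is_decoy`, `is_contaminant`, `peptide_fdr`,
#'   `protein_fdr`, `engines_confirming`.
#' @return data.frame.
#' @export
readPsmTable <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("spectrum_id", "tmt_set", "peptide_seq", "protein_accessions",
            TMT_CHANNELS, "is_decoy", "is_contaminant", "peptide_fdr",
            "protein_fdr", "engines_confirming")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("PSM table lacks columns: ", paste(missing, collapse = ", "))
  for (ch in TMT_CHANNELS) {
    x[[ch]] <- as.numeric(x[[ch]])
    x[[ch]][!is.na(x[[ch]]) & x[[ch]] == 0] <- NA_real_
  }
  x
}

#' Read a sample metadata table
#' @param path TSV with one row per channel-in-set (donor covariates,
#'   reference flag, questionnaire columns).
#' @return data.frame.
#' @export
readSampleTable <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tmt_set", "channel", "is_reference")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("sample table lacks columns: ", paste(missing, collapse = ", "))
  x
}

#' Read a protein annotation table
#'
#' @param path TSV with columns `accession` and `categories`
#'   (semicolon-separated labels; a protein may carry several).
#' @return data.frame with list-column `categories`.
#' @export
readAnnotation <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("accession", "categories") %in% names(x)))
    stop("annotation table needs columns accession, categories")
  if (anyDuplicated(x$accession))
    stop("annotation accessions must be unique")
  x$categories <- strsplit(as.character(x$categories), ";", fixed = TRUE)
  x$categories <- lapply(x$categories, function(v) trimws(v[nzchar(trimws(v))]))
  x
}

#' Read a 6x6 reporter purity matrix from TSV
#' @param path TSV of 6 rows x 6 numeric columns (no header semantics
#'   beyond channel order 126..131).
#' @return 6x6 numeric matrix.
#' @export
readPurityMatrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, header = FALSE))
  storage.mode(m) <- "double"
  if (!identical(dim(m), c(6L, 6L)))
    stop("purity matrix must be 6x6")
  dimnames(m) <- list(TMT_CHANNELS, TMT_CHANNELS)
  m
}

#' Read a protein-by-sample matrix TSV back into a ProteinQuantMatrix
#'
#' @param path TSV written by the pipeline (`protein_matrix.tsv`): first
#'   column `accession`, remaining columns samples.
#' @param samples optional sample metadata table to attach as `colData`.
#' @param loading_corrected flag recorded in the metadata (the pipeline
#'   writes the matrix after loading correction).
#' @return a [ProteinQuantMatrix-class].
#' @export
readProteinMatrix <- function(path, samples = NULL,
                              loading_corrected = TRUE) {
  x <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (names(x)[1] != "accession")
    stop("protein matrix must have 'accession' as its first column")
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$accession
  cd <- if (!is.null(samples)) {
    s <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
    S4Vectors::DataFrame(s, row.names = colnames(m))
  } else {
    S4Vectors::DataFrame(sample_id = colnames(m), row.names = colnames(m))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2ratio = m), colData = cd,
    metadata = list(loading_corrected = loading_corrected))
  new("ProteinQuantMatrix", se)
}
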