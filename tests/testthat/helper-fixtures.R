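## Fixtures built in code: a hand-crafted 12-record PSM table exercising
## each retention rule exactly once, a bare quant-matrix constructor, and a
## small-cohort shortcut.

## quant matrix from a plain numeric matrix (rownames = accessions,
## colnames = sample ids)
makeQuantMatrix <- function(m, loading_corrected = FALSE) {
  cd <- S4Vectors::DataFrame(sample_id = colnames(m),
                             row.names = colnames(m))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2ratio = m),
    colData = cd,
    metadata = list(loading_corrected = loading_corrected))
  new("ProteinQuantMatrix", se)
}

## one PSM row with sensible defaults; override fields by name
psmRow <- function(spectrum_id, peptide_seq, protein_accessions,
                   tmt_set = 1L, intensities = c(10, 11, 12, 13, 14, 15),
                   is_decoy = FALSE, is_contaminant = FALSE,
                   peptide_fdr = 5e-4, protein_fdr = 5e-3,
                   engines_confirming = 2L) {
  x <- data.frame(spectrum_id = spectrum_id, tmt_set = tmt_set,
                  peptide_seq = peptide_seq,
                  protein_accessions = protein_accessions,
                  stringsAsFactors = FALSE)
  x[, tmtpa:::TMT_CHANNELS] <- rbind(intensities)
  x$is_decoy <- is_decoy
  x$is_contaminant <- is_contaminant
  x$peptide_fdr <- peptide_fdr
  x$protein_fdr <- protein_fdr
  x$engines_confirming <- engines_confirming
  x
}

## 12-record fixture: one record falls to each of the eight rules, four
## survive. The roster has donors only in set 1; set 2 is a reference-only
## set, so a peptide seen only in set 2 fails the coverage rule.
makeFilterFixture <- function() {
  psm <- rbind(
    psmRow("r01", "AAAAK", "DEC1", is_decoy = TRUE),             # rule 1
    psmRow("r02", "CCCCK", "KRT1", is_contaminant = TRUE),       # rule 2
    psmRow("r03", "PEPAK", "PA", peptide_fdr = 0.005),           # rule 3
    psmRow("r04", "PEPAK", "PA", protein_fdr = 0.02),            # rule 4
    psmRow("r05", "PEPAK", "PA;PB"),                             # rule 5
    psmRow("r06", "PEPAK", "PA",
           intensities = c(10, 11, 12, 13, 14, NA)),             # rule 6
    psmRow("r07", "PEPBK", "PB2", tmt_set = 2L),                 # rule 7
    psmRow("r08", "PEPCK", "PC", engines_confirming = 1L),       # rule 8
    psmRow("r09", "PEPAK", "PA"),
    psmRow("r10", "PEPAK", "PA", intensities = c(9, 9, 9, 9, 9, 9)),
    psmRow("r11", "PEPDK", "PA"),
    psmRow("r12", "PEPDK", "PA", intensities = c(20, 21, 22, 23, 24, 25))
  )
  samples <- data.frame(
    sample_id = c(sprintf("S%d", 1:5), "REF1", "REF2"),
    donor_id = c(sprintf("D%d", 1:5), NA, NA),
    tmt_set = c(rep(1L, 6), 2L),
    channel = c(1:6, 6L),
    is_reference = c(rep(FALSE, 5), TRUE, TRUE),
    stringsAsFactors = FALSE)
  list(psm = psm, samples = samples)
}

## small default-noise cohort for structural tests
smallCohort <- function(seed = 1L, n_proteins = 40L, ...) {
  simulateCohort(cohortConfig(n_proteins = n_proteins, seed = seed, ...))
}

## run a cohort through processing + quantification
quantifyCohort <- function(cohort, purity = defaultPurityMatrix()) {
  flt <- filterPSM(applyPurityCorrection(cohort$psm, purity),
                   cohort$samples)
  quantifyProteins(flt$psm, cohort$samples)
}

## independent brute-force step-up BH: q_(i) = min_{j >= i} m * p_(j) / j
bhBrute <- function(p) {
  m <- length(p)
  o <- order(p)
  psort <- p[o]
  ranks <- seq_len(m)
  qs <- vapply(ranks, function(i) min(1, m * psort[i:m] / ranks[i:m]),
               numeric(1))
  q <- numeric(m)
  q[o] <- qs
  q
}
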