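test_that("log2 transform and its error on nonpositive intensities", {
  p <- psmRow("s1", "PEPAK", "PA", intensities = c(8, 1, 2^0.5, 4, 2, 16))
  out <- log2Transform(p)
  expect_equal(unlist(out[, tmtpa:::TMT_CHANNELS], use.names = FALSE),
               c(3, 0, 0.5, 2, 1, 4))
  bad <- psmRow("s2", "PEPAK", "PA", intensities = c(0, 1, 1, 1, 1, 1))
  bad$i126 <- 0
  expect_error(log2Transform(bad), "s2")
})

test_that("within-protein centering zeroes the per-(protein,set) median", {
  p <- psmRow("s1", "PEPAK", "PA", intensities = 1:6)
  out <- normalizeWithinProtein(p)
  expect_equal(unlist(out[, tmtpa:::TMT_CHANNELS], use.names = FALSE),
               c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5))

  ## constant values center to zero; centering is idempotent
  q <- psmRow("s2", "PEPBK", "PB", intensities = rep(7, 6))
  expect_equal(unlist(normalizeWithinProtein(q)[, tmtpa:::TMT_CHANNELS],
                      use.names = FALSE), rep(0, 6))
  once <- normalizeWithinProtein(rbind(p, q))
  expect_equal(normalizeWithinProtein(once), once)

  ## per-(protein, set) medians are zero under set-scope centering
  co <- smallCohort(seed = 23, n_proteins = 25)
  flt <- filterPSM(applyPurityCorrection(co$psm, defaultPurityMatrix()),
                   co$samples)
  raw <- log2Transform(flt$psm)
  ctr <- normalizeWithinProtein(raw, scope = "set")
  M <- as.matrix(ctr[, tmtpa:::TMT_CHANNELS])
  g <- paste(ctr$protein_accessions, ctr$tmt_set)
  meds <- tapply(seq_len(nrow(M)), g, function(i) median(M[i, ]))
  expect_true(all(abs(meds) < 1e-9))

  ## per-protein medians are zero under the default global centering
  ctg <- normalizeWithinProtein(raw)
  Mg <- as.matrix(ctg[, tmtpa:::TMT_CHANNELS])
  gmeds <- tapply(seq_len(nrow(Mg)), ctg$protein_accessions,
                  function(i) median(Mg[i, ]))
  expect_true(all(abs(gmeds) < 1e-9))

  ## centering preserves the value ordering within each (protein, set)
  Mr <- as.matrix(raw[, tmtpa:::TMT_CHANNELS])
  for (grp in sample(unique(g), 10)) {
    i <- which(g == grp)
    expect_equal(order(as.vector(M[i, ])), order(as.vector(Mr[i, ])))
    expect_equal(order(as.vector(Mg[i, ])), order(as.vector(Mr[i, ])))
  }
})

test_that("protein roll-up takes pooled spectrum medians per channel", {
  samples <- data.frame(
    sample_id = c(sprintf("S%d", 1:5), "REF1"),
    donor_id = c(sprintf("D%d", 1:5), NA), tmt_set = 1L, channel = 1:6,
    is_reference = c(rep(FALSE, 5), TRUE), stringsAsFactors = FALSE)
  psm <- rbind(
    psmRow("s1", "PEPAK", "PA", intensities = c(0.1, 0.1, 1, 1, 1, 1)),
    psmRow("s2", "PEPAK", "PA", intensities = c(0.3, 0.3, 2, 2, 2, 2)),
    psmRow("s3", "PEPBK", "PA", intensities = c(0.2, 0.2, 9, 9, 9, 9)),
    psmRow("s4", "PEPCK", "PB", intensities = c(5, 6, 7, 8, 9, 10)))
  x <- rollupProtein(psm, samples)
  m <- quantMatrix(x)
  ## odd count: median of {0.1, 0.3, 0.2}
  expect_equal(m["PA", "S1"], 0.2)
  ## even-count convention via a two-spectrum protein
  psm2 <- psm[psm$spectrum_id %in% c("s1", "s2"), ]
  m2 <- quantMatrix(rollupProtein(psm2, samples))
  expect_equal(m2["PA", "S1"], 0.2)  # mean of middle pair (0.1, 0.3)
  ## singleton passes through
  expect_equal(m["PB", "S1"], 5)
  ## reference channel excluded from columns
  expect_false("REF1" %in% colnames(m))
  ## provenance counts
  expect_equal(SummarizedExperiment::assay(x, "n_spectra")["PA", "S1"], 3L)
  expect_equal(SummarizedExperiment::assay(x, "n_peptides")["PA", "S1"], 2L)
  ## peptide-median alternative weights peptides equally:
  ## PEPAK median = 0.2, PEPBK = 0.2 -> protein = 0.2; differs on channel 3
  ## where pooled median of {1, 2, 9} = 2 but peptide medians {1.5, 9} -> 5.25
  xp <- rollupProtein(psm, samples, method = "peptide_median")
  expect_equal(quantMatrix(xp)["PA", "S1"], 0.2)
  expect_equal(quantMatrix(xp)["PA", "S3"], 5.25)
  expect_equal(quantMatrix(x)["PA", "S3"], 2)
})

test_that("median polish zeroes column medians and is shift-invariant", {
  m <- matrix(c(1, 2, 3, 4, 6, 8, -1, 0, 1), 3, 3,
              dimnames = list(paste0("p", 1:3), paste0("s", 1:3)))
  x <- medianPolishLoading(makeQuantMatrix(m))
  out <- quantMatrix(x)
  expect_equal(unname(out[, 1]), c(-1, 0, 1))
  expect_true(isLoadingCorrected(x))
  expect_equal(unname(S4Vectors::metadata(x)$loading_offsets),
               c(2, 6, 0))
  ## fixed point: polishing again changes nothing
  expect_equal(quantMatrix(medianPolishLoading(x)), out)
  ## adding a constant to one column is exactly undone
  m_shift <- m; m_shift[, 2] <- m_shift[, 2] + 5
  expect_equal(quantMatrix(medianPolishLoading(makeQuantMatrix(m_shift))),
               out)
})

test_that("generator loading offsets are removed exactly at matrix level", {
  co <- smallCohort(seed = 29, n_proteins = 20)
  flt <- filterPSM(applyPurityCorrection(co$psm, defaultPurityMatrix()),
                   co$samples)
  pre <- rollupProtein(normalizeWithinProtein(log2Transform(flt$psm)),
                       co$samples)
  M <- quantMatrix(pre)
  set.seed(1)
  offs <- rnorm(ncol(M), 0, 0.5)
  shifted <- pre
  SummarizedExperiment::assay(shifted, "log2ratio") <- sweep(M, 2, -offs)
  a <- quantMatrix(medianPolishLoading(pre))
  b <- quantMatrix(medianPolishLoading(shifted))
  expect_equal(a, b, tolerance = 1e-12)
  ## and the invariant: every column median is zero
  expect_true(all(abs(apply(a, 2, median)) < 1e-9))
})

test_that("the full quantification chain yields a complete matrix", {
  co <- smallCohort(seed = 37, n_proteins = 25)
  pqm <- quantifyCohort(co)
  m <- quantMatrix(pqm)
  expect_false(anyNA(m))
  expect_equal(ncol(m), sum(!co$samples$is_reference))
  expect_true(isLoadingCorrected(pqm))
  expect_true(all(abs(apply(m, 2, median)) < 1e-9))
})
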