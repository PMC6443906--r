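test_that("cohort generation is bit-reproducible given the seed", {
  a <- simulateCohort(cohortConfig(n_donors = 15, n_proteins = 12, seed = 9))
  b <- simulateCohort(cohortConfig(n_donors = 15, n_proteins = 12, seed = 9))
  expect_identical(a, b)
  c2 <- simulateCohort(cohortConfig(n_donors = 15, n_proteins = 12, seed = 10))
  expect_false(identical(a$psm, c2$psm))
})

test_that("simulated questionnaire records round-trip the MVPA target", {
  set.seed(101)
  targets <- c(0, 20, 30, 37, 60, 74, 75, 100, 149, 150, 151, 200, 333, 420)
  for (t in targets) {
    for (rep in 1:3) {
      recs <- simulateActivityRecords(t)
      expect_equal(computeMvpaMinutes(recs), t, info = paste("target", t))
    }
  }
  ## zero target yields no MVPA records (casual walking may remain)
  set.seed(5)
  r0 <- simulateActivityRecords(0)
  expect_false(any(r0$activity_type %in% tmtpa:::MVPA_TYPES))
  expect_error(simulateActivityRecords(-5), "nonnegative")
})

test_that("every generated donor's records round-trip through scoring", {
  co <- smallCohort(seed = 21, n_proteins = 10)
  covs <- buildCovariates(co$samples)
  truth <- co$truth$sample_truth
  idx <- match(covs$donor_id, truth$donor_id)
  expect_equal(covs$mvpa_minutes, truth$pa_minutes[idx])
  expect_identical(as.integer(covs$pa_code), as.integer(truth$pa_code[idx]))
})

test_that("cohort tables have the designed TMT layout", {
  cfg <- cohortConfig(n_donors = 20, n_proteins = 15, seed = 2)
  co <- simulateCohort(cfg)
  s <- co$samples
  expect_equal(nSets(cfg), 4L)
  expect_equal(sum(!s$is_reference), 20L)
  expect_equal(sum(s$is_reference), 4L)
  ## each set: 5 donors + 1 reference, channels 1..6 once each
  for (b in unique(s$tmt_set)) {
    sb <- s[s$tmt_set == b, ]
    expect_setequal(sb$channel, 1:6)
    expect_equal(sum(sb$is_reference), 1L)
  }
  ## one donor per age stratum per set
  strata <- findInterval(s$age[!s$is_reference], c(35, 50, 65, 80))
  expect_true(all(table(s$tmt_set[!s$is_reference], strata) == 1))
  ## truth effect magnitudes respect the configured range
  eff <- co$truth$protein_effects
  nz <- eff$beta_pa[!eff$is_null]
  expect_true(all(abs(nz) >= cfg@beta_range[1] - 1e-12 &
                    abs(nz) <= cfg@beta_range[2] + 1e-12))
  expect_true(all(eff$beta_pa[eff$is_null] == 0))
})

test_that("nuisance record fractions are realized within binomial error", {
  cfg <- cohortConfig(n_donors = 30, n_proteins = 120, seed = 31,
                      frac_shared = 0.10, frac_missing_channel = 0.05,
                      frac_decoy = 0.04, frac_contaminant = 0.02,
                      frac_incomplete_peptide = 0)
  co <- simulateCohort(cfg)
  psm <- co$psm
  real <- psm[!psm$is_decoy & !psm$is_contaminant, ]
  ## shared/missing flags apply to non-myosin spectra only (myosins are
  ## pinned so the fiber covariate always exists)
  eligible <- !grepl("^MYH", real$protein_accessions)
  n <- sum(eligible)
  expect_gt(n, 1000)
  band <- function(p) 3 * sqrt(n * p * (1 - p))
  n_shared <- sum(grepl(";", real$protein_accessions[eligible], fixed = TRUE))
  expect_lt(abs(n_shared - n * 0.10), band(0.10))
  n_miss <- sum(apply(is.na(real[eligible, tmtpa:::TMT_CHANNELS]), 1, any))
  expect_lt(abs(n_miss - n * 0.05), band(0.05))
  n_all <- nrow(real)
  n_decoy <- sum(psm$is_decoy)
  expect_lt(abs(n_decoy - n_all * 0.04), 3 * sqrt(n_all * 0.04 * 0.96))
  n_con <- sum(psm$is_contaminant)
  expect_lt(abs(n_con - n_all * 0.02), 3 * sqrt(n_all * 0.02 * 0.98))
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(frac_decoy = 1.5), "proportions")
  expect_error(cohortConfig(sigma_spectrum = -0.1), "nonnegative")
  expect_error(cohortConfig(n_proteins = 2), "MYH")
  bad_purity <- matrix(1 / 6, 6, 6)  # no dominant diagonal
  expect_error(cohortConfig(purity_matrix = bad_purity), "diagonal")
  expect_error(cohortConfig(beta_range = c(0.2, 0.1)), "beta_range")
})

test_that("a coverage-destroying config warns in the generation report", {
  expect_warning(
    simulateCohort(cohortConfig(n_donors = 10, n_proteins = 10,
                                frac_incomplete_peptide = 1, seed = 4)),
    "coverage")
})

test_that("emitted intensities are linear-scale and purity-mixed", {
  ## with identity purity and all noise off, channel intensities of a null
  ## protein's spectrum are exactly 2^(m0 + e_j) on reference channels
  cfg <- cohortConfig(n_donors = 5, n_proteins = 4, frac_nonnull = 0,
                      sigma_spectrum = 0, tau_batch = 0, loading_sd = 0,
                      peptide_offset_sd = 0, beta_age_sd = 0, beta_bmi_sd = 0,
                      frac_decoy = 0, frac_contaminant = 0, frac_shared = 0,
                      frac_missing_channel = 0, frac_incomplete_peptide = 0,
                      purity_matrix = diag(6), seed = 8)
  co <- simulateCohort(cfg)
  eff <- co$truth$protein_effects
  for (i in 1:4) {
    rows <- co$psm[co$psm$protein_accessions == eff$accession[i], ]
    vals <- as.matrix(rows[, tmtpa:::TMT_CHANNELS])
    expect_equal(unname(vals),
                 matrix(2^eff$m0[i], nrow(vals), 6), tolerance = 1e-12)
  }
})
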