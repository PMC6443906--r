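## Seeded synthetic TMT cohort generator: PSM table + sample metadata +
## ground truth, with the statistical structure the downstream analysis
## assumes, so every stage is testable without the deposited raw data.

#' Default TMT 6-plex reporter isotopic-purity matrix
#'
#' Crosstalk matrix of a typical 6-plex lot: each tag leaks small fractions
#' of its signal into the -2/-1/+1/+2 mass neighbors (0.1%, 2.5%, 6%, 0.2%
#' here); the diagonal holds the remainder. Entry (i, j) is the fraction of
#' channel j's true signal observed in channel i, so observed = P %*% true
#' and correction solves that linear system.
#'
#' @return 6x6 numeric matrix with dominant diagonal.
#' @export
defaultPurityMatrix <- function() {
  leak <- c(m2 = 0.001, m1 = 0.025, p1 = 0.060, p2 = 0.002)
  P <- matrix(0, 6, 6, dimnames = list(TMT_CHANNELS, TMT_CHANNELS))
  for (j in 1:6) {
    P[j, j] <- 1 - sum(leak)
    if (j - 2 >= 1) P[j - 2, j] <- leak["m2"]
    if (j - 1 >= 1) P[j - 1, j] <- leak["m1"]
    if (j + 1 <= 6) P[j + 1, j] <- leak["p1"]
    if (j + 2 <= 6) P[j + 2, j] <- leak["p2"]
  }
  P
}

#' Construct a synthetic-cohort configuration
#'
#' Defaults mirror the study design this generator emulates: 60 donors in
#' twelve 6-plex TMT sets, each set holding one donor from each of five age
#' strata (20-34, 35-49, 50-64, 65-79, 80+) plus a pooled reference in
#' channel 6; activity codes distributed as in the study cohort; nonzero
#' activity slopes spanning the reported per-protein effect magnitudes
#' (0.02-0.22 log2 units per activity point, two-thirds negative).
#'
#' @param n_donors,donors_per_set cohort size and donors per set.
#' @param n_proteins proteins simulated (>= 4; MYH7/MYH1/MYH2/MYH4 are
#'   always among them, with null activity effects, so the fiber-ratio
#'   covariate is available).
#' @param peptides_per_protein,spectra_per_peptide integer ranges (min, max).
#' @param frac_nonnull,beta_range,frac_beta_negative activity-effect
#'   structure.
#' @param beta_age_sd,beta_bmi_sd SDs of per-protein age/BMI slopes.
#' @param sigma_spectrum,tau_batch,loading_sd,peptide_offset_sd variance
#'   components in log2 units.
#' @param frac_decoy,frac_contaminant,frac_shared,frac_missing_channel,frac_incomplete_peptide
#'   nuisance-record rates.
#' @param purity_matrix 6x6 crosstalk matrix applied to emitted intensities.
#' @param seed integer RNG seed; every stochastic draw of the generator is
#'   routed through the single stream it initializes.
#' @return a validated [CohortConfig-class] object.
#' @examples
#' cfg <- cohortConfig(n_proteins = 50, seed = 7)
#' nSets(cfg)
#' @export
cohortConfig <- function(n_donors = 60L,
                         donors_per_set = 5L,
                         n_proteins = 200L,
                         peptides_per_protein = c(1L, 4L),
                         spectra_per_peptide = c(1L, 3L),
                         frac_nonnull = 0.25,
                         beta_range = c(0.02, 0.22),
                         frac_beta_negative = 0.68,
                         beta_age_sd = 0.001,
                         beta_bmi_sd = 0.003,
                         sigma_spectrum = 0.2,
                         tau_batch = 0.05,
                         loading_sd = 0.1,
                         peptide_offset_sd = 0.3,
                         frac_decoy = 0.02,
                         frac_contaminant = 0.01,
                         frac_shared = 0.05,
                         frac_missing_channel = 0.02,
                         frac_incomplete_peptide = 0.03,
                         purity_matrix = defaultPurityMatrix(),
                         seed = 1L) {
  new("CohortConfig",
      n_donors = as.integer(n_donors),
      donors_per_set = as.integer(donors_per_set),
      n_proteins = as.integer(n_proteins),
      peptides_per_protein = as.integer(peptides_per_protein),
      spectra_per_peptide = as.integer(spectra_per_peptide),
      frac_nonnull = frac_nonnull,
      beta_range = as.numeric(beta_range),
      frac_beta_negative = frac_beta_negative,
      beta_age_sd = beta_age_sd,
      beta_bmi_sd = beta_bmi_sd,
      sigma_spectrum = sigma_spectrum,
      tau_batch = tau_batch,
      loading_sd = loading_sd,
      peptide_offset_sd = peptide_offset_sd,
      frac_decoy = frac_decoy,
      frac_contaminant = frac_contaminant,
      frac_shared = frac_shared,
      frac_missing_channel = frac_missing_channel,
      frac_incomplete_peptide = frac_incomplete_peptide,
      purity_matrix = purity_matrix,
      seed = as.integer(seed))
}

## sample one integer uniformly from a (min,max) range
.rint <- function(range, n = 1L) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate questionnaire records realizing a target MVPA level
#'
#' Builds a plausible set of activity records (brisk walking, weight or
#' circuit training, up to four vigorous activities) whose frequency x
#' duration total over two weeks, halved, reproduces `pa_minutes_target`
#' exactly: the two-week total is split into whole sessions whose durations
#' are exact divisors, so [computeMvpaMinutes()] on the output round-trips
#' the target. A casual-walking record is generated independently and never
#' contributes to MVPA.
#'
#' @param pa_minutes_target desired weekly MVPA minutes (nonnegative; a
#'   whole number of minutes over the two-week window, i.e. a multiple of
#'   0.5 per week, is reproduced exactly).
#' @return data.frame of activity records.
#' @export
simulateActivityRecords <- function(pa_minutes_target) {
  if (!is.finite(pa_minutes_target) || pa_minutes_target < 0)
    stop("pa_minutes_target must be finite and nonnegative")
  recs <- list()
  M <- 2 * pa_minutes_target          # minutes over the two-week window
  if (M > 0) {
    if (abs(M - round(M)) < 1e-9) M <- round(M)
    k <- sample(1:3, 1, prob = c(0.4, 0.4, 0.2))
    k <- min(k, max(1, floor(M / 10)))  # keep sessions >= ~10 min when possible
    types <- sample(MVPA_TYPES, k,
                    prob = c(0.25, 0.2, 0.35, 0.1, 0.05, 0.05)[seq_along(MVPA_TYPES)])
    if (k == 1L || M != round(M)) {
      parts <- M
      types <- types[1]
    } else {
      cuts <- sort(sample(seq_len(M - 1), k - 1))
      parts <- diff(c(0, cuts, M))
    }
    for (i in seq_along(parts)) {
      p <- parts[i]
      if (p == round(p)) {
        div <- which(p %% seq_len(min(14, p)) == 0)    # candidate frequencies
        good <- div[p / div >= 10 & p / div <= 90]
        f <- if (length(good)) sample(rep(good, 2L), 1) else sample(rep(div, 2L), 1)
        d <- p / f
      } else {
        f <- 1; d <- p
      }
      recs[[length(recs) + 1L]] <- activityRecord(types[i], f, d)
    }
  }
  if (runif(1) < 0.85) {
    recs[[length(recs) + 1L]] <-
      activityRecord("casual_walking", sample(1:14, 1),
                     sample(seq(10, 90, by = 5), 1))
  }
  if (!length(recs))
    return(data.frame(activity_type = character(), performed = logical(),
                      frequency = numeric(), duration = numeric()))
  do.call(rbind, recs)
}

## draw a target weekly MVPA level for a donor: code frequencies follow the
## study cohort (11/8/14/25 of 58), minutes uniform within the code's band
.drawPaTarget <- function() {
  code <- sample(0:3, 1, prob = c(11, 8, 14, 25) / 58)
  switch(as.character(code),
         "0" = if (runif(1) < 0.5) 0 else sample(5:29, 1),
         "1" = sample(30:74, 1),
         "2" = sample(75:149, 1),
         "3" = sample(150:420, 1))
}

#' Generate a synthetic TMT cohort
#'
#' Produces a PSM-level quantification table, a sample metadata table and
#' the generating ground truth. The log2 intensity of spectrum s (peptide j
#' of protein p) in channel c of set b is
#' `m_p + e_j + beta_PA,p * PA_i + beta_age,p * age_i + beta_BMI,p * BMI_i
#'  + u_pb + L_bc + eps`, with `u ~ N(0, tau_batch^2)` per protein x set,
#' `L ~ N(0, loading_sd^2)` per set x channel, and `eps ~ N(0,
#' sigma_spectrum^2)` per spectrum x channel; the reference channel carries
#' the covariate-free pooled profile. Intensities are emitted on the linear
#' scale (2^log2) and then mixed through the purity matrix. Nuisance
#' records (decoys, contaminants, shared spectra, spectra with an absent
#' channel, peptides missing from whole sets) are injected at the
#' configured rates. The generator is reproducible bit-for-bit given the
#' config seed.
#'
#' @param config a [CohortConfig-class].
#' @return list with elements `psm` (data.frame, one row per spectrum),
#'   `samples` (data.frame, one row per channel-in-set) and `truth` (list:
#'   `protein_effects`, `sample_truth`, `loading_offsets`,
#'   `batch_intercepts`).
#' @examples
#' cohort <- simulateCohort(cohortConfig(n_donors = 10, n_proteins = 20,
#'                                       seed = 42))
#' head(cohort$psm)
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  set.seed(config@seed)
  n_sets <- nSets(config)
  dps <- config@donors_per_set

  ## ---- donors -------------------------------------------------------------
  age_bounds <- list(c(20, 34), c(35, 49), c(50, 64), c(65, 79), c(80, 94))
  n_d <- config@n_donors
  donor_id <- sprintf("D%03d", seq_len(n_d))
  donor_set <- rep(seq_len(n_sets), each = dps)[seq_len(n_d)]
  ## one donor per age stratum within each set (cycling when dps < 5)
  donor_group <- (seq_len(n_d) - 1L) %% dps %% 5L + 1L
  age <- vapply(donor_group, function(g)
    sample(seq(age_bounds[[g]][1], age_bounds[[g]][2]), 1), numeric(1))
  sex <- sample(c("M", "F"), n_d, replace = TRUE, prob = c(0.62, 0.38))
  race <- sample(c("C", "AA", "A"), n_d, replace = TRUE,
                 prob = c(0.71, 0.24, 0.05))
  bmi <- round(pmin(pmax(rnorm(n_d, 26, 3), 19), 29.9), 1)
  pa_minutes <- vapply(seq_len(n_d), function(i) .drawPaTarget(), numeric(1))
  records <- lapply(pa_minutes, simulateActivityRecords)
  pa_code <- categorizeActivity(pa_minutes)

  ## channel assignment: donors shuffled over channels 1..dps within a set,
  ## channel 6 (and any channel left unfilled) is the pooled reference
  channel <- integer(n_d)
  for (b in seq_len(n_sets)) {
    idx <- which(donor_set == b)
    channel[idx] <- sample(seq_len(dps))[seq_along(idx)]
  }

  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_d)),
    donor_id = donor_id, tmt_set = donor_set, channel = channel,
    is_reference = FALSE, age = age, sex = sex, race = race, bmi = bmi,
    stringsAsFactors = FALSE)
  samples <- cbind(samples, do.call(rbind, lapply(records, recordsToWide)))
  ref_rows <- do.call(rbind, lapply(seq_len(n_sets), function(b) {
    filled <- samples$channel[samples$tmt_set == b]
    refch <- setdiff(1:6, filled)
    data.frame(sample_id = sprintf("REF%02d_c%d", b, refch),
               donor_id = NA_character_, tmt_set = b, channel = refch,
               is_reference = TRUE, age = NA_real_, sex = NA_character_,
               race = NA_character_, bmi = NA_real_,
               stringsAsFactors = FALSE)
  }))
  ref_rows <- cbind(ref_rows, recordsToWide(NULL)[rep(1, nrow(ref_rows)), ])
  samples <- rbind(samples, ref_rows)
  samples <- samples[order(samples$tmt_set, samples$channel), ]
  rownames(samples) <- NULL

  ## per-(set, channel) covariate vectors (0 on reference channels)
  PA <- AGE <- BMIm <- matrix(0, n_sets, 6)
  for (i in seq_len(n_d)) {
    PA[donor_set[i], channel[i]] <- pa_code[i]
    AGE[donor_set[i], channel[i]] <- age[i]
    BMIm[donor_set[i], channel[i]] <- bmi[i]
  }

  ## ---- proteins, peptides -------------------------------------------------
  n_p <- config@n_proteins
  myh <- c("MYH7", "MYH1", "MYH2", "MYH4")
  accession <- c(myh, sprintf("P%04d", seq_len(n_p - 4L)))
  m0 <- c(rnorm(4, 19, 0.5), rnorm(n_p - 4L, 16, 1.5))
  nonnull <- runif(n_p) < config@frac_nonnull
  nonnull[1:4] <- FALSE   # MYH rows stay null so the fiber covariate is clean
  beta_pa <- numeric(n_p)
  nn <- sum(nonnull)
  if (nn) {
    mag <- runif(nn, config@beta_range[1], config@beta_range[2])
    sgn <- ifelse(runif(nn) < config@frac_beta_negative, -1, 1)
    beta_pa[nonnull] <- sgn * mag
  }
  beta_age <- if (config@beta_age_sd > 0) rnorm(n_p, 0, config@beta_age_sd) else numeric(n_p)
  beta_bmi <- if (config@beta_bmi_sd > 0) rnorm(n_p, 0, config@beta_bmi_sd) else numeric(n_p)
  beta_age[1:4] <- beta_bmi[1:4] <- 0

  n_pep <- .rint(config@peptides_per_protein, n_p)
  ## the four myosins are saturatingly abundant in muscle and always fully
  ## quantified; pin their peptide counts so the fiber covariate exists
  n_pep[1:4] <- max(config@peptides_per_protein[2], 2L)
  pep_protein <- rep(seq_len(n_p), n_pep)
  n_peptides <- length(pep_protein)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pep_seq <- vapply(seq_len(n_peptides), function(j)
    paste0(paste(sample(aa, sample(7:14, 1), replace = TRUE), collapse = ""),
           c("K", "R")[sample(1:2, 1)]),
    character(1))
  e_pep <- if (config@peptide_offset_sd > 0)
    rnorm(n_peptides, 0, config@peptide_offset_sd) else numeric(n_peptides)

  ## batch intercepts and loading offsets
  U <- matrix(if (config@tau_batch > 0) rnorm(n_p * n_sets, 0, config@tau_batch)
              else 0, n_p, n_sets)
  L <- matrix(if (config@loading_sd > 0) rnorm(n_sets * 6, 0, config@loading_sd)
              else 0, n_sets, 6)

  ## ---- spectra ------------------------------------------------------------
  ## each peptide acquires spectra in every set (coverage gaps injected later)
  n_spec_js <- .rint(config@spectra_per_peptide, n_peptides * n_sets)
  pep_row <- rep(rep(seq_len(n_peptides), times = n_sets),
                 times = n_spec_js)
  set_row <- rep(rep(seq_len(n_sets), each = n_peptides),
                 times = n_spec_js)
  N <- length(pep_row)
  prot_row <- pep_protein[pep_row]

  base <- m0[prot_row] + e_pep[pep_row] + U[cbind(prot_row, set_row)]
  log2I <- matrix(0, N, 6)
  for (cc in 1:6) {
    log2I[, cc] <- base +
      beta_pa[prot_row] * PA[cbind(set_row, cc)] +
      beta_age[prot_row] * AGE[cbind(set_row, cc)] +
      beta_bmi[prot_row] * BMIm[cbind(set_row, cc)] +
      L[cbind(set_row, cc)] +
      if (config@sigma_spectrum > 0) rnorm(N, 0, config@sigma_spectrum) else 0
  }
  intens <- 2^log2I %*% t(config@purity_matrix)   # observed = P %*% true, per row

  ## ---- nuisance injection -------------------------------------------------
  acc_col <- accession[prot_row]
  myh_row <- prot_row <= 4L   # myosin spectra stay pristine (see above)
  shared <- runif(N) < config@frac_shared & !myh_row
  if (any(shared)) {
    other <- vapply(prot_row[shared], function(p)
      sample(accession[-p], 1), character(1))
    acc_col[shared] <- paste(acc_col[shared], other, sep = ";")
  }
  miss <- runif(N) < config@frac_missing_channel & !myh_row
  if (any(miss)) {
    ch <- sample(1:6, sum(miss), replace = TRUE)
    intens[cbind(which(miss), ch)] <- NA_real_
  }
  drop_row <- rep(FALSE, N)
  incomplete <- which(runif(n_peptides) < config@frac_incomplete_peptide &
                        pep_protein > 4L)
  for (j in incomplete) {
    b <- sample(seq_len(n_sets), 1)
    drop_row[pep_row == j & set_row == b] <- TRUE
  }

  psm <- data.frame(
    spectrum_id = NA_character_,
    tmt_set = set_row,
    peptide_seq = pep_seq[pep_row],
    protein_accessions = acc_col,
    stringsAsFactors = FALSE)
  psm <- cbind(psm, as.data.frame(intens))
  names(psm)[4L + 1:6] <- TMT_CHANNELS
  psm$is_decoy <- FALSE
  psm$is_contaminant <- FALSE
  psm <- psm[!drop_row, , drop = FALSE]

  ## decoys and contaminants: extra records with their own accession space
  mkNoise <- function(n, prefix, decoy, contam) {
    if (n == 0L) return(NULL)
    x <- data.frame(
      spectrum_id = NA_character_,
      tmt_set = sample(seq_len(n_sets), n, replace = TRUE),
      peptide_seq = vapply(seq_len(n), function(i)
        paste0(paste(sample(aa, 10, replace = TRUE), collapse = ""), "K"),
        character(1)),
      protein_accessions = sprintf("%s%04d", prefix, sample(500, n, TRUE)),
      stringsAsFactors = FALSE)
    noise <- matrix(2^rnorm(n * 6, 15, 2), n, 6)
    x <- cbind(x, as.data.frame(noise))
    names(x)[4L + 1:6] <- TMT_CHANNELS
    x$is_decoy <- decoy
    x$is_contaminant <- contam
    x
  }
  n_real <- nrow(psm)
  psm <- rbind(psm,
               mkNoise(rbinom(1, n_real, config@frac_decoy), "DECOY_", TRUE, FALSE),
               mkNoise(rbinom(1, n_real, config@frac_contaminant), "CON_", FALSE, TRUE))
  n_tot <- nrow(psm)
  psm$peptide_fdr <- runif(n_tot, 0, 0.001)
  psm$protein_fdr <- runif(n_tot, 0, 0.01)
  psm$engines_confirming <- sample(1:3, n_tot, replace = TRUE,
                                   prob = c(0.15, 0.55, 0.30))
  psm <- psm[order(psm$tmt_set, psm$protein_accessions, psm$peptide_seq), ]
  psm$spectrum_id <- sprintf("sp%06d", seq_len(n_tot))
  rownames(psm) <- NULL

  ## generation report: will anything beyond the pinned myosins survive the
  ## peptide-coverage rule?
  other_pep <- which(pep_protein > 4L)
  if (length(other_pep) && all(other_pep %in% incomplete))
    warning("generation report: every non-myosin peptide has incomplete ",
            "sample coverage; downstream filtering would retain no proteins ",
            "beyond MYH7/MYH1/MYH2/MYH4")

  truth <- list(
    protein_effects = data.frame(
      accession = accession, m0 = m0, beta_pa = beta_pa,
      beta_age = beta_age, beta_bmi = beta_bmi,
      tau_batch = rep(config@tau_batch, n_p),
      is_null = !nonnull, stringsAsFactors = FALSE),
    sample_truth = data.frame(
      donor_id = donor_id, pa_minutes = pa_minutes, pa_code = pa_code,
      age = age, sex = sex, race = race, bmi = bmi,
      stringsAsFactors = FALSE),
    loading_offsets = data.frame(
      tmt_set = rep(seq_len(n_sets), each = 6L),
      channel = rep(1:6, times = n_sets),
      offset = as.vector(t(L))),
    batch_intercepts = data.frame(
      accession = rep(accession, times = n_sets),
      tmt_set = rep(seq_len(n_sets), each = n_p),
      u = as.vector(U))
  )
  list(psm = psm, samples = samples, truth = truth)
}

#' Write a simulated cohort to TSV files
#'
#' @param cohort result of [simulateCohort()].
#' @param dir output directory (created if needed); writes `psm.tsv`,
#'   `samples.tsv`, `truth.tsv` (per-protein effects), `truth_loading.tsv`.
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("psm.tsv", "samples.tsv", "truth.tsv",
                            "truth_loading.tsv"))
  writeTsv(cohort$psm, paths[1])
  writeTsv(cohort$samples, paths[2])
  writeTsv(cohort$truth$protein_effects, paths[3])
  writeTsv(cohort$truth$loading_offsets, paths[4])
  invisible(paths)
}
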