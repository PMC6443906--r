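## random modeling frame for oracle checks
randomDesign <- function(n = 40, n_sets = 4) {
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    pa_code = sample(0:3, n, replace = TRUE),
    age = runif(n, 20, 90),
    race = sample(c("C", "AA", "A"), n, replace = TRUE),
    bmi = runif(n, 19, 30),
    fiber_ratio = runif(n, 0.2, 0.6),
    tmt_set = sample(seq_len(n_sets), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

## closed-form OLS for the activity slope: solve the normal equations
olsOracle <- function(y, d, spec) {
  ref <- names(which.max(table(d$race)))
  d$race <- stats::relevel(factor(d$race), ref = ref)
  X <- stats::model.matrix(~ pa_code + age + race + bmi + fiber_ratio, d)
  bh <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% bh
  s2 <- sum(res^2) / (length(y) - ncol(X))
  se <- sqrt(diag(solve(t(X) %*% X)) * s2)
  list(beta = bh["pa_code", 1], se = se["pa_code"])
}

test_that("boundary-variance mixed fits equal closed-form least squares", {
  set.seed(11)
  n_checked <- 0
  for (i in 1:60) {
    d <- randomDesign(n = 30 + sample(0:30, 1), n_sets = sample(3:6, 1))
    X <- stats::model.matrix(~ pa_code + age + race + bmi + fiber_ratio, d)
    y <- as.numeric(X %*% rnorm(ncol(X), 0, 0.1)) + rnorm(nrow(d), 0, 0.3)
    r <- fitProteinMixedModel(y, d, modelSpec())
    expect_true(r$converged)
    if (r$singular) {
      o <- olsOracle(y, d, modelSpec())
      expect_equal(r$beta, unname(o$beta), tolerance = 1e-6)
      expect_equal(r$se, unname(o$se), tolerance = 1e-6)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 15)
})

test_that("a zero response gives a zero slope with p at 1", {
  d <- randomDesign(n = 40)
  r <- suppressWarnings(fitProteinMixedModel(rep(0, 40), d, modelSpec()))
  expect_equal(r$beta, 0)
  expect_equal(r$p, 1)
})

test_that("estimates are invariant to sample permutation", {
  set.seed(19)
  d <- randomDesign(n = 45, n_sets = 5)
  y <- rnorm(45, 0, 0.2) + 0.05 * d$pa_code
  r1 <- fitProteinMixedModel(y, d, modelSpec())
  perm <- sample(45)
  r2 <- fitProteinMixedModel(y[perm], d[perm, ], modelSpec())
  expect_equal(r1$beta, r2$beta, tolerance = 1e-8)
  expect_equal(r1$se, r2$se, tolerance = 1e-8)
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
})

test_that("rank-deficient designs fail loudly, naming the column", {
  d <- randomDesign(n = 40)
  d$fiber_ratio <- 0.4   # constant -> collinear with intercept
  expect_error(fitProteinMixedModel(rnorm(40), d, modelSpec()),
               "fiber_ratio")
  d2 <- randomDesign(n = 40)
  d2$tmt_set <- 1L
  expect_error(fitProteinMixedModel(rnorm(40), d2, modelSpec()),
               "two TMT sets")
})

test_that("Benjamini-Hochberg equals the brute-force step-up rule", {
  expect_equal(adjustBH(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjustBH(0.2), 0.2)
  expect_equal(adjustBH(rep(0.07, 5)), rep(0.07, 5))
  set.seed(33)
  for (i in 1:200) {
    n <- sample(1:20, 1)
    p <- round(runif(n), sample(c(1, 2, 6), 1))  # rounding creates ties
    expect_equal(adjustBH(p), bhBrute(p), info = paste("case", i))
  }
  expect_error(adjustBH(c(0.5, 1.2)), "0, 1")
})

test_that("direction calls follow sign and significance", {
  expect_identical(classifyDirection(0.05, 0.001), "up")
  expect_identical(classifyDirection(-0.0281, 6.61e-7), "down")
  expect_identical(classifyDirection(0.1, 0.2), "ns")
  expect_identical(classifyDirection(0, 0.001), "ns")
  expect_identical(classifyDirection(c(1, -1, 1), c(0.01, 0.01, 0.99)),
                   c("up", "down", "ns"))
})

test_that("the per-protein sweep is complete and internally consistent", {
  co <- smallCohort(seed = 41, n_proteins = 25)
  pqm <- quantifyCohort(co)
  covs <- buildCovariates(co$samples, pqm)
  res <- fitAllProteins(pqm, covs)
  expect_equal(nrow(res), nrow(pqm))
  expect_false(anyNA(res$beta))
  expect_false(anyNA(res$p_value))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_true(all(res$q_value >= 0 & res$q_value <= 1))
  expect_identical(res$direction,
                   classifyDirection(res$beta, res$p_value, 0.05))
  ## deterministic given inputs
  res2 <- fitAllProteins(pqm, covs)
  expect_equal(as.data.frame(res), as.data.frame(res2))
  ## misaligned covariates rejected
  bad <- covs; bad$sample_id[1] <- "nope"
  expect_error(fitAllProteins(pqm, bad, modelSpec()), "match")
})
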