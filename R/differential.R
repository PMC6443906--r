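## Per-protein linear mixed models of log2 abundance on the ordinal
## activity code, with age, race, BMI and fiber-type ratio as fixed
## covariates and the TMT set as a random intercept; Satterthwaite
## p-values, Benjamini-Hochberg correction, and direction calls.

#' Construct a model specification
#'
#' @param batch `"random"` (TMT set as a random intercept, the default) or
#'   `"fixed"` (set as a fixed factor).
#' @param reml use REML estimation (default TRUE).
#' @param df `"Satterthwaite"` (default) or `"residual"` degrees of freedom
#'   for the activity-slope t-test.
#' @param alpha significance level for direction calls (default 0.05, raw
#'   p-values).
#' @param use_fiber_ratio include the myosin fiber-type ratio covariate
#'   (default TRUE).
#' @return a [ModelSpec-class].
#' @export
modelSpec <- function(batch = c("random", "fixed"), reml = TRUE,
                      df = c("Satterthwaite", "residual"), alpha = 0.05,
                      use_fiber_ratio = TRUE) {
  new("ModelSpec", batch = match.arg(batch), reml = reml,
      df = match.arg(df), alpha = alpha, use_fiber_ratio = use_fiber_ratio)
}

## assemble the modeling frame; race releveled to its most frequent level
.modelFrame <- function(y, covariates, spec) {
  need <- c("pa_code", "age", "race", "bmi", "tmt_set")
  if (spec@use_fiber_ratio) need <- c(need, "fiber_ratio")
  missing <- setdiff(need, names(covariates))
  if (length(missing))
    stop("covariate table lacks: ", paste(missing, collapse = ", "))
  d <- covariates[, need, drop = FALSE]
  d$y <- y
  race <- factor(d$race)
  d$race <- stats::relevel(race, ref = names(which.max(table(race))))
  d$tmt_set <- factor(d$tmt_set)
  d
}

.fixedFormula <- function(spec) {
  rhs <- "pa_code + age + race + bmi"
  if (spec@use_fiber_ratio) rhs <- paste(rhs, "+ fiber_ratio")
  rhs
}

## error if the fixed-effect design is rank deficient, naming the columns
.checkRank <- function(d, spec) {
  X <- stats::model.matrix(stats::as.formula(paste("y ~", .fixedFormula(spec))), d)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  invisible(X)
}

## degenerate zero-variance responses give se = 0 and an undefined t;
## resolve by the t -> 0 limit (p = 1) for a zero slope
.fixDegenerateP <- function(beta, se, p) {
  if (!is.finite(p) && is.finite(beta)) p <- if (abs(beta) < 1e-12) 1 else 0
  p
}

#' Fit the mixed model for one protein
#'
#' REML fit of `y ~ pa_code + age + race + bmi + fiber_ratio +
#' (1 | tmt_set)` via lme4/lmerTest; the returned coefficient is the single
#' activity slope (the ordinal code enters as a numeric regressor) with its
#' standard error, Satterthwaite degrees of freedom, and t-test p-value.
#' When the batch variance is estimated at the zero boundary the fit
#' coincides with ordinary least squares. If the mixed fit fails to
#' converge, the model is refitted without the random effect (residual df)
#' and flagged.
#'
#' @param y per-sample log2 abundance, aligned with `covariates` rows.
#' @param covariates covariate table from [buildCovariates()].
#' @param spec a [ModelSpec-class].
#' @return list with `beta`, `se`, `df`, `p`, `converged`, `singular`.
#' @export
fitProteinMixedModel <- function(y, covariates, spec = modelSpec()) {
  stopifnot(length(y) == nrow(covariates))
  d <- .modelFrame(y, covariates, spec)
  if (nlevels(d$tmt_set) < 2L)
    stop("at least two TMT sets are required")
  .checkRank(d, spec)

  if (spec@batch == "fixed") {
    f <- stats::as.formula(paste("y ~", .fixedFormula(spec), "+ tmt_set"))
    fit <- stats::lm(f, data = d)
    co <- summary(fit)$coefficients["pa_code", ]
    return(list(beta = unname(co[1]), se = unname(co[2]),
                df = fit$df.residual,
                p = .fixDegenerateP(co[1], co[2], unname(co[4])),
                converged = TRUE, singular = FALSE))
  }

  f <- stats::as.formula(paste("y ~", .fixedFormula(spec), "+ (1 | tmt_set)"))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(f, data = d, REML = spec@reml))),
    error = function(e) NULL)
  ## a boundary (singular) fit is a valid REML solution (it coincides with
  ## ordinary least squares); only genuine optimizer failures trigger the
  ## fixed-effects fallback
  msgs <- if (!is.null(fit)) fit@optinfo$conv$lme4$messages else "fit error"
  conv_ok <- !is.null(fit) &&
    (is.null(msgs) || all(grepl("singular", msgs, fixed = TRUE)))
  if (!conv_ok) {
    ## fall back to the fixed-effects-only least-squares fit, flagged
    f0 <- stats::as.formula(paste("y ~", .fixedFormula(spec)))
    fit0 <- stats::lm(f0, data = d)
    co <- summary(fit0)$coefficients["pa_code", ]
    return(list(beta = unname(co[1]), se = unname(co[2]),
                df = fit0$df.residual,
                p = .fixDegenerateP(co[1], co[2], unname(co[4])),
                converged = FALSE, singular = FALSE))
  }
  co <- stats::coef(summary(fit, ddf = "Satterthwaite"))["pa_code", ]
  df_out <- unname(co["df"])
  p_out <- unname(co["Pr(>|t|)"])
  if (spec@df == "residual") {
    df_out <- nrow(d) - length(lme4::fixef(fit))
    tval <- unname(co["t value"])
    p_out <- 2 * stats::pt(abs(tval), df_out, lower.tail = FALSE)
  }
  list(beta = unname(co["Estimate"]), se = unname(co["Std. Error"]),
       df = df_out, p = .fixDegenerateP(co["Estimate"], co["Std. Error"], p_out),
       converged = TRUE, singular = lme4::isSingular(fit))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment (p * m / rank with running
#' minimum from the largest p down); ties are preserved.
#'
#' @param p_values numeric vector of p-values in \[0, 1\]; `NA`s allowed and
#'   propagated.
#' @return q-values in \[0, 1\].
#' @export
adjustBH <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Classify association direction
#'
#' A protein is called `"up"` (higher abundance with higher activity) if
#' its activity slope is positive and significant at `alpha`, `"down"` if
#' negative and significant, otherwise `"ns"`; a slope of exactly zero is
#' `"ns"` regardless of p.
#'
#' @param beta activity slope(s).
#' @param p raw p-value(s).
#' @param alpha significance level (default 0.05).
#' @return character vector in `c("up", "down", "ns")`.
#' @export
classifyDirection <- function(beta, p, alpha = 0.05) {
  out <- rep("ns", length(beta))
  sig <- !is.na(p) & !is.na(beta) & p < alpha
  out[sig & beta > 0] <- "up"
  out[sig & beta < 0] <- "down"
  out
}

#' Fit the activity model for every protein
#'
#' Sweeps [fitProteinMixedModel()] over the rows of the quant matrix,
#' aligning samples to the covariate table, then applies
#' Benjamini-Hochberg correction across all fitted proteins and calls
#' directions at `spec@alpha`. A failure for one protein is captured in its
#' row (NA estimates, `converged = FALSE`) and never aborts the sweep.
#'
#' @param x a loading-corrected [ProteinQuantMatrix-class].
#' @param covariates covariate table from [buildCovariates()].
#' @param spec a [ModelSpec-class].
#' @param verbose log progress every 100 proteins.
#' @return a [S4Vectors::DataFrame-class] with one row per protein:
#'   `accession`, `beta`, `se`, `df`, `p_value`, `q_value`, `direction`,
#'   `converged`.
#' @export
fitAllProteins <- function(x, covariates, spec = modelSpec(),
                           verbose = FALSE) {
  stopifnot(is(x, "ProteinQuantMatrix"))
  if (!all(covariates$sample_id %in% colnames(x)))
    stop("covariate rows do not match quant-matrix columns")
  m <- quantMatrix(x)[, covariates$sample_id, drop = FALSE]
  n <- nrow(m)
  beta <- se <- df <- p <- rep(NA_real_, n)
  converged <- rep(FALSE, n)
  for (i in seq_len(n)) {
    res <- tryCatch(fitProteinMixedModel(m[i, ], covariates, spec),
                    error = function(e) NULL)
    if (!is.null(res)) {
      beta[i] <- res$beta; se[i] <- res$se; df[i] <- res$df; p[i] <- res$p
      converged[i] <- res$converged
    }
    if (verbose && i %% 100L == 0L)
      message("fitted ", i, "/", n, " proteins")
  }
  q <- adjustBH(p)
  S4Vectors::DataFrame(
    accession = rownames(m), beta = beta, se = se, df = df,
    p_value = p, q_value = q,
    direction = classifyDirection(beta, p, spec@alpha),
    converged = converged, row.names = rownames(m))
}
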