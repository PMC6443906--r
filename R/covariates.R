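## Questionnaire scoring: weekly MVPA minutes, the 0-3 ordinal activity
## code, and the myosin fiber-type ratio covariate.

## Activity types collected by the questionnaire. The first six count toward
## moderate-to-vigorous physical activity (MVPA); casual walking is tabulated
## separately and never contributes.
ACTIVITY_TYPES <- c("brisk_walking", "weight_circuit",
                    paste0("vigorous_", 1:4), "casual_walking")
MVPA_TYPES <- ACTIVITY_TYPES[1:6]

#' Build an activity questionnaire record
#'
#' One row per activity: whether it was performed in the past two weeks, how
#' many sessions, and the average minutes per session.
#'
#' @param activity_type one of `"brisk_walking"`, `"weight_circuit"`,
#'   `"vigorous_1"` .. `"vigorous_4"`, `"casual_walking"`.
#' @param frequency sessions in the past two weeks.
#' @param duration average minutes per session.
#' @param performed logical; when `FALSE`, frequency and duration are ignored.
#' @return a one-row data.frame with columns `activity_type`, `performed`,
#'   `frequency`, `duration`.
#' @examples
#' activityRecord("vigorous_1", frequency = 6, duration = 40)
#' @export
activityRecord <- function(activity_type, frequency = 0, duration = 0,
                           performed = TRUE) {
  activity_type <- match.arg(activity_type, ACTIVITY_TYPES)
  if (frequency < 0 || duration < 0)
    stop("frequency and duration must be nonnegative")
  data.frame(activity_type = activity_type, performed = performed,
             frequency = frequency, duration = duration,
             stringsAsFactors = FALSE)
}

#' Weekly minutes of moderate-to-vigorous physical activity
#'
#' Scores questionnaire records by multiplying frequency by minutes per
#' session for each MVPA activity (brisk walking, weight/circuit training,
#' up to four vigorous activities), summing, and halving to convert the
#' two-week recall window to minutes per week. Casual walking is excluded.
#'
#' @param records data.frame of activity records (see [activityRecord()]);
#'   may be empty.
#' @return minutes per week of MVPA (numeric scalar).
#' @examples
#' r <- rbind(activityRecord("brisk_walking", 4, 30),
#'            activityRecord("weight_circuit", 2, 45))
#' computeMvpaMinutes(r)  # (120 + 90) / 2 = 105
#' @export
computeMvpaMinutes <- function(records) {
  if (is.null(records) || nrow(records) == 0L) return(0)
  stopifnot(all(c("activity_type", "performed", "frequency", "duration")
                %in% names(records)))
  if (any(records$frequency < 0, na.rm = TRUE) ||
      any(records$duration < 0, na.rm = TRUE))
    stop("negative frequency or duration in activity records")
  keep <- records$performed & records$activity_type %in% MVPA_TYPES
  sum(records$frequency[keep] * records$duration[keep]) / 2
}

#' Weekly minutes of casual walking
#'
#' Same frequency x duration / 2 scoring, restricted to casual walking.
#' @inheritParams computeMvpaMinutes
#' @return minutes per week (numeric scalar).
#' @export
computeCasualWalkingMinutes <- function(records) {
  if (is.null(records) || nrow(records) == 0L) return(0)
  keep <- records$performed & records$activity_type == "casual_walking"
  sum(records$frequency[keep] * records$duration[keep]) / 2
}

#' Ordinal physical-activity code
#'
#' Maps weekly MVPA minutes to the 0-3 ordinal code used as the exposure in
#' the per-protein models: `< 30` min/week is "not active" (0), `>= 30` and
#' `< 75` "moderately active" (1), `>= 75` and `< 150` "active" (2), and
#' `>= 150` "highly active" (3). Boundaries are inclusive on the lower edge.
#'
#' @param mvpa_minutes weekly MVPA minutes (vectorized, nonnegative).
#' @return integer code(s) in 0..3.
#' @examples
#' categorizeActivity(c(20, 30, 75, 150))  # 0 1 2 3
#' @export
categorizeActivity <- function(mvpa_minutes) {
  if (any(!is.finite(mvpa_minutes)) || any(mvpa_minutes < 0))
    stop("mvpa_minutes must be finite and nonnegative")
  findInterval(mvpa_minutes, c(30, 75, 150))
}

#' Myosin fiber-type ratio per sample
#'
#' Estimates the type I / type II fiber composition of each sample as the
#' abundance of MYH7 (type I myosin heavy chain) over the summed abundances
#' of MYH1, MYH2 and MYH4 (type II). Abundances in the quant matrix are log2
#' ratios, so by default they are returned to the linear scale (`2^x`)
#' before forming the ratio, which keeps it positive and stable; `scale =
#' "log2"` instead forms the ratio of the log2 values directly.
#'
#' @param x a [ProteinQuantMatrix-class] containing rows `MYH7`, `MYH1`,
#'   `MYH2`, `MYH4`.
#' @param scale `"linear"` (default) or `"log2"`.
#' @return data.frame with columns `sample_id`, `fiber_ratio`, and the four
#'   MYH log2 abundances.
#' @export
computeFiberRatio <- function(x, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is(x, "ProteinQuantMatrix"))
  myh <- c("MYH7", "MYH1", "MYH2", "MYH4")
  missing <- setdiff(myh, rownames(x))
  if (length(missing))
    stop("fiber-type ratio requires MYH7/MYH1/MYH2/MYH4; missing: ",
         paste(missing, collapse = ", "))
  m <- quantMatrix(x)[myh, , drop = FALSE]
  ratio <- if (scale == "linear") {
    2^m["MYH7", ] / (2^m["MYH1", ] + 2^m["MYH2", ] + 2^m["MYH4", ])
  } else {
    m["MYH7", ] / (m["MYH1", ] + m["MYH2", ] + m["MYH4", ])
  }
  data.frame(sample_id = colnames(m), fiber_ratio = as.numeric(ratio),
             MYH7 = m["MYH7", ], MYH1 = m["MYH1", ], MYH2 = m["MYH2", ],
             MYH4 = m["MYH4", ], row.names = NULL, stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## wide <-> long activity records in the sample table
## ---------------------------------------------------------------------------

## The sample metadata TSV carries the questionnaire as wide columns
## (<type>_performed / _freq / _dur). These helpers convert to and from the
## long record format the scoring functions use.

activityWideColumns <- function() {
  as.vector(t(outer(ACTIVITY_TYPES, c("_performed", "_freq", "_dur"),
                    paste0)))
}

recordsToWide <- function(records) {
  out <- as.list(setNames(rep(list(0), length(activityWideColumns())),
                          activityWideColumns()))
  for (t in ACTIVITY_TYPES) out[[paste0(t, "_performed")]] <- FALSE
  if (!is.null(records) && nrow(records)) {
    for (i in seq_len(nrow(records))) {
      t <- records$activity_type[i]
      out[[paste0(t, "_performed")]] <- records$performed[i]
      out[[paste0(t, "_freq")]] <- records$frequency[i]
      out[[paste0(t, "_dur")]] <- records$duration[i]
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Extract questionnaire records for one sample-table row
#'
#' @param sample_row a one-row data.frame from the sample metadata table
#'   with the wide activity columns (`<type>_performed`, `<type>_freq`,
#'   `<type>_dur`).
#' @return long-format records suitable for [computeMvpaMinutes()].
#' @export
sampleActivityRecords <- function(sample_row) {
  stopifnot(nrow(sample_row) == 1L)
  recs <- lapply(ACTIVITY_TYPES, function(t) {
    pcol <- paste0(t, "_performed")
    if (!pcol %in% names(sample_row) || !isTRUE(sample_row[[pcol]] == TRUE))
      return(NULL)
    activityRecord(t, frequency = sample_row[[paste0(t, "_freq")]],
                   duration = sample_row[[paste0(t, "_dur")]])
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs))
    return(data.frame(activity_type = character(), performed = logical(),
                      frequency = numeric(), duration = numeric()))
  do.call(rbind, recs)
}

#' Assemble the per-sample covariate table for modeling
#'
#' Scores each non-reference sample's questionnaire into weekly MVPA
#' minutes and the 0-3 code, computes the fiber-type ratio from the quant
#' matrix when available, and returns the covariate table consumed by
#' [fitAllProteins()].
#'
#' @param samples sample metadata table (one row per channel-in-set).
#' @param x optional [ProteinQuantMatrix-class] for the fiber-type ratio;
#'   when `NULL` the `fiber_ratio` column is `NA`.
#' @param fiber_scale passed to [computeFiberRatio()].
#' @return data.frame with columns `sample_id`, `donor_id`, `tmt_set`,
#'   `channel`, `age`, `sex`, `race`, `bmi`, `mvpa_minutes`,
#'   `casual_walking_minutes`, `pa_code`, `fiber_ratio`.
#' @export
buildCovariates <- function(samples, x = NULL,
                            fiber_scale = c("linear", "log2")) {
  fiber_scale <- match.arg(fiber_scale)
  stopifnot(all(c("sample_id", "tmt_set", "is_reference") %in% names(samples)))
  s <- samples[!samples$is_reference, , drop = FALSE]
  mvpa <- casual <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    recs <- sampleActivityRecords(s[i, , drop = FALSE])
    mvpa[i] <- computeMvpaMinutes(recs)
    casual[i] <- computeCasualWalkingMinutes(recs)
  }
  out <- data.frame(
    sample_id = s$sample_id, donor_id = s$donor_id, tmt_set = s$tmt_set,
    channel = s$channel, age = s$age, sex = s$sex, race = s$race,
    bmi = s$bmi, mvpa_minutes = mvpa, casual_walking_minutes = casual,
    pa_code = categorizeActivity(mvpa), fiber_ratio = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(x)) {
    fr <- computeFiberRatio(x, scale = fiber_scale)
    out$fiber_ratio <- fr$fiber_ratio[match(out$sample_id, fr$sample_id)]
  }
  out
}
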