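## Join per-protein results to an annotation table and count up/down
## regulated proteins per category (the figure-ready summary).

#' Summarize results by annotation category
#'
#' Counts quantified, significant, up- and down-regulated proteins per
#' category. Multi-label proteins increment every category they carry;
#' proteins absent from the annotation fall into `"other"`. Annotation
#' accessions that never appear in the results are reported via a message,
#' not an error.
#'
#' @param results per-protein result table from [fitAllProteins()] (needs
#'   columns `accession`, `p_value`, `direction`).
#' @param annotation annotation table from [readAnnotation()], or a
#'   data.frame with `accession` and list-column `categories`; may have
#'   zero rows.
#' @param alpha significance level for the counts (default 0.05, raw p).
#' @param multi_label `"each"` (default) counts a multi-label protein in
#'   every category it carries; `"first"` counts it only in its first
#'   listed category.
#' @return data.frame with one row per category: `category`,
#'   `n_quantified`, `n_significant`, `n_up`, `n_down`,
#'   `fraction_up_of_significant`.
#' @export
summarizeCategories <- function(results, annotation, alpha = 0.05,
                                multi_label = c("each", "first")) {
  multi_label <- match.arg(multi_label)
  results <- as.data.frame(results)
  stopifnot(all(c("accession", "p_value", "direction") %in% names(results)))
  if (is.null(annotation) || nrow(annotation) == 0L) {
    annotation <- data.frame(accession = character(),
                             stringsAsFactors = FALSE)
    annotation$categories <- list()
  }
  unseen <- setdiff(annotation$accession, results$accession)
  if (length(unseen))
    message(length(unseen), " annotated accession(s) absent from results (",
            paste(head(unseen, 5), collapse = ", "),
            if (length(unseen) > 5) ", ..." else "", ")")
  labels <- annotation$categories[match(results$accession,
                                        annotation$accession)]
  labels <- lapply(labels, function(v) if (is.null(v) || !length(v)) "other" else v)
  if (multi_label == "first") labels <- lapply(labels, `[`, 1L)
  cats <- sort(unique(unlist(labels)))
  sig <- !is.na(results$p_value) & results$p_value < alpha
  up <- sig & results$direction == "up"
  down <- sig & results$direction == "down"
  out <- do.call(rbind, lapply(cats, function(cat) {
    inCat <- vapply(labels, function(v) cat %in% v, logical(1))
    ns <- sum(sig & inCat)
    data.frame(category = cat,
               n_quantified = sum(inCat),
               n_significant = ns,
               n_up = sum(up & inCat),
               n_down = sum(down & inCat),
               fraction_up_of_significant = if (ns) sum(up & inCat) / ns
                                            else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
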