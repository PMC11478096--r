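#' Summarise a labeled classification run
#'
#' Aggregates either per-query classification records (from
#' [classify_set()], with expected labels) or a per-class count table in
#' the shape of `make_table_counts("labeled_testing")` into the headline
#' quantities of a labeled evaluation: overall agreement between
#' predicted and expected classes (percent, 1 decimal), the fraction of
#' queries whose length falls outside their class's reference length
#' range (integer percent), and per-region disagreement counts. Counts
#' are split by length region because annotation transfer is only
#' structurally safeguarded within the reference length range; the
#' interesting question is where the disagreements concentrate.
#'
#' @param x Classification record data frame or labeled count table.
#' @return List of class `"eba_summary"` with `mode = "labeled"`,
#'   `per_class` (the count table), `total`, `agreement_pct`,
#'   `outside_rlr_pct`, and `disagreements` (named vector: within, below,
#'   above).
#' @export
summarize_labeled <- function(x) {
  counts <- if (is_count_table(x)) x else records_to_counts(x)
  need <- c("exp_within", "pred_within", "exp_below", "pred_below",
            "exp_above", "pred_above")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("malformed labeled count table; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  exp_tot <- sum(counts$exp_within) + sum(counts$exp_below) +
    sum(counts$exp_above)
  pred_tot <- sum(counts$pred_within) + sum(counts$pred_below) +
    sum(counts$pred_above)
  if (exp_tot == 0L) stop("no expected counts to summarise", call. = FALSE)
  outside <- sum(counts$exp_below) + sum(counts$exp_above)
  structure(list(
    mode = "labeled",
    per_class = counts,
    total = exp_tot,
    agreement_pct = round(100 * pred_tot / exp_tot, 1),
    outside_rlr_pct = round(100 * outside / exp_tot),
    disagreements = c(
      within = sum(counts$exp_within) - sum(counts$pred_within),
      below = sum(counts$exp_below) - sum(counts$pred_below),
      above = sum(counts$exp_above) - sum(counts$pred_above))),
    class = "eba_summary")
}

#' Summarise an unlabeled classification run
#'
#' For classification of queries without expected labels, reports which
#' fraction of the total was assigned a class at a length compatible with
#' the predicted class's reference length range (`within_rlr_pct`) and
#' which fraction fell outside it (`outside_rlr_pct`), both as integer
#' percents. Accepts per-query records or a region-by-group count table
#' in the shape of `make_table_counts("unlabeled_trial")` (rows `within`,
#' `below`, `above` and optionally `total`; the `total` row sets the
#' denominator, accommodating runs where some queries end up unclassified).
#'
#' @param x Classification record data frame or region count table.
#' @return List of class `"eba_summary"` with `mode = "unlabeled"`,
#'   `region_counts` (named vector), `total`, `within_rlr_pct`,
#'   `outside_rlr_pct`.
#' @export
summarize_unlabeled <- function(x) {
  if (is.data.frame(x) && "region" %in% names(x) &&
      !"query_id" %in% names(x)) {
    num <- x[, setdiff(names(x), "region"), drop = FALSE]
    if (!nrow(x) || !ncol(num) || !all(vapply(num, is.numeric, logical(1))))
      stop("malformed region count table", call. = FALSE)
    rows <- rowSums(num)
    names(rows) <- x$region
    need <- c("within", "below", "above")
    if (!all(need %in% names(rows)))
      stop("malformed region count table; need rows within/below/above",
           call. = FALSE)
    counts <- rows[need]
    total <- if ("total" %in% names(rows)) unname(rows["total"])
             else sum(counts)
  } else if (is.data.frame(x) && "region" %in% names(x)) {
    counts <- c(within = sum(x$region == "within"),
                below = sum(x$region == "below"),
                above = sum(x$region == "above"))
    total <- nrow(x)
  } else stop("malformed input for unlabeled summary", call. = FALSE)
  if (total == 0) stop("no queries to summarise", call. = FALSE)
  structure(list(
    mode = "unlabeled",
    region_counts = counts,
    total = total,
    within_rlr_pct = round(100 * counts[["within"]] / total),
    outside_rlr_pct = round(100 * (counts[["below"]] + counts[["above"]]) / total)),
    class = "eba_summary")
}

is_count_table <- function(x) {
  is.data.frame(x) && all(c("exp_within", "pred_within") %in% names(x))
}

#' @export
print.eba_summary <- function(x, ...) {
  if (x$mode == "labeled") {
    cat("Labeled classification summary\n")
    cat(sprintf("  queries:            %d\n", x$total))
    cat(sprintf("  overall agreement:  %.1f%%\n", x$agreement_pct))
    cat(sprintf("  outside length range: %d%%\n", x$outside_rlr_pct))
    cat(sprintf("  disagreements (within/below/above): %d / %d / %d\n",
                x$disagreements[["within"]], x$disagreements[["below"]],
                x$disagreements[["above"]]))
  } else {
    cat("Unlabeled classification summary\n")
    cat(sprintf("  queries:             %d\n", round(x$total)))
    cat(sprintf("  within length range: %d%%\n", x$within_rlr_pct))
    cat(sprintf("  outside length range: %d%%\n", x$outside_rlr_pct))
  }
  invisible(x)
}
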