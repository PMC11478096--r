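#' Length-region triage against a class's reference length range
#'
#' Calls a query length `within` its predicted class's closed reference
#' length range, `below` it, or `above` it. Because every bait carries a
#' validated fold, only within-range queries can conserve the class's
#' structural template; outside the range annotation transfer still works
#' at the domain/motif level but fold conservation is not guaranteed.
#'
#' @param query_length Integer vector of query lengths.
#' @param predicted_class Character vector (recycled) of class labels.
#' @param rlr_map Data frame from [compute_rlr()].
#' @return Character vector of `"within"`, `"below"`, `"above"`.
#' @examples
#' rlr <- data.frame(class_label = "Mu", min_len = 211, max_len = 225)
#' triage_length(c(210, 211, 225, 226), "Mu", rlr)
#' @export
triage_length <- function(query_length, predicted_class, rlr_map) {
  n <- max(length(query_length), length(predicted_class))
  query_length <- rep_len(query_length, n)
  predicted_class <- rep_len(predicted_class, n)
  idx <- match(predicted_class, rlr_map$class_label)
  if (anyNA(idx))
    stop("class(es) absent from the length-range map: ",
         paste(unique(predicted_class[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  lo <- rlr_map$min_len[idx]
  hi <- rlr_map$max_len[idx]
  ifelse(query_length < lo, "below",
         ifelse(query_length > hi, "above", "within"))
}

#' Classify one query by nearest-bait annotation transfer
#'
#' Aligns the query embedding against every bait of the reference set,
#' scores each pair with `EBAmin`, and transfers the class of the
#' best-scoring bait. A bait whose id equals the query id is excluded
#' (self-hit); sequence-identical baits under different ids are
#' legitimate neighbours. Exact score ties are resolved by higher path
#' identity to the query, then by lexicographically smaller bait id.
#'
#' @param query List or one-row data frame with `id`, `sequence` and
#'   optionally `expected_class`.
#' @param query_embedding The query's l x D matrix (D must match the
#'   reference store).
#' @param refset A [reference_set()].
#' @param gap_open,gap_extend Gap penalties passed to [global_align()].
#' @param enhance Use signal enhancement (default) or negated raw
#'   distances.
#' @param rlr_map Precomputed [compute_rlr()] table (computed on the fly
#'   if omitted).
#' @return One-row data frame: `query_id`, `query_length`,
#'   `predicted_class`, `best_bait_id`, `eba_min`, `runner_up_class`,
#'   `margin` (best minus best-of-other-class `EBAmin`; `NA` with a
#'   single-class reference), `region`, `identity_pct` (path identity to
#'   the best bait), `expected_class`, `agree`, `region_expected` (triage
#'   against the expected class when its range is known).
#' @export
classify_query <- function(query, query_embedding, refset,
                           gap_open = -1.0, gap_extend = -0.1,
                           enhance = TRUE, rlr_map = NULL) {
  stopifnot(inherits(refset, "reference_set"))
  recs <- refset$records
  if (nrow(recs) == 0L) stop("empty reference set", call. = FALSE)
  if (ncol(query_embedding) != refset$store$dim)
    stop("query embedding dimension ", ncol(query_embedding),
         " does not match reference store dimension ", refset$store$dim,
         call. = FALSE)
  qid <- query$id
  keep <- recs$id != qid
  if (!any(keep))
    stop("no baits left after self-exclusion for ", qid, call. = FALSE)
  recs <- recs[keep, , drop = FALSE]

  n <- nrow(recs)
  scores <- numeric(n)
  alns <- vector("list", n)
  for (k in seq_len(n)) {
    aln <- align_pair(query_embedding, get_embedding(refset$store, recs$id[k]),
                      gap_open = gap_open, gap_extend = gap_extend,
                      enhance = enhance)
    scores[k] <- aln$eba_min
    alns[[k]] <- aln
  }
  best_score <- max(scores)
  cand <- which(scores == best_score)
  if (length(cand) > 1L) {
    idents <- vapply(cand, function(k)
      path_identity(alns[[k]]$path, query$sequence, recs$sequence[k]),
      numeric(1))
    cand <- cand[idents == max(idents)]
    if (length(cand) > 1L) cand <- cand[order(recs$id[cand])[1L]]
  }
  best <- cand[1L]
  pred <- recs$class_label[best]
  other <- recs$class_label != pred
  runner_score <- if (any(other)) max(scores[other]) else NA_real_
  runner_class <- if (any(other))
    recs$class_label[other][which.max(scores[other])] else NA_character_

  if (is.null(rlr_map)) rlr_map <- compute_rlr(refset)
  qlen <- nchar(query$sequence)
  expected <- if (!is.null(query$expected_class)) query$expected_class
              else NA_character_
  region_expected <- if (!is.na(expected) && expected %in% rlr_map$class_label)
    triage_length(qlen, expected, rlr_map) else NA_character_

  data.frame(
    query_id = qid,
    query_length = qlen,
    predicted_class = pred,
    best_bait_id = recs$id[best],
    eba_min = best_score,
    runner_up_class = runner_class,
    margin = if (is.na(runner_score)) NA_real_ else best_score - runner_score,
    region = triage_length(qlen, pred, rlr_map),
    identity_pct = path_identity(alns[[best]]$path, query$sequence,
                                 recs$sequence[best]),
    expected_class = expected,
    agree = if (is.na(expected)) NA else identical(pred, expected),
    region_expected = region_expected,
    stringsAsFactors = FALSE)
}

#' Classify a set of queries
#'
#' Runs [classify_query()] for every query, preserving input order.
#' Per-query failures do not abort the run: failing queries are dropped
#' from the output and collected (id + message) in the `"failures"`
#' attribute of the result.
#'
#' @param queries Data frame with columns `id`, `sequence`, optionally
#'   `expected_class`.
#' @param query_store [embedding_store()] holding the query embeddings.
#' @param refset A [reference_set()].
#' @inheritParams classify_query
#' @return Data frame of classification records (see [classify_query()]);
#'   attribute `failures` is a data frame of `id`, `error`.
#' @export
classify_set <- function(queries, query_store, refset,
                         gap_open = -1.0, gap_extend = -0.1, enhance = TRUE) {
  queries <- as.data.frame(queries)
  rlr_map <- compute_rlr(refset)
  out <- vector("list", nrow(queries))
  fails <- list()
  for (k in seq_len(nrow(queries))) {
    q <- queries[k, , drop = FALSE]
    res <- tryCatch({
      emb <- get_embedding(query_store, q$id)
      if (nrow(emb) != nchar(q$sequence))
        stop("embedding for ", q$id, " has ", nrow(emb),
             " rows but the sequence has ", nchar(q$sequence), " residues",
             call. = FALSE)
      classify_query(q, emb, refset, gap_open = gap_open,
                     gap_extend = gap_extend, enhance = enhance,
                     rlr_map = rlr_map)
    }, error = function(e)
      structure(conditionMessage(e), class = "classify_failure"))
    if (inherits(res, "classify_failure"))
      fails[[length(fails) + 1L]] <- data.frame(id = q$id,
                                                error = unclass(res))
    else out[[k]] <- res
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- classify_query_prototype()
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails)
    else data.frame(id = character(), error = character())
  out
}

classify_query_prototype <- function() {
  data.frame(query_id = character(), query_length = integer(),
             predicted_class = character(), best_bait_id = character(),
             eba_min = numeric(), runner_up_class = character(),
             margin = numeric(), region = character(),
             identity_pct = numeric(), expected_class = character(),
             agree = logical(), region_expected = character(),
             stringsAsFactors = FALSE)
}
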