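#' Pairwise percent sequence identity
#'
#' Standard alignment-based identity: the two raw amino-acid sequences are
#' globally aligned (Needleman-Wunsch, BLOSUM62 substitution scores,
#' affine gap opening -11 / extension -1) and identity is the percentage
#' of aligned residue pairs (gaps excluded) that match. Scoring scheme and
#' gap penalties are configurable; the convention in use is recorded in
#' redundancy-filter reports.
#'
#' @param seq1,seq2 Non-empty amino-acid strings.
#' @param substitution_matrix Name of a substitution matrix shipped with
#'   Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Positive penalties as Biostrings expects.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' sequence_identity("ACDEFG", "ACDEYG")  # 83.3
#' @export
sequence_identity <- function(seq1, seq2, substitution_matrix = "BLOSUM62",
                              gap_open = 11, gap_extend = 1) {
  if (!nzchar(seq1) || !nzchar(seq2))
    stop("cannot compute identity of an empty sequence", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq1), Biostrings::AAString(seq2),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  if (nm + nmm == 0L) return(0)
  100 * nm / (nm + nmm)
}

#' Remove queries redundant with the reference set
#'
#' Drops every query whose maximum percent identity to any bait is
#' strictly greater than `threshold` (default 95): queries at exactly the
#' threshold are retained. Keeping near-duplicates of the reference would
#' make any evaluation of annotation transfer trivially easy, so they are
#' filtered before testing.
#'
#' @param queries Data frame with columns `id` and `sequence`.
#' @param refset A [reference_set()].
#' @param threshold Percent identity cutoff in `(0, 100]`.
#' @param identity_fn Pairwise identity function; defaults to
#'   [sequence_identity()].
#' @return List with `retained` (the surviving subset of `queries`) and
#'   `report`, a list of class `"filter_report"`: `input_count`,
#'   `retained_count`, `removed` (data frame `id`, `max_identity`,
#'   `nearest_bait`, `reason`), `threshold`, `identity_method`.
#' @export
redundancy_filter <- function(queries, refset, threshold = 95,
                              identity_fn = sequence_identity) {
  if (threshold <= 0 || threshold > 100)
    stop("threshold must be in (0, 100]", call. = FALSE)
  queries <- as.data.frame(queries)
  baits <- refset$records
  n <- nrow(queries)
  removed <- list()
  keep <- logical(n)
  for (k in seq_len(n)) {
    ids <- vapply(baits$sequence, identity_fn, numeric(1),
                  seq1 = queries$sequence[k])
    top <- which.max(ids)
    if (ids[top] > threshold) {
      removed[[length(removed) + 1L]] <- data.frame(
        id = queries$id[k],
        max_identity = ids[top],
        nearest_bait = baits$id[top],
        reason = sprintf("identity %.1f%% to %s exceeds %s%%",
                         ids[top], baits$id[top], threshold))
    } else keep[k] <- TRUE
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(id = character(), max_identity = numeric(),
               nearest_bait = character(), reason = character())
  rownames(removed) <- NULL
  report <- structure(list(
    input_count = n,
    retained_count = sum(keep),
    removed = removed,
    threshold = threshold,
    identity_method = "global alignment, matches / aligned pairs (gaps excluded)"),
    class = "filter_report")
  stopifnot(report$retained_count + nrow(removed) == n)
  list(retained = queries[keep, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("redundancy filter: %d in, %d retained, %d removed (> %s%% to reference)\n",
              x$input_count, x$retained_count, nrow(x$removed), x$threshold))
  cat("identity: ", x$identity_method, "\n", sep = "")
  invisible(x)
}
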