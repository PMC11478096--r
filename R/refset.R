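#' Construct a labeled reference set of baits
#'
#' A reference set couples curated protein records (id, sequence, class
#' label, optional taxon) with their per-residue embeddings. Each labeled
#' reference protein acts as a "bait": queries are aligned against every
#' bait and take the class of the best-scoring one.
#'
#' @param records Data frame with columns `id`, `sequence`, `class_label`
#'   and optionally `taxon`. Ids must be unique and non-empty; class
#'   labels non-empty; a `length` column is derived from the sequences.
#' @param store An [embedding_store()] holding one matrix per record id,
#'   with row counts equal to the sequence lengths.
#' @return An object of class `"reference_set"`.
#' @export
reference_set <- function(records, store) {
  records <- as.data.frame(records)
  need <- c("id", "sequence", "class_label")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  if (any(!nzchar(records$id)) || anyDuplicated(records$id))
    stop("record ids must be unique and non-empty", call. = FALSE)
  if (any(is.na(records$class_label) | !nzchar(records$class_label)))
    stop("every bait needs a non-empty class label", call. = FALSE)
  records$length <- nchar(records$sequence)
  if (any(records$length < 1L)) stop("empty sequence in records", call. = FALSE)
  if (is.null(records$taxon)) records$taxon <- NA_character_
  for (k in seq_len(nrow(records))) {
    id <- records$id[k]
    if (!id %in% store_ids(store))
      stop("missing embedding for bait ", id, call. = FALSE)
    nr <- nrow(get_embedding(store, id))
    if (nr != records$length[k])
      stop("embedding/sequence length mismatch for ", id, ": embedding has ",
           nr, " rows, sequence has ", records$length[k], " residues",
           call. = FALSE)
  }
  rownames(records) <- NULL
  structure(list(records = records, store = store), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d bait(s) in %d class(es), D = %s\n",
              nrow(x$records), length(unique(x$records$class_label)),
              x$store$dim))
  invisible(x)
}

#' Load a reference set from FASTA + labels TSV + embedding store
#'
#' @param fasta_path FASTA file of bait sequences.
#' @param labels_path Tab-separated labels table with a header row and
#'   columns `id`, `class` and optionally `taxon`. Every FASTA id must
#'   appear in the table; class names are free strings compared
#'   case-sensitively.
#' @param embedding_store An [embedding_store()] or the path of a store
#'   written by [write_embedding_store()].
#' @return A [reference_set()].
#' @export
load_reference_set <- function(fasta_path, labels_path, embedding_store) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("no records in ", fasta_path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  labels <- read.delim(labels_path, colClasses = "character")
  if (!all(c("id", "class") %in% names(labels)))
    stop("labels table needs columns 'id' and 'class'", call. = FALSE)
  unlabeled <- setdiff(ids, labels$id)
  if (length(unlabeled))
    stop("no class label for id(s): ", paste(unlabeled, collapse = ", "),
         call. = FALSE)
  lab <- labels[match(ids, labels$id), , drop = FALSE]
  if (is.character(embedding_store))
    embedding_store <- read_embedding_store(embedding_store)
  reference_set(
    data.frame(id = ids,
               sequence = as.character(seqs),
               class_label = lab$class,
               taxon = if ("taxon" %in% names(lab)) lab$taxon else NA_character_),
    embedding_store)
}

#' Per-class reference length ranges (RLR)
#'
#' For each class, the closed interval from the shortest to the longest
#' bait sequence. Because all baits carry an experimentally grounded fold,
#' a query whose length falls inside its predicted class's range can
#' plausibly conserve the class's structural template; queries below or
#' above it cannot, which is the basis of the length triage.
#'
#' @param refset A [reference_set()].
#' @return Data frame with columns `class_label`, `min_len`, `max_len`,
#'   one row per class, ordered by class label.
#' @export
compute_rlr <- function(refset) {
  stopifnot(inherits(refset, "reference_set"))
  r <- refset$records
  agg <- aggregate(r$length, by = list(class_label = r$class_label),
                   FUN = function(v) c(min = min(v), max = max(v)))
  out <- data.frame(class_label = agg$class_label,
                    min_len = agg$x[, "min"], max_len = agg$x[, "max"])
  out <- out[order(out$class_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Within-class sequence identity range
#'
#' Minimum and maximum pairwise percent identity over all bait pairs of
#' one class, mirroring the per-class identity spread reported for
#' curated reference sets (classes spanning below ~30% contain remote
#' homologs).
#'
#' @param refset A [reference_set()].
#' @param class_label Class to evaluate (needs at least two baits).
#' @param identity_fn Pairwise identity function taking two sequences and
#'   returning a percentage; defaults to [sequence_identity()].
#' @return Named numeric vector `c(min, max)`.
#' @export
class_identity_range <- function(refset, class_label,
                                 identity_fn = sequence_identity) {
  stopifnot(inherits(refset, "reference_set"))
  seqs <- refset$records$sequence[refset$records$class_label == class_label]
  if (length(seqs) < 2L)
    stop("class ", class_label, " has fewer than 2 baits; ",
         "identity range undefined", call. = FALSE)
  pairs <- combn(length(seqs), 2L)
  ids <- apply(pairs, 2L, function(p) identity_fn(seqs[p[1L]], seqs[p[2L]]))
  c(min = min(ids), max = max(ids))
}
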