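#' In-memory per-residue embedding store
#'
#' A store holds one l x D float matrix per protein id, a model tag
#' identifying how the embeddings were produced (language model name and
#' layer, or `"synthetic"`), and the common embedding dimension D. All
#' matrices in one store must share D and contain only finite values.
#'
#' @param matrices Named list of numeric matrices (one row per residue).
#' @param model_tag Free-text provenance tag.
#' @return An object of class `"embedding_store"`.
#' @export
embedding_store <- function(matrices = list(), model_tag = "unspecified") {
  if (length(matrices)) {
    ids <- names(matrices)
    if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
      stop("matrices must be uniquely named by protein id", call. = FALSE)
    matrices <- lapply(matrices, as.matrix)
    dims <- vapply(matrices, ncol, integer(1))
    if (length(unique(dims)) > 1L)
      stop("mixed embedding dimensions in one store: ",
           paste(unique(dims), collapse = ", "), call. = FALSE)
    ok <- vapply(matrices, function(m) all(is.finite(m)), logical(1))
    if (!all(ok))
      stop("non-finite embedding values for id(s): ",
           paste(ids[!ok], collapse = ", "), call. = FALSE)
  }
  structure(list(matrices = matrices, model_tag = model_tag,
                 dim = if (length(matrices)) ncol(matrices[[1L]]) else NA_integer_),
            class = "embedding_store")
}

#' @export
print.embedding_store <- function(x, ...) {
  cat(sprintf("embedding_store: %d protein(s), D = %s, model = %s\n",
              length(x$matrices), x$dim, x$model_tag))
  invisible(x)
}

#' @rdname embedding_store
#' @param store An `embedding_store`.
#' @export
store_ids <- function(store) names(store$matrices)

#' @rdname embedding_store
#' @param id Protein identifier.
#' @export
get_embedding <- function(store, id) {
  m <- store$matrices[[id]]
  if (is.null(m))
    stop("no embedding stored for id(s): ", id, call. = FALSE)
  m
}

#' @rdname embedding_store
#' @param new Named list of matrices to add; ids must be new to the store
#'   and dimensions must match the store's D.
#' @export
add_embeddings <- function(store, new) {
  if (any(names(new) %in% store_ids(store)))
    stop("duplicate ids on add", call. = FALSE)
  merged <- embedding_store(c(store$matrices, lapply(new, as.matrix)),
                            model_tag = store$model_tag)
  if (!is.na(store$dim) && merged$dim != store$dim)
    stop("mixed embedding dimensions in one store: ", store$dim, " vs ",
         merged$dim, call. = FALSE)
  merged
}

#' Write / read an embedding store on disk
#'
#' The on-disk container is a single serialised file holding the named
#' matrices plus `model_tag` and `dim`; round trips are bit-exact. For
#' small plain-text fixtures see [export_embeddings_tsv()].
#'
#' @param store An `embedding_store`.
#' @param path File path.
#' @param ids Optional subset of ids to load; by default all. Requesting
#'   an absent id is an error listing the missing ids.
#' @return `read_embedding_store()` returns an `embedding_store`;
#'   `write_embedding_store()` returns `path` invisibly.
#' @export
write_embedding_store <- function(store, path) {
  stopifnot(inherits(store, "embedding_store"))
  saveRDS(list(matrices = store$matrices, model_tag = store$model_tag,
               dim = store$dim), path)
  invisible(path)
}

#' @rdname write_embedding_store
#' @export
read_embedding_store <- function(path, ids = NULL) {
  raw <- readRDS(path)
  if (!is.null(ids)) {
    absent <- setdiff(ids, names(raw$matrices))
    if (length(absent))
      stop("no embedding stored for id(s): ", paste(absent, collapse = ", "),
           call. = FALSE)
    raw$matrices <- raw$matrices[ids]
  }
  embedding_store(raw$matrices, model_tag = raw$model_tag)
}

#' Plain-text embedding exchange (one TSV per protein)
#'
#' Writes each matrix as a tab-separated file (one row per residue) plus a
#' `manifest.tsv` recording id, length, dimension and the store's model
#' tag. Values are printed with 17 significant digits so doubles survive
#' the round trip. Intended for small, reviewable fixtures.
#'
#' @param store An `embedding_store`.
#' @param dir Directory to create/populate.
#' @return `import_embeddings_tsv()` returns an `embedding_store`.
#' @export
export_embeddings_tsv <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- store_ids(store)
  for (id in ids) {
    write.table(format(store$matrices[[id]], digits = 17, scientific = TRUE,
                       trim = TRUE),
                file.path(dir, paste0(id, ".tsv")),
                sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  }
  manifest <- data.frame(
    id = ids,
    length = vapply(store$matrices, nrow, integer(1)),
    dim = store$dim,
    model_tag = store$model_tag)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname export_embeddings_tsv
#' @export
import_embeddings_tsv <- function(dir) {
  manifest <- read.delim(file.path(dir, "manifest.tsv"))
  mats <- lapply(manifest$id, function(id) {
    as.matrix(read.delim(file.path(dir, paste0(id, ".tsv")), header = FALSE))
  })
  mats <- lapply(mats, function(m) { dimnames(m) <- NULL; m })
  names(mats) <- manifest$id
  embedding_store(mats, model_tag = manifest$model_tag[1L])
}

#' Obtain the per-residue embedding of a sequence
#'
#' Uniform entry point over embedding backends. The `"precomputed"`
#' backend looks the id up in a store (the normal production path: run the
#' language model elsewhere, store the matrices, classify here). The
#' `"synthetic"` backend draws a seeded random matrix, useful for
#' plumbing tests where embedding geometry does not matter; class-aware
#' synthetic data comes from [generate_synthetic()] instead. An adapter
#' invoking a real protein language model can be registered behind the
#' same contract but is never required.
#'
#' @param sequence Amino-acid string (length >= 1).
#' @param backend `"precomputed"` or `"synthetic"`.
#' @param store Embedding store (required for `"precomputed"`).
#' @param id Protein id to look up in the store.
#' @param dim Embedding dimension for the synthetic backend.
#' @param seed Integer seed making the synthetic backend deterministic.
#' @return An l x D numeric matrix, l = `nchar(sequence)`.
#' @export
embed_sequence <- function(sequence, backend = c("precomputed", "synthetic"),
                           store = NULL, id = NULL, dim = 32L, seed = 1L) {
  backend <- match.arg(backend)
  l <- nchar(sequence)
  if (l < 1L) stop("cannot embed a length-0 sequence", call. = FALSE)
  if (backend == "precomputed") {
    if (is.null(store) || is.null(id))
      stop("precomputed backend needs a store and an id", call. = FALSE)
    m <- get_embedding(store, id)
    if (nrow(m) != l)
      stop("stored embedding for ", id, " has ", nrow(m),
           " rows but the sequence has ", l, " residues", call. = FALSE)
    return(m)
  }
  with_seed(seed, matrix(rnorm(l * dim), nrow = l, ncol = dim))
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
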