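#' Curated GST reference-set metadata
#'
#' Per-class metadata of the 284-protein, 20-class Glutathione
#' S-transferase (GST) reference set: per-taxon bait counts and the
#' shortest/longest bait length of each class. Delta and Epsilon are one
#' merged "Delta-Epsilon" class and Rho is its own class. Cytosolic,
#' mitochondrial (Kappa) and microsomal (MAPEG) classes are all present.
#'
#' @return Data frame with one row per class: `class`, twelve taxon count
#'   columns, `total`, `min_len`, `max_len`.
#' @export
gst_class_table <- function() {
  read.delim(system.file("extdata", "gst_refset_classes.tsv",
                         package = "embalign"))
}

#' Synthetic stand-in for the GST reference set
#'
#' Builds a [reference_set()] whose class structure, per-taxon bait
#' counts and per-class length ranges follow [gst_class_table()] exactly
#' (bait lengths are spread over each class range with the endpoints
#' always attained, so derived length ranges reproduce the metadata), but
#' whose sequences and embeddings are synthetic: real bait sequences and
#' language-model embeddings can be supplied by the user through
#' [load_reference_set()] using the same structure. With the default
#' metadata this yields 284 baits in 20 classes.
#'
#' @param dim Embedding dimension of the synthetic store.
#' @param seed Integer seed.
#' @param class_table Metadata table, by default [gst_class_table()].
#' @return A [reference_set()].
#' @export
gst_reference_fixture <- function(dim = 16L, seed = 42L,
                                  class_table = gst_class_table()) {
  taxa <- setdiff(names(class_table), c("class", "total", "min_len", "max_len"))
  with_seed(seed, {
    K <- nrow(class_table)
    centroids <- draw_centroids(K, dim, sep = 6)
    drifts <- lapply(seq_len(K), function(k) draw_drift(dim, amp = 0.75))
    rec <- list(); mat <- list()
    for (k in seq_len(K)) {
      cl <- class_table$class[k]
      n <- class_table$total[k]
      taxon_of <- rep(taxa, times = as.integer(class_table[k, taxa]))
      stopifnot(length(taxon_of) == n)
      lens <- if (n == 1L) class_table$min_len[k] else
        round(seq(class_table$min_len[k], class_table$max_len[k],
                  length.out = n))
      profile <- rgamma(20L, shape = 2); profile <- profile / sum(profile)
      for (b in seq_len(n)) {
        id <- sprintf("GST_%s_%03d", gsub("[^A-Za-z0-9]", "", cl), b)
        rec[[id]] <- data.frame(id = id,
                                sequence = synth_sequence(lens[b], profile),
                                class_label = cl, taxon = taxon_of[b])
        mat[[id]] <- synth_embedding(lens[b], centroids[k, ], sigma = 0.75,
                                     drift = drifts[[k]])
      }
    }
    reference_set(do.call(rbind, rec),
                  embedding_store(mat, model_tag = "synthetic"))
  })
}

#' Write a reference set to FASTA + labels TSV + embedding store
#'
#' Companion of [load_reference_set()]; mainly useful for exporting
#' fixtures and for the command-line interface.
#'
#' @param refset A [reference_set()].
#' @param fasta_path,labels_path,store_path Output file paths.
#' @return Invisibly, a named vector of the three paths.
#' @export
write_reference_set <- function(refset, fasta_path, labels_path, store_path) {
  stopifnot(inherits(refset, "reference_set"))
  seqs <- Biostrings::AAStringSet(setNames(refset$records$sequence,
                                           refset$records$id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  labels <- data.frame(id = refset$records$id,
                       class = refset$records$class_label,
                       taxon = refset$records$taxon)
  write.table(labels, labels_path, sep = "\t", row.names = FALSE, quote = FALSE)
  write_embedding_store(refset$store, store_path)
  invisible(c(fasta = fasta_path, labels = labels_path, store = store_path))
}
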