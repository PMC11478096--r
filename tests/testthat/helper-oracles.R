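# Independent oracles and small generators shared across tests.

# Exhaustive global-alignment oracle: enumerates every alignment path
# (move sequences over diagonal / up / left) and returns the maximum total
# score. Gap runs cost open + (k-1)*extend; switching gap sides re-opens.
# Feasible for matrices up to about 5x5.
oracle_align_score <- function(S, gap_open, gap_extend) {
  n <- nrow(S); m <- ncol(S)
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i == n && j == m) {
      if (score > best) best <<- score
      return(invisible(NULL))
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, score + S[i + 1L, j + 1L], "D")
    if (i < n) rec(i + 1L, j,
                   score + if (identical(last, "U")) gap_extend else gap_open,
                   "U")
    if (j < m) rec(i, j + 1L,
                   score + if (identical(last, "L")) gap_extend else gap_open,
                   "L")
  }
  rec(0L, 0L, 0, "start")
  best
}

# Brute-force Euclidean distances, element by element.
oracle_distance_matrix <- function(e1, e2) {
  d <- matrix(0, nrow(e1), nrow(e2))
  for (i in seq_len(nrow(e1)))
    for (j in seq_len(nrow(e2)))
      d[i, j] <- sqrt(sum((e1[i, ] - e2[j, ])^2))
  d
}

random_aa <- function(l) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               l, replace = TRUE), collapse = "")
}

# Tiny labeled reference set with distinct per-class embeddings, for
# plumbing tests where generator realism does not matter.
tiny_refset <- function(n_classes = 3L, dim = 8L, len = 12L, seed = 11L) {
  withr::with_seed(seed, {
    mats <- list(); rec <- list()
    for (k in seq_len(n_classes)) {
      centroid <- rnorm(dim, mean = 4 * k)
      # class-level positional wave: within-class pairs share structure
      # that survives the background normalisation
      u <- rnorm(dim); u <- u / sqrt(sum(u^2))
      wave <- sin(2 * pi * seq_len(len) / len + k)
      for (b in 1:2) {
        id <- sprintf("ref%d_%d", k, b)
        mats[[id]] <- matrix(centroid, len, dim, byrow = TRUE) +
          outer(wave, u) +
          matrix(rnorm(len * dim, sd = 0.1), len)
        rec[[id]] <- data.frame(id = id, sequence = random_aa(len),
                                class_label = paste0("C", k),
                                taxon = NA_character_)
      }
    }
    reference_set(do.call(rbind, rec),
                  embedding_store(mats, model_tag = "synthetic"))
  })
}
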