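AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Configuration of the class-structured synthetic generator
#'
#' The generator emulates the geometry that makes embedding-based
#' classification work: each class has a centroid vector in embedding
#' space, every residue embedding of a protein is its class centroid plus
#' a smooth low-frequency positional drift (so residues are not i.i.d.,
#' mimicking contextual embeddings) plus independent Gaussian noise.
#' Sequences are drawn from class-specific residue frequency profiles and
#' bait lengths uniformly from each class's configured range, so derived
#' reference length ranges (RLR) and length triage are exercised
#' end to end.
#'
#' @param n_classes Number of classes K (>= 2).
#' @param dim Embedding dimension D.
#' @param class_length_ranges List of `c(min, max)` protein lengths, one
#'   per class; `NULL` picks K disjoint ranges of width 15 starting at 60
#'   residues, spaced 30 apart.
#' @param centroid_separation Minimum pairwise Euclidean distance Delta
#'   between class centroids. The default 6 puts enhanced match scores on
#'   the order of 1, commensurate with the default gap penalties.
#' @param residue_noise_sd Per-coordinate noise standard deviation sigma;
#'   defaults to Delta/8.
#' @param n_baits_per_class,n_queries_per_class Set sizes per class.
#' @param region_mix Proportions (summing to 1) of query lengths drawn
#'   within, below and above the class length range.
#' @param seed Integer seed; the whole generation is reproducible from it.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_classes = 5L, dim = 32L,
                             class_length_ranges = NULL,
                             centroid_separation = 6,
                             residue_noise_sd = centroid_separation / 8,
                             n_baits_per_class = 20L,
                             n_queries_per_class = 20L,
                             region_mix = c(within = 0.6, below = 0.2, above = 0.2),
                             seed = 1L) {
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  if (centroid_separation <= 0) stop("centroid_separation must be > 0", call. = FALSE)
  if (residue_noise_sd < 0) stop("residue_noise_sd must be >= 0", call. = FALSE)
  if (is.null(class_length_ranges))
    class_length_ranges <- lapply(seq_len(n_classes) - 1L,
                                  function(k) c(60L + 30L * k, 75L + 30L * k))
  if (length(class_length_ranges) != n_classes)
    stop("need one length range per class", call. = FALSE)
  region_mix <- region_mix / sum(region_mix)
  if (length(region_mix) != 3L)
    stop("region_mix must give within/below/above proportions", call. = FALSE)
  names(region_mix) <- c("within", "below", "above")
  mins <- vapply(class_length_ranges, `[`, numeric(1), 1L)
  if (region_mix["below"] > 0 && any(mins <= 1))
    stop("below-range queries requested but a class minimum length is 1",
         call. = FALSE)
  structure(list(n_classes = as.integer(n_classes), dim = as.integer(dim),
                 class_length_ranges = class_length_ranges,
                 centroid_separation = centroid_separation,
                 residue_noise_sd = residue_noise_sd,
                 n_baits_per_class = as.integer(n_baits_per_class),
                 n_queries_per_class = as.integer(n_queries_per_class),
                 region_mix = region_mix, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Class centroids with enforced minimum pairwise separation: a standard
# Gaussian draw rescaled so the closest pair sits exactly at `sep`.
draw_centroids <- function(k, dim, sep) {
  C <- matrix(rnorm(k * dim), nrow = k)
  dmin <- min(dist(C))
  C * (sep / dmin)
}

# A class's positional drift field: a low-frequency sinusoid along a fixed
# direction, evaluated at relative sequence position. Members of one class
# share the field, so their per-residue embeddings carry a common positional
# structure (as contextual embeddings of homologs do) that the alignment can
# recover; background normalisation removes any constant offset, so this
# within-pair contrast is what carries the class signal.
draw_drift <- function(dim, amp) {
  u <- rnorm(dim)
  list(u = u / sqrt(sum(u^2)), freq = sample(1:3, 1L),
       phase = runif(1L, 0, 2 * pi), amp = amp)
}

# One protein's embedding: class centroid + the class drift field stretched
# over the protein's length + i.i.d. Gaussian noise.
synth_embedding <- function(l, centroid, sigma, drift = NULL) {
  dim <- length(centroid)
  m <- matrix(centroid, nrow = l, ncol = dim, byrow = TRUE)
  if (!is.null(drift)) {
    wave <- drift$amp * sin(2 * pi * drift$freq * seq_len(l) / l + drift$phase)
    m <- m + outer(wave, drift$u)
  }
  if (sigma > 0) m <- m + matrix(rnorm(l * dim, sd = sigma), nrow = l)
  m
}

synth_sequence <- function(l, profile) {
  paste(sample(AA20, l, replace = TRUE, prob = profile), collapse = "")
}

#' Generate a synthetic reference set and query set
#'
#' Draws class centroids, bait proteins (uniform lengths inside each class
#' range) and query proteins whose lengths follow `region_mix`: below- and
#' above-range queries fall up to 25 residues outside the class range.
#' Every protein gets a sequence from its class's residue profile and an
#' embedding around its class centroid. The result is fully reproducible
#' from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `refset` (a [reference_set()]), `queries`
#'   (data frame: `id`, `sequence`, `length`, `expected_class`) and
#'   `query_store` (an [embedding_store()]).
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    K <- config$n_classes
    classes <- sprintf("class%02d", seq_len(K))
    centroids <- draw_centroids(K, config$dim, config$centroid_separation)
    drifts <- lapply(seq_len(K), function(k)
      draw_drift(config$dim, amp = config$centroid_separation / 8))
    profiles <- lapply(seq_len(K), function(k) {
      p <- rgamma(20L, shape = 2)
      p / sum(p)
    })

    bait_rec <- list(); bait_mat <- list()
    qry_rec <- list(); qry_mat <- list()
    for (k in seq_len(K)) {
      rng <- config$class_length_ranges[[k]]
      for (b in seq_len(config$n_baits_per_class)) {
        l <- sample(rng[1L]:rng[2L], 1L)
        id <- sprintf("B_%s_%03d", classes[k], b)
        bait_rec[[id]] <- data.frame(id = id,
                                     sequence = synth_sequence(l, profiles[[k]]),
                                     class_label = classes[k],
                                     taxon = NA_character_)
        bait_mat[[id]] <- synth_embedding(l, centroids[k, ],
                                          config$residue_noise_sd,
                                          drift = drifts[[k]])
      }
      nq <- config$n_queries_per_class
      regions <- sample(c("within", "below", "above"), nq, replace = TRUE,
                        prob = config$region_mix)
      for (q in seq_len(nq)) {
        l <- switch(regions[q],
          within = sample(rng[1L]:rng[2L], 1L),
          below  = sample(max(5L, rng[1L] - 25L):(rng[1L] - 1L), 1L),
          above  = sample((rng[2L] + 1L):(rng[2L] + 25L), 1L))
        id <- sprintf("Q_%s_%03d", classes[k], q)
        qry_rec[[id]] <- data.frame(id = id,
                                    sequence = synth_sequence(l, profiles[[k]]),
                                    length = l,
                                    expected_class = classes[k])
        qry_mat[[id]] <- synth_embedding(l, centroids[k, ],
                                         config$residue_noise_sd,
                                         drift = drifts[[k]])
      }
    }
    refset <- reference_set(do.call(rbind, bait_rec),
                            embedding_store(bait_mat, model_tag = "synthetic"))
    list(refset = refset,
         queries = `rownames<-`(do.call(rbind, qry_rec), NULL),
         query_store = embedding_store(qry_mat, model_tag = "synthetic"))
  })
}

#' Count tables for the reporting module
#'
#' Returns count tables in the two shapes the summary arithmetic
#' consumes. `"labeled_testing"` is the per-class table of a labeled
#' evaluation (expected vs agreeing predictions, split by length region);
#' the packaged fixture carries the published 15,061-protein GST testing
#' comparison against the ARBA annotation. `"unlabeled_trial"` is the
#' region-by-taxon table of an unlabeled classification run; the packaged
#' fixture carries the published 64,207-protein trial set. `"synthetic"`
#' tabulates a data frame of classification records produced by
#' [classify_set()].
#'
#' @param scenario One of `"labeled_testing"`, `"unlabeled_trial"`,
#'   `"synthetic"`.
#' @param records For `"synthetic"`: a classification record data frame.
#' @return A data frame in the corresponding shape.
#' @export
make_table_counts <- function(scenario = c("labeled_testing",
                                           "unlabeled_trial", "synthetic"),
                              records = NULL) {
  scenario <- match.arg(scenario)
  if (scenario == "labeled_testing")
    return(read.delim(system.file("extdata", "labeled_testing_counts.tsv",
                                  package = "embalign")))
  if (scenario == "unlabeled_trial")
    return(read.delim(system.file("extdata", "unlabeled_trial_counts.tsv",
                                  package = "embalign")))
  if (is.null(records))
    stop("scenario 'synthetic' needs classification records", call. = FALSE)
  records_to_counts(records)
}

# Collapse per-query classification records into the labeled per-class
# count-table shape. Triage keys on the expected class's length range when
# available (region_expected), falling back to the predicted-class region.
records_to_counts <- function(records) {
  reg <- if (!is.null(records$region_expected) &&
             !all(is.na(records$region_expected)))
    records$region_expected else records$region
  cls <- if (!is.null(records$expected_class) &&
             !all(is.na(records$expected_class)))
    records$expected_class else records$predicted_class
  agree <- if (!is.null(records$agree)) records$agree else
    rep(TRUE, nrow(records))
  out <- lapply(sort(unique(cls)), function(cl) {
    sel <- cls == cl
    row <- data.frame(class = cl, total = sum(sel))
    for (r in c("within", "below", "above")) {
      s <- sel & reg == r
      row[[paste0("exp_", r)]] <- sum(s)
      row[[paste0("pred_", r)]] <- sum(s & agree)
      if (r != "within") row[[paste0("err_", r)]] <- sum(s & !agree)
    }
    row
  })
  out <- do.call(rbind, out)
  out[, c("class", "total", "exp_within", "pred_within", "exp_below",
          "pred_below", "err_below", "exp_above", "pred_above", "err_above")]
}
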