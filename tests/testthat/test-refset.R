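test_that("GST fixture loads 284 baits in 20 classes and reproduces the published length ranges", {
  tab <- gst_class_table()
  expect_equal(nrow(tab), 20)
  expect_equal(sum(tab$total), 284)

  rs <- gst_reference_fixture()
  expect_equal(nrow(rs$records), 284)
  expect_equal(length(unique(rs$records$class_label)), 20)

  rlr <- compute_rlr(rs)
  m <- merge(tab, rlr, by.x = "class", by.y = "class_label")
  expect_equal(nrow(m), 20)
  expect_equal(m$min_len.y, m$min_len.x)
  expect_equal(m$max_len.y, m$max_len.x)
  # spot checks against the published per-class ranges
  expect_equal(unlist(rlr[rlr$class_label == "Mu", 2:3], use.names = FALSE),
               c(211, 225))
  expect_equal(unlist(rlr[rlr$class_label == "MAPEG", 2:3], use.names = FALSE),
               c(146, 155))

  # per-taxon composition preserved
  taxa <- table(rs$records$taxon)
  expect_equal(unname(taxa[["mammalia"]]), 112)
  expect_equal(unname(taxa[["bacteria"]]), 12)
})

test_that("reference set round-trips through FASTA + labels TSV + store", {
  rs <- tiny_refset()
  dir <- withr::local_tempdir()
  paths <- c(fasta = file.path(dir, "ref.fa"),
             labels = file.path(dir, "ref.tsv"),
             store = file.path(dir, "ref.rds"))
  write_reference_set(rs, paths["fasta"], paths["labels"], paths["store"])
  rs2 <- load_reference_set(paths["fasta"], paths["labels"], paths["store"])
  expect_equal(rs2$records$id, rs$records$id)
  expect_equal(rs2$records$sequence, rs$records$sequence)
  expect_equal(rs2$records$class_label, rs$records$class_label)
  expect_equal(rs2$store$matrices, rs$store$matrices)
})

test_that("loader errors name the offending id", {
  rs <- tiny_refset()
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "ref.fa"); tsv <- file.path(dir, "ref.tsv")
  st <- file.path(dir, "ref.rds")
  write_reference_set(rs, fa, tsv, st)

  # missing label
  lab <- read.delim(tsv)
  write.table(lab[lab$id != "ref2_1", ], tsv, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(load_reference_set(fa, tsv, st), "ref2_1")

  # empty FASTA
  empty_fa <- file.path(dir, "empty.fa")
  writeLines(character(), empty_fa)
  write_reference_set(rs, fa, tsv, st)  # restore labels
  expect_error(load_reference_set(empty_fa, tsv, st), "no records")

  # embedding length off by one
  bad <- rs$store$matrices
  bad[["ref1_2"]] <- bad[["ref1_2"]][-1, , drop = FALSE]
  write_embedding_store(embedding_store(bad, "synthetic"), st)
  err <- tryCatch(load_reference_set(fa, tsv, st), error = conditionMessage)
  expect_match(err, "ref1_2")
  expect_match(err, "11")
  expect_match(err, "12")
})

test_that("reference length ranges are closed min/max over bait lengths", {
  rs <- tiny_refset()
  # single-bait class: degenerate closed interval
  one <- rs$records[1, , drop = FALSE]
  one$id <- "solo"; one$class_label <- "Solo"
  one$sequence <- paste(rep("A", 300), collapse = "")
  solo_mat <- list(solo = matrix(rnorm(300 * 8), 300, 8))
  rs2 <- reference_set(rbind(rs$records, one),
                       add_embeddings(rs$store, solo_mat))
  rlr <- compute_rlr(rs2)
  expect_equal(unlist(rlr[rlr$class_label == "Solo", 2:3], use.names = FALSE),
               c(300, 300))
  # every bait length lies inside its class interval
  idx <- match(rs2$records$class_label, rlr$class_label)
  expect_true(all(rs2$records$length >= rlr$min_len[idx] &
                  rs2$records$length <= rlr$max_len[idx]))
})

test_that("adding an interior-length bait leaves the class range unchanged", {
  sim <- generate_synthetic(synthetic_config(
    n_classes = 2L, dim = 8L, n_baits_per_class = 6L,
    n_queries_per_class = 1L, seed = 4L))
  rs <- sim$refset
  before <- compute_rlr(rs)
  cl <- before$class_label[1]
  lo <- before$min_len[1]; hi <- before$max_len[1]
  mid <- as.integer(floor((lo + hi) / 2))
  extra <- data.frame(id = "interior", sequence = random_aa(mid),
                      class_label = cl, taxon = NA_character_,
                      length = mid)
  rs2 <- reference_set(rbind(rs$records, extra),
                       add_embeddings(rs$store,
                                      list(interior = matrix(rnorm(mid * 8), mid, 8))))
  expect_equal(compute_rlr(rs2), before)
})

test_that("within-class identity range spans min/max of pairwise identities", {
  # three equal-length sequences built so the ungapped diagonal alignment
  # is strictly optimal (any gap costs more than the worst mismatch run);
  # pairwise matches are 4/10, 6/10 and 8/10, hence identities {40, 60, 80}
  recs <- data.frame(id = c("a", "b", "c"),
                     sequence = c("ACDEFGHIWY",   # a~b: 40, a~c: 60, b~c: 80
                                  "ACDEKLMNPQ",
                                  "ACDEKLMNWY"),
                     class_label = "C1", taxon = NA)
  store <- embedding_store(setNames(lapply(1:3, function(i)
    matrix(0.0 + i, 10, 4)), recs$id), "synthetic")
  rs <- reference_set(recs, store)
  expect_equal(class_identity_range(rs, "C1"), c(min = 40, max = 80))

  # identical sequences give (100, 100) under the real identity
  recs2 <- data.frame(id = c("x", "y"), sequence = c("ACDEFGHIK", "ACDEFGHIK"),
                      class_label = "C1", taxon = NA)
  store2 <- embedding_store(list(x = matrix(1, 9, 4), y = matrix(2, 9, 4)),
                            "synthetic")
  expect_equal(class_identity_range(reference_set(recs2, store2), "C1"),
               c(min = 100, max = 100))

  # a single-bait class is an error
  expect_error(class_identity_range(rs, "missing"), "fewer than 2")
})
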