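test_that("distance matrix matches hand cases and a brute-force double loop", {
  expect_equal(euclidean_distance_matrix(matrix(0, 1, 2), matrix(0, 1, 2)),
               matrix(0, 1, 1), ignore_attr = TRUE)
  expect_equal(euclidean_distance_matrix(matrix(c(0, 0), 1),
                                         matrix(c(3, 4), 1))[1, 1], 5)
  withr::with_seed(5, {
    e1 <- matrix(rnorm(6), 3, 2)
    e2 <- matrix(rnorm(8), 4, 2)
    expect_equal(euclidean_distance_matrix(e1, e2),
                 oracle_distance_matrix(e1, e2),
                 tolerance = 1e-12, ignore_attr = TRUE)
  })
  expect_error(euclidean_distance_matrix(matrix(0, 2, 3), matrix(0, 2, 4)),
               "dimension mismatch")
})

test_that("signal enhancement: constant background vanishes, hand case, transpose equivariance", {
  const <- matrix(3.7, 4, 6)
  expect_equal(signal_enhance(const), matrix(0, 4, 6), ignore_attr = TRUE)
  expect_equal(signal_enhance(matrix(c(1, 0, 0, 1), 2)),
               matrix(c(-0.5, 0.5, 0.5, -0.5), 2), ignore_attr = TRUE)
  withr::with_seed(9, {
    for (r in 1:5) {
      d <- matrix(abs(rnorm(12)), 3, 4)
      expect_equal(signal_enhance(t(d)), t(signal_enhance(d)),
                   ignore_attr = TRUE)
    }
  })
  expect_error(signal_enhance(matrix(numeric(0), 0, 0)), "empty")
})

test_that("enhanced matrix of a square doubly regular input has zero mean", {
  # constant row and column means: circulant-style construction
  base <- c(1, 2, 4, 8)
  d <- sapply(0:3, function(s) base[(seq_along(base) + s - 1) %% 4 + 1])
  expect_equal(rowMeans(d), rep(mean(base), 4))
  expect_equal(colMeans(d), rep(mean(base), 4))
  expect_equal(mean(signal_enhance(d)), 0, tolerance = 1e-12)
})

test_that("global alignment equals the exhaustive-enumeration oracle on small matrices", {
  expect_equal(global_align(matrix(2, 1, 1), -1, -0.5)$s_align, 2)
  expect_equal(global_align(matrix(2, 1, 1), -1, -0.5)$path,
               matrix(c(1L, 1L), 1), ignore_attr = TRUE)

  # linear-gap hand case: diagonal dominates
  a <- global_align(matrix(c(1, -1, -1, 1), 2), gap_open = -1, gap_extend = -1)
  expect_equal(a$s_align, 2)
  expect_equal(a$path, cbind(i = 1:2, j = 1:2), ignore_attr = TRUE)

  withr::with_seed(101, {
    for (case in 1:220) {
      n <- sample(1:5, 1); m <- sample(1:5, 1)
      S <- matrix(rnorm(n * m), n, m)
      go <- -runif(1, 0.2, 2); ge <- go * runif(1, 0.05, 1)
      got <- global_align(S, gap_open = go, gap_extend = ge)
      expect_equal(got$s_align, oracle_align_score(S, go, ge),
                   tolerance = 1e-10)
    }
  })
})

test_that("alignment path is monotone and reproduces its own score", {
  withr::with_seed(77, {
    for (case in 1:20) {
      n <- sample(2:9, 1); m <- sample(2:9, 1)
      S <- matrix(rnorm(n * m), n, m)
      aln <- global_align(S, -1, -0.1)
      p <- aln$path
      expect_true(all(diff(p[!is.na(p[, 1]), 1]) == 1))
      expect_true(all(diff(p[!is.na(p[, 2]), 2]) == 1))
      expect_equal(sum(!is.na(p[, 1])), n)
      expect_equal(sum(!is.na(p[, 2])), m)
      # rescore the path: matched cells + affine gap runs
      sc <- sum(S[p[!is.na(p[, 1]) & !is.na(p[, 2]), , drop = FALSE]])
      gap <- is.na(p[, 1]) | is.na(p[, 2])
      if (any(gap)) {
        side <- ifelse(is.na(p[, 1]), "L", ifelse(is.na(p[, 2]), "U", "D"))
        runs <- rle(side)
        glen <- runs$lengths[runs$values != "D"]
        sc <- sc + sum(-1 + (glen - 1) * -0.1)
      }
      expect_equal(sc, aln$s_align, tolerance = 1e-10)
    }
  })
})

test_that("swap symmetry: score invariant, paths transposed", {
  withr::with_seed(13, {
    for (case in 1:10) {
      e1 <- matrix(rnorm(40), 8, 5)
      e2 <- matrix(rnorm(30), 6, 5)
      a <- align_pair(e1, e2)
      b <- align_pair(e2, e1)
      expect_equal(a$s_align, b$s_align, tolerance = 1e-10)
      expect_equal(a$eba_min, b$eba_min, tolerance = 1e-10)
      expect_equal(unname(a$path), unname(b$path[, c(2, 1)]))
    }
  })
})

test_that("EBAmin/EBAmax follow the length normalisation contract", {
  expect_equal(eba_scores(100, 200, 250),
               c(eba_min = 0.4, eba_max = 0.5))
  expect_equal(eba_scores(0, 3, 9), c(eba_min = 0, eba_max = 0))
  expect_error(eba_scores(1, 0, 5), "lengths")
  withr::with_seed(3, {
    for (case in 1:50) {
      s <- rnorm(1, sd = 10)
      l1 <- sample(1:400, 1); l2 <- sample(1:400, 1)
      sc <- eba_scores(abs(s), l1, l2)
      expect_lte(sc[["eba_min"]], sc[["eba_max"]])
      if (l1 == l2) expect_equal(sc[["eba_min"]], sc[["eba_max"]])
      if (l1 != l2 && s != 0) expect_false(sc[["eba_min"]] == sc[["eba_max"]])
    }
  })
})

test_that("path identity counts matching aligned pairs only", {
  diag3 <- cbind(i = 1:3, j = 1:3)
  expect_equal(path_identity(diag3, "ACD", "ACD"), 100)
  expect_equal(path_identity(diag3, "ACD", "AED"), 100 * 2 / 3)
  expect_equal(path_identity(diag3, "ACD", "WYH"), 0)
  gapped <- cbind(i = c(1, 2, NA), j = c(1, NA, 2))
  expect_equal(path_identity(gapped, "AC", "AG"), 100)  # only pair (1,1) aligned
  expect_warning(out <- path_identity(matrix(NA_integer_, 0, 2), "A", "A"),
                 "empty")
  expect_equal(out, 0)
})
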