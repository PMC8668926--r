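test_that("coordinate converters are exact at bin boundaries", {
  region <- region_preset("pitx1-mm9")
  expect_equal(pos_to_bin(54000001, region, 5000), 0L)
  expect_equal(pos_to_bin(54005000, region, 5000), 0L)
  expect_equal(pos_to_bin(54005001, region, 5000), 1L)
  expect_equal(n_bins(region, 5000), 660L)
  iv <- bin_to_interval(0, region, 5000)
  expect_equal(c(iv$start, iv$end), c(54000001, 54005000))
  expect_error(pos_to_bin(53000000, region, 5000), "outside region")
})

test_that("binning matches a hand tally and conserves pair count", {
  region <- genomic_interval("chrT", 1, 4000)
  # bins (0-based): a->0, b->1; pairs: (0,1), (1,1), (0,1)
  pairs <- contact_pairs(region, c(500, 1500, 900), c(1200, 1800, 1100))
  m <- bin_pairs(pairs, 1000)
  expect_equal(m$M[1, 2], 2)
  expect_equal(m$M[2, 1], 2)
  expect_equal(m$M[2, 2], 1)
  expect_equal(sum(m$M[upper.tri(m$M, diag = TRUE)]), 3)
  # conservation on random pairs
  set.seed(17)
  pr <- contact_pairs(region, sample(4000, 200, TRUE), sample(4000, 200, TRUE))
  mr <- bin_pairs(pr, 250)
  expect_equal(sum(mr$M[upper.tri(mr$M, diag = TRUE)]), 200)
  expect_lt(max(abs(mr$M - t(mr$M))), 1e-12)
  # empty input gives the zero matrix
  m0 <- bin_pairs(contact_pairs(region, numeric(0), numeric(0)), 1000)
  expect_true(all(m0$M == 0))
  expect_error(contact_pairs(region, 5000, 100), "outside region at index 1")
})

test_that("KR balancing of a constant matrix is uniform", {
  m <- toy_contact_matrix(matrix(1, 4, 4))
  bal <- kr_balance(m)
  expect_equal(max(bal$bias) / min(bal$bias), 1, tolerance = 1e-8)
  rs <- rowSums(bal$M)
  expect_lt(sd(rs) / mean(rs), 1e-8)
  expect_equal(sum(bal$M), sum(m$M))  # mass preserved
})

test_that("KR balancing agrees with the alternating-scaling oracle", {
  set.seed(23)
  for (k in 1:5) {
    n <- sample(5:20, 1)
    A <- matrix(runif(n * n, 0.1, 3), n)
    A <- (A + t(A)) / 2
    bal <- kr_balance(toy_contact_matrix(A), tol = 1e-10)
    unit <- bal$M * (n / sum(A))   # rescale to row sums 1
    expect_lt(max(abs(unit - sinkhorn_balance(A))), 1e-6)
  }
})

test_that("zero-marginal bins are masked and the rest balanced", {
  A <- matrix(runif(25, 0.5, 2), 5)
  A <- (A + t(A)) / 2
  A[3, ] <- 0
  A[, 3] <- 0
  bal <- kr_balance(toy_contact_matrix(A))
  expect_false(bal$mask[3])
  expect_true(all(bal$M[3, ] == 0))
  expect_true(is.na(bal$bias[3]))
  rs <- rowSums(bal$M)[bal$mask]
  expect_lt(sd(rs) / mean(rs), 1e-7)
  expect_true(all(bal$bias[bal$mask] > 0))
})

test_that("non-convergence raises rather than returning a partial result", {
  # support pattern without total support: x1*(x1+x2)=1, x1*x2=1 has no
  # positive solution, so the iteration cannot converge
  A <- matrix(c(1, 1, 1, 0), 2)
  expect_error(kr_balance(toy_contact_matrix(A), max_iter = 10L),
               "did not converge")
})

balanced_pair <- function(seed = 31, n = 30) {
  set.seed(seed)
  A <- matrix(runif(n * n, 0.5, 2), n); A <- (A + t(A)) / 2
  B <- matrix(runif(n * n, 0.5, 2), n); B <- (B + t(B)) / 2
  list(a = kr_balance(toy_contact_matrix(A)),
       b = kr_balance(toy_contact_matrix(B)))
}

test_that("joint subdiagonal scaling equalizes per-offset means", {
  p <- balanced_pair()
  sc <- subdiagonal_scale(p$a, p$b)
  nb <- nrow(sc$a$M)
  for (d in c(0, 1, 5, nb - 1)) {
    i <- seq_len(nb - d)
    expect_equal(mean(sc$a$M[cbind(i, i + d)]),
                 mean(sc$b$M[cbind(i, i + d)]), tolerance = 1e-12)
  }
  # identical inputs are returned unchanged
  sc2 <- subdiagonal_scale(p$a, p$a)
  expect_equal(sc2$a$M, p$a$M, tolerance = 1e-12)
  expect_equal(sc2$b$M, p$a$M, tolerance = 1e-12)
})

test_that("a map with entries 2x the other converges to 1.5x the smaller", {
  p <- balanced_pair(seed = 33)
  b2 <- p$a
  b2$M <- p$a$M * 2
  b2$bias <- NULL
  sc <- subdiagonal_scale(p$a, b2)
  expect_equal(sc$a$M, 1.5 * p$a$M, tolerance = 1e-10)
  expect_equal(sc$b$M, 1.5 * p$a$M, tolerance = 1e-10)
})

test_that("subtraction is antisymmetric, exact on a hand example, and gated", {
  p <- balanced_pair(seed = 35, n = 10)
  expect_error(subtract_maps(p$a, p$b), "scaled together")
  sc <- subdiagonal_scale(p$a, p$b)
  d1 <- subtract_maps(sc$a, sc$b)
  d2 <- subtract_maps(sc$b, sc$a)
  expect_equal(d1$M, -d2$M)
  d0 <- subtract_maps(sc$a, sc$a)
  expect_true(all(d0$M == 0))
  # hand 3x3 difference via force on raw matrices
  A <- toy_contact_matrix(matrix(c(4, 1, 0, 1, 5, 2, 0, 2, 6), 3))
  B <- toy_contact_matrix(matrix(c(1, 1, 1, 1, 1, 1, 1, 1, 1), 3))
  d <- subtract_maps(A, B, force = TRUE)
  expect_equal(d$M, A$M - B$M)
})

test_that("percentile truncation clips only the extreme entries", {
  m <- toy_contact_matrix(matrix(5, 4, 4))
  expect_equal(truncate_percentile(m, 99)$M, m$M)  # constant unchanged
  # 100 distinct upper-triangle values: only the maximum is clipped
  n <- 13  # 13*14/2 = 91 ... use bigger to hit >= 100
  n <- 14  # 105 entries
  vals <- matrix(0, n, n)
  vals[upper.tri(vals, diag = TRUE)] <- seq_len(n * (n + 1) / 2)
  A <- vals + t(vals) - diag(diag(vals))
  m2 <- toy_contact_matrix(A)
  tr <- truncate_percentile(m2, 99)
  ut <- m2$M[upper.tri(m2$M, diag = TRUE)]
  cut <- as.numeric(quantile(ut, 0.99, type = 7))
  expect_equal(attr(tr, "cutoff"), cut)
  expect_equal(sum(tr$M[upper.tri(tr$M, diag = TRUE)] < m2$M[upper.tri(m2$M, diag = TRUE)]),
               sum(ut > cut))
  expect_lte(max(tr$M), max(m2$M))
  expect_error(truncate_percentile(m2, 100), "q must be")
})

test_that("triplet round-trip preserves the matrix", {
  set.seed(3)
  A <- matrix(rpois(36, 2), 6); A <- A + t(A)
  m <- toy_contact_matrix(A)
  f <- tempfile(fileext = ".tsv")
  write_matrix_triplet(m, f)
  m2 <- read_matrix_triplet(f)
  expect_equal(m2$M, m$M)
  expect_equal(m2$bin_size, m$bin_size)
})
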