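toy_expr <- function() {
  counts <- matrix(c(100, 200, 0, 50,
                     10, 10, 10, 10,
                     0, 0, 0, 0,
                     400, 100, 400, 100,
                     5, 80, 5, 80),
                   nrow = 5, byrow = TRUE,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expression_matrix(counts, gene_lengths = c(1000, 2000, 500, 1000, 4000),
                    sample_totals = rep(1e7, 4),
                    sample_groups = c(s1 = "A", s2 = "B", s3 = "A",
                                      s4 = "B"))
}

test_that("RPKM matches its closed form and scaling laws", {
  m <- rpkm(toy_expr())
  # count 100, length 1000 bp, total 1e7 -> 10.0
  expect_equal(m$values["g1", "s1"], 10)
  expect_equal(m$values["g3", ], setNames(rep(0, 4), paste0("s", 1:4)))
  # doubling one sample's total halves that sample's RPKM
  e2 <- toy_expr()
  e2$sample_totals[2] <- 2e7
  m2 <- rpkm(e2)
  expect_equal(m2$values[, "s2"], m$values[, "s2"] / 2)
  expect_equal(m2$values[, "s1"], m$values[, "s1"])
})

test_that("the RPKM floor filter matches exhaustive evaluation on a toy matrix", {
  m <- rpkm(toy_expr())
  keep_by_hand <- apply(m$values, 1, function(x) any(x > 1))
  filt <- rpkm_floor_filter(m, threshold = 1)
  expect_equal(rownames(filt$values), names(which(keep_by_hand)))
  expect_equal(attr(filt, "removed_genes"), names(which(!keep_by_hand)))
  # a gene at exactly the floor everywhere is removed (rule is <=)
  flat <- expression_matrix(
    matrix(1, 1, 2, dimnames = list("g", c("s1", "s2"))),
    gene_lengths = 1, sample_totals = c(1, 1), unit = "rpkm"
  )
  expect_equal(nrow(rpkm_floor_filter(flat)$values), 0L)
  # ... but 1.01 in one subset sample rescues it
  near <- expression_matrix(
    matrix(c(1, 1.01), 1, 2, dimnames = list("g", c("s1", "s2"))),
    gene_lengths = 1, sample_totals = c(1, 1), unit = "rpkm"
  )
  expect_equal(nrow(rpkm_floor_filter(near)$values), 1L)
  expect_equal(nrow(rpkm_floor_filter(near, sample_subset = "s1")$values), 0L)
  expect_error(rpkm_floor_filter(near, sample_subset = character(0)),
               "non-empty")
})

test_that("per-gene z-scores follow the stated sd convention", {
  m <- expression_matrix(
    matrix(c(1, 2, 3), 1, 3, dimnames = list("g", c("s1", "s2", "s3"))),
    gene_lengths = 1, sample_totals = rep(1, 3), unit = "rpkm"
  )
  # sd(1,2,3) is exactly 1 with the sample (n-1) convention, sqrt(2/3)
  # with the population one
  z <- gene_zscore(m)
  expect_equal(as.numeric(z), c(-1, 0, 1))
  zp <- gene_zscore(m, sd_type = "population")
  expect_equal(as.numeric(zp), c(-1, 0, 1) / sqrt(2 / 3))
})

test_that("z-score rows are centred, unit-scaled, and constant genes flagged", {
  set.seed(19)
  v <- matrix(rexp(40), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  v[4, ] <- 2.5
  m <- expression_matrix(v, gene_lengths = rep(1000, 8),
                         sample_totals = rep(1e6, 5), unit = "rpkm")
  z <- gene_zscore(m)
  expect_equal(attr(z, "flagged_genes"), "g4")
  expect_true(all(is.na(z[4, ])))
  ok <- setdiff(rownames(z), "g4")
  expect_true(all(abs(rowMeans(z[ok, ])) < 1e-9))
  expect_equal(unname(apply(z[ok, ], 1, sd)), rep(1, 7))
})

test_that("group log2 fold changes follow the closed form and negate on swap", {
  m <- rpkm(toy_expr())
  fc0 <- group_log2fc(m, "A", "B", pseudocount = 0)
  # g4: mean_A = 40, mean_B = 10 -> log2 4 = 2
  expect_equal(unname(fc0["g4"]), 2)
  expect_equal(unname(fc0["g2"]), 0)  # equal means -> 0
  fc <- group_log2fc(m, "A", "B")
  expect_equal(group_log2fc(m, "B", "A"), -fc)
  expect_error(group_log2fc(m, "A", "nope"), "unknown")
})

test_that("the rpkm -> filter -> zscore pipeline keeps survivors consistent", {
  m <- rpkm(toy_expr())
  filt <- rpkm_floor_filter(m, threshold = 1)
  z <- gene_zscore(filt)
  expect_equal(rownames(z), rownames(filt$values))
  expect_true(all(apply(filt$values, 1, function(x) any(x > 1))))
})
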