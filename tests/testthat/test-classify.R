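mk_cells <- function(expr, cluster = "A", axis = "proximal",
                     genotype = "WT", tissue = "HL") {
  data.frame(cell_id = seq_along(expr), genotype = genotype, tissue = tissue,
             cluster = cluster, axis = axis, norm_expr = expr,
             stringsAsFactors = FALSE)
}

test_that("class boundaries belong to the lower class", {
  cells <- classify_cells(mk_cells(c(0, 0.3, 0.3000001, 1.45, 1.4500001, 3)))
  expect_equal(as.character(cells$class),
               c("nonlow", "nonlow", "intermediate", "intermediate",
                 "high", "high"))
})

test_that("classification is a monotone step function with custom thresholds", {
  th <- expression_thresholds(0.5, 2)
  v <- seq(0, 3, by = 0.01)
  cls <- classify_cells(mk_cells(v), th)$class
  expect_true(all(diff(as.integer(cls)) >= 0))
  expect_equal(nlevels(cls), 3L)
  expect_error(expression_thresholds(2, 1), "t_low < t_high")
})

test_that("class proportions match hand counts and sum to one", {
  cells <- classify_cells(mk_cells(c(0.1, 0.2, 1.0, 2.0)))
  p <- class_proportions(cells, group_by = "cluster")
  expect_equal(p$frac_nonlow, 0.5)
  expect_equal(p$frac_intermediate, 0.25)
  expect_equal(p$frac_high, 0.25)
  expect_equal(p$n_cells, 4L)
})

test_that("groups partition the cells: weighted union recovers pooled fractions", {
  set.seed(13)
  cells <- classify_cells(mk_cells(runif(300, 0, 3),
                                   cluster = sample(c("A", "B", "C"), 300,
                                                    replace = TRUE)))
  by_cl <- class_proportions(cells, group_by = "cluster")
  pooled <- class_proportions(cells, group_by = "condition")
  for (col in c("frac_nonlow", "frac_intermediate", "frac_high")) {
    expect_equal(sum(by_cl[[col]] * by_cl$n_cells) / sum(by_cl$n_cells),
                 pooled[[col]])
  }
  expect_equal(sum(by_cl$n_cells), pooled$n_cells)
  expect_true(all(abs(by_cl$frac_nonlow + by_cl$frac_intermediate +
                        by_cl$frac_high - 1) < 1e-9))
})

test_that("axis grouping drops unassigned cells with a warning", {
  cells <- classify_cells(mk_cells(c(0.1, 2, 1), axis = c("proximal",
                                                          "distal", NA)))
  expect_warning(p <- class_proportions(cells, group_by = "axis"), "omitted")
  expect_equal(sort(p$group), c("distal", "proximal"))
})

test_that("non/low fold changes follow the ratio arithmetic", {
  ref <- data.frame(group = c("prox", "dist", "zero"),
                    frac_nonlow = c(0.13, 0.29, 0))
  alt <- data.frame(group = c("prox", "dist", "zero"),
                    frac_nonlow = c(0.28, 0.45, 0.1))
  fc <- fold_change_nonlow(ref, alt)
  expect_equal(fc$fold[fc$group == "prox"], 0.28 / 0.13)
  expect_equal(fc$fold[fc$group == "dist"], 0.45 / 0.29)
  expect_true(fc$undefined[fc$group == "zero"])
  expect_true(is.na(fc$fold[fc$group == "zero"]))
  # identical tables give fold 1 everywhere
  fc1 <- fold_change_nonlow(ref[1:2, ], ref[1:2, ])
  expect_equal(fc1$fold, c(1, 1))
  expect_error(fold_change_nonlow(ref, alt[1:2, ]), "match")
})
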