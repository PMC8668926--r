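test_that("a degenerate all-non/low mixture never produces expressing cells", {
  cfg <- cell_sim_config(
    conditions = data.frame(genotype = "WT", tissue = "HL"),
    n_per_condition = 100L,
    clusters = data.frame(cluster = "ICT", axis = "proximal"),
    cluster_shares = list("WT-HL" = 1),
    class_weights = list("WT-HL" = matrix(c(1, 0, 0), 1, 3,
      dimnames = list("ICT", c("nonlow", "intermediate", "high")))),
    seed = 101
  )
  res <- gen_cells(cfg)
  expect_equal(nrow(res$cells), 100L)
  cells <- classify_cells(log_normalize(res$cells))
  expect_true(all(res$cells$target_count == 0 | cells$class == "nonlow"))
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- cell_sim_config(n_per_condition = 300L, seed = 7)
  r1 <- gen_cells(cfg)
  r2 <- gen_cells(cfg)
  expect_identical(r1, r2)
  f1 <- tempfile(); f2 <- tempfile()
  write_cell_table(r1$cells, f1)
  write_cell_table(r2$cells, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("empirical class fractions recover configured weights (3 binomial SE)", {
  cfg <- cell_sim_config(n_per_condition = 5000L, seed = 11)
  res <- gen_cells(cfg)
  cells <- classify_cells(log_normalize(qc_filter(res$cells)))
  props <- class_proportions(cells, group_by = "condition")
  for (cond in unique(res$truth$condition)) {
    tr <- res$truth[res$truth$condition == cond, ]
    w <- colSums(tr[, c("w_nonlow", "w_intermediate", "w_high")] *
                   tr$n_cells) / sum(tr$n_cells)
    row <- props[props$condition == cond, ]
    obs <- as.numeric(row[c("frac_nonlow", "frac_intermediate", "frac_high")])
    se3 <- 3 * sqrt(w * (1 - w) / row$n_cells)
    expect_true(all(abs(obs - w) <= se3),
                label = paste("class recovery for", cond))
  }
})

test_that("recovery error shrinks with the number of cells", {
  err_at <- function(n, seed) {
    cfg <- cell_sim_config(
      conditions = data.frame(genotype = "WT", tissue = "HL"),
      n_per_condition = as.integer(n), seed = seed
    )
    res <- gen_cells(cfg)
    cells <- classify_cells(log_normalize(res$cells))
    props <- class_proportions(cells, group_by = "condition")
    tr <- res$truth
    w <- colSums(tr[, c("w_nonlow", "w_intermediate", "w_high")] *
                   tr$n_cells) / sum(tr$n_cells)
    obs <- as.numeric(props[1, c("frac_nonlow", "frac_intermediate",
                                 "frac_high")])
    max(abs(obs - w))
  }
  expect_lt(err_at(1e5, 23), err_at(1e3, 23))
})

test_that("invalid configurations are rejected with messages", {
  expect_error(cell_sim_config(n_per_condition = 100L), "seed")
  expect_error(cell_sim_config(n_per_condition = -5L, seed = 1), "positive")
  bad_w <- list("WT-HL" = matrix(c(0.5, 0.2, 0.2), 1, 3,
    dimnames = list("ICT", c("nonlow", "intermediate", "high"))))
  expect_error(cell_sim_config(
    conditions = data.frame(genotype = "WT", tissue = "HL"),
    clusters = data.frame(cluster = "ICT", axis = "proximal"),
    cluster_shares = list("WT-HL" = 1),
    class_weights = bad_w, seed = 1
  ), "sum to 1")
})
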