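v4c_region <- genomic_interval("chrT", 1, 100000)
v4c_vp <- genomic_interval("chrT", 40001, 50000)

test_that("no pairs gives an all-zero profile of the right geometry", {
  p <- virtual_4c(contact_pairs(v4c_region, numeric(0), numeric(0)),
                  v4c_vp, raw_bin = 1000, interval_size = 5000)
  expect_length(p$values, 20L)
  expect_true(all(p$values == 0))
  expect_equal(sum(p$viewpoint_overlap), 2L)
})

test_that("pairs with both mates inside the viewpoint contribute nothing", {
  pairs <- contact_pairs(v4c_region, c(41000, 42000), c(49000, 43000))
  p <- virtual_4c(pairs, v4c_vp)
  expect_equal(p$n_qualifying, 0L)
  expect_true(all(p$values == 0))
})

test_that("the profile equals the brute-force oracle on random pairs", {
  set.seed(29)
  pairs <- contact_pairs(v4c_region, sample(100000, 50, TRUE),
                         sample(100000, 50, TRUE))
  p <- virtual_4c(pairs, v4c_vp, raw_bin = 1000, interval_size = 5000)
  orc <- v4c_oracle(pairs, v4c_vp, 1000, 5000)
  expect_equal(p$values, orc$values)
  expect_equal(p$raw_counts, orc$raw)
  expect_equal(p$n_qualifying, orc$n_qualifying)
  expect_equal(sum(p$raw_counts), p$n_qualifying)
})

test_that("geometry violations are rejected", {
  pairs <- contact_pairs(v4c_region, 1000, 2000)
  expect_error(virtual_4c(pairs, genomic_interval("chrT", 99000, 120000)),
               "outside region")
  expect_error(virtual_4c(pairs, v4c_vp, raw_bin = 1000,
                          interval_size = 2500), "multiple")
})

test_that("per-million normalization rescales by qualifying pairs", {
  pairs <- contact_pairs(v4c_region, c(45000, 45000), c(10500, 80500))
  raw <- virtual_4c(pairs, v4c_vp)
  pm <- virtual_4c(pairs, v4c_vp, normalize = "per_million")
  expect_equal(pm$values, raw$values * 1e6 / 2)
})

test_that("profile subtraction is elementwise and antisymmetric", {
  pa <- contact_pairs(v4c_region, c(45000, 45000, 45000),
                      c(10500, 10800, 80500))
  pb <- contact_pairs(v4c_region, 45000, 10500)
  a <- virtual_4c(pa, v4c_vp)
  b <- virtual_4c(pb, v4c_vp)
  d <- profile_subtract(a, b)
  expect_equal(d$values, a$values - b$values)
  expect_equal(profile_subtract(b, a)$values, -d$values)
  expect_true(all(profile_subtract(a, a)$values == 0))
  other <- virtual_4c(pb, genomic_interval("chrT", 30001, 40000))
  expect_error(profile_subtract(a, other), "geometry")
})

test_that("bedGraph export uses exact 0-based half-open intervals", {
  pairs <- contact_pairs(v4c_region, 45000, 10500)
  p <- virtual_4c(pairs, v4c_vp)
  f <- tempfile(fileext = ".bedgraph")
  write_bedgraph(p, f, track_name = "t")
  lines <- readLines(f)
  expect_match(lines[1], "track type=bedGraph")
  first <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(first[2]), 0L)
  expect_equal(as.integer(first[3]), 5000L)
  last <- strsplit(lines[length(lines)], "\t")[[1]]
  expect_equal(as.integer(last[3]), 100000L)
  # the 10.5 kb mate sits in the third 5 kb interval, mean over 5 raw bins
  third <- strsplit(lines[4], "\t")[[1]]
  expect_equal(as.numeric(third[4]), 0.2)
})
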