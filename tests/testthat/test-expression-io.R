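write_toy_table <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

test_that("a minimal table parses to the right shape", {
  p <- write_toy_table(c(
    "gene_id\tT0_R1\tT4_R1\tT8_R1",
    "A\t1\t2\t3",
    "B\t4\t5\t6"
  ))
  x <- read_expression_table(p, "CTRL")
  expect_equal(dim(x), c(2L, 3L, 1L))
  expect_equal(x$gene_ids, c("A", "B"))
  expect_equal(x$time_grid, c(0, 4, 8))
  expect_equal(x$values["B", , 1], c(4, 5, 6))
})

test_that("malformed tables produce descriptive errors", {
  dup <- write_toy_table(c("gene_id\tT0_R1\tT2_R1", "A\t1\t2", "A\t3\t4"))
  expect_error(read_expression_table(dup), "A")

  hdr <- write_toy_table(c("gene_id\tT0_R1\tfoo", "A\t1\t2"))
  expect_error(read_expression_table(hdr), "foo")

  bad <- write_toy_table(c("gene_id\tT0_R1\tT2_R1", "A\t1\txyz"))
  expect_error(read_expression_table(bad), "non-numeric")

  expect_error(read_expression_table(tempfile()), "no such file")
})

test_that("write/read round-trips a simulated study", {
  cfg <- sim_config(n_genes = 30, n_dynamic = 10, n_modules = 2, seed = 4)
  st <- simulate_study(cfg)
  p <- tempfile(fileext = ".tsv")
  write_expression_table(st$conditions$EGF, p)
  back <- read_expression_table(p, "EGF")
  expect_equal(back$values, st$conditions$EGF$values, tolerance = 1e-12)
  expect_equal(back$gene_ids, st$conditions$EGF$gene_ids)
  expect_equal(back$time_grid, st$conditions$EGF$time_grid)
})

test_that("replicate medians match the sort-and-pick oracle", {
  # forced arithmetic
  v <- array(c(1, 2, 9), dim = c(1, 1, 3))
  x <- expression_time_course(array(rep(v, 2), dim = c(1, 2, 3)),
                              c(0, 1), "g1")
  expect_equal(profile_matrix(median_over_replicates(x))[1, ], c(2, 2))

  # N = 1 is the identity
  one <- expression_time_course(matrix(1:6, 2, 3), c(0, 1, 2), c("a", "b"))
  expect_equal(median_over_replicates(one)$values, one$values)

  # random array vs element-wise middle-of-sorted oracle
  set.seed(5)
  vals <- array(rnorm(100 * 14 * 3), dim = c(100, 14, 3))
  x3 <- expression_time_course(vals, seq(0, 13), sprintf("g%03d", 1:100))
  med <- profile_matrix(median_over_replicates(x3))
  oracle <- apply(vals, c(1, 2), function(z) sort(z)[2])
  expect_equal(unname(med), oracle, tolerance = 1e-12)

  # idempotent and invariant to replicate permutation
  expect_equal(median_over_replicates(median_over_replicates(x3))$values,
               median_over_replicates(x3)$values)
  xp <- expression_time_course(vals[, , c(3, 1, 2)], seq(0, 13),
                               sprintf("g%03d", 1:100))
  expect_equal(median_over_replicates(xp)$values,
               median_over_replicates(x3)$values)
})

test_that("fold-change is taken against control at time zero", {
  ctrl <- expression_time_course(matrix(c(2, 4, 8, 1, 1, 1), 2, 3,
                                        byrow = TRUE),
                                 c(0, 2, 4), c("a", "b"), "CTRL")
  x <- expression_time_course(matrix(c(8, 2, 2, 3, 1, 0.5), 2, 3,
                                     byrow = TRUE),
                              c(0, 2, 4), c("a", "b"), "EGF")
  fc <- fold_change_vs_control_t0(x, ctrl, log2 = TRUE)
  expect_equal(profile_matrix(fc)["a", ], log2(c(8, 2, 2) / 2))
  expect_equal(unname(profile_matrix(fc)["a", 1]), 2)  # baseline 2, value 8

  # control relative to itself is exactly 0 at t = 0 on the log scale
  self <- fold_change_vs_control_t0(ctrl, ctrl)
  expect_equal(unname(profile_matrix(self)[, 1]), c(0, 0))

  bad <- expression_time_course(matrix(c(0, 1, 1, 2, 2, 2), 2, 3,
                                       byrow = TRUE),
                                c(0, 2, 4), c("a", "b"), "CTRL")
  expect_error(fold_change_vs_control_t0(x, bad), "a")
})

test_that("centering removes the temporal mean exactly", {
  x <- expression_time_course(matrix(c(5, 5, 5, 1, 2, 3), 2, 3, byrow = TRUE),
                              c(0, 1, 2), c("const", "lin"))
  ce <- center_profiles(x)
  expect_equal(unname(profile_matrix(ce)["const", ]), c(0, 0, 0))
  expect_equal(unname(profile_matrix(ce)["lin", ]), c(-1, 0, 1))

  set.seed(2)
  y <- expression_time_course(matrix(rnorm(50 * 10), 50), seq(0, 9),
                              sprintf("g%02d", 1:50))
  expect_lt(max(abs(rowMeans(profile_matrix(center_profiles(y))))), 1e-10)
  # idempotent
  expect_equal(center_profiles(center_profiles(y))$values,
               center_profiles(y)$values)
})

test_that("missing replicate cells fall back to present replicates", {
  vals <- array(rnorm(2 * 3 * 2), dim = c(2, 3, 2))
  vals[1, 2, 1] <- NA  # one replicate missing: median of the rest
  x <- expression_time_course(vals, c(0, 1, 2), c("a", "b"))
  med <- profile_matrix(median_over_replicates(x))
  expect_equal(unname(med[1, 2]), vals[1, 2, 2])

  vals[2, 3, ] <- NA  # whole time point missing: gene dropped with warning
  x2 <- expression_time_course(vals, c(0, 1, 2), c("a", "b"))
  expect_warning(m2 <- median_over_replicates(x2), "dropped")
  expect_equal(m2$gene_ids, "a")
})
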