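test_that("pairwise Spearman values match the rank-difference formula", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(3, 1, 2, 5, 4)
  expect_equal(spearman_cor(x, y), 0.6)
  expect_equal(spearman_cor(x, y), rank_formula_rho(x, y))
  expect_equal(spearman_cor(x, x), 1)
  expect_equal(spearman_cor(x, -x), -1)
  expect_true(is.na(spearman_cor(rep(1, 5), x)))

  set.seed(44)
  a <- matrix(rnorm(20 * 9), 20, dimnames = list(sprintf("g%02d", 1:20), NULL))
  b <- matrix(rnorm(20 * 9), 20, dimnames = list(sprintf("g%02d", 1:20), NULL))
  rho <- spearman_between_conditions(a, b)
  oracle <- vapply(1:20, function(i) rank_formula_rho(a[i, ], b[i, ]), 0)
  expect_equal(unname(rho), oracle)
})

test_that("correlation bins are disjoint, exhaustive and correctly scaled", {
  all_one <- bin_correlations(rep(1, 10))
  expect_equal(all_one$percent[all_one$bin == "similar"], 100)

  four <- bin_correlations(c(0.8, -0.8, 0.0, 0.5))
  expect_equal(four$count, c(1L, 1L, 1L, 1L))

  set.seed(10)
  rhos <- runif(3000, -1, 1)
  tab <- bin_correlations(rhos)
  expect_equal(sum(tab$count), 3000)
  expect_equal(tab$percent, 100 * tab$count / 3000)
  # exhaustive partition for any finite rho
  expect_equal(tab$count[1], sum(rhos > 0.7))
  expect_equal(tab$count[2], sum(rhos < -0.7))
  expect_equal(tab$count[3], sum(abs(rhos) < 0.1))

  with_na <- bin_correlations(c(0.9, NA, 0.2))
  expect_equal(attr(with_na, "n_missing"), 1)
  expect_equal(sum(with_na$count), 2)
})

test_that("differential activity uses the strict 0.7 cutoff", {
  t5 <- 1:5
  expect_false(as.logical(differential_activity(t5, t5)))
  expect_true(as.logical(differential_activity(t5, rev(t5))))

  # a permutation with sum(d^2) = 6 gives rho = 1 - 36/120 = 0.7 exactly:
  # the strict inequality keeps it non-differential
  y07 <- c(2, 3, 1, 4, 5)
  expect_equal(spearman_cor(t5, y07), 0.7)
  expect_false(as.logical(differential_activity(t5, y07)))

  flat <- differential_activity(rep(2, 5), t5)
  expect_true(as.logical(flat))
  expect_true(attr(flat, "undefined"))
})

test_that("significant variation is inclusive at 1.96", {
  expect_false(significant_variation(rep(5, 10)))
  expect_true(significant_variation(c(0, 1.96)))
  expect_true(significant_variation(c(-1.5, 0.3, 0.5)))
  expect_false(significant_variation(c(-0.9, 0.9)))
})

test_that("the classifier applies all criteria with single-criterion vetoes", {
  cv <- toy_curves()
  same <- lapply(cv, function(z) cv$SHH)
  expect_equal(classify_crosstalk(same)$classification, "neither")

  expect_error(classify_crosstalk(cv[c("CTRL", "SHH", "EGF")]), "EGF_SHH")

  # a fully qualifying cross-talk pattern
  r <- classify_crosstalk(cv)
  expect_equal(r$classification, "crosstalk")
  expect_true(all(unlist(r[1, grep("^ct_", names(r))])))

  # flattening the SHH response vetoes via significant variation
  cv_flat <- cv
  cv_flat$SHH <- cv$SHH * 0.1
  expect_equal(classify_crosstalk(cv_flat)$classification, "neither")

  # co-activation: same response to single stimuli, new pattern combined
  co <- list(CTRL = cv$SHH, SHH = cv$SHH, EGF = cv$SHH, EGF_SHH = cv$EGF)
  rco <- classify_crosstalk(co)
  expect_equal(rco$classification, "coactivation")

  # cross-talk and co-activation are mutually exclusive on random curves
  set.seed(55)
  for (i in 1:50) {
    curves <- lapply(1:4, function(j) rnorm(14))
    names(curves) <- c("CTRL", "SHH", "EGF", "EGF_SHH")
    r <- classify_crosstalk(curves)
    expect_false(all(unlist(r[1, grep("^ct_", names(r))])) &&
                   all(unlist(r[1, grep("^co_", names(r))])))
  }
})

test_that("the two-stage screen recovers planted patterns and only them", {
  cfg <- sim_config(n_genes = 300, n_dynamic = 90, n_modules = 4,
                    n_crosstalk = 12, n_coactivation = 6, seed = 3)
  st <- simulate_study(cfg)
  drg <- list(); raw <- list()
  for (cc in names(st$conditions)) {
    x <- center_profiles(median_over_replicates(st$conditions[[cc]]))
    drg[[cc]] <- detect_drgs(x)
    raw[[cc]] <- profile_matrix(x)
  }
  ref <- drg$SHH$gene_id[drg$SHH$is_drg]
  gs <- ihc_cluster(attr(drg$SHH, "fitted")[ref, , drop = FALSE],
                    st$truth$time_grid, condition = "SHH")
  scr <- screen_grms(gs, raw)
  found_ct <- scr$gene_report$gene_id[scr$gene_report$classification == "crosstalk"]
  found_co <- scr$gene_report$gene_id[scr$gene_report$classification == "coactivation"]
  expect_gte(mean(st$truth$crosstalk_genes %in% found_ct), 0.9)
  expect_gte(mean(st$truth$coactivation_genes %in% found_co), 0.8)
  # the two planted classes are never confused
  expect_length(intersect(found_ct, st$truth$coactivation_genes), 0)
  expect_length(intersect(found_co, st$truth$crosstalk_genes), 0)

  # a study without planted patterns yields empty gene lists
  cfg0 <- sim_config(n_genes = 150, n_dynamic = 40, n_modules = 3, seed = 6)
  st0 <- simulate_study(cfg0)
  drg0 <- list(); raw0 <- list()
  for (cc in names(st0$conditions)) {
    x <- center_profiles(median_over_replicates(st0$conditions[[cc]]))
    drg0[[cc]] <- detect_drgs(x)
    raw0[[cc]] <- profile_matrix(x)
  }
  ref0 <- drg0$SHH$gene_id[drg0$SHH$is_drg]
  gs0 <- ihc_cluster(attr(drg0$SHH, "fitted")[ref0, , drop = FALSE],
                     st0$truth$time_grid, condition = "SHH")
  scr0 <- screen_grms(gs0, raw0)
  expect_equal(sum(scr0$gene_report$classification %in%
                     c("crosstalk", "coactivation")), 0)
})
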