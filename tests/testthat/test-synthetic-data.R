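test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genes = 10, n_dynamic = 20), "n_dynamic")
  expect_error(sim_config(n_dynamic = 10, n_crosstalk = 8, n_coactivation = 8),
               "n_crosstalk")
  expect_error(sim_config(n_timepoints = 7), "8 time points")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
})

test_that("template curves are smooth, scaled and mutually separable", {
  tg <- seq(0, 24, length.out = 14)
  one <- make_template_curves(1, tg, 2, seed = 5)
  expect_equal(dim(one), c(1L, 14L))
  expect_equal(diff(range(one)), 2)

  expect_error(make_template_curves(2, tg, 0, seed = 1), "amplitude")

  # pairwise separability verified with the classical rank-difference
  # formula, not the package's correlation helper
  tpl <- make_template_curves(6, tg, 3, seed = 1)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_lt(rank_formula_rho(tpl[i, ], tpl[j, ]), 0.7)
    }
  }
})

test_that("simulated conditions follow the additive noise model", {
  # no dynamic genes: everything is mean-zero noise
  cfg0 <- sim_config(n_genes = 50, n_dynamic = 0, n_modules = 1, seed = 2)
  tpl <- make_template_curves(1, sim_time_grid(cfg0), 3, seed = 2)
  sim0 <- simulate_condition(cfg0, tpl, rep(0L, 50), seed = 3)
  expect_equal(dim(sim0$data), c(50L, 14L, 3L))
  expect_lt(abs(mean(sim0$data$values)), 0.05)

  # noiseless limit: observations equal the planted templates exactly
  cfgn <- sim_config(n_genes = 10, n_dynamic = 10, n_modules = 2,
                     noise_sd = 1e-12, seed = 6)
  tpl2 <- make_template_curves(2, sim_time_grid(cfgn), 3, seed = 6)
  simn <- simulate_condition(cfgn, tpl2, rep(1:2, 5), seed = 6)
  for (g in 1:10) {
    expect_equal(unname(simn$data$values[g, , 1]),
                 unname(tpl2[rep(1:2, 5)[g], ]), tolerance = 1e-9)
  }

  # determinism: same seed, bit-identical draws
  again <- simulate_condition(cfgn, tpl2, rep(1:2, 5), seed = 6)
  expect_identical(simn$data$values, again$data$values)
})

test_that("empirical residual variance matches the configured noise", {
  cfg <- sim_config(n_genes = 1000, n_dynamic = 300, n_modules = 5,
                    noise_sd = 0.5, seed = 7)
  tpl <- make_template_curves(5, sim_time_grid(cfg), 3, seed = 7)
  assign <- c(rep(1:5, length.out = 300), rep(0L, 700))
  sim <- simulate_condition(cfg, tpl, assign, seed = 7)
  signal <- matrix(0, 1000, 14)
  signal[1:300, ] <- tpl[assign[1:300], ]
  resid <- sweep(sim$data$values, c(1, 2), signal)
  # direct summation oracle for the pooled variance
  v <- sum(resid^2) / length(resid)
  expect_lt(abs(v - 0.25) / 0.25, 0.05)
})

test_that("planted patterns satisfy their defining criteria by construction", {
  cfg <- sim_config(n_genes = 200, n_dynamic = 80, n_modules = 4,
                    n_crosstalk = 20, n_coactivation = 10, seed = 3)
  st <- simulate_study(cfg)
  tr <- st$truth
  expect_length(intersect(tr$crosstalk_genes, tr$coactivation_genes), 0)
  expect_equal(sum(tr$drg_flags[, "SHH"]), 80)
  expect_equal(sum(tr$drg_flags[, "CTRL"]), 80 - 20)  # cross-talk flat in CTRL

  # re-evaluate the criteria directly on the noiseless planted curves
  noiseless <- lapply(colnames(tr$module_labels), function(cc) {
    lab <- tr$module_labels[, cc]
    m <- matrix(0, nrow(tr$module_labels), length(tr$time_grid),
                dimnames = list(rownames(tr$module_labels), NULL))
    m[lab > 0, ] <- tr$templates[lab[lab > 0], ]
    m
  })
  names(noiseless) <- colnames(tr$module_labels)
  for (g in tr$crosstalk_genes) {
    r <- classify_crosstalk(lapply(noiseless, function(m) m[g, ]))
    expect_equal(r$classification, "crosstalk")
  }
  for (g in tr$coactivation_genes) {
    r <- classify_crosstalk(lapply(noiseless, function(m) m[g, ]))
    expect_equal(r$classification, "coactivation")
  }

  # determinism of the whole study
  st2 <- simulate_study(cfg)
  for (cc in names(st$conditions)) {
    expect_identical(st$conditions[[cc]]$values, st2$conditions[[cc]]$values)
  }
})

test_that("a study writes to disk with its ground-truth sidecar", {
  cfg <- sim_config(n_genes = 20, n_dynamic = 8, n_modules = 2,
                    n_crosstalk = 3, seed = 8)
  st <- simulate_study(cfg)
  dir <- tempfile()
  write_study(st, dir)
  expect_setequal(list.files(dir),
                  c("CTRL.tsv", "SHH.tsv", "EGF.tsv", "EGF_SHH.tsv",
                    "ground_truth.json"))
  back <- read_expression_table(file.path(dir, "SHH.tsv"), "SHH")
  expect_equal(back$values, st$conditions$SHH$values, tolerance = 1e-12)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_setequal(gt$crosstalk_genes, st$truth$crosstalk_genes)
})
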