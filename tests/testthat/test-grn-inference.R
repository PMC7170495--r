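test_that("rate-curve estimation matches closed-form derivatives", {
  tg <- seq(0, 10, length.out = 30)
  expect_lt(max(abs(estimate_derivatives(rbind(rep(2, 30)), tg))), 1e-8)
  expect_lt(max(abs(estimate_derivatives(rbind(3 * tg), tg) - 3)), 1e-6)

  tg2 <- seq(0, 2 * pi, length.out = 50)
  d <- estimate_derivatives(rbind(sin(tg2)), tg2)
  expect_lt(max(abs(d - cos(tg2))[5:45]), 0.05)
})

test_that("a single decaying module recovers its self-regulation", {
  tg <- seq(0, 3, length.out = 30)
  m <- rbind(GRM1 = exp(-tg))
  fit <- fit_grn(m, tg)
  expect_true(fit$support[1, 1])
  expect_lt(abs(fit$coefficients[1, 1] - (-1)) / 1, 0.05)
  expect_lt(abs(fit$intercepts[1]), 0.05)
})

test_that("constant modules give an empty static model", {
  m <- rbind(GRM1 = rep(2, 14), GRM2 = rep(-1, 14))
  fit <- fit_grn(m, seq(0, 13))
  expect_equal(sum(fit$support), 0)
  expect_equal(unname(fit$intercepts), c(0, 0))
})

test_that("noiseless small systems are identified exactly", {
  # selection and refit given the exact rate curves
  sys <- simulate_grn_system(Q = 4, t_grid = seq(0, 3, length.out = 14),
                             n_traj = 4, noise_sd = 0, seed = 5)
  A <- t(sys$coefficients)
  td <- lapply(sys$clean, function(m) {
    d <- A %*% m
    dimnames(d) <- dimnames(m)
    d
  })
  fit <- fit_grn(sys$clean, sys$t_grid, derivatives = td)
  expect_equal(unname(fit$support), unname(sys$support))
  expect_lt(max(abs(fit$coefficients - sys$coefficients)), 1e-6)

  # the full path (spline derivatives included) on a grid dense enough
  # that the derivative error is negligible
  sys2 <- simulate_grn_system(Q = 4, t_grid = seq(0, 3, length.out = 30),
                              n_traj = 4, noise_sd = 0, seed = 5)
  fit2 <- fit_grn(sys2$clean, sys2$t_grid)
  expect_equal(unname(fit2$support), unname(sys2$support))
  on_support <- fit2$support & sys2$support
  expect_true(all(sign(fit2$coefficients[on_support]) ==
                    sign(sys2$coefficients[on_support])))
  expect_lt(max(abs(fit2$coefficients[on_support] -
                      sys2$coefficients[on_support])), 0.05)
})

test_that("refit residuals are orthogonal to the selected regressors", {
  sys <- simulate_grn_system(Q = 5, n_traj = 3, noise_sd = 0.02, seed = 17)
  fit <- fit_grn(sys$curves, sys$t_grid)
  X <- t(do.call(cbind, sys$curves))
  D <- do.call(cbind, lapply(sys$curves, estimate_derivatives,
                             time_grid = sys$t_grid))
  for (q in seq_len(5)) {
    sel <- which(fit$support[, q])
    if (length(sel) == 0) next
    resid <- D[q, ] - fit$intercepts[q] -
      X[, sel, drop = FALSE] %*% fit$coefficients[sel, q]
    expect_lt(max(abs(crossprod(X[, sel, drop = FALSE], resid))), 1e-6)
  }
})

test_that("rescaling a module's curve rescales its outgoing coefficients", {
  sys <- simulate_grn_system(Q = 4, n_traj = 4, noise_sd = 0, seed = 5)
  fit <- fit_grn(sys$clean, sys$t_grid)
  c_scale <- 4
  scaled <- lapply(sys$clean, function(m) {
    m[2, ] <- c_scale * m[2, ]
    m
  })
  # derivatives of the scaled module scale too; selection fixed by passing
  # the planted support through the same OLS refit
  d_scaled <- lapply(scaled, estimate_derivatives, time_grid = sys$t_grid)
  fit2 <- fit_grn(scaled, sys$t_grid, derivatives = d_scaled)
  out_edges <- which(fit$support[2, ] & fit2$support[2, ])
  out_edges <- setdiff(out_edges, 2)
  expect_gt(length(out_edges), 0)
  expect_equal(fit2$coefficients[2, out_edges],
               fit$coefficients[2, out_edges] / c_scale, tolerance = 1e-3)
})

test_that("the exported graph mirrors the fitted support", {
  sys <- simulate_grn_system(Q = 6, n_traj = 4, noise_sd = 0.02, seed = 23)
  fit <- fit_grn(sys$curves, sys$t_grid)
  g <- network_from_model(fit)
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  expect_equal(unname(adj > 0), unname(fit$support))

  edges <- grn_edges(fit)
  expect_equal(nrow(edges), sum(fit$support))
  expect_true(all(edges$sign[edges$weight > 0] == "stimulation"))

  # degenerate supports
  empty <- fit
  empty$coefficients[] <- 0
  empty$support[] <- FALSE
  expect_equal(igraph::ecount(network_from_model(empty)), 0)
})

test_that("duplicate module curves are rejected", {
  m <- rbind(GRM1 = sin(1:14), GRM2 = sin(1:14))
  expect_error(fit_grn(m, seq(0, 13)), "duplicated")
})
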