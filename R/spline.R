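# Natural cubic smoothing-spline engine.
#
# Every gene in a dataset is observed on the same time grid, so the hat
# matrix S(lambda) = (I + lambda * P)^-1 is shared across genes and each
# candidate lambda is applied to the whole expression matrix at once.
# P is the Reinsch curvature penalty: P = t(D) %*% solve(W) %*% D, so that
# fitted = argmin ||y - f||^2 + lambda * integral f''(t)^2 dt over natural
# cubic splines with knots at the observation times.

# Reinsch penalty matrices for knots t (strictly increasing, length >= 3)
.spline_penalty <- function(t) {
  K <- length(t)
  if (K < 3) stop("need at least 3 time points for a cubic smoothing spline")
  h <- diff(t)
  D <- matrix(0, K - 2L, K)
  W <- matrix(0, K - 2L, K - 2L)
  for (i in seq_len(K - 2L)) {
    D[i, i] <- 1 / h[i]
    D[i, i + 1L] <- -(1 / h[i] + 1 / h[i + 1L])
    D[i, i + 2L] <- 1 / h[i + 1L]
    W[i, i] <- (h[i] + h[i + 1L]) / 3
    if (i < K - 2L) {
      W[i, i + 1L] <- h[i + 1L] / 6
      W[i + 1L, i] <- h[i + 1L] / 6
    }
  }
  list(D = D, W = W, P = crossprod(D, solve(W, D)))
}

#' Default smoothing-parameter grid
#'
#' Fifty log-spaced penalty values spanning near-interpolating
#' (effective df close to the number of time points) to near-linear fits
#' (effective df close to 2). The grid scales with `range(t)^3` so that
#' generalized cross-validation selects the same fit whether time is
#' measured in hours or minutes.
#'
#' @param t numeric time grid.
#' @param n number of grid values.
#' @return numeric vector of penalty values, increasing.
#' @export
default_lambda_grid <- function(t, n = 50L) {
  diff(range(t))^3 * 10^seq(-8, 2, length.out = n)
}

# Smooth all rows of Y (genes x K) on grid t by GCV over a fixed lambda grid.
# Returns fitted matrix plus per-gene lambda index, edf, rss and gcv score.
.smooth_profiles <- function(Y, t, lambda = NULL, max_edf = NULL) {
  Y <- rbind(Y)  # promote vector to 1 x K
  K <- ncol(Y)
  stopifnot(length(t) == K)
  if (is.null(lambda)) lambda <- default_lambda_grid(t)
  pen <- .spline_penalty(t)
  if (!is.null(max_edf)) {
    # keep only penalties leaving at least K - max_edf residual df, so the
    # F reference distribution has a usable denominator
    edf_all <- vapply(lambda, function(l) sum(diag(solve(diag(K) + l * pen$P))), 0)
    lambda <- lambda[edf_all <= max_edf]
    if (length(lambda) == 0L) stop("no smoothing penalty satisfies the edf bound")
  }
  n <- nrow(Y)
  best_gcv <- rep(Inf, n)
  best_idx <- rep(NA_integer_, n)
  best_fit <- matrix(0, n, K)
  edf <- numeric(length(lambda))
  IK <- diag(K)
  for (l in seq_along(lambda)) {
    S <- solve(IK + lambda[l] * pen$P)
    edf[l] <- sum(diag(S))
    fit_l <- Y %*% S  # S symmetric
    rss_l <- rowSums((Y - fit_l)^2)
    gcv_l <- K * rss_l / (K - edf[l])^2
    upd <- gcv_l < best_gcv
    if (any(upd)) {
      best_gcv[upd] <- gcv_l[upd]
      best_idx[upd] <- l
      best_fit[upd, ] <- fit_l[upd, , drop = FALSE]
    }
  }
  list(
    fitted = best_fit,
    lambda_index = best_idx,
    lambda = lambda[best_idx],
    edf = edf[best_idx],
    rss = rowSums((Y - best_fit)^2),
    gcv = best_gcv,
    lambda_grid = lambda,
    edf_grid = edf,
    penalty = pen,
    t = t
  )
}

# First derivative of a natural cubic spline given its values at the knots.
# gamma (the second derivatives at interior knots) comes from the Reinsch
# system; the natural boundary condition sets gamma = 0 at the end knots.
.spline_deriv_values <- function(f, t, pen) {
  f <- as.numeric(f)
  K <- length(t)
  h <- diff(t)
  gam <- c(0, solve(pen$W, pen$D %*% f), 0)
  d <- numeric(K)
  i <- seq_len(K - 1L)
  d[i] <- diff(f) / h - h * (2 * gam[i] + gam[i + 1L]) / 6
  d[K] <- (f[K] - f[K - 1L]) / h[K - 1L] + h[K - 1L] * (gam[K - 1L] + 2 * gam[K]) / 6
  d
}

#' Fit a penalized cubic smoothing spline to one expression profile
#'
#' Fits a natural cubic smoothing spline with the curvature penalty
#' `lambda * integral f''^2`, choosing `lambda` by generalized
#' cross-validation (GCV) over a fixed log-spaced grid. Linear trends lie in
#' the null space of the penalty and are reproduced exactly at large
#' `lambda`; at the small end of the grid the fit approaches interpolation.
#'
#' Dynamic-response testing assumes a minimum of 8 time points; shorter
#' series are refused.
#'
#' @param y numeric profile (centered expression values), length K.
#' @param t time grid, strictly increasing, length K.
#' @param lambda optional penalty grid; defaults to [default_lambda_grid()].
#' @param gene_id optional identifier carried in the result.
#' @return an object of class `smooth_fit` with elements `fitted`, `lambda`,
#'   `edf` (effective degrees of freedom, trace of the hat matrix),
#'   `rss_alt` (residual sum of squares), `t`, `y`, and `basis` (a short
#'   description of the spline basis).
#' @examples
#' t <- seq(0, 24, length.out = 14)
#' fit <- fit_smoothing_spline(sin(t / 4) + rnorm(14, 0, 0.2), t)
#' fit$edf
#' @export
fit_smoothing_spline <- function(y, t, lambda = NULL, gene_id = NA_character_) {
  y <- as.numeric(y)
  if (length(t) < 8L) {
    stop("at least 8 time points are required for spline smoothing and the ",
         "functional F-test; got ", length(t))
  }
  if (length(y) != length(t)) stop("y and t must have equal length")
  if (any(!is.finite(y))) stop("non-finite values in profile")
  if (any(diff(t) <= 0)) stop("time grid must be strictly increasing")
  sm <- .smooth_profiles(y, t, lambda)
  structure(
    list(
      gene_id = gene_id,
      t = t,
      y = y,
      fitted = as.numeric(sm$fitted),
      lambda = unname(sm$lambda),
      lambda_index = unname(sm$lambda_index),
      lambda_grid = sm$lambda_grid,
      edf = unname(sm$edf),
      rss_alt = unname(sm$rss),
      gcv = unname(sm$gcv),
      basis = list(type = "natural cubic spline", order = 4L, knots = t),
      penalty = sm$penalty
    ),
    class = "smooth_fit"
  )
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat("Smoothing-spline fit", if (!is.na(x$gene_id)) paste0("(", x$gene_id, ")"),
      "\n  K =", length(x$t), " edf =", signif(x$edf, 4),
      " lambda =", signif(x$lambda, 4), " RSS =", signif(x$rss_alt, 4), "\n")
  invisible(x)
}

#' First derivative of a fitted smoothing spline on its time grid
#'
#' Analytic derivative of the fitted natural cubic spline, evaluated at the
#' knots (no finite differencing of raw values).
#'
#' @param fit a `smooth_fit` object.
#' @return numeric vector of derivative values on `fit$t`.
#' @export
spline_derivative <- function(fit) {
  stopifnot(inherits(fit, "smooth_fit"))
  .spline_deriv_values(fit$fitted, fit$t, fit$penalty)
}
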