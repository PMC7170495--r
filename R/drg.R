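# Dynamic response gene (DRG) detection.
#
# Each gene's centered profile y is modelled as a smooth signal plus i.i.d.
# noise; the gene is dynamic when the smooth signal is not identically
# zero. The test compares the null model (centered profile identically 0;
# the centering mean is its single fitted parameter) with the GCV-selected
# smoothing-spline fit:
#
#   F = [(RSS0 - RSS1) / (edf - 1)] / [RSS1 / (K - edf)]
#
# with RSS0 = sum(y^2), RSS1 the spline residual sum of squares and edf the
# trace of the smoother matrix. Parametric p-values use the F reference
# distribution with (edf - 1, K - edf) degrees of freedom; the permutation
# mode instead compares each gene's F against F statistics recomputed after
# shuffling the time labels, which is exact under exchangeable noise.

# vectorized F statistic for rows of Y (genes x K, centered)
.fstat_matrix <- function(Y, t, lambda = NULL) {
  Y <- rbind(Y)
  # the alternative fit must leave residual degrees of freedom to
  # estimate the noise variance in the denominator of F, so penalties
  # giving edf above K - 4 are excluded from the testing fit
  sm <- .smooth_profiles(Y, t, lambda, max_edf = ncol(Y) - 4)
  K <- ncol(Y)
  rss0 <- rowSums(Y^2)
  rss1 <- sm$rss
  df1 <- sm$edf - 1
  df2 <- K - sm$edf
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  f[rss0 == 0] <- 0                       # exactly null input
  f[rss1 == 0 & rss0 > 0] <- Inf          # perfect fit of a non-null profile
  f[f < 0] <- 0                           # numerical guard near rss0 ~ rss1
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[f == 0] <- 1
  p[is.infinite(f)] <- 0
  list(f = f, p = p, edf = sm$edf, rss0 = rss0, rss1 = rss1, fitted = sm$fitted,
       lambda_index = sm$lambda_index)
}

#' Functional F-test for a dynamic response
#'
#' Tests whether a gene's smoothed centered trajectory differs from the
#' zero function, using the fit returned by [fit_smoothing_spline()].
#'
#' @param fit a `smooth_fit` object.
#' @param y the centered profile the fit was computed on (defaults to
#'   `fit$y`).
#' @param mode `"parametric"` (F reference distribution) or
#'   `"permutation"` (time labels of `y` are shuffled and the full
#'   fit-and-test procedure is re-run per permutation).
#' @param n_perm permutations for `mode = "permutation"`.
#' @param seed seed for the permutations.
#' @return list with `f_ratio` and `p_value`.
#' @export
f_ratio_test <- function(fit, y = fit$y, mode = c("parametric", "permutation"),
                         n_perm = 200L, seed = 1L) {
  stopifnot(inherits(fit, "smooth_fit"))
  mode <- match.arg(mode)
  K <- length(fit$t)
  rss0 <- sum(y^2)
  rss1 <- fit$rss_alt
  df1 <- fit$edf - 1
  df2 <- K - fit$edf
  f <- if (rss0 == 0) 0 else if (rss1 == 0) Inf else ((rss0 - rss1) / df1) / (rss1 / df2)
  f <- max(f, 0)
  if (mode == "parametric") {
    p <- if (f == 0) 1 else if (is.infinite(f)) 0 else
      stats::pf(f, df1, df2, lower.tail = FALSE)
  } else {
    set.seed(seed)
    perm <- matrix(NA_real_, n_perm, K)
    for (b in seq_len(n_perm)) perm[b, ] <- y[sample.int(K)]
    fb <- .fstat_matrix(perm, fit$t, fit$lambda_grid)$f
    p <- (1 + sum(fb >= f)) / (n_perm + 1)
  }
  list(f_ratio = f, p_value = p)
}

#' Rank genes by interquartile range and keep the top fraction
#'
#' Flat trajectories carry no dynamic information; the estimation subset
#' keeps the genes with the widest centered profiles. Quartiles use the
#' linear-interpolation convention (`stats::quantile` type 7); ties are
#' broken by gene id.
#'
#' @param x a centered single-replicate `expr_tc`.
#' @param top_fraction fraction of genes to keep, in (0, 1].
#' @return character vector of gene ids, IQR-descending.
#' @export
rank_by_iqr <- function(x, top_fraction = 1) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  m <- profile_matrix(x)
  iqr <- apply(m, 1L, stats::IQR, type = 7)
  ord <- order(-iqr, rownames(m))
  k <- ceiling(top_fraction * nrow(m))
  rownames(m)[ord][seq_len(k)]
}

#' Detect dynamic response genes
#'
#' Smooths every centered profile (shared GCV grid), computes the
#' functional F-ratio and p-value per gene, adjusts for multiple testing
#' and flags genes with adjusted p below `alpha`.
#'
#' In permutation mode the time labels of every gene are shuffled
#' `n_perm` times and the full fit-and-test procedure is re-run on each
#' shuffle, giving an assumption-free p-value that stays calibrated in
#' spite of the data-driven smoothing-parameter selection.
#'
#' @param x a centered single-replicate `expr_tc`.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param mtc multiple-testing correction passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @param mode `"parametric"` or `"permutation"`.
#' @param n_perm permutations per gene (default 199).
#' @param seed permutation seed.
#' @param lambda optional smoothing-parameter grid.
#' @return a `data.frame` (one row per gene, F-ratio descending, ties by
#'   gene id) with columns `gene_id`, `f_ratio`, `p_value`, `p_adj`,
#'   `iqr`, `edf`, `is_drg`, `rank`, and the fitted smooth curves in
#'   `attr(, "fitted")`.
#' @export
detect_drgs <- function(x, alpha = 0.05, mtc = "BH",
                        mode = c("parametric", "permutation"),
                        n_perm = 199L, seed = 1L, lambda = NULL) {
  mode <- match.arg(mode)
  m <- profile_matrix(x)
  if (nrow(m) == 0L) {
    out <- data.frame(gene_id = character(), f_ratio = numeric(),
                      p_value = numeric(), p_adj = numeric(), iqr = numeric(),
                      edf = numeric(), is_drg = logical(), rank = integer())
    attr(out, "fitted") <- matrix(numeric(), 0L, ncol(m))
    return(out)
  }
  if (ncol(m) < 8L) {
    stop("at least 8 time points are required for the functional F-test")
  }
  if (is.null(lambda)) lambda <- default_lambda_grid(x$time_grid)
  st <- .fstat_matrix(m, x$time_grid, lambda)
  p <- st$p
  if (mode == "permutation") {
    # per-gene permutation null: each gene's time labels are shuffled and
    # the full fit-and-test procedure re-run, so the p-value is exact under
    # exchangeable noise regardless of the GCV selection step
    set.seed(seed)
    exceed <- integer(nrow(m))
    for (b in seq_len(n_perm)) {
      perm <- t(apply(m, 1L, sample))
      fb <- .fstat_matrix(perm, x$time_grid, lambda)$f
      exceed <- exceed + (fb >= st$f)
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  p_adj <- stats::p.adjust(p, method = mtc)
  iqr <- apply(m, 1L, stats::IQR, type = 7)
  ord <- order(-st$f, rownames(m))
  out <- data.frame(
    gene_id = rownames(m)[ord],
    f_ratio = st$f[ord],
    p_value = p[ord],
    p_adj = p_adj[ord],
    iqr = iqr[ord],
    edf = st$edf[ord],
    is_drg = (p_adj < alpha)[ord],
    rank = seq_len(nrow(m)),
    row.names = NULL
  )
  fitted <- st$fitted[ord, , drop = FALSE]
  rownames(fitted) <- out$gene_id
  attr(out, "fitted") <- fitted
  attr(out, "time_grid") <- x$time_grid
  out
}

#' Select the top k dynamic genes by F-ratio
#'
#' Keeps the `k` flagged DRGs with the largest F-ratios (ties broken by
#' gene id). If fewer than `k` genes are DRGs, all of them are returned
#' with a warning.
#'
#' @param records output of [detect_drgs()].
#' @param k number of genes to keep (default 3000).
#' @return character vector of gene ids.
#' @export
top_k_by_fratio <- function(records, k = 3000L) {
  drg <- records[records$is_drg, , drop = FALSE]
  drg <- drg[order(-drg$f_ratio, drg$gene_id), , drop = FALSE]
  if (k >= nrow(drg)) {
    if (k > nrow(drg)) {
      warning("requested top ", k, " but only ", nrow(drg),
              " dynamic genes available; returning all")
    }
    return(drg$gene_id)
  }
  drg$gene_id[seq_len(max(k, 0L))]
}
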