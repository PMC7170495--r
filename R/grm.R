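# Gene response modules (GRMs) by iterative hierarchical clustering (IHC).
#
# IHC refines an initial average-linkage cut with three repeated phases:
# merge cluster pairs whose mean curves are similar, reassign every gene to
# the best-correlated mean (genes similar to no mean become singletons),
# then recompute means. It captures both large and very small clusters and
# chooses the number of clusters automatically.

.mean_curves <- function(m, labels) {
  agg <- rowsum(m, labels)
  agg <- agg / as.vector(table(labels)[rownames(agg)])
  agg[order(as.integer(rownames(agg))), , drop = FALSE]  # numeric label order
}

#' Cluster temporal profiles into gene response modules
#'
#' @param profiles numeric matrix, genes in rows (row names = gene ids),
#'   time points in columns; typically the smoothed curves of the selected
#'   DRGs.
#' @param time_grid observation times (carried into the result).
#' @param rho_threshold Spearman similarity threshold in (0, 1): clusters
#'   merge when their mean curves correlate at or above it, and a gene stays
#'   in a cluster only if it correlates with the cluster mean at or above
#'   it (default 0.7, the pipeline's global similarity cutoff).
#' @param max_iter iteration cap for the merge/reassign/recenter loop.
#' @return a `grm_set`: list with `modules` (each having `module_id`,
#'   `members`, `mean_curve`, `size`), `time_grid`, `condition`, and
#'   `labels` (named integer vector; module 1 is the largest).
#' @export
ihc_cluster <- function(profiles, time_grid = NULL, rho_threshold = 0.7,
                        max_iter = 100L, condition = NA_character_) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 1L)
  if (rho_threshold <= 0 || rho_threshold >= 1) stop("rho_threshold must be in (0,1)")
  if (any(!is.finite(profiles))) stop("non-finite profiles")
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- sprintf("g%d", seq_len(nrow(profiles)))
  }
  if (is.null(time_grid)) time_grid <- seq_len(ncol(profiles)) - 1
  m <- profiles
  n <- nrow(m)

  # phase 0: average-linkage hierarchical clustering on 1 - Spearman,
  # cut at distance 1 - rho_threshold
  if (n == 1L) {
    labels <- c(1L)
  } else {
    rho <- .spearman_rows(m, m)
    rho[is.na(rho)] <- 0  # constant profiles are similar to nothing
    hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
    labels <- stats::cutree(hc, h = 1 - rho_threshold)
  }
  names(labels) <- rownames(m)

  canon <- function(l) match(l, unique(l))
  for (iter in seq_len(max_iter)) {
    old <- canon(labels)
    # (a) merge clusters with similar mean curves
    repeat {
      mc <- .mean_curves(m, labels)
      if (nrow(mc) < 2L) break
      rho <- .spearman_rows(mc, mc)
      rho[is.na(rho)] <- -Inf
      diag(rho) <- -Inf
      if (max(rho) < rho_threshold) break
      best <- which(rho == max(rho), arr.ind = TRUE)[1L, ]
      a <- rownames(mc)[best[1L]]; b <- rownames(mc)[best[2L]]
      labels[labels == as.integer(b)] <- as.integer(a)
    }
    # (b) reassign each gene to the best-correlated mean (ties: first
    # cluster in label order), else make it a singleton
    mc <- .mean_curves(m, labels)
    rho <- .spearman_rows(m, mc)
    rho[is.na(rho)] <- -Inf
    best <- apply(rho, 1L, which.max)
    best_rho <- rho[cbind(seq_len(n), best)]
    new_labels <- as.integer(rownames(mc))[best]
    next_free <- max(labels) + 1L
    for (i in which(best_rho < rho_threshold)) {
      new_labels[i] <- next_free
      next_free <- next_free + 1L
    }
    labels <- new_labels
    names(labels) <- rownames(m)
    if (identical(canon(labels), old)) break
  }

  # number modules by size descending (ties by first appearance)
  sizes <- table(labels)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  renum <- stats::setNames(seq_along(ord), names(sizes)[ord])
  labels <- stats::setNames(as.integer(renum[as.character(labels)]), rownames(m))
  mc <- .mean_curves(m, labels)
  modules <- lapply(sort(as.integer(rownames(mc))), function(id) {
    members <- names(labels)[labels == id]
    list(module_id = paste0("GRM", id),
         condition = condition,
         members = members,
         mean_curve = as.numeric(mc[as.character(id), ]),
         size = length(members))
  })
  structure(list(modules = modules, labels = labels, time_grid = time_grid,
                 condition = condition, rho_threshold = rho_threshold),
            class = "grm_set")
}

#' @export
print.grm_set <- function(x, ...) {
  sizes <- vapply(x$modules, `[[`, 1L, "size")
  cat("GRM set", if (!is.na(x$condition)) paste0("[", x$condition, "]"),
      ": ", length(x$modules), " modules over ", sum(sizes), " genes; ",
      "largest = ", max(sizes), "\n", sep = "")
  invisible(x)
}

#' Filter large-size gene response modules
#'
#' A large-size GRM (LS-GRM) contains `min_size` (default 70) or more
#' genes; the bound is inclusive.
#'
#' @param grms a `grm_set` or plain list of modules.
#' @param min_size minimum module size.
#' @return list of modules with `size >= min_size`, order preserved.
#' @export
large_size_grms <- function(grms, min_size = 70L) {
  mods <- if (inherits(grms, "grm_set")) grms$modules else grms
  Filter(function(m) m$size >= min_size, mods)
}

#' Mean-curve matrix of a module list
#' @param grms a `grm_set` or list of modules.
#' @return matrix modules x time, row names = module ids.
#' @export
grm_mean_curves <- function(grms) {
  mods <- if (inherits(grms, "grm_set")) grms$modules else grms
  out <- do.call(rbind, lapply(mods, `[[`, "mean_curve"))
  rownames(out) <- vapply(mods, `[[`, "", "module_id")
  out
}

#' Pair modules across two conditions by greedy best correlation
#'
#' Repeatedly pairs the yet-unmatched module pair (one from each side) with
#' the highest Spearman correlation between mean curves until one side is
#' exhausted.
#'
#' @param grms_a,grms_b module lists (e.g. LS-GRMs) on the same time grid.
#' @return `data.frame` with columns `module_a`, `module_b`, `rho`, in
#'   pairing order.
#' @export
match_modules <- function(grms_a, grms_b) {
  A <- grm_mean_curves(grms_a)
  B <- grm_mean_curves(grms_b)
  rho <- .spearman_rows(A, B)
  rho[is.na(rho)] <- -Inf
  pairs <- list()
  while (nrow(rho) > 0L && ncol(rho) > 0L && any(is.finite(rho))) {
    best <- which(rho == max(rho), arr.ind = TRUE)[1L, ]
    pairs[[length(pairs) + 1L]] <- data.frame(
      module_a = rownames(rho)[best[1L]],
      module_b = colnames(rho)[best[2L]],
      rho = rho[best[1L], best[2L]]
    )
    rho <- rho[-best[1L], -best[2L], drop = FALSE]
  }
  if (length(pairs) == 0L) {
    return(data.frame(module_a = character(), module_b = character(),
                      rho = numeric()))
  }
  do.call(rbind, pairs)
}
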