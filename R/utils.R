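# shared small helpers

#' Spearman rank correlation of two curves
#'
#' Average ranks for ties; returns `NA` when either curve is constant
#' (zero rank variance makes the correlation undefined).
#'
#' @param x,y numeric vectors of equal length.
#' @return Spearman's rho, or `NA_real_`.
#' @export
spearman_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

# Spearman correlation between the rows of A (n x K) and rows of B (m x K),
# returning an n x m matrix; constant rows yield NA entries.
.spearman_rows <- function(A, B) {
  ra <- t(apply(A, 1L, rank))
  rb <- t(apply(B, 1L, rank))
  const_a <- apply(ra, 1L, stats::sd) == 0
  const_b <- apply(rb, 1L, stats::sd) == 0
  out <- suppressWarnings(stats::cor(t(ra), t(rb)))
  out[const_a, ] <- NA_real_
  out[, const_b] <- NA_real_
  out
}

# rbind data frames with differing column sets, filling missing with NA
.pad_rbind <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA
    r[cols]
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Percent change between two counts
#'
#' `100 * (new - reference) / reference`, the arithmetic behind statements
#' like "50% more dynamic genes than control".
#'
#' @param new,reference counts.
#' @return percent change.
#' @export
percent_change <- function(new, reference) 100 * (new - reference) / reference
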