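# ExpressionTimeCourse: the pipeline's universal input. A condition's data
# are a genes x timepoints x replicates array on a common time grid starting
# at 0 h; replicates share the biological signal and differ only in noise.

#' Construct an expression time course
#'
#' @param values numeric array `n_genes x K x N` (or an `n_genes x K` matrix,
#'   promoted to a single replicate). `NA` cells are allowed (missing
#'   replicate measurements); they are resolved by [median_over_replicates()].
#' @param time_grid hours, strictly increasing, first point 0.
#' @param gene_ids character vector of unique gene identifiers.
#' @param condition condition label, e.g. one of `"CTRL"`, `"SHH"`, `"EGF"`,
#'   `"EGF_SHH"`.
#' @return an object of class `expr_tc`.
#' @export
expression_time_course <- function(values, time_grid, gene_ids,
                                   condition = "CTRL") {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (length(dim(values)) != 3L) stop("values must be a genes x time x replicate array")
  n <- dim(values)[1L]; K <- dim(values)[2L]; N <- dim(values)[3L]
  if (length(gene_ids) != n) stop("gene_ids length does not match values")
  gene_ids <- as.character(gene_ids)
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0) stop("duplicated gene id(s): ", paste(dup, collapse = ", "))
  if (length(time_grid) != K) stop("time_grid length does not match values")
  if (any(diff(time_grid) <= 0)) stop("time_grid must be strictly increasing")
  if (time_grid[1L] != 0) stop("time grid must start at 0")
  if (any(is.nan(values) | is.infinite(values))) stop("non-finite values in expression array")
  dimnames(values) <- list(gene_ids, NULL, NULL)
  structure(
    list(values = values, time_grid = as.numeric(time_grid),
         gene_ids = gene_ids, condition = as.character(condition)),
    class = "expr_tc"
  )
}

#' @export
print.expr_tc <- function(x, ...) {
  d <- dim(x$values)
  cat("Expression time course [", x$condition, "]: ",
      d[1L], " genes x ", d[2L], " time points x ", d[3L], " replicate(s); ",
      "t = ", x$time_grid[1L], "..", x$time_grid[length(x$time_grid)], " h\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_tc <- function(x) dim(x$values)

# single-replicate matrix view (genes x K), used throughout the pipeline
#' Extract the genes x time matrix of a single-replicate time course
#' @param x an `expr_tc` with one replicate.
#' @return numeric matrix with gene ids as row names.
#' @export
profile_matrix <- function(x) {
  stopifnot(inherits(x, "expr_tc"))
  if (dim(x$values)[3L] != 1L) stop("expected a single-replicate time course; collapse replicates first")
  m <- x$values[, , 1L, drop = FALSE]
  dim(m) <- dim(x$values)[1:2]
  rownames(m) <- x$gene_ids
  m
}

#' Read a tab-separated expression table
#'
#' The expected format has a `gene_id` first column and one column per
#' (time point, replicate) pair, with headers `T<hours>_R<replicate>`, e.g.
#' `T0_R1`, `T1.85_R2`. Every time point must be present for every
#' replicate index.
#'
#' @param path file path.
#' @param condition condition label to attach.
#' @return an [expression_time_course()] object.
#' @export
read_expression_table <- function(path, condition = "CTRL") {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L || names(tab)[1L] != "gene_id") {
    stop("malformed header in ", path, ": first column must be 'gene_id'")
  }
  hdr <- names(tab)[-1L]
  m <- regmatches(hdr, regexec("^T([0-9.]+)_R([0-9]+)$", hdr))
  bad <- which(lengths(m) != 3L)
  if (length(bad) > 0) {
    stop("malformed header column '", hdr[bad[1L]], "' in ", path,
         ": expected T<time>_R<replicate>")
  }
  times <- as.numeric(vapply(m, `[`, "", 2L))
  reps <- as.integer(vapply(m, `[`, "", 3L))
  tg <- sort(unique(times))
  rg <- sort(unique(reps))
  if (length(hdr) != length(tg) * length(rg)) {
    stop("header of ", path, " is not a full time x replicate crossing")
  }
  gene_ids <- tab[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0) {
    stop("duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  num <- suppressWarnings(vapply(tab[-1L], as.numeric, numeric(nrow(tab))))
  num <- rbind(num)  # keep matrix for single-gene tables
  nonnum <- which(is.na(num) & !(toupper(as.matrix(tab[-1L])) %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(nonnum) > 0) {
    stop("non-numeric cell in ", path, " at row ", nonnum[1L, 1L],
         " (gene ", gene_ids[nonnum[1L, 1L]], "), column '", hdr[nonnum[1L, 2L]], "'")
  }
  vals <- array(NA_real_, dim = c(nrow(tab), length(tg), length(rg)))
  for (j in seq_along(hdr)) {
    vals[, match(times[j], tg), match(reps[j], rg)] <- num[, j]
  }
  expression_time_course(vals, tg, gene_ids, condition)
}

#' Write an expression time course as a tab-separated table
#'
#' Inverse of [read_expression_table()]: `gene_id` column plus
#' `T<time>_R<replicate>` columns.
#'
#' @param x an `expr_tc`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expr_tc"))
  d <- dim(x$values)
  cols <- list(gene_id = x$gene_ids)
  for (r in seq_len(d[3L])) {
    for (k in seq_len(d[2L])) {
      cols[[sprintf("T%.15g_R%d", x$time_grid[k], r)]] <- x$values[, k, r]
    }
  }
  utils::write.table(as.data.frame(cols, check.names = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse replicates by their median
#'
#' Per gene and time point, takes the median of the replicate values
#' (robust to unexpected variation in single replicates). `NA` replicate
#' cells are ignored; a gene with no observed replicate at some time point
#' cannot be smoothed and is dropped with a warning.
#'
#' @param x an `expr_tc`.
#' @return an `expr_tc` with one replicate.
#' @export
median_over_replicates <- function(x) {
  stopifnot(inherits(x, "expr_tc"))
  d <- dim(x$values)
  med <- apply(x$values, c(1L, 2L), stats::median, na.rm = TRUE)
  med <- rbind(med)
  all_missing <- rowSums(is.na(med)) > 0
  if (any(all_missing)) {
    warning(sum(all_missing), " gene(s) dropped: no replicate observed at ",
            "some time point (e.g. ", x$gene_ids[which(all_missing)[1L]], ")")
    med <- med[!all_missing, , drop = FALSE]
  }
  expression_time_course(med, x$time_grid, x$gene_ids[!all_missing], x$condition)
}

#' Fold-change ratios relative to time 0 under control
#'
#' Divides every raw expression value by the same gene's control baseline
#' (the control value at t = 0, median across control replicates). By
#' default the ratio is log2-transformed so up- and down-regulation are
#' symmetric; `log2 = FALSE` keeps raw ratios.
#'
#' @param x an `expr_tc` on the raw expression scale.
#' @param control the control-condition `expr_tc`, same genes in the same
#'   order.
#' @param log2 logical; log2-transform the ratio (default `TRUE`).
#' @return an `expr_tc` of (log) fold-change ratios.
#' @export
fold_change_vs_control_t0 <- function(x, control, log2 = TRUE) {
  stopifnot(inherits(x, "expr_tc"), inherits(control, "expr_tc"))
  if (!identical(x$gene_ids, control$gene_ids)) {
    stop("gene sets of x and control must be identical and aligned")
  }
  base <- apply(control$values[, 1L, , drop = FALSE], 1L, stats::median, na.rm = TRUE)
  bad <- which(!is.finite(base) | base <= 0)
  if (length(bad) > 0) {
    stop("non-positive control baseline for gene(s): ",
         paste(utils::head(x$gene_ids[bad], 10L), collapse = ", "))
  }
  vals <- sweep(x$values, 1L, base, "/")
  if (log2) vals <- log2(vals)
  expression_time_course(vals, x$time_grid, x$gene_ids, x$condition)
}

#' Center each gene's temporal profile
#'
#' Subtracts the gene's temporal mean so every profile has mean zero; the
#' functional F-test's null hypothesis (the centered trajectory is
#' identically zero) is formulated on this scale.
#'
#' @param x a single-replicate `expr_tc`.
#' @return an `expr_tc` of centered profiles.
#' @export
center_profiles <- function(x) {
  m <- profile_matrix(x)
  m <- m - rowMeans(m)
  expression_time_course(m, x$time_grid, x$gene_ids, x$condition)
}
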