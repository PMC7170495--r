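# Cross-condition comparison machinery and the cross-talk / co-activation
# classifier.
#
# Similarity between a gene's (or module's) trajectories under two
# conditions is the Spearman correlation of the curves on the common time
# grid. "Differential activity" between two conditions means rho < 0.7
# (strict); "significant variation" means the curve's max-minus-min range
# is at least 1.96 on the standardized log2 fold-change scale (the 0.05
# two-sided normal critical value).
#
# A cross-talk gene responds to each single stimulus (differential vs CTRL
# with significant variation under both SHH and EGF) yet follows a pattern
# under co-stimulation that resembles neither single-stimulus pattern. A
# co-activation gene is unresponsive to either single stimulus (no
# differential activity vs CTRL) but differential under co-stimulation
# versus SHH.

#' Per-gene Spearman correlation between two conditions
#'
#' @param curves_a,curves_b matrices (genes x time) with matching row names
#'   and the same time grid.
#' @return named numeric vector of rho values; `NA` where either curve is
#'   constant (similarity undefined).
#' @export
spearman_between_conditions <- function(curves_a, curves_b) {
  stopifnot(is.matrix(curves_a), is.matrix(curves_b))
  if (!identical(rownames(curves_a), rownames(curves_b))) {
    stop("curves_a and curves_b must cover the same genes in the same order")
  }
  if (ncol(curves_a) != ncol(curves_b)) stop("time grids differ")
  out <- vapply(seq_len(nrow(curves_a)), function(i) {
    spearman_cor(curves_a[i, ], curves_b[i, ])
  }, 0)
  stats::setNames(out, rownames(curves_a))
}

#' Bin a set of correlations into the similarity table
#'
#' Four disjoint, exhaustive bins: similar (`rho > 0.7`), opposite
#' (`rho < -0.7`), near-zero (`|rho| < 0.1`) and other. Undefined (`NA`)
#' correlations are excluded from the bins and counted separately;
#' percentages are relative to the number of binned genes.
#'
#' @param rhos numeric vector of Spearman correlations (may contain `NA`).
#' @return `data.frame` with `bin`, `count`, `percent`; the number of
#'   excluded values is in `attr(, "n_missing")`.
#' @export
bin_correlations <- function(rhos) {
  n_missing <- sum(is.na(rhos))
  r <- rhos[!is.na(rhos)]
  counts <- c(
    similar = sum(r > 0.7),
    opposite = sum(r < -0.7),
    near_zero = sum(abs(r) < 0.1),
    other = sum(r <= 0.7 & r >= -0.7 & abs(r) >= 0.1)
  )
  out <- data.frame(
    bin = names(counts),
    count = as.integer(counts),
    percent = if (length(r) > 0) 100 * as.integer(counts) / length(r) else rep(NA_real_, 4L),
    row.names = NULL
  )
  attr(out, "n_missing") <- n_missing
  out
}

#' Differential activity between two curves
#'
#' `TRUE` when the Spearman correlation between the curves is strictly
#' below 0.7. A constant curve cannot certify similarity, so an undefined
#' correlation is reported as differential with the `undefined` attribute
#' set.
#'
#' @param curve_a,curve_b numeric curves on the same time grid.
#' @param rho_threshold similarity cutoff (default 0.7).
#' @return logical scalar with attributes `rho` and `undefined`.
#' @export
differential_activity <- function(curve_a, curve_b, rho_threshold = 0.7) {
  rho <- spearman_cor(curve_a, curve_b)
  if (is.na(rho)) {
    return(structure(TRUE, rho = NA_real_, undefined = TRUE))
  }
  # strict inequality with a float guard so rank correlations that are
  # mathematically equal to the threshold do not trip it
  structure(rho < rho_threshold - 1e-12, rho = rho, undefined = FALSE)
}

#' Significant variation of an expression curve
#'
#' `TRUE` when the range (max minus min) of the curve is not smaller than
#' the threshold (inclusive). The default 1.96 is the two-sided 0.05
#' normal critical value on the standardized log2 fold-change scale.
#'
#' @param curve numeric curve.
#' @param threshold range threshold (default 1.96).
#' @return logical scalar.
#' @export
significant_variation <- function(curve, threshold = 1.96) {
  diff(range(curve)) >= threshold
}

#' Classify one gene's four-condition curves
#'
#' Evaluates the six cross-talk criteria (differential SHH vs CTRL;
#' significant variation under SHH; differential EGF vs CTRL; significant
#' variation under EGF; differential EGF_SHH vs SHH; differential EGF_SHH
#' vs EGF) and the three co-activation criteria (no differential SHH vs
#' CTRL; no differential EGF vs CTRL; differential EGF_SHH vs SHH). The
#' classification is `"crosstalk"` when all six hold, `"coactivation"`
#' when all three hold, else `"neither"`; the two patterns are mutually
#' exclusive because each requires the opposite of the other's first
#' criterion.
#'
#' `coactivation_rule = "strict"` additionally requires differential
#' activity of EGF_SHH vs EGF and significant variation under EGF_SHH.
#'
#' @param curves named list with elements `CTRL`, `SHH`, `EGF`, `EGF_SHH`
#'   (numeric curves on a common grid).
#' @param rho_threshold similarity cutoff (default 0.7).
#' @param range_threshold significant-variation range (default 1.96).
#' @param coactivation_rule `"literal"` (default) or `"strict"`.
#' @return one-row `data.frame` of the nine criterion flags, per-condition
#'   ranges, pairwise correlations and the final `classification`.
#' @export
classify_crosstalk <- function(curves, rho_threshold = 0.7,
                               range_threshold = 1.96,
                               coactivation_rule = c("literal", "strict")) {
  coactivation_rule <- match.arg(coactivation_rule)
  need <- c("CTRL", "SHH", "EGF", "EGF_SHH")
  missing <- setdiff(need, names(curves))
  if (length(missing) > 0) {
    stop("missing condition curve(s): ", paste(missing, collapse = ", "))
  }
  da <- function(a, b) differential_activity(curves[[a]], curves[[b]], rho_threshold)
  d_shh_ctrl <- da("SHH", "CTRL")
  d_egf_ctrl <- da("EGF", "CTRL")
  d_both_shh <- da("EGF_SHH", "SHH")
  d_both_egf <- da("EGF_SHH", "EGF")
  v_shh <- significant_variation(curves$SHH, range_threshold)
  v_egf <- significant_variation(curves$EGF, range_threshold)
  ct <- c(
    ct_diff_shh_ctrl = as.logical(d_shh_ctrl),
    ct_var_shh = v_shh,
    ct_diff_egf_ctrl = as.logical(d_egf_ctrl),
    ct_var_egf = v_egf,
    ct_diff_both_shh = as.logical(d_both_shh),
    ct_diff_both_egf = as.logical(d_both_egf)
  )
  co <- c(
    co_nodiff_shh_ctrl = !as.logical(d_shh_ctrl),
    co_nodiff_egf_ctrl = !as.logical(d_egf_ctrl),
    co_diff_both_shh = as.logical(d_both_shh)
  )
  is_co <- all(co)
  if (coactivation_rule == "strict") {
    is_co <- is_co && as.logical(d_both_egf) &&
      significant_variation(curves$EGF_SHH, range_threshold)
  }
  classification <- if (all(ct)) "crosstalk" else if (is_co) "coactivation" else "neither"
  out <- data.frame(t(c(ct, co)))
  out$classification <- classification
  out$range_ctrl <- diff(range(curves$CTRL))
  out$range_shh <- diff(range(curves$SHH))
  out$range_egf <- diff(range(curves$EGF))
  out$range_both <- diff(range(curves$EGF_SHH))
  out$rho_shh_ctrl <- attr(d_shh_ctrl, "rho")
  out$rho_egf_ctrl <- attr(d_egf_ctrl, "rho")
  out$rho_both_shh <- attr(d_both_shh, "rho")
  out$rho_both_egf <- attr(d_both_egf, "rho")
  out
}

# classify many genes given per-condition curve matrices; rows of each
# matrix are genes (aligned by row name). Genes missing under any
# condition are returned with classification "unevaluable".
.classify_genes <- function(curves_by_condition, gene_ids, ...) {
  rows <- lapply(gene_ids, function(g) {
    have <- vapply(curves_by_condition, function(m) g %in% rownames(m), TRUE)
    if (!all(have)) {
      row <- data.frame(gene_id = g, classification = "unevaluable")
      return(row)
    }
    r <- classify_crosstalk(lapply(curves_by_condition, function(m) m[g, ]), ...)
    cbind(data.frame(gene_id = g), r)
  })
  .pad_rbind(rows)
}

#' Two-stage cross-talk screen over modules and their genes
#'
#' Stage 1 classifies every module by its mean curves under the four
#' conditions (a module's curve under a condition is the mean of its member
#' genes' curves under that condition). Stage 2 re-applies the classifier
#' to the individual genes of qualifying modules; a gene is reported as
#' cross-talk (or co-activation) only when its module and its own curves
#' both exhibit the pattern. Genes without curves under every condition are
#' reported as unevaluable.
#'
#' @param grms a `grm_set` (modules computed under the reference
#'   condition, e.g. SHH).
#' @param curves_by_condition named list (`CTRL`, `SHH`, `EGF`, `EGF_SHH`)
#'   of gene x time curve matrices, row names = gene ids. The pipeline
#'   passes raw centered profiles: similarity is judged on expression
#'   values, and smoothing an essentially flat profile leaves a low-rank
#'   trend whose rank correlation with a real template is erratic.
#'   Smoothed fits may be passed instead.
#' @param ... passed to [classify_crosstalk()].
#' @return list with `grm_report` (per-module flags and classification)
#'   and `gene_report` (per-gene rows for genes of qualifying modules,
#'   with `module_id` and final `classification`).
#' @export
screen_grms <- function(grms, curves_by_condition, ...) {
  need <- c("CTRL", "SHH", "EGF", "EGF_SHH")
  missing <- setdiff(need, names(curves_by_condition))
  if (length(missing) > 0) {
    stop("missing condition curve matrices: ", paste(missing, collapse = ", "))
  }
  mods <- if (inherits(grms, "grm_set")) grms$modules else grms
  grm_rows <- lapply(mods, function(mod) {
    mc <- lapply(curves_by_condition, function(m) {
      members <- intersect(mod$members, rownames(m))
      if (length(members) == 0L) return(NULL)
      colMeans(m[members, , drop = FALSE])
    })
    if (any(vapply(mc, is.null, TRUE))) {
      return(data.frame(module_id = mod$module_id, size = mod$size,
                        classification = "unevaluable"))
    }
    cbind(data.frame(module_id = mod$module_id, size = mod$size),
          classify_crosstalk(mc, ...))
  })
  grm_report <- .pad_rbind(grm_rows)
  qualifying <- grm_report$module_id[grm_report$classification %in%
                                       c("crosstalk", "coactivation")]
  gene_rows <- lapply(qualifying, function(mid) {
    mod <- mods[[which(vapply(mods, `[[`, "", "module_id") == mid)]]
    gr <- .classify_genes(curves_by_condition, mod$members, ...)
    grm_class <- grm_report$classification[grm_report$module_id == mid]
    # a gene is retained only when it matches its module's pattern
    keep_class <- ifelse(
      gr$classification == "unevaluable", "unevaluable",
      ifelse(gr$classification == grm_class, gr$classification, "neither")
    )
    cbind(data.frame(module_id = mid), gr[, "gene_id", drop = FALSE],
          data.frame(gene_classification = gr$classification,
                     classification = keep_class))
  })
  gene_report <- if (length(gene_rows) > 0) {
    .pad_rbind(gene_rows)
  } else {
    data.frame(module_id = character(), gene_id = character(),
               gene_classification = character(), classification = character())
  }
  list(grm_report = grm_report, gene_report = gene_report)
}
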