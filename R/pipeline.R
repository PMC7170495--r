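# End-to-end orchestration: io -> DRG detection per condition -> top-k
# selection -> IHC clustering -> LS-GRM filtering and cross-condition
# pairing -> ODE network inference -> network statistics and important
# modules -> similarity tables -> cross-talk screen. Every stage writes
# tab-separated artifacts plus a log; identical configuration and seed give
# identical outputs.

#' Pipeline configuration
#'
#' @param paths named list/vector of four expression-table paths, names
#'   `CTRL`, `SHH`, `EGF`, `EGF_SHH`.
#' @param scale `"as_is"` (input already on the centered-ready log
#'   fold-change scale), `"log2_ratio"` (raw scale: compute log2
#'   fold-change vs control time 0) or `"ratio"` (raw-ratio mode).
#' @param alpha,mtc significance level and multiple-testing correction for
#'   DRG detection.
#' @param p_mode `"parametric"` or `"permutation"` p-values.
#' @param rho_threshold clustering/similarity threshold (default 0.7).
#' @param min_module_size LS-GRM size bound (default 70).
#' @param top_k DRGs retained per condition for clustering (default 3000).
#' @param importance_mode `"top_k"` or `"percentile"` (see
#'   [important_grms()]).
#' @param importance_k modules per criterion in top-k mode (default 20).
#' @param reference_condition condition whose DRGs seed the cross-talk
#'   screen (default `"SHH"`).
#' @param seed integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(paths, scale = c("as_is", "log2_ratio", "ratio"),
                            alpha = 0.05, mtc = "BH",
                            p_mode = c("parametric", "permutation"),
                            rho_threshold = 0.7, min_module_size = 70L,
                            top_k = 3000L, importance_mode = c("top_k", "percentile"),
                            importance_k = 20L, reference_condition = "SHH",
                            seed = 1L) {
  scale <- match.arg(scale)
  p_mode <- match.arg(p_mode)
  importance_mode <- match.arg(importance_mode)
  need <- c("CTRL", "SHH", "EGF", "EGF_SHH")
  paths <- as.list(paths)
  missing <- setdiff(need, names(paths))
  if (length(missing) > 0) stop("paths must name conditions: ", paste(missing, collapse = ", "))
  for (cond in need) {
    if (!file.exists(paths[[cond]])) {
      stop("expression table for ", cond, " not found: ", paths[[cond]])
    }
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (rho_threshold <= 0 || rho_threshold >= 1) stop("rho_threshold must be in (0,1)")
  structure(
    list(paths = paths[need], scale = scale, alpha = alpha, mtc = mtc,
         p_mode = p_mode, rho_threshold = rho_threshold,
         min_module_size = as.integer(min_module_size),
         top_k = as.integer(top_k), importance_mode = importance_mode,
         importance_k = as.integer(importance_k),
         reference_condition = reference_condition, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with the fields of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory for artifacts (created if needed).
#' @return the output directory, invisibly; artifacts and `run.log` inside.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  say <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  set.seed(config$seed)
  conds <- names(config$paths)
  say("pipeline run: conditions ", paste(conds, collapse = ", "),
      "; scale=", config$scale, " alpha=", config$alpha, " mtc=", config$mtc,
      " p_mode=", config$p_mode, " rho=", config$rho_threshold,
      " min_module_size=", config$min_module_size, " top_k=", config$top_k,
      " seed=", config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      say("stage '", name, "' failed: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- io ---
  raw <- stage("io", {
    out <- lapply(conds, function(cc) read_expression_table(config$paths[[cc]], cc))
    names(out) <- conds
    out
  })
  centered <- stage("normalize", {
    med <- lapply(raw, median_over_replicates)
    if (config$scale != "as_is") {
      med <- lapply(med, fold_change_vs_control_t0, control = raw$CTRL,
                    log2 = config$scale == "log2_ratio")
    }
    lapply(med, center_profiles)
  })
  for (cc in conds) {
    say("io: ", cc, " -> ", length(centered[[cc]]$gene_ids), " genes, ",
        length(centered[[cc]]$time_grid), " time points")
  }

  # --- DRG detection ---
  drg <- stage("drg", {
    out <- lapply(conds, function(cc) {
      rec <- detect_drgs(centered[[cc]], alpha = config$alpha, mtc = config$mtc,
                         mode = config$p_mode, seed = config$seed)
      .write_tsv(rec, file.path(out_dir, paste0("drg_", cc, ".tsv")))
      say("drg: ", cc, " -> ", sum(rec$is_drg), " dynamic genes of ", nrow(rec))
      rec
    })
    names(out) <- conds
    out
  })

  # --- top-k selection + clustering ---
  grms <- stage("cluster", {
    out <- lapply(conds, function(cc) {
      top <- suppressWarnings(top_k_by_fratio(drg[[cc]], config$top_k))
      fitted <- attr(drg[[cc]], "fitted")[top, , drop = FALSE]
      gs <- ihc_cluster(fitted, centered[[cc]]$time_grid,
                        rho_threshold = config$rho_threshold, condition = cc)
      members <- data.frame(
        gene_id = names(gs$labels),
        module_id = paste0("GRM", unname(gs$labels))
      )
      .write_tsv(members, file.path(out_dir, paste0("grm_", cc, "_members.tsv")))
      mc <- grm_mean_curves(gs)
      .write_tsv(cbind(data.frame(module_id = rownames(mc)), as.data.frame(mc)),
                 file.path(out_dir, paste0("grm_", cc, "_means.tsv")))
      say("cluster: ", cc, " -> ", length(gs$modules), " modules over ",
          length(top), " genes; ", length(large_size_grms(gs, config$min_module_size)),
          " of size >= ", config$min_module_size)
      gs
    })
    names(out) <- conds
    out
  })

  # --- LS-GRM pairing across conditions ---
  stage("match", {
    for (pair in list(c("CTRL", "SHH"), c("EGF", "EGF_SHH"))) {
      a <- large_size_grms(grms[[pair[1L]]], config$min_module_size)
      b <- large_size_grms(grms[[pair[2L]]], config$min_module_size)
      if (length(a) > 0 && length(b) > 0) {
        mm <- match_modules(a, b)
        .write_tsv(mm, file.path(out_dir, paste0("pairing_", pair[1L], "_",
                                                 pair[2L], ".tsv")))
        say("match: ", pair[1L], " vs ", pair[2L], " -> ", nrow(mm), " pairs")
      }
    }
  })

  # --- network inference + statistics ---
  nets <- stage("network", {
    out <- lapply(conds, function(cc) {
      mc <- grm_mean_curves(grms[[cc]])
      model <- fit_grn(mc, centered[[cc]]$time_grid)
      .write_tsv(grn_edges(model), file.path(out_dir, paste0("grn_", cc, "_edges.tsv")))
      .write_tsv(cbind(data.frame(module_id = rownames(model$coefficients)),
                       as.data.frame(model$coefficients)),
                 file.path(out_dir, paste0("grn_", cc, "_adjacency.tsv")))
      g <- network_from_model(model)
      st <- network_stats(g)
      .write_tsv(st$nodes, file.path(out_dir, paste0("network_", cc, "_nodes.tsv")))
      imp <- important_grms(st, mode = config$importance_mode, k = config$importance_k)
      .write_tsv(imp, file.path(out_dir, paste0("important_", cc, ".tsv")))
      say("network: ", cc, " -> ", sum(model$support), " edges; density=",
          signif(st$density, 3), " mean_clustering=", signif(st$mean_clustering, 3))
      list(model = model, stats = st, important = imp)
    })
    names(out) <- conds
    out
  })

  # --- cross-condition similarity tables (on raw centered profiles:
  # similarity is judged on expression values, and smoothing near-flat
  # profiles would leave trend artifacts that bias the correlation) ---
  raw_profiles <- lapply(centered, profile_matrix)
  stage("compare", {
    rows <- list()
    for (a in conds) {
      top <- suppressWarnings(top_k_by_fratio(drg[[a]], config$top_k))
      fa <- raw_profiles[[a]]
      for (b in setdiff(conds, a)) {
        fb <- raw_profiles[[b]]
        common <- intersect(top, rownames(fb))
        rho <- spearman_between_conditions(fa[common, , drop = FALSE],
                                           fb[common, , drop = FALSE])
        bins <- bin_correlations(rho)
        rows[[paste(a, b)]] <- cbind(
          data.frame(condition_a = a, condition_b = b,
                     n = length(rho), n_undefined = attr(bins, "n_missing")),
          stats::setNames(as.data.frame(t(bins$count)), paste0("n_", bins$bin)),
          stats::setNames(as.data.frame(t(round(bins$percent, 1))),
                          paste0("pct_", bins$bin))
        )
      }
    }
    .write_tsv(do.call(rbind, rows), file.path(out_dir, "similarity_bins.tsv"))
    say("compare: ", length(rows), " condition pairs binned")
  })

  # --- cross-talk screen ---
  stage("crosstalk", {
    ref <- config$reference_condition
    ref_drgs <- drg[[ref]]$gene_id[drg[[ref]]$is_drg]
    fitted_ref <- attr(drg[[ref]], "fitted")[ref_drgs, , drop = FALSE]
    gs <- ihc_cluster(fitted_ref, centered[[ref]]$time_grid,
                      rho_threshold = config$rho_threshold, condition = ref)
    scr <- screen_grms(gs, raw_profiles)
    .write_tsv(scr$grm_report, file.path(out_dir, "crosstalk_grms.tsv"))
    .write_tsv(scr$gene_report, file.path(out_dir, "crosstalk_genes.tsv"))
    say("crosstalk: ", length(gs$modules), " modules screened under ", ref, "; ",
        sum(scr$gene_report$classification == "crosstalk"), " cross-talk and ",
        sum(scr$gene_report$classification == "coactivation"),
        " co-activation genes")
  })

  # --- summary ---
  stage("summary", {
    rows <- lapply(conds, function(cc) {
      sizes <- sort(vapply(grms[[cc]]$modules, `[[`, 1L, "size"), decreasing = TRUE)
      n_top <- sum(sizes)
      first <- function(k) sum(sizes[seq_len(min(k, length(sizes)))])
      data.frame(
        condition = cc,
        n_genes = nrow(drg[[cc]]),
        n_drg = sum(drg[[cc]]$is_drg),
        n_clustered = n_top,
        n_grm = length(sizes),
        n_lsgrm = sum(sizes >= config$min_module_size),
        size_grm1 = sizes[1L],
        frac_first6 = round(first(6L) / n_top, 2),
        frac_first8 = round(first(8L) / n_top, 2),
        frac_first12 = round(first(12L) / n_top, 2),
        density = nets[[cc]]$stats$density,
        mean_clustering = nets[[cc]]$stats$mean_clustering
      )
    })
    .write_tsv(do.call(rbind, rows), file.path(out_dir, "summary.tsv"))
  })
  say("pipeline complete")
  invisible(out_dir)
}

#' Summary table of a completed run
#'
#' Per condition: gene and DRG counts, module counts, LS-GRM counts, the
#' size of the largest module, the fraction of clustered genes in the
#' largest 6/8/12 modules, and the network density and mean clustering
#' coefficient.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return `data.frame`, one row per condition.
#' @export
summarize_run <- function(run_dir) {
  path <- file.path(run_dir, "summary.tsv")
  if (!file.exists(path)) {
    have <- list.files(run_dir)
    stop("incomplete run in ", run_dir, ": summary.tsv missing; found ",
         if (length(have)) paste(have, collapse = ", ") else "no artifacts")
  }
  utils::read.delim(path)
}
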