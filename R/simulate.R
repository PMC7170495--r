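# Synthetic four-condition time-course generator with full ground truth.
#
# The observation model mirrors the analysis model: a gene's centered
# profile is a smooth signal plus i.i.d. noise with a single sd shared by
# all genes and replicates. Values are generated directly on the centered
# log2 fold-change scale (so the per-gene centering mean is 0), which is
# the scale the pipeline smooths and tests on.

#' Simulation configuration
#'
#' Defaults emulate the study design the pipeline targets: 14 time points
#' over 24 h, 3 biological replicates, four conditions (CTRL, SHH, EGF,
#' EGF_SHH). `module_amplitude` is the max-minus-min range of each planted
#' template on the log2 fold-change scale; the default 3 (an 8-fold total
#' swing) comfortably exceeds the 1.96 "significant variation" range
#' threshold. `noise_sd` defaults to 0.5 log2 units of replicate noise.
#'
#' @param n_genes total genes.
#' @param n_dynamic genes carrying a planted temporal signal (includes any
#'   cross-talk / co-activation genes).
#' @param n_modules number of distinct template curves for ordinary dynamic
#'   genes.
#' @param n_timepoints number of observation times (minimum 8; the
#'   functional F-test needs at least that many).
#' @param t_max last observation time, hours.
#' @param n_replicates biological replicates per condition.
#' @param noise_sd sd of the i.i.d. observation noise, log2 units.
#' @param module_amplitude range of each template curve, log2 units.
#' @param n_crosstalk planted cross-talk genes.
#' @param n_coactivation planted co-activation genes.
#' @param seed integer seed; the full study is a deterministic function of
#'   the configuration.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000L, n_dynamic = 200L, n_modules = 5L,
                       n_timepoints = 14L, t_max = 24, n_replicates = 3L,
                       noise_sd = 0.5, module_amplitude = 3,
                       n_crosstalk = 0L, n_coactivation = 0L, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_dynamic = as.integer(n_dynamic),
              n_modules = as.integer(n_modules),
              n_timepoints = as.integer(n_timepoints), t_max = t_max,
              n_replicates = as.integer(n_replicates), noise_sd = noise_sd,
              module_amplitude = module_amplitude,
              n_crosstalk = as.integer(n_crosstalk),
              n_coactivation = as.integer(n_coactivation),
              seed = as.integer(seed))
  if (cfg$n_dynamic > cfg$n_genes) stop("n_dynamic must not exceed n_genes")
  if (cfg$n_crosstalk + cfg$n_coactivation > cfg$n_dynamic) {
    stop("n_crosstalk + n_coactivation must not exceed n_dynamic")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (cfg$n_timepoints < 8L) stop("at least 8 time points are required")
  if (cfg$n_modules < 1L) stop("n_modules must be >= 1")
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1")
  if (cfg$t_max <= 0) stop("t_max must be positive")
  structure(cfg, class = "sim_config")
}

#' Time grid of a simulation configuration
#' @param config a `sim_config`.
#' @return equally spaced grid from 0 to `t_max`, length `n_timepoints`.
#' @export
sim_time_grid <- function(config) {
  seq(0, config$t_max, length.out = config$n_timepoints)
}

#' Generate mutually separable smooth template curves
#'
#' Templates are sums of two low-frequency sinusoids (0.5 to 2 cycles over
#' the observation window) with random amplitudes and phases, rescaled to
#' the requested range and centered. Candidates are drawn until all pairwise
#' Spearman correlations are below `rho_max`, so planted modules are
#' separable under the pipeline's similarity threshold; generation fails if
#' separability cannot be achieved within `max_tries` draws.
#'
#' @param n_modules number of templates.
#' @param time_grid strictly increasing observation times.
#' @param amplitude range (max - min) of each template; must be positive.
#' @param seed integer seed.
#' @param rho_max pairwise Spearman separability bound (default 0.7).
#' @param max_tries candidate draws before giving up.
#' @param existing optional matrix of already-accepted curves the new
#'   templates must also be separable from (bound `rho_max_existing`).
#' @param rho_max_existing separability bound against `existing` rows.
#' @return matrix `n_modules x length(time_grid)`, one template per row.
#' @export
make_template_curves <- function(n_modules, time_grid, amplitude, seed = 1L,
                                 rho_max = 0.7, max_tries = 500L,
                                 existing = NULL, rho_max_existing = rho_max) {
  if (n_modules < 1L) stop("n_modules must be >= 1")
  if (any(diff(time_grid) <= 0)) stop("time_grid must be strictly increasing")
  if (!is.finite(amplitude) || amplitude <= 0) {
    stop("amplitude must be positive: flat templates cannot show significant variation")
  }
  set.seed(seed)
  tau <- (time_grid - min(time_grid)) / diff(range(time_grid))
  draw <- function() {
    f <- sample(c(0.5, 0.75, 1, 1.5, 2), 2L)
    a <- stats::runif(2L, 0.3, 1)
    ph <- stats::runif(2L, 0, 2 * pi)
    y <- a[1L] * sin(2 * pi * f[1L] * tau + ph[1L]) +
      a[2L] * sin(2 * pi * f[2L] * tau + ph[2L])
    y <- y - min(y)
    y <- y / max(y) * amplitude
    y - mean(y)
  }
  out <- matrix(NA_real_, n_modules, length(time_grid))
  accepted <- 0L
  for (i in seq_len(max_tries)) {
    cand <- draw()
    ok <- TRUE
    if (accepted > 0L) {
      rho <- apply(out[seq_len(accepted), , drop = FALSE], 1L,
                   spearman_cor, y = cand)
      ok <- all(rho < rho_max)
    }
    if (ok && !is.null(existing) && nrow(existing) > 0L) {
      rho_e <- apply(existing, 1L, spearman_cor, y = cand)
      ok <- all(rho_e < rho_max_existing)
    }
    if (ok) {
      accepted <- accepted + 1L
      out[accepted, ] <- cand
      if (accepted == n_modules) break
    }
  }
  if (accepted < n_modules) {
    stop("could not draw ", n_modules, " templates with pairwise Spearman < ",
         rho_max, " in ", max_tries, " tries")
  }
  rownames(out) <- paste0("template", seq_len(n_modules))
  out
}

# internal: build one condition's array from a per-gene template assignment
# (0 = flat). Rows of `templates` are indexed by the assignment.
.simulate_values <- function(config, templates, assignment) {
  n <- config$n_genes; K <- config$n_timepoints; N <- config$n_replicates
  signal <- matrix(0, n, K)
  dyn <- assignment > 0L
  if (any(dyn)) signal[dyn, ] <- templates[assignment[dyn], , drop = FALSE]
  vals <- array(stats::rnorm(n * K * N, 0, config$noise_sd), dim = c(n, K, N))
  vals + array(signal, dim = c(n, K, N))
}

#' Simulate one condition from templates and an assignment plan
#'
#' Flat genes are pure i.i.d. noise around mean zero; dynamic genes add
#' their assigned template. Replicates share the signal and differ only in
#' noise. The same seed gives bit-identical output.
#'
#' @param config a [sim_config()].
#' @param templates template matrix (rows indexed by `assignment`).
#' @param assignment integer per-gene template index, 0 for flat genes.
#' @param condition condition label.
#' @param seed seed for this condition's noise.
#' @return list with `data` (an `expr_tc`) and `assignment`.
#' @export
simulate_condition <- function(config, templates, assignment,
                               condition = "CTRL", seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (length(assignment) != config$n_genes) stop("assignment length must equal n_genes")
  if (any(assignment > 0L) && max(assignment) > nrow(templates)) {
    stop("assignment refers to a missing template row")
  }
  set.seed(seed)
  vals <- .simulate_values(config, templates, as.integer(assignment))
  ids <- sprintf("G%05d", seq_len(config$n_genes))
  list(
    data = expression_time_course(vals, sim_time_grid(config), ids, condition),
    assignment = as.integer(assignment)
  )
}

#' Simulate a four-condition co-stimulation study with ground truth
#'
#' Generates CTRL, SHH, EGF and EGF_SHH datasets sharing one gene panel.
#' Ordinary dynamic genes keep the same template under all four conditions
#' (dynamic everywhere, never differential). Planted cross-talk genes are
#' flat under CTRL and follow three mutually dissimilar templates (pairwise
#' Spearman < 0.7, each with range >= 1.96) under SHH, EGF and EGF_SHH, so
#' they satisfy all six cross-talk criteria by construction. Planted
#' co-activation genes follow one template under CTRL, SHH and EGF and a
#' dissimilar one under EGF_SHH, satisfying the three co-activation
#' criteria. Remaining genes are flat noise.
#'
#' @param config a [sim_config()].
#' @return list with `conditions` (named list of `expr_tc`), `templates`,
#'   and `truth` (a `ground_truth` list: `drg_flags` gene x condition
#'   logical matrix, `module_labels` gene x condition template index matrix,
#'   `crosstalk_genes`, `coactivation_genes`, `ode_matrix`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tg <- sim_time_grid(config)
  # ordinary module templates plus 5 dedicated pattern templates:
  # A, B, C for cross-talk (SHH / EGF / EGF_SHH), D, E for co-activation.
  # The dedicated templates are drawn with a stricter bound (pairwise
  # Spearman < 0.4, also against the ordinary templates) so the planted
  # differential-activity criteria hold with margin, not just at the 0.7
  # decision boundary where observation noise would erode the ground
  # truth, and so planted-pattern genes do not co-cluster with ordinary
  # modules.
  ordinary <- make_template_curves(config$n_modules, tg,
                                   config$module_amplitude,
                                   seed = config$seed)
  dedicated <- make_template_curves(5L, tg, config$module_amplitude,
                                    seed = config$seed + 997L,
                                    rho_max = 0.4, existing = ordinary,
                                    rho_max_existing = 0.4)
  templates <- rbind(ordinary, dedicated)
  rownames(templates) <- paste0("template", seq_len(nrow(templates)))
  if (config$module_amplitude < 1.96 &&
      (config$n_crosstalk > 0L || config$n_coactivation > 0L)) {
    stop("module_amplitude below 1.96: planted cross-talk genes could not ",
         "show significant variation")
  }
  iA <- config$n_modules + 1L; iB <- iA + 1L; iC <- iB + 1L
  iD <- iC + 1L; iE <- iD + 1L

  n <- config$n_genes
  n_ct <- config$n_crosstalk; n_co <- config$n_coactivation
  n_ord <- config$n_dynamic - n_ct - n_co
  ids <- sprintf("G%05d", seq_len(n))
  # gene layout: [ordinary dynamic | crosstalk | coactivation | flat]
  ord_idx <- seq_len(n_ord)
  ct_idx <- seq_len(n_ct) + n_ord
  co_idx <- seq_len(n_co) + n_ord + n_ct

  conds <- c("CTRL", "SHH", "EGF", "EGF_SHH")
  assign <- matrix(0L, n, 4L, dimnames = list(ids, conds))
  if (n_ord > 0L) {
    mod <- rep_len(seq_len(config$n_modules), n_ord)
    assign[ord_idx, ] <- mod  # same template everywhere
  }
  assign[ct_idx, "SHH"] <- iA
  assign[ct_idx, "EGF"] <- iB
  assign[ct_idx, "EGF_SHH"] <- iC
  assign[co_idx, c("CTRL", "SHH", "EGF")] <- iD
  assign[co_idx, "EGF_SHH"] <- iE

  conditions <- list()
  for (j in seq_along(conds)) {
    conditions[[conds[j]]] <- simulate_condition(
      config, templates, assign[, j], condition = conds[j],
      seed = config$seed + j
    )$data
  }
  truth <- structure(
    list(
      drg_flags = assign > 0L,
      module_labels = assign,
      crosstalk_genes = ids[ct_idx],
      coactivation_genes = ids[co_idx],
      ode_matrix = NULL,
      templates = templates,
      time_grid = tg
    ),
    class = "ground_truth"
  )
  list(conditions = conditions, templates = templates, truth = truth,
       config = config)
}

#' Write a simulated study to a directory
#'
#' One tab-separated expression table per condition (the format read by
#' [read_expression_table()]) plus a `ground_truth.json` sidecar.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in names(study$conditions)) {
    write_expression_table(study$conditions[[cond]],
                           file.path(dir, paste0(cond, ".tsv")))
  }
  tr <- study$truth
  jsonlite::write_json(
    list(
      drg_flags = tr$drg_flags,
      module_labels = tr$module_labels,
      crosstalk_genes = tr$crosstalk_genes,
      coactivation_genes = tr$coactivation_genes,
      gene_ids = rownames(tr$module_labels),
      time_grid = tr$time_grid,
      templates = tr$templates
    ),
    file.path(dir, "ground_truth.json"),
    digits = NA
  )
  invisible(dir)
}
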