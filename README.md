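# dyncross

Dynamic gene-expression analysis of pathway cross-talk for four-condition
time-course studies.

`dyncross` is for analysts of stimulation experiments in which one cell
system is profiled over time under a control, two single stimuli (e.g.
Sonic Hedgehog and EGF) and their co-stimulation, with a handful of
biological replicates. It answers, in order: which genes respond
dynamically in each condition; which temporal patterns those genes share;
how the patterns regulate each other; and which genes behave under
co-stimulation in a way neither single stimulus explains.

## The method in brief

1. **Dynamic response genes (DRGs).** Each gene's replicate-median,
   fold-change, centered profile is modelled as a smooth signal plus
   i.i.d. noise, `Y(t_k) − μ = X(t_k) + E(t_k)`. `X` is a natural cubic
   smoothing spline with GCV-selected penalty; the gene is dynamic when
   the functional F-ratio

   `F = [(RSS0 − RSS1)/(edf − 1)] / [RSS1/(K − edf)]`

   rejects `H0: X(t) ≡ 0` (Benjamini–Hochberg adjusted, parametric or
   permutation p-values).
2. **Gene response modules (GRMs).** The top-3,000 DRGs by F-ratio are
   clustered by iterative hierarchical clustering on Spearman distance
   with the 0.7 similarity threshold; modules of 70+ genes are
   "large-size" and can be paired across conditions by greedy
   best-correlation matching.
3. **Gene regulatory network (GRN).** Module mean curves obey sparse
   linear rate equations `dM_q/dt = α0_q + Σ_p α_pq M_p`; spline-derivative
   responses are regressed on module curves with L1-path/BIC selection,
   backward BIC pruning and OLS refit. Degree, unnormalized betweenness
   `Bet(v) = Σ_{s≠t} σ_st(v)/σ_st`, density and clustering coefficient
   identify "important" modules (top-20 or 95th-percentile rules).
4. **Cross-talk / co-activation.** A gene is *cross-talk* when it is
   differential vs control under each single stimulus (Spearman ρ < 0.7)
   with significant variation (range ≥ 1.96 log2 units) under both, and
   its co-stimulation curve is differential vs both single-stimulus
   curves; it is *co-activation* when it is non-differential under both
   single stimuli but differential under co-stimulation vs SHH. The
   screen runs module-first, then gene-by-gene inside qualifying modules.

A synthetic-data generator (`simulate_study`, `simulate_grn_system`)
plants all of this structure with known ground truth, so every stage is
testable offline.

## Worked example

```r
library(dyncross)

cfg <- sim_config(n_genes = 500, n_dynamic = 150, n_modules = 5,
                  n_crosstalk = 20, n_coactivation = 10, seed = 3)
study <- simulate_study(cfg)
dir <- tempfile(); write_study(study, dir)

pc <- pipeline_config(list(CTRL = file.path(dir, "CTRL.tsv"),
                           SHH = file.path(dir, "SHH.tsv"),
                           EGF = file.path(dir, "EGF.tsv"),
                           EGF_SHH = file.path(dir, "EGF_SHH.tsv")),
                      seed = 3)
run_pipeline(pc, file.path(dir, "run"))
summarize_run(file.path(dir, "run"))
```

The run log prints each stage as it completes:

```
drg: CTRL -> 136 dynamic genes of 500
drg: SHH -> 152 dynamic genes of 500
drg: EGF -> 163 dynamic genes of 500
drg: EGF_SHH -> 160 dynamic genes of 500
cluster: SHH -> 10 modules over 152 genes; 0 of size >= 70
network: SHH -> 59 edges; density=0.611 mean_clustering=0.855
crosstalk: 10 modules screened under SHH; 20 cross-talk and 10 co-activation genes
```

and the summary table reports one row per condition:

```
  condition n_genes n_drg n_grm size_grm1 frac_first6 density mean_clustering
1      CTRL     500   136    12        28        0.96   0.568           0.767
2       SHH     500   152    10        24        0.91   0.611           0.855
3       EGF     500   163    12        27        0.89   0.545           0.823
4   EGF_SHH    500   160    12        26        0.89   0.629           0.854
```

Here all 20 planted cross-talk genes and all 10 planted co-activation
genes are recovered (`crosstalk_genes.tsv` in the run directory), with
densities and module counts describing the per-condition networks. Each
artifact is a TSV keyed by gene or module id; `run.log` echoes every
parameter for reproducibility. A thin command-line wrapper lives at
`inst/scripts/dyncross.R` (`simulate` / `run` / `summarize` subcommands).

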