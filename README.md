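# zibench16S

Benchmarking zero-imputation and normalization pipelines for sparse 16S
rRNA-gene count data.

## The problem

OTU/ASV count tables from 16S amplicon sequencing are extremely sparse
(typically 70–95% zeros) and compositional: each sample's total is an
arbitrary instrument-imposed sequencing depth, so counts only carry
relative information. A zero can be *biological* (the species is genuinely
absent) or *technical* (the species was present but fell below the reach of
the sequencing run). Standard 16S workflows normalize library sizes but
never attempt to recover technical zeros, although analogous
*zero-imputation* steps are routine in single-cell RNA-seq.

`zibench16S` provides everything needed to ask, quantitatively, whether a
zero-imputation step helps a 16S analysis:

* **A ground-truth-generating simulator.** Counts are produced in two
  steps: per-replicate species abundances `a_ij ~ Gamma(shape = 1/v_i,
  scale = phi_i v_i)` (mean `phi_i`, squared coefficient of variation
  `v_i`; `phi_i = 0` marks structural absence), then a sequencing step that
  draws each sample's depth `N_j` *without replacement* from a discretized
  community pool (multivariate hypergeometric), so that rare species are
  lost exactly the way multiplexed sequencing loses them. The step-1 matrix
  is the ground truth; the step-2 matrix is the observed raw table.
* **Five normalizations** behind stable ids: `tss` (proportions), `css`
  (cumulative-sum scaling to an adaptively chosen quantile), `tmm`
  (trimmed mean of M-values), `deseq` (median-of-ratios size factors),
  `gmpr` (geometric mean of pairwise ratios, designed for zero-inflated
  tables).
* **Five zero-imputation methods**: `llsimpute` (local least squares on
  K-nearest feature neighbours), `zcomp_sq` / `zcomp_czm` (Bayesian
  square-root and rounded-zero multiplicative replacement for
  compositions), `scimpute` (per-feature Gamma–Normal dropout mixture +
  nonnegative least-squares prediction from similar samples), `drimpute`
  (consensus clustering over Spearman/Pearson distances and a range of
  cluster numbers, averaging cluster-mean estimates).
* **The 35-pipeline combinator**: 5 normalization-only + 5 imputation-only
  + 25 normalization→imputation pipelines.
* **An evaluation suite** against the simulator's ground truth: total
  sparsity; technical/biological zero classification
  (sensitivity/specificity); per-sample SMAPE and Aitchison distance on
  the CPM scale; observed richness and Pielou evenness errors with paired
  rank tests, BH correction and Cohen's d magnitude labels; Whittaker and
  Bray–Curtis beta diversity with NMDS; Mann–Whitney + BH differential
  abundance and Jaccard concordance with the ground truth's DA calls.

## Worked example

```r
library(zibench16S)

preset <- scenario_moderate_preset(seed = 1)  # 4 groups x 5 reps x 300 features
ds <- simulate_dataset(preset)
ds
#> simulated_dataset: 300 features x 20 samples | truth sparsity 40.00%, raw sparsity 47.17%

reg <- build_registry()          # all 35 pipelines
out <- run_pipeline(ds$raw, reg[["gmpr + scimpute"]], config = list(seed = 1))

total_sparsity(out)
#> [1] 42.13333
zero_confusion(ds$ground_truth, ds$raw, out)
#> zero_confusion: TP 302 FP 0 FN 128 TN 2400 | sens 70.23% spec 100.00%

rep <- evaluate_all(ds$ground_truth, ds$raw, list("gmpr + scimpute" = out),
                    nmds = FALSE)
aggregate(cbind(smape, aitchison) ~ pipeline, rep$abundance_error, median)
#>          pipeline    smape aitchison
#> 1 gmpr + scimpute 10.18163  13.39226
#> 2             raw 12.43029  14.78991
rep$summary
#>          pipeline sparsity  smape aitchison     da
#> 1 gmpr + scimpute   better better    better better
```

Reading the numbers: sequencing turned 40% structural zeros into 47.2%
observed zeros; the `gmpr + scimpute` pipeline re-imputed 70% of the lost
(technical) zeros without touching a single biological zero (specificity
100%), bringing sparsity back to 42.1% and lowering the median per-sample
abundance error (SMAPE) from 12.4% to 10.2%.

A shell interface covering `simulate`, `preprocess`, `evaluate`,
`benchmark` and `report` lives at `inst/cli/zibench`; `benchmark` drives a
whole study from one YAML config (see `read_config()`).

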