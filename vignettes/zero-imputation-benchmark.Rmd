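---
title: "Benchmarking zero-imputation for 16S count tables: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking zero-imputation for 16S count tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zibench16S)
```

# Why a simulator-anchored benchmark

Whether replacing zeros in an OTU/ASV table helps or hurts can only be
decided against a known truth, and real experiments never expose one: an
observed count table is itself a lossy sample of the community. The
package therefore builds its own truth. Every evaluation in `zibench16S`
compares a preprocessed matrix against the *pre-sequencing* abundance
matrix of a simulation whose loss mechanism is explicit, so that each zero
in the raw table is unambiguously biological (absent from the ground
truth) or technical (present but unsampled).

# The two-step count model

**Step 1 — biology.** Each condition is described by a vector of mean
relative intensities $\phi$ (zeros mark structurally absent species) and
each feature by a dispersion $v_i$. A biological replicate draws
$a_{ij} \sim \mathrm{Gamma}(\text{shape}=1/v_i,\ \text{scale}=\phi_i v_i)$,
giving mean $\phi_i$ and squared coefficient of variation $v_i$. This
parameterization was chosen because it makes the two preset knobs directly
interpretable: $\phi$ sets the expected composition, $v$ the
between-replicate CV. A feature with $\phi_i>0$ but $v_i \le 0$ is floored
at $v=10^{-6}$ (a degenerate "no variability" request should produce an
almost-deterministic draw, not an error).

**Step 2 — sequencing.** The sampled community is finite, so reads are
drawn *without replacement*: each sample's abundance vector is discretized
into an integer pool of total $P$ (largest-remainder rounding, so the pool
sums to exactly $P$ and structural zeros stay zero), and the sample's
depth $N_j$ — uniform on the preset's depth range — is drawn from the pool
by exact sequential hypergeometric conditioning. $P$ defaults to
$10\times$ the maximum depth: large enough that the pool discretization is
not the binding resolution limit, small enough that the
without-replacement character (saturation of abundant species, loss of
rare ones) is retained. As the depth approaches $P$ the draw becomes a
census and the raw proportions converge to the pooled truth — a limit the
tests exercise.

Reproducibility is structural: depths use the preset seed, and each
sample's gamma and sequencing draws use `seed + sample index` substreams,
so any column can be regenerated in isolation.

**What the generator does and does not emulate.** It reproduces the
features the benchmark depends on: heavy-tailed intensity distributions
(log-normal base intensities), condition-specific structural zeros with a
core/occasional occupancy structure, gamma replicate variability, and
depth-dependent technical zero injection. It does not model taxonomy or
phylogenetic relatedness, species interaction networks, amplification or
primer bias, chimeras, or contamination. Consequently, passing results
here say that a pipeline recovers information lost by *random
without-replacement undersampling of a fixed community*; they cannot say
how a pipeline copes with systematically biased loss.

**Presets.** Three built-in presets mirror the benchmark's scenario
contrasts at desk scale (hundreds of features, 10 replicates per
condition): (1) moderate sparsity / low variability, 14 conditions × 332
features, raw sparsity targeted at the 60–80% band; (2) low sparsity /
high variability ($v \in [0.5, 2]$), 8 conditions × 252 features; (3) high
sparsity / high depth, 12 conditions × 380 features, 88–96% band. The
structural-zero fractions and depth ranges were tuned once so that the
simulated raw sparsity lands inside those documented bands, and then
frozen. A fixed-design `scenario_moderate_preset()` (4 conditions × 5
replicates × 300 features, exactly 40% structural zeros, depths
5,000–20,000) is the workhorse of the test suite and the acceptance
script: large enough for every pipeline to behave non-trivially, small
enough to simulate and evaluate in seconds.

# Normalization conventions

The five methods follow their published descriptions; where a published
equation is ambiguous the package takes the reading the original method
requires, and records the convention here.

* **TSS / CPM**: per-sample proportions; CPM is the common scale on which
  every evaluation metric compares matrices, because the methods leave
  columns on wildly different scales.
* **CSS**: the quantile grid has one level per feature and is computed
  over *positive* counts. The selected level is the smallest $l$ with
  $d_{l+1}-d_l \ge 0.1\,d_l$, where $d_l$ is the median absolute deviation
  of sample quantiles around the median quantile. Since $d_l$ is defined
  across samples, one shared level is used for all samples (a per-sample
  level would make the selection rule incoherent). If the rule never
  fires, the median (0.50) level is used and flagged in the returned
  stats.
* **TMM**: reference sample = the one whose 75th percentile of
  positive-count CPM is closest to the mean such percentile; zeros in
  either sample are excluded (their log-fold-change is undefined); 30%
  two-sided trim on M, 5% on A; weights are inverse delta-method
  variances; factors rescaled to geometric mean 1. If fewer than 10
  features survive trimming the factor falls back to 1 with a warning —
  note this makes the non-degenerate branch unreachable for tables of
  ~20 features, where a 30% two-sided trim leaves at most ~8.
* **Median-of-ratios**: the pseudo-reference is the geometric mean across
  samples (with the $1/n$ root; the formula is meaningless without it),
  restricted to features positive in every sample. When no such feature
  exists the method errors rather than inventing a pseudo-count.
* **GMPR**: median count ratios over shared-nonzero features; a sample's
  factor is the geometric mean over its usable partners, with the
  exponent shrunk when pairs had to be skipped; factors rescaled to
  median 1. Scale equivariance holds exactly at the pairwise-ratio level
  ($r_{jk} \mapsto f\,r_{jk}$); after the global rescale the *factor*
  ratio is $f^{n/(n-1)}$, because every partner's factor absorbs
  $f^{-1/(n-1)}$.

Normalization never creates or destroys zeros — this is why
normalization-only pipelines reproduce raw sparsity, raw richness, and raw
SMAPE/Aitchison distances exactly, and why their zero-classification
sensitivity is identically 0%.

# Imputation conventions

All five imputers obey one contract: same-shape nonnegative output,
deterministic under a fixed seed, and — except for the two compositional
replacement methods, which by construction touch only zeros as well —
non-zero entries are returned bit-unchanged. Imputed values below
$10^{-9}$ are floored to 0 so denormal noise never counts as a recovered
species.

* **Local least squares** (`llsimpute`): per feature with zeros, the K
  nearest features (Euclidean distance on the feature's observed columns)
  form the regressors of an ordinary least-squares fit; predictions for
  the zero columns are clamped at 0. Features observed in fewer than two
  samples are skipped and recorded. `K = 10` by default.
* **Compositional replacement** (`zcomp_sq`, `zcomp_czm`): the square-root
  variant replaces each zero part with its posterior-expected proportion
  under a uniform Dirichlet prior of total strength $\sqrt{n}$; the CZM
  variant uses a fixed fraction (default 0.65) of the detection limit
  $1/(n+1)$. In both, non-zero proportions are multiplied by one minus the
  replaced mass, preserving their ratios, and the column is rescaled to
  its original total. The evidence total $n$ is the *sequencing depth*:
  when these methods run after a normalization stage the pipeline passes
  the raw library sizes through, because a normalized column total (e.g. 1
  after TSS) carries no information about how much evidence backs the
  zeros — and taken literally it would make the replaced mass exceed the
  simplex. On raw counts the two definitions coincide.
* **Dropout-model imputer** (`scimpute`): on log1p-CPM values, each
  feature's mixture of a Gamma (dropout, near zero) and a Normal
  (expressed) component is fitted by EM across *all* samples — at desk
  scale a per-group fit would see as few as five points, too few for a
  two-component mixture. EM details: initialization by a 10th-percentile
  split (median split when degenerate), moment-based gamma updates, gamma
  density evaluated at $\max(x, 10^{-3})$, at most 200 iterations,
  relative log-likelihood tolerance $10^{-6}$; features whose fit fails
  are skipped and recorded. Zero entries whose posterior dropout
  probability exceeds `t = 0.5` become candidates; each sample's
  candidates are predicted by nonnegative least squares from its group
  members (or clusters on the leading principal directions when no labels
  exist), fitted on the sample's reliable features. Pooling the mixture
  across groups does not endanger biological zeros: if a feature is absent
  from the whole group, every regressor value is zero and the NNLS
  prediction is zero.
* **Consensus-clustering imputer** (`drimpute`): on log1p-CPM values, for
  every combination of correlation metric (Spearman, Pearson) and cluster
  number $k$ (default 10–15), samples are clustered by average-linkage
  hierarchical clustering on $1-\rho$; a zero entry's estimate is the
  leave-self-out mean of its cluster (the target's own zero would
  otherwise drag every estimate down); the final value averages the
  combinations. Singleton clusters contribute a zero estimate.

# Evaluation conventions

* **SMAPE** is computed per sample across features on the CPM scale, with
  the 0/0 term defined as 0, and summarized as the median across samples.
* **Aitchison distance** is computed through the clr identity (the
  $\tfrac1m$ double-loop form equals the Euclidean distance between clr
  vectors; the suite verifies this against a literal double loop). Zeros
  must be repaired first; the default rule replaces them with half the
  smallest positive value across the two vectors being compared, is
  configurable, and is recorded with the result.
* **Rank tests**: pipeline-vs-raw comparisons of paired per-sample error
  distributions use a one-sided Wilcoxon *signed-rank* test; independent
  group comparisons (alpha diversity between conditions, differential
  abundance) use the Mann–Whitney U test, two-sided for DA and one-sided
  in both directions for the up/down/ns labels. Ties are handled by
  midranks with the normal approximation.
* **BH families**: across features within a condition pair (DA); across
  pipelines within a metric (improvement tests); across group pairs
  within an index (alpha comparisons).
* **Jaccard of two empty DA sets is 1**: if neither the ground truth nor
  the pipeline finds any differentially abundant feature, they agree
  perfectly.
* **DA testing** excludes features that are all-zero in both groups (no
  information, and they would dilute the BH family), and uses the neutral
  rank test rather than any model-based DA tool so that the benchmark
  does not inherit a DA model's assumptions.
* **Cohen's d** uses the pooled-SD form and the conventional magnitude
  ladder (Negligible < 0.01 ≤ Very small < 0.20 ≤ Small < 0.50 ≤ Medium
  < 0.80 ≤ Large < 1.20 ≤ Very large < 2.0 ≤ Huge).
* **NMDS** is delegated to vegan's stress-minimizing engine with random
  restarts under a fixed seed; the report keeps coordinates and final
  stress only.
* The qualitative summary grid labels each pipeline better / comparable /
  worse than raw per metric with a 2% relative margin — deliberately
  coarse, mirroring how such benchmarks are read in practice.

# Problem sizes and determinism

The test suite and the acceptance script run entirely on data simulated
in-process: the 300-feature scenario above (seconds to simulate and
evaluate), toy matrices of at most 60×5 for the brute-force oracle
comparisons, a 500-feature identical-groups simulation for the
false-positive calibration of the DA test, and one full 35-pipeline
benchmark on a 40-feature smoke dataset driven through the CLI. These
sizes were chosen so a complete run stays interactive while every code
path — including the EM fits, the consensus clustering and the NNLS
predictions — is exercised with realistic sparsity.

Every stochastic stage takes an explicit seed, and the simulator derives
per-sample substreams, so reruns are bit-identical and individual samples
are reproducible in isolation.

# Known limitations

* The imputer implementations follow the published descriptions of their
  methods, with the open micro-choices documented above; numeric parity
  with the original released tools is not claimed.
* The gamma/hypergeometric generator cannot probe robustness to biased
  (non-random) read loss, compositional interactions, or taxonomic
  structure.
* The dropout-mixture imputer's pooled fit assumes conditions share a
  broadly similar expression scale after CPM; strongly batch-confounded
  designs would call for a per-cluster fit and more samples.
* CSS's selection rule can fire at the very first quantile level when all
  samples are near-identical (the deviation sequence is flat at zero);
  the result is still a valid scaling, but the "instability"
  interpretation is vacuous there.
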