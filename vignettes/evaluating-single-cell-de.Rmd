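---
title: "Evaluating differential expression methods for single-cell data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating differential expression methods for single-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudobulkDE)
```

## The problem

Single-cell RNA-seq experiments that compare two conditions almost always
contain *biological replicates*: multiple animals, patients, or culture
wells per condition. Within one condition, replicates differ from each other
-- in cell composition, state, and technical handling -- and these
differences are not noise to be averaged away by collecting more cells: they
are the unit of variation against which a condition effect must be judged.

Statistical tests that compare *individual cells* between conditions treat
every cell as an independent observation. With hundreds or thousands of
cells per group, such tests can resolve arbitrarily small differences
between the pooled cell populations -- including the differences that exist
between replicates for reasons unrelated to the condition. The consequence
is a systematic excess of false discoveries, concentrated among highly
expressed genes (where power is greatest), that grows with the number of
cells and shrinks with the number of replicates.

The *pseudobulk* alternative sums counts over all cells of one replicate
(optionally within one cell type), producing a genes-by-replicates matrix
that bulk RNA-seq machinery -- negative binomial GLMs with moderated
dispersions, moderated t-statistics, precision-weighted linear models --
handles with the correct error unit. This package implements both families
of tests, the diagnostics that expose the difference between them, and a
simulator that generates data in which the truth is known: *no* gene has a
condition effect, while between-replicate heterogeneity is under explicit
control.

## The null simulator

`simulate_null_dataset()` follows a gamma-Poisson (splatter-style) recipe:

1. per-gene base mean $\lambda_g \sim \mathrm{Gamma}(\texttt{mean\_shape},
   \texttt{mean\_rate})$;
2. per replicate $r$, each gene is selected with probability
   `de_prob`; selected genes receive a factor
   $f_{gr} = e^{N(\texttt{de\_facLoc},\, \texttt{de\_facScale})}$, inverted
   to $1/f_{gr}$ with probability `de_downProb`; unselected genes keep
   $f_{gr} = 1$;
3. per-cell library size $L_c \sim \mathrm{LogNormal}(\texttt{lib\_loc},
   \texttt{lib\_scale})$;
4. expected counts $\mu_{gc} = L_c\, \lambda_g f_{g r(c)} / \sum_g
   \lambda_g f_{g r(c)}$ (so each cell's expected total is exactly $L_c$);
5. counts $\sim \mathrm{NB}(\mu_{gc}, \phi_g)$ with
   $\sqrt{\phi_g} = (\texttt{bcv\_common} + 1/\sqrt{\bar\mu_g})
   \sqrt{\texttt{bcv\_df}/\chi^2_{\texttt{bcv\_df}}}$.

The factors $f_{gr}$ are the only source of structure: they make
replicates differ from each other, but since conditions are assigned to
replicates *after* generation (`assign_null_conditions()`), expected counts
never depend on condition. Every DE call on such data is a false discovery.

Defaults: 10,000 genes, 500 cells, 3 replicates per condition, `de_prob`
0.5, `de_facLoc` 0.5 varied over [0, 1] in sweeps, `de_facScale` 0.4 and
`de_downProb` 0.5 (conventional simulator defaults), Gamma(0.6, 0.3) base
means, log-normal libraries with median 2,000 counts per cell (a typical
droplet depth), BCV 0.2 on 60 df. Note two consequences of the BCV formula:
`de_facLoc = 0` alone does *not* give a homogeneous dataset (factors
$e^{N(0, 0.4)}$ still vary; both `de_facLoc` and `de_facScale` must be 0),
and the $1/\sqrt{\bar\mu}$ term means counts are over-Poisson at every
setting -- a deliberate property of this family of simulators that any
Poisson-likelihood test will feel.

A single integer seed drives independent sub-streams per stage (means,
factors, libraries, BCV, counts), so changing, say, the number of cells
never perturbs the gene-level draws.

### What the simulator does not model

Expression outliers, dropout layers beyond NB sampling, trajectories,
batch structure within a replicate, and cell-type mixtures are not
modeled. Passing tests on these data therefore show that a method handles
(or mishandles) *replicate-level* variation under clean NB noise; they do
not certify behavior on real data with additional structure.

## The spike-in panel

`simulate_spikein_dataset()` emulates the classic control experiment: a
panel of 92 synthetic RNA species at known, equal-across-cells relative
concentrations (log-uniform over five decades of expected counts), spiked
into every cell alongside a carrier transcriptome that makes up ~95% of
each library. Because no spike-in differs between conditions, any inferred
differential expression is an artifact, and correlating each spike-in's
mean expression with its $-\log_{10} p$ (`spikein_bias()`) measures a
method's expression-level bias directly.

For the artifact to exist at all, some technical variation has to survive
library-size normalization. A per-cell capture factor shared by all
transcripts cancels exactly when each cell is scaled by its total counts --
under such a law every test is calibrated and no bias can emerge. What
survives in real plate-based data is *batch-level* structure, which the
generator models with three log-normal terms: a per-well-batch dilution of
the whole panel relative to cellular mRNA (sdlog 0.3; the master mix fixes
relative ratios but the captured spike-in fraction varies between wells), a
per-(batch, spike-in) residual ratio noise (sdlog 0.3), and per-(batch,
carrier gene) biological heterogeneity (sdlog 0.3, so the mean-dispersion
trend a pseudobulk method estimates reflects genuine replicate
variability). Residual NB dispersion is 0.05 -- near-Poisson technical
noise once capture variation is accounted for -- and the scales sit in the
middle of well-to-well spike-in variability reported for plate protocols
(roughly 20-50% CV). Cell-level tests pool wells and convert this batch
variability into significance that grows with abundance; replicate-aware
pseudobulk tests absorb it.

## The DE tests

All tests return a uniform table (`gene`, `log2fc`, `statistic`, `pval`,
`qval`, `rank`, `method`). Ranking is by |statistic| (descending), then p,
then gene id: p-values from cell-level tests routinely underflow double
precision (~2e-308), and a statistic-first key keeps the top of the
ranking meaningful where p collapses to 0. BH adjustment is used for q
throughout, and all tests are two-sided. Genes with identical values in
both groups get statistic 0 and p 1.

Single-cell tests (`de_single_cell()`), all run on every gene with no
expression filters: Wilcoxon rank-sum and Welch t on log-CP10K values;
logistic regression (condition ~ expression, 1-df LRT); Poisson and NB
GLMs on counts with log total-count offsets (1-df LRT) -- the offset is a
deliberate choice to prevent library-size confounding; a zero/normal
mixture LRT on log values with per-group detection rate, mean and variance
(3 df); and a two-part hurdle combining a binomial detection LRT with a
pooled-variance Gaussian LRT on positive values (2 df). The hurdle model
is a simplified two-part test: no empirical-Bayes shrinkage of the
continuous part and no detection-rate covariate, hence the name
`hurdle_lrt` rather than any package's trademark. The single-cell NB test
estimates its per-gene dispersion by solving the Pearson moment equation
$\sum_c (y-\hat\mu)^2 / (\hat\mu(1+\phi\hat\mu)) = n-2$, a choice that
keeps a genes-by-cells fit tractable.

Pseudobulk tests (`de_pseudobulk()`), on `aggregate_pseudobulk()` output:

* `nb_lrt` / `nb_wald` -- NB GLM with log library-size offsets at the
  *shrunk* dispersions, tested by 1-df LRT or by coefficient /
  Fisher-information SE;
* `nb_qlf` -- NB fit at *trended* dispersions plus a per-gene
  quasi-dispersion (residual deviance / df) squeezed by the same
  empirical-Bayes machinery as the variances, referenced to an F
  distribution. This is the finite-sample-robust member of the family;
* `mod_t_trend` -- per-gene linear model on log2-CPM, variances squeezed
  toward a lowess trend in average expression, t on d0 + df degrees of
  freedom;
* `voom` -- the mean-variance trend converted to per-observation precision
  weights (interpolated fourth-power inverse of the trend fitted to
  sqrt-residual-SD versus log-count), weighted least squares, then the
  moderated t without a trend on the prior.

### Dispersion estimation

`fit_nb_dispersion()` maximizes the Cox-Reid adjusted profile likelihood
(the $-\tfrac12\log\det I$ correction for the two estimated group means)
over a dense grid in $\log_{10}\phi$ (floor 1e-8, ceiling 1e3, step 0.1)
with parabolic interpolation at the optimum -- accuracy about 1e-3 in
log-dispersion, ample for testing, at a cost that stays vectorized across
genes. Without the Cox-Reid term the six-sample profile MLE is biased low
and the LRT's type I error roughly doubles. The log-dispersion trend is a
lowess fit against average log-CPM using only genes whose optimum is
interior to the grid (floor-stuck genes would drag the trend down), and
raw estimates are shrunk toward the trend on the log scale with weights
$d/(d + \texttt{prior\_df})$, default prior 10 df. All-zero genes have no
estimable dispersion and are excluded from NB result tables.

`squeeze_variances()` fits the scaled-F hierarchy
($s^2 \sim s_0^2 F(d, d_0)$) by matching moments of $\log s^2$, with a
Newton inversion of the trigamma function; when the observed spread is no
larger than sampling alone, $d_0$ is capped at 1e9 and, in the exactly
degenerate all-equal case, $s_0^2$ is set to the common value so the
posterior reproduces it exactly.

## Concordance and bias diagnostics

`aucc()` quantifies agreement between two DE rankings: for each depth
$j = 1..k$ the size of the intersection of the top-$j$ sets is summed and
divided by the maximum $k(k+1)/2$; $k = 500$ by default. It is symmetric,
lies in [0, 1], and, because rankings come from the statistic-first rank,
is immune to p underflow. `signed_spearman()` complements it
transcriptome-wide: |statistic| signed by the log-fold-change, rank
correlated between methods. `aucc_by_expression_tercile()` recomputes the
AUCC inside three equal bins of mean expression (ties broken by gene id
for determinism); `false_positive_genes()` / `false_negative_genes()`
extract the discrepant calls at a 10% FDR against a reference analysis;
`expression_quantile_bias()` maps each gene's mean expression through the
empirical CDF (average-rank tie convention) and averages over a method's
200 top-ranked genes, so 0.5 is unbiased and values near 1 mean the method
chases highly expressed genes.

## Delta-variance

`shuffle_pseudoreplicates()` permutes replicate labels uniformly *within
each condition* -- preserving the two-group design and every sample's cell
count while destroying which cells actually came from which replicate.
`delta_variance()` compares per-gene variance of log2-CPM expression
across biological pseudobulks versus these pseudo-replicates (variance
computed within condition, then averaged, so any condition-level signal is
never counted); `delta = var_pseudo - var_bio`, negative when shuffling
destroys variance. Under replicate heterogeneity the vast majority of
genes lose variance -- the mechanism by which pseudo-replicates (and,
in the limit of one cell per pseudo-replicate, cell-level tests) overstate
significance. `delta_variance_correlations()` ties the loss to expression
level and to expression variance (Spearman, plus rank-based partial
correlations), and `decile_de_counts()` shows discoveries concentrating in
the high-|delta| deciles.

## Experiment scale choices

The calibration and false-discovery experiments run at the simulator's
default scale (10,000 genes, 500 cells, 3 + 3 replicates, 10 simulations),
with DE-gene counting at BH q < 0.05. The delta-variance experiment
instead uses 2,000 cells and the standard detection filter (genes in at
least 3 cells): the variance-loss signature is a property of real datasets
with hundreds of cells per replicate, and at ~83 cells per pseudobulk the
counting noise of weakly expressed genes masks the sign of delta for a
sizable minority of genes. Scaling sweeps use 2,000 genes and 5
simulations per grid point over 3-10 replicates and 100-2,000 cells --
gene count does not affect per-gene calibration, only the resolution of
the counts, and the trends under test are directions, not magnitudes.

Under the fully homogeneous null, the moderated tests (`nb_qlf`,
`mod_t_trend`, `voom`) and the cell-level rank/mean tests hold their
nominal size closely. Two families do not, for reasons inherent to the
models rather than the implementation: the Poisson LRT is misspecified on
NB counts (the simulator's BCV floor guarantees overdispersion) and
rejects far above nominal; the 3-df mixture LRT inherits the variance
component's sensitivity to non-normal log counts. The unadjusted NB tests
(`nb_lrt`, `nb_wald`) run a few points above nominal at three samples per
group -- the known finite-sample cost that quasi-likelihood moderation
exists to pay down.

## Reproducibility

Every stochastic function takes an explicit seed, experiment drivers
derive per-simulation seeds from a master seed, and a fixed configuration
reproduces identical outputs. `scripts/acceptance.R` re-derives the
package's reference quantity (the AUCC of a DE ranking against itself at
k = 500) from a fresh simulation and DE run.
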