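---
title: "Deconvolving RNA- and protein-level regulation from paired time courses"
author: "rateshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving RNA- and protein-level regulation from paired time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rateshift)
```

## The problem

When a cell responds to a stimulus — the motivating setting is tunicamycin-
induced ER stress sampled at 0, 0.5, 1, 2, 8, 16, 24 and 30 h in two
biological replicates — changes in protein concentration can be driven at
the RNA level (transcription and mRNA degradation) or at the protein level
(translation and protein degradation). Concentration data alone cannot
separate synthesis from degradation, but their *ratio* is identifiable:
under first-order kinetics with synthesis rate $s$ and degradation rate
$d$, an outcome molecule $Y$ tracks its precursor $X$ at quasi-steady state
as $Y \approx (s/d)\,X$. On the natural-log scale,

$$\log Y_t - \log X_t = \theta_t + \varepsilon_t,
\qquad \theta_t = \log(s_t/d_t),$$

so the residual series of log outcome minus log precursor carries the log
synthesis:degradation rate ratio plus measurement noise. The package runs
this deconvolution twice per replicate: an **RNA-level** analysis with a
constant artificial precursor (DNA copy number, assumed unchanged over
30 h), whose residuals are simply log RNA; and a **protein-level** analysis
with RNA as precursor and protein as outcome. Replicates are always fitted
separately, because replicate discrepancies are themselves of interest.

## The change-point model

$\theta$ is modelled as piecewise constant over the inter-timepoint
intervals, with possible jumps only at the interior grid points (0.5, 1, 2,
8, 16, 24 h for the 8-point grid). The observation at time $t_j$ reports
the $\theta$ of the interval *ending* at $t_j$; the $t=0$ observation is
attached to the first interval. A change at an interior point separates
the interval ending there from the interval starting there, which matches
the interpretation of a rate ratio estimated from data at the beginning and
end of each time period.

For a gene with residuals $y$ and change indicators
$z \in \{0,1\}^{6}$:

* $z$ has an exchangeable Beta–Bernoulli prior, $\mathrm{Beta}(a, b)$ with
  $a = 1, b = 4$ (prior change probability 0.2, weak).
* Within each segment implied by $z$, the level $\theta_s$ has a Gaussian
  slab $N(m_0, \sigma^2/\kappa_0)$, conjugate with a shared
  Inverse-Gamma$(\alpha, \beta)$ prior on the gene's noise variance
  $\sigma^2$. The coupling $\kappa_0 = \beta / ((\alpha - 1)\,v_0)$ is
  chosen so the *marginal* slab variance equals the configured $v_0$.

With this Normal–Inverse-Gamma structure the marginal likelihood of every
segmentation is closed-form, so the exact posterior over all
$2^6 = 64$ segmentations is computed by enumeration (`mode = "enumerate"`,
the default). The **change point score** at an interior time point is the
posterior probability $\Pr(z_t = 1 \mid y)$; the per-interval posterior
mean and SD of $\theta$ follow by mixing the conjugate segment posteriors
over segmentations. A collapsed Gibbs sampler (`mode = "gibbs"`) samples
$z$ coordinate-wise from the same marginals for grids with more than 20
interior points, and is validated against enumeration in the test suite
(agreement within 3 Monte-Carlo standard errors, batch-means SEs with a
floor of $\sqrt{\tilde p (1-\tilde p)/n}$, $\tilde p = (x + 0.5)/(n+1)$,
so saturated frequencies keep nonzero uncertainty).

### Empirical-Bayes hyperparameters

Defaults are estimated from the residual matrix at fit time and can all be
overridden in `peca_config()`:

* **Slab centre and width** — median and variance of the per-gene mean
  residuals. These describe where segment levels live (gene baselines span
  about one log unit in the motivating data).
* **Noise variance prior** — per-gene variances estimated from successive
  differences: with a piecewise-constant mean, at most a couple of the
  seven differences straddle a change point, so the median of the squared
  differences estimates $2\sigma^2$ robustly, uncontaminated by the
  regulated minority's signal. The estimator's small-sample bias and
  effective degrees of freedom were calibrated once by Monte Carlo
  (150,000 normal series per length; e.g. bias 1.36, df 2.5 at 8 points)
  and the between-gene spread is deconvolved with `limma::fitFDist`. When
  the fit reports infinite prior df — noise genuinely shared across genes,
  as in homoscedastic data — the Inverse-Gamma shape is capped at 100.
  A naive method-of-moments fit on raw per-gene variances was rejected
  during development: signal variance from regulated genes inflates it
  several-fold and blunts the detection of single-observation pulses.
* **Change rate** (`eb_pi = TRUE`, default) — after a first pass the
  expected number of changes is pooled over all genes and interior points
  into the Beta prior, and the fit is repeated until the genome-wide
  change rate is self-consistent (an EM iteration on the shared rate;
  it converges in 3–4 passes). Without this second stage the weak
  Beta(1, 4) prior leaves mid-range scores overconfident — isolated noise
  excursions of 2–3 SD claim posterior change probabilities near 0.5 while
  almost never being true changes — which in turn makes the direct
  posterior FDR anticonservative. Pooling the rate across genes is the
  same logic limma applies to variances.

### Significance and FDR

Scores are pooled per level and replicate, and the cutoff $c$ is the
smallest observed CPS with

$$\widehat{\mathrm{FDR}}(c) =
\frac{\sum_{\mathrm{CPS}_i \ge c} (1 - \mathrm{CPS}_i)}
     {\#\{\mathrm{CPS}_i \ge c\}} \le 0.05 .$$

If no cutoff qualifies the threshold is `NA` (no signal at that FDR) and
nothing is called. Event direction is the sign of the posterior-mean
$\theta$ difference across the point; an exact zero reports `"none"`.

## Preprocessing

The chain mirrors standard practice for microarray/LFQ time courses, in
this order: RNA — natural-log transform, quantile normalization per
replicate (`limma::normalizeQuantiles`; ties share the mean reference value
of their ranks), complete-case filter, spikiness filter, lowess smoothing.
Protein — sum normalization of LFQ intensities per sample excluding the
`ceiling(0.05 n)` largest values (so extremely abundant proteins cannot
dominate the normalizer), then the same chain with log transform and no
quantile step.

The **spikiness** statistic jackknifes the total range of variation:
delete one point at a time, record $\mathrm{TRV}_j = \max - \min$ of the
remainder, and report $\mathrm{median(TRV)}/\mathrm{min(TRV)}$. A single
aberrant point inflates every TRV except the one where it was deleted.
Genes at or above 3 (RNA) or 2 (protein) are removed. Conventions for the
degenerate cases: a constant series scores 1 (all TRVs zero — maximally
clean, retained); a flat series with one spike scores `Inf` (removed).
Lowess smoothing (`stats::lowess`, default span 2/3 and 3 robustifying
iterations) runs on the actual hour axis, not the sample index, because the
grid spacing varies 16-fold. The replicate consistency measure is the
Pearson correlation between the replicates' series with the usual
$t_{n-2}$ p-value; at $n = 8$ points, $r = 0.7$ corresponds to $p = 0.05$.

## Synthetic data with known kinetics

Two generators share one truth model (per gene and level: baseline
$\theta$, pattern, shift sign) and differ in how concentrations arise:

* `simulate_qss()` draws data from exactly the model the inference
  assumes: log RNA $= \theta^{R} + $ noise, log protein $=$ noise-free log
  RNA $+\ \theta^{P} +$ noise. It is the calibration instrument — on it,
  posterior probabilities should be honest.
* `simulate_ode()` integrates $dM/dt = s_R - d_R M$,
  $dP/dt = s_P M - d_P P$ with piecewise-constant rates, starting at
  steady state, using exact piecewise-analytic solutions. Concentrations
  relax toward new rate ratios with first-order lags, so this generator is
  deliberately *mismatched* to the quasi-steady-state inference model and
  probes robustness. It converges to the QSS relationship as degradation
  rates grow.

Regulatory programs follow the two shapes seen in the motivating study:
a **pulse** shifts $\theta$ at 2 h and reverts at 8 h (so only the 2–8 h
interval carries the shifted ratio — observed RNA regulation is typically
transient), and a **switch** shifts at 2 h permanently (protein regulation
typically establishes a new steady state). Default conditions are the
study design: 8-point grid, 2 replicates, 10% regulated genes per level,
1.5 log-unit shifts with random sign, log-normal noise with SD 0.2,
baselines $N(5,1)$ (RNA) and $N(2,1)$ (protein rate ratio). The noise
model is an assumption — the study reports no generative noise model —
and single-point spikes (`inject_spikes`) and missing values
(`inject_missing`, exact-count placement `round(rate × cells)` for
testability) are injected separately so the filters can be exercised.
All randomness flows from the single config seed through a fixed draw
order (RNA truth, protein truth, then per-replicate noise).

What the generators do **not** emulate: peptide-level MS artefacts,
probe effects, protein-group ambiguity, cell-population dynamics, or
correlated (non-iid) measurement noise. Passing calibration on QSS data
therefore shows the statistics are internally consistent, not that real
data meet the model's assumptions; the ODE generator covers one specific,
kinetically motivated form of misspecification.

## Phase summaries, discordance, buffering, clustering

Interior points map to response phases: early (< 2 h), intermediate
(2–8 h, both boundaries included, following the figure axes of the
motivating study), late (> 8 h). A gene's phase call takes the maximum
CPS over the phase's points (ties toward the earlier point), with
direction at the maximizing point; phase-wise 3×3 RNA × protein direction
tables follow. **Discordant** genes have negatively correlated RNA- and
protein-level $\theta$ trajectories in *both* replicates plus at least one
significant event at each level (in at least one replicate — the wording
of the source filter is ambiguous; the per-replicate detail is returned so
either reading can be audited). **Buffered** genes are discordant genes
whose protein fold span (max/min over the course, the strictest natural
reading of "changes smaller than 1.5-fold") stays below 1.5 in both
replicates.

Clustering uses correlation distance (1 − Pearson, rows centered) with
average linkage. The static mode cuts at height 0.604; the dynamic mode is
a simplified hybrid tree cut written for this package (the reference
algorithm's implementation is not a dependency): the static cut is refined
by reassigning clusters smaller than the minimum size (default 30) to the
large cluster whose mean profile they correlate with best. Static cut is
the reference mode for tests. Cluster-averaged $\theta$ trajectories are
reported for the six largest clusters, and heatmap export orders genes by
cluster, centers rows at their medians, and converts natural logs to base
10 for display.

## Numerical choices and limitations

* Enumeration is exact and vectorised over genes; 1,000 genes fit in
  under a second per replicate. The Gibbs mode memoises segmentation
  marginals per gene and is only needed beyond 20 interior points.
* The test suite and the acceptance script use 150–1,000-gene simulations
  with 2 replicates — sizes chosen so the full calibration suite runs in
  well under a minute while keeping binomial error on FDR/power estimates
  a few percent.
* Quantile normalization can partially absorb a single-point spike into
  the reference distribution (rank mapping); the spikiness filter
  therefore operates after normalization, as in the source protocol, and
  its exact-removal guarantees are tested on the protein chain whose sum
  normalization preserves spikes.
* Identifiability: $s$ and $d$ are never separated, only their ratio; a
  simultaneous proportional change in both is invisible by design.
* The direct posterior FDR is only as honest as the CPS. On QSS
  simulations at the study conditions the empirical FDR at the 0.05
  threshold sits near 0.08 (slightly anticonservative, within the
  tolerance the calibration tests assert); on strongly misspecified data
  it inherits whatever miscalibration the model has.
* Single-observation segments (a pulse's 2–8 h interval) are detected at
  ~0.95 per-gene probability under default conditions but are the first
  casualties of weaker effects or heavier noise.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 300, seed = 7)
sim <- simulate_qss(cfg)
pipe <- peca_pipeline(sim$rna, sim$protein)
pipe$rna$thresholds[[1]]
head(pipe$protein$events[[1]])
calls <- phase_calls(pipe$rna$fits[[1]],
                     pipe$rna$thresholds[[1]]$threshold)
contingency_table(calls,
                  phase_calls(pipe$protein$fits[[1]],
                              pipe$protein$thresholds[[1]]$threshold),
                  "intermediate")
```
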