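# rateshift

Deconvolution of paired mRNA/protein expression time courses into RNA-level
and protein-level regulation, for systems biologists studying stress
responses (the motivating setting is the unfolded protein response under ER
stress, sampled at 0, 0.5, 1, 2, 8, 16, 24, 30 h in two replicates).

Concentrations alone cannot separate synthesis from degradation, but under
first-order kinetics at quasi-steady state the outcome tracks its precursor
through the rate *ratio*:

    log Y_t − log X_t = θ_t + ε_t,   θ_t = log(s_t / d_t)

The package models θ as piecewise constant between sampling times, with
possible jumps at interior grid points, and computes for each gene the
exact Bayesian posterior over all segmentations (conjugate
Normal–Inverse-Gamma likelihood, Beta–Bernoulli change prior, 2^6
enumeration for the 8-point grid; a collapsed Gibbs sampler for longer
grids). The **change point score** (CPS) at an interior time point is the
posterior probability that θ changed there; calls are thresholded by the
direct posterior FDR, estFDR(c) = Σ(1−CPS)/#{CPS ≥ c} ≤ 0.05.

Run with a constant artificial precursor, the residuals are log RNA and
the result is RNA-level regulation (transcription vs mRNA decay); run with
RNA as precursor and protein as outcome, it is protein-level regulation
(translation vs protein decay). Replicates are fitted separately.

Around the model sit the accompanying stages:

* preprocessing: natural-log transform, per-replicate quantile
  normalization (RNA), LFQ sum normalization excluding the top 5%
  intensities (protein), complete-case filtering, a jackknife
  total-range-of-variation "spikiness" filter (median(TRV)/min(TRV),
  thresholds 3 / 2), lowess smoothing on the hour axis, and the replicate
  consistency measure (Pearson r between replicates; r = 0.7 at n = 8 is
  p = 0.05);
* phase summaries (early < 2 h, intermediate 2–8 h, late > 8 h), RNA ×
  protein direction contingency tables, discordant-gene detection
  (anticorrelated θ trajectories in both replicates plus significant
  events at both levels) and buffering (protein fold span < 1.5 in both
  replicates);
* profile clustering (correlation distance, average linkage, static
  0.604 cut or a simplified dynamic tree cut) with cluster-averaged θ
  trajectories;
* two seeded simulators with known kinetic ground truth — one matched to
  the inference model (calibration), one integrating the first-order ODEs
  (robustness) — plus spike and missing-value injection.

## Worked example

```r
library(rateshift)
cfg  <- sim_config(n_genes = 300, seed = 7)   # 10% regulated per level
sim  <- simulate_qss(cfg)
pipe <- peca_pipeline(sim$rna, sim$protein)

pipe$rna$thresholds[[1]]
#> $threshold
#> [1] 0.3343084
#> $est_fdr
#> [1] 0.04094376

head(pipe$protein$events[[1]], 3)
#>   gene_id time       cps direction
#> 2 G000002    2 0.9999977      down
#> 3 G000045    2 0.9989461        up
#> 4 G000059    2 0.9999550      down
```

The replicate-1 RNA threshold is the smallest observed CPS keeping the
estimated FDR at or under 5% (here 0.334, attaining 0.041); the protein
events table lists each significant protein-level regulation change with
its interior time point (here 2 h, where the simulator places switch
shifts), CPS, and direction of the θ change. Phase-wise joint direction
counts:

```r
rna_calls  <- phase_calls(pipe$rna$fits[[1]],     pipe$rna$thresholds[[1]]$threshold)
prot_calls <- phase_calls(pipe$protein$fits[[1]], pipe$protein$thresholds[[1]]$threshold)
contingency_table(rna_calls, prot_calls, "intermediate")
#>       protein
#> RNA     up none down
#>   up     0   16    0
#>   none  11  247   11
#>   down   1   14    0
```

Of 300 genes, 16 are regulated up at the RNA level only and 22 at the
protein level only during the intermediate phase — the two regulatory
layers acting independently, as the off-diagonal structure shows.

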