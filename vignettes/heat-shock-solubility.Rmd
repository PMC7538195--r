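---
title: "Modelling heat-shock proteome solubility, disaggregation and thermal stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heat-shock proteome solubility, disaggregation and thermal stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatsol)
```

## The analysis and its assumptions

`heatsol` implements a proteome-wide analysis of protein solubility under a
brief, non-lethal heat shock in human cells. The measurement design it
models: cells are heat-shocked (44 °C, 10 min) or mock-shocked (37 °C),
sampled over a recovery time course (0, 1, 2, 3 and 5 h), lysed with a mild
detergent (NP-40, recovering the soluble pool) or with SDS (recovering total
protein), and quantified by TMT reporter intensities. A dynamic-SILAC medium
switch ~90 min before the shock splits the proteome into a light
(pre-existing) and a heavy (newly synthesized) fraction. A companion
two-dimensional thermal-proteome-profiling (2D-TPP) experiment exposes
aliquots to a 12-point temperature gradient (37.0–66.3 °C; 2 mock and 3
heat-shock replicates) and quantifies the soluble remnant at each
temperature.

The quantities the pipeline derives, and the rules it applies:

* **Solubility** of a protein at time $t$ is the replicate-matched log2
  ratio of its soluble-fraction intensity between heat- and mock-shocked
  samples. The package computes replicate-matched differences, not
  differences of replicate means; the two coincide in expectation, and the
  matched form is what the replicate-paired moderated test requires. This
  is an assumption worth stating because raw channel pairing across
  replicates is a design choice, not a mathematical necessity.
* An **aggregator** is a protein with BH-adjusted moderated-t p-value
  < 0.05 *and* solubility below $\log_2(2/3) \approx -0.585$ at the
  heat-shock time point (t = 0). Both cuts are strict, matching the
  "below"/"lower than" phrasing of the thresholds. Only t = 0 is tested;
  the later time points enter through the disaggregation fit instead.
* The **moderated t** shrinks per-protein variances toward an
  empirical-Bayes prior fitted by the method of moments on the log
  variances (digamma/trigamma matching). When the observed spread of log
  variances does not exceed the sampling spread, the prior degrees of
  freedom are infinite and the prior variance is the mean sample variance
  (the unbiased choice under the chi-square model). With prior df 0 the
  statistic reduces exactly to the ordinary one-sample t, which the test
  suite exploits as an equivalence oracle.
* The **disaggregation rate** is the OLS slope of mean solubility against
  time over the full course, t = 0 included; fits use across-replicate
  means (one trajectory per protein). Proteins with fewer than three
  quantified time points are not fitted.
* A pre-existing **insoluble sub-population** is flagged when the pre-shock
  total solubility (NP-40/SDS log2 ratio) is strictly below −0.6.
* The **2D-TPP stability score** of a protein is
  $\sum_T (d_T - b)$ with $d_T$ the heat-minus-mock difference of log2
  fold changes relative to the 37.0 °C channel and $b$ the mean of $d$ at
  the two sub-shock temperatures (37.0, 37.8 °C). The baseline removes the
  signal of aggregation that happened before the gradient, under the stated
  assumption that the mock sample has not aggregated at those temperatures.
  Replicates are resampled 500 times (one heat and one mock replicate drawn
  per temperature), scores are z-standardized across proteins within each
  round, each protein's 500 standardized scores are tested against zero
  (BH-adjusted: the "local FDR"), the per-protein means are standardized
  again into the final score, and a robust empirical null on the final
  scores yields tail-area q-values (the "global FDR"). A hit requires both
  FDRs below 0.01 and quantification at ≥ 6 temperatures; the sign of the
  final score separates stabilized from destabilized.

## Choices where the design was genuinely open

* **Round-wise z-direction.** "Scores transformed to z-scores" admits two
  readings; the package standardizes *across proteins within a round*, so
  rounds are comparable and the final across-protein z is meaningful. The
  bootstrap draws are also shared across proteins (a replicate is an
  experiment-level unit), which is what makes a per-round cross-protein
  panel well defined. A consequence, stated honestly: per-protein bootstrap
  deviations from exhaustive-enumeration means are one strongly correlated
  block, so convergence checks are calibrated on the panel average rather
  than protein by protein.
* **The 500 bootstrap values in a t-test.** The per-protein deviation test
  treats the 500 resampled z-scores as a sample, although they are
  dependent (only $3^{12} \times 2^{12}$ distinct composites exist, drawn
  with replacement). This is a faithfulness choice, not a statistical
  endorsement; the dual-FDR gate downstream is what controls the hit rate,
  and the null calibration test shows the combination holds (≤ 2% hits on
  heat ≡ mock data).
* **"Local FDR".** Implemented literally as the BH-adjusted bootstrap
  p-value; the empirical-null machinery (robust sigma from the central 50%
  of scores via the MAD, a central-mass $\pi_0$ estimate, BH on tail-area
  p-values) lives in the global FDR.
* **Variance-stabilizing calibration.** The vsn-like step is written in the
  package as quantile-matched affine calibration per channel followed by
  glog2: channel quantiles (10th–90th percentile) are regressed on a
  reference channel's, and $x \mapsto \mathrm{glog2}((x-a_c)/b_c)$ is
  applied. This preserves the defining contract (monotone, variance roughly
  independent of intensity, exact recovery of affine distortions) while
  keeping the coefficients explicit, so they can be frozen on the light
  fraction and transferred to the heavy fraction, whose intensity *growth*
  over the time course is signal that must not be normalized away.
  Light/heavy channels are matched by their physical TMT coordinates
  (condition, time, replicate, lysis), not by label.
* **Batch correction** is the additive per-protein model: batch means are
  equalized, the per-protein grand mean is preserved, and the operation is
  idempotent. On balanced designs it agrees with limma's
  `removeBatchEffect` up to a per-protein constant (a test asserts this).
* **Imputation** draws missing cells from a down-shifted Gaussian
  (mean $\mu_c - 1.8\sigma_c$, SD $0.3\sigma_c$ per channel): the standard
  left-censored proteomics choice, matching the missing-at-low-intensity
  mechanism the generator plants. A channel with fewer than three observed
  values is an error rather than a silent fallback.
* **Hsp70-binding motifs.** The verbal rule (4–5 hydrophobic residues
  flanked by positive residues) is pinned as: a maximal run of 4 or 5
  residues from {L, I, V, F, M, W, Y} immediately preceded *and* followed
  by K or R. Because the flanks are disjoint from the core set, a
  basic-bounded run is automatically maximal and counts once; the alphabet
  sits behind one constant.
* **pI** uses the EMBOSS pKa set (pinned and exported in the feature-table
  attributes), bisection on the strictly decreasing net-charge curve to
  1e-4. **Molecular weight** uses average residue masses plus one water.
  **Gravy** is the *sum* of Kyte–Doolittle values over the sequence — the
  convention of this analysis, deliberately not the length-normalized mean,
  which is available via `normalize = TRUE`.
* **Scrambled complexes.** "Maintaining the frequency distribution of
  aggregators in complexes" is implemented by resampling per-complex
  aggregator slot counts from the empirical real-complex counts and filling
  slots without replacement from the pooled aggregator set; the real and
  null sets then share their size structure. The real-vs-null comparison is
  a rank-sum (independent-samples) Wilcoxon of per-complex mean pairwise
  Euclidean distances, exact when both sides have ≤ 10 untied values.
  Complex eligibility: ≥ 75% of members quantified and ≥ 2 aggregators;
  display selection: ≥ 75% quantified and ≥ 60% aggregators.
* **Recovery normalization** divides each recovery time point by the t = 0
  solubility (1 = still fully aggregated, 0 = recovered); subtraction is
  available behind `method = "subtract"`.

## What the synthetic generator emulates

`generate_proteome()` plants, per protein: class (6.3% aggregators by
default, the study's observed fraction of ~300/4786), a log2 solubility
drop of $-(0.6 + \mathrm{Lognormal}(\log 0.5, 0.5))$ for aggregators (so
every planted aggregator sits strictly below the calling cut), a linear
recovery slope, disorder fraction, abundance, synthesis kinetics with a
rare HSP-like heat induction, melting parameters (midpoint, slope, plateau)
with optional heat-induced midpoint shifts, an amino-acid sequence, and
complex memberships with aggregator-biased and coherence-planted
complexes.

Numerical choices worth recording:

* **Rank correlations are planted exactly.** The drop–slope and
  disorder–slope Spearman targets (−0.42 and +0.25, the magnitudes the
  recovery analysis is built around) are induced by an Iman–Conover
  rearrangement with a few calibration iterations, so the *sample* rank
  correlation of the emitted truth table sits within ~0.005 of target for
  every seed, not just in expectation.
* **Slopes are slow.** Recovery slopes are Gamma(2, scale 0.05) — mean
  0.1 solubility-units/h — so the median planted loss is only ~45%
  recovered at 5 h. Disaggregation in human cells over this window is slow
  and partial, and the slow regime also keeps trajectories inside the
  linear-relaxation domain: with fast slopes most trajectories truncate at
  zero within the window, and the truncation biases the measured
  drop–slope correlation well beyond its planted value.
* **Relaxation is linear and truncated**: expected log2 solubility is
  $\min(0, \mathrm{drop} + \mathrm{slope}\cdot t)$, which makes the OLS
  slope of an untruncated noise-free trajectory exactly the planted rate.
* **Sequences** are per-class multinomial draws (lognormal lengths;
  aggregators longer) over human-like amino-acid frequencies, with
  aggregators enriched for K, R, E and depleted of I, L, V, F. That single
  composition shift reproduces all four downstream feature contrasts
  (lower gravy, higher pI, higher MW via length, and the negative
  correlation between composition differences and hydrophobicity).
* **Heavy-label kinetics**: $1 - e^{-k(t + 1.5\,\mathrm{h})}$, the 1.5 h
  mirroring label incorporation during the medium-switch window, damped
  after heat shock by a translational stall (depth 0.5, 1 h recovery
  constant) — newly synthesized proteins carry the same solubility factor
  as the pre-existing pool, so both fractions show the same aggregators.
* **Noise model**: per-cell log-normal noise (σ = 0.15 log2 units for the
  course, 0.1 for TPP), per-channel scale effects (σ = 0.05), per-batch
  offsets (σ = 0.1), and probit left-censoring around a detection quantile
  (3% by default). Values without a stated counterpart in the source
  analysis are the package's own choices of a realistic regime and are
  deliberately not revisited.
* **TPP curves** are plateau-lifted falling logistics in temperature; heat
  curves shift by the planted ΔTm, and aggregators' heat channels at the
  two sub-shock temperatures are scaled by $2^{\mathrm{drop}}$ (the pool
  already lost to aggregates). Through the 37 °C-referenced fold changes
  and the baseline correction this makes aggregators read out as
  *stabilized* — the soluble-remnant effect the 2D-TPP analysis reports —
  without any ΔTm shift.

What the generator does *not* emulate: peptide- and spectrum-level effects
(ratio compression, co-isolation), cell-to-cell variability, nonlinear or
chaperone-limited disaggregation kinetics, and any coupling between a
protein's sequence and its planted kinetic parameters beyond class
membership. Passing tests therefore certify the statistical machinery and
its calibration on data with the assumed structure — not that real
mass-spectrometry data satisfies that structure.

## Problem sizes used in the checks

The test suite and the acceptance script run at desk scale, chosen so each
check has the power it needs: 2,000–4,500 proteins for calling, FDR and
correlation recovery (≥ 250 called aggregators for the correlation bands),
20 seeds × 2,000 proteins for null calibrations, 500 bootstrap rounds
against the exhaustive 64-assignment oracle on reduced 3-temperature
instances, 200 permutation runs for null-uniformity, and 10,000 scrambled
complexes where the frequency-preservation contract is asserted exactly.

## Known limitations

* The bootstrap deviation test inherits the dependence of its resamples;
  its raw p-values are anti-conservative and should only ever be used
  inside the dual-FDR gate, as here.
* The glog transform compresses genuinely low-intensity signals; transferred
  light coefficients are therefore least accurate for the dimmest heavy
  channels (the light/heavy consistency test compares the bulk, not the
  extreme tail).
* The empirical-null global FDR assumes the central 50% of final scores is
  null-dominated; with a majority of truly shifted proteins the null width
  would be overestimated and the gate conservative.
* `fit_slope` is deliberately linear; it reports the average recovery rate
  over the window, not a mechanistic rate constant.
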