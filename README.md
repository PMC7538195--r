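# heatsol

Proteome-wide analysis of protein solubility under heat shock in human
cells, for proteomics researchers working with dynamic-SILAC/TMT solubility
time courses and two-dimensional thermal proteome profiling (2D-TPP).

A brief heat shock drives a small set of proteins out of the
detergent-soluble pool; over the following hours they disaggregate at
protein-specific rates, and their soluble remnants show altered thermal
stability. `heatsol` implements the statistics of that analysis end to end,
together with a synthetic-data generator that plants known ground truth so
every stage can be verified without the original mass-spectrometry data.

## The statistics at the core

* **Solubility**: per protein, replicate and time point, the
  replicate-matched log2 ratio of soluble-fraction (NP-40) intensity
  between heat- and mock-shocked samples.
* **Aggregator calling**: empirical-Bayes moderated one-sample t on the
  t = 0 replicate differences — prior fitted by digamma/trigamma
  method-of-moments, posterior variance
  (d₀s₀² + d·s_g²)/(d₀ + d) — with BH adjustment; a protein is an
  aggregator iff adjusted p < 0.05 **and** solubility < log₂(2/3).
* **Disaggregation rate**: OLS slope of mean solubility over the 0–5 h
  recovery course; feature correlations (hydropathy, pI, MW, disorder, …)
  use Pearson or Spearman under a Shapiro–Wilk gate at p ≥ 0.05.
* **Sequence features**: summed Kyte–Doolittle hydropathy (gravy),
  isoelectric point (EMBOSS pKa set, bisection on the net-charge curve),
  average molecular weight, amino-acid composition, and a scanner for
  Hsp70-binding motifs (4–5 hydrophobic residues flanked by K/R).
* **Complex coherence**: mean pairwise Euclidean distance between complex
  members' solubility vectors, tested against scrambled complexes that
  preserve the per-complex aggregator-count distribution (rank-sum
  Wilcoxon); Fisher's exact test for membership enrichment.
* **2D-TPP stability score**: per-temperature vsn-style normalization, log2
  fold changes against the 37.0 °C channel, baseline-corrected summed
  heat-minus-mock differences (baseline = mean of the two sub-shock
  temperatures), a 500-round replicate-resampling bootstrap, per-round
  z-standardization across proteins, and dual FDR hit calling (BH-adjusted
  bootstrap p < 0.01 **and** empirical-null tail-area q < 0.01, ≥ 6
  temperatures quantified).

## Worked example

```r
library(heatsol)

truth    <- generate_proteome(n_proteins = 2000, seed = 42)
course   <- filter_quality(simulate_solubility_course(truth, seed = 43))
light    <- subset_channels(course, course$channel_meta$silac == "light" &
                                    course$channel_meta$lysis == "NP40")
profiles <- compute_solubility(
  impute_missing(correct_batches(normalize_vs(light)), seed = 44))
calls    <- call_aggregators(profiles)
summary(calls)
#> Aggregator calling (moderated t + fold-change gate)
#>   proteins tested:  1917
#>   aggregators:      123
#>   soluble:          1794
#>   prior: d0 = Inf, s0^2 = 0.04836

slopes <- fit_slopes(profiles)
agg    <- calls$class == "aggregator"
cor.test(calls$solubility_hs[agg], slopes$slope[agg],
         method = "spearman", exact = FALSE)
#> rho = -0.43, p = 7.3e-07

tpp <- tpp2d(simulate_tpp2d(truth, seed = 45), seed = 46)
tpp
#> tpp2d_fit: 2000 proteins, 500 bootstrap rounds
#>   hits (local & global FDR < 0.01, >= 6 temps): 132 stabilized, 12 destabilized
#>   empirical null: sigma0 = 0.265, pi0 = 0.699
```

Reading the numbers: of 2,000 simulated proteins, 1,917 pass the
two-peptide/two-replicate quality filter and 123 are called aggregators
(126 were planted, 6.3%); the infinite prior df means the replicate
variances were homogeneous enough to pool completely. The called
aggregators' solubility drop and recovery slope are rank-correlated at
−0.43 — deeper drops, faster disaggregation — recovering the planted
−0.42. In the thermal readout, aggregators dominate the 132 stabilized
hits because the pool already lost to aggregates before the gradient
raises the soluble remnant's apparent stability.

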