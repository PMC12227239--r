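# orthotherm

Comparative analysis of protein thermal stability between closely related
species, built around thermal proteome profiling (TPP). Two yeasts that
differ in thermotolerance — *Saccharomyces cerevisiae* and *S. uvarum* —
also differ proteome-wide in how hot their proteins can get before
falling out of solution. `orthotherm` provides the full analysis chain
for quantifying that divergence: from peptide-level TMT reporter
intensities to per-protein melting temperatures, ortholog-pair
statistics, allele-specific contrasts in an interspecific hybrid,
orthogonal spectroscopic and enzymatic melt estimates, and
structure-based ΔΔG divergence summaries. A synthetic-data generator with
recorded ground truth makes every stage testable end to end.

## What it computes

**Melting temperatures from TPP.** Soluble-fraction profiles are built
from MaxQuant-evidence-like tables: intensities are standardized to a
spiked-in reference protein (BSA), summed over PSMs per protein, and
scaled to the lowest treatment temperature. Each profile is fit with a
four-parameter logistic

  f(T) = c + (d − c) / (1 + exp(b (T − e)))

and the reported Tm is the temperature at which the fitted curve falls to
half its value at the lowest treatment temperature. Bootstrap 95% CIs are
computed by resampling PSMs (proteins with ≥ 8 PSMs). Datasets run on
different effective temperature scales are made comparable by regressing
reference Tm on the other dataset's Tm and applying the fitted affine map
to that dataset's temperature vector before refitting.

**Ortholog divergence statistics.** Mean ΔTm and the fraction of pairs in
which one species is more stable (exact binomial sign test), consistency
across replicate datasets, Wilcoxon and paired-t hybrid-versus-parent
contrasts, Fisher-exact annotation enrichment with a logistic
species-interaction test, abundance-adjusted species effects
(Tm ~ species + abundance), and Spearman rank correlations.

**Orthogonal melt estimates.** Two-state van 't Hoff fits
(K(T) = exp(−ΔH/R (1/T − 1/Tm)), ΔCp = 0) to circular-dichroism melts
with optional linear baselines; five-parameter logistic IT50 estimation
from growth-yield and blank-corrected residual enzyme-activity series.

**ΔΔG divergence.** Per-substitution forward and reverse folding
free-energy predictions are combined antisymmetrically
((forward − reverse)/2; negative means the *S. uvarum* residue is less
stable), filtered on structure confidence (mean pLDDT ≥ 70,
lDDT ≥ 0.70), aggregated per protein (mean, sum, max + min − mean), and
summarized proteome-wide with direction sign tests and |ΔΔG| effect bins.

## Worked example

```r
library(orthotherm)

cfg <- sim_config(n_proteins = 60, seed = 3)      # study-like defaults
sim <- simulate_tpp_experiment(cfg)               # 2 parental replicates
res <- fit_dataset(sim$evidence$rep1, sim$specs$rep1)
pairs <- filter_fits(res$fits)$pairs
divergence_summary(pairs$delta_tm)
```

```
Ortholog Tm divergence summary
  pairs: 41   mean dTm: +1.628 degC
  fraction positive: 0.829 (n = 41)   binomial p: 2.53e-05
```

Of the 60 simulated ortholog pairs, 41 survive the quality funnel
(PSM ≥ 3 in both species, fit r² ≥ 0.8). The recovered mean Tm difference
(+1.63 °C, *S. cerevisiae* minus *S. uvarum*) and the fraction of pairs
with the *S. cerevisiae* ortholog more stable (83%) match the generating
parameters (1.6 °C, 85%); the sign test rejects equal stability.

A single fit is an ordinary model object:

```r
prof <- build_profiles(standardize_to_spike(sim$evidence$rep1, sim$specs$rep1),
                       sim$specs$rep1)$profiles
p1 <- prof[prof$protein_id == prof$protein_id[1], ]
fit <- fit_melt_curve(p1$temperature, p1$value, protein_id = p1$protein_id[1])
print(fit); coef(fit); plot(fit)
```

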