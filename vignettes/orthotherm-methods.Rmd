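---
title: "Models and methods in orthotherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in orthotherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthotherm)
```

`orthotherm` quantifies interspecies divergence in protein thermal
stability. This vignette documents the models it fits, the assumptions
behind them, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical and design choices a careful user should know about.

## The TPP melt model

Thermal proteome profiling heats lysate aliquots across a temperature
gradient, removes aggregated protein, and quantifies what remains soluble
by multiplexed (TMT) mass spectrometry. For each protein the relative
soluble fraction across temperatures is modeled with a four-parameter
logistic,

$$f(T) = c + \frac{d - c}{1 + e^{b (T - e)}},$$

with upper asymptote $d$ (the low-temperature level), lower plateau $c$,
steepness $b$ (1/°C, $b > 0$ for a melting protein) and inflection $e$.

**Definition of Tm.** The reported melting temperature is the temperature
at which the *fitted* curve equals half its fitted value at the lowest
treatment temperature. This is the operational "soluble level reduced by
half" definition; with a nonzero plateau it differs from the inflection
parameter, which is also returned (`tm_infl`). When the fitted plateau
lies above half the initial level the half-crossing does not exist and
the fit is flagged (`no_half_crossing`) rather than reported.

**Profile construction.** Peptide intensities are first standardized to
the spiked-in reference protein: every channel is divided by the spike's
summed intensity in that channel. Because any per-channel loading or
labeling factor multiplies the spike and the analytes alike, this cancels
channel effects exactly up to the spike's own measurement noise. Profiles
are then PSM sums per protein scaled to the lowest-temperature channel,
which makes the profile an intensity-weighted mean of per-PSM profiles.
Proteins with fewer than 3 PSMs are dropped (configurable), and fits with
$r^2 < 0.8$ are excluded downstream; both thresholds follow standard TPP
practice, and the $r^2$ rule is *inclusive* (exactly 0.8 is retained,
since the exclusion is of fits strictly below the cutoff).

**Optimization.** The fitter is Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with three starts (inflection at the 25th/50th/75th
percentile of the temperature range; ties broken by lowest SSE, then
lowest Tm), followed by a refinement on the profiled objective: given
$(b, e)$ the model is linear in $(c, d)$, so the two nonlinear parameters
are polished on the closed-form-profiled SSE (quasi-Newton, then
restarted Nelder–Mead at `reltol` $10^{-16}$), with $c$ clamped at 0. The
refinement matters because the 4PL SSE surface around its minimum is a
long, shallow valley: optimizers that stop at a conventional relative
tolerance can sit $10^{-9}$ above the minimum yet report a Tm several
hundredths of a degree away. With the refinement, the fitter agrees with
an independent dense-grid-search oracle to 0.05 °C on essentially every
profile, which is what the test suite asserts. Degenerate inputs (fewer
than 5 usable points, constant profiles, non-convergence) yield flagged
records, never errors, so a pipeline run always completes with an
auditable funnel report.

**Bootstrap confidence intervals.** For proteins with at least 8 PSMs,
95% CIs come from a percentile bootstrap over PSMs (default 100
resamples, seeded). A known limitation: at typical PSM counts the
percentile interval mildly undercovers — in our simulations long-run
coverage of the nominal 95% interval is about 88%. Intervals are withheld
(not fabricated) below 8 PSMs.

**Cross-dataset renormalization.** Datasets run on different days or
plexes sit on slightly different effective temperature scales. Following
the regression-calibration approach, Tm values are estimated in each
dataset separately, the reference dataset's Tms are regressed on the
other dataset's Tms over shared proteins (both species included, so both
receive equivalent adjustment), and the fitted affine map is applied to
the other dataset's *temperature vector*, after which all its profiles
are refit. Because the map is affine with positive slope, within-dataset
Tm rank order is preserved. Two caveats are inherent to the procedure:
ordinary least squares on noisy Tm estimates attenuates the slope
slightly toward zero (errors-in-variables), and any *differential*
biological effect present in the dataset being calibrated — such as a
hybrid-specific stabilization of one species' alleles — is partially
absorbed into the calibration line (roughly half of a one-species shift
moves into the intercept when the two species contribute equally). For
this reason the hybrid stabilization contrast in the tests is computed on
unrenormalized fits, where the generator guarantees no global scale
difference; with real multi-batch data the bias trade-off should be kept
in mind when interpreting per-species hybrid shifts.

## Hybrid allele-specific analysis

In an interspecific hybrid both parental alleles share one cellular
environment, so allele-resolved Tms separate sequence-encoded stability
from cellular context. Peptides whose sequence occurs in both parental
proteomes cannot be assigned to an allele and are removed before
quantification (the removed fraction is reported; exact string matching,
I/L distinct). Two contrasts are computed on proteins measured in both
contexts: a Wilcoxon signed-rank test of paired |ΔTm| (do ortholog
differences shrink in the common environment?) and per-species paired
t-tests of Tm(hybrid) − Tm(parent) (which species' alleles moved?). The
Wilcoxon test uses the exact distribution for n ≤ 25 and the
continuity-corrected normal approximation above, trading exactness for
runtime reproducibly.

## Direction statistics and covariates

Sign tests are exact two-sided binomial tests (minimum-likelihood
two-sided convention, as in `binom.test`). Pairs with exactly zero ΔTm
are dropped from the sign-test denominator by default — the standard
sign-test convention — and the all-pairs denominator is reported
alongside, since published percentages do not always state their
treatment of ties. Annotation enrichment uses Fisher's exact test per
species plus a logistic regression `stabilized ~ annotation * species`
whose interaction term tests whether enrichment differs between species.
The abundance adjustment fits `Tm ~ species` and
`Tm ~ species + abundance` by OLS and reports both species coefficients;
the Wald p-value of the abundance term is reported as the test of whether
abundance changes the species effect (the literature formulation of this
"difference test" is not standardized; this choice is simple and
conservative).

## Two-state spectroscopic melts

Circular-dichroism melts are normalized to mean residue ellipticity,
$[\theta]_{MR} = 100\,\theta/(l c N)$, and scaled by the trace minimum to
give a normalized secondary-structure index. Unfolding is modeled as
two-state with van 't Hoff equilibrium $K(T) = e^{-\Delta H/R\,(1/T -
1/T_m)}$ ($\Delta C_p = 0$, $R = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹,
Kelvin internally, °C at the interface), fraction folded $f = 1/(1+K)$,
so $f(T_m) = 0.5$ identically. Model 1 fits the normalized trace with
flat baselines (1 and 0); Model 2 adds linear pre- and post-transition
baselines in the observed signal. The exact baseline parameterization is
reconstructed from the standard two-state description; it is validated by
round-trip recovery tests (noiseless traces return Tm to < 0.05 °C and
ΔH to < 1%) rather than by matching any specific legacy implementation.
Aggregation of these proteins is irreversible in practice, so the fits
are operational melt summaries, not equilibrium thermodynamics.

## IT50 dose-response

Thermotolerance endpoints (growth yield after temperature challenge;
residual enzyme activity after heat treatment) are fit with the decadic
five-parameter logistic

$$y = B + \frac{Top - B}{\left(1 + 10^{\,b(m - T)}\right)^s},$$

whose asymmetry exponent $s$ accommodates skewed transitions. IT50 is the
temperature at which the fitted response falls to half the fitted maximum
over the observed range, found by root bracketing on a 512-point grid and
`uniroot`; only *descending* crossings count, so monotonically rising
responses are flagged as having no inhibition point. When $s = 1$ and
$B = 0$ this reduces to the midpoint parameter $m$. CIs are a seeded
parametric bootstrap of residuals. Residual activity is the maximum
kinetic slope over a fixed window of consecutive plate-reader time points
(default window 6, the minimum of the conventional 6–12 range, maximizing
sensitivity to the fastest linear phase; an OLS-slope option exists),
blank-corrected and normalized to the 25 °C treatment. Negative
blank-corrected slopes at high temperature are retained — the 5PL bottom
asymptote absorbs them.

## Antisymmetric ΔΔG divergence

Substitution-stability predictors are approximately antisymmetric:
ΔΔG(X→Y) ≈ −ΔΔG(Y→X). Averaging the forward prediction with the negative
of the reverse, $(F - R)/2$, cancels symmetric prediction bias and halves
independent noise variance ($\mathrm{Var}((F-R)/2) = \sigma^2/2$ when
both carry independent noise of variance $\sigma^2$). The sign convention
is fixed once — negative means the *S. uvarum* residue is less stable —
and every downstream direction derives from it, so relabeling the species
negates all combined values, all aggregates, and maps a direction
fraction $f$ to $1-f$ (a property the tests assert). Substitutions are
extracted from pairwise alignments at columns where both residues are
present and differ; indel columns are counted separately and excluded,
since the predictors score substitutions only. Records missing either the
forward or reverse member are excluded from combined aggregates but kept
in the table. Structure-confidence filters (mean pLDDT ≥ 70 across both
species, lDDT ≥ 0.70 versus the reference structure set) are inclusive at
the cutoff, matching "removed below threshold" semantics. Per-protein
aggregates are the mean, the sum, and the largest-deviation metric
max + min − mean. Proteome direction summaries report both the
sign-informative and the all-protein denominators, since published
percentages do not always state which was used. Effect bins on |ΔΔG| are
half-open $[lo, hi)$ with an open top bin, so edge values assign
deterministically; bin bootstrap SEs resample substitutions within
protein.

## The synthetic-data generator

The generator emulates the statistical structure of a two-species TPP
study with an interspecific hybrid; its defaults are the study
conditions the package is validated against:

| parameter | default | meaning |
|---|---|---|
| `n_proteins` | 500 | ortholog pairs |
| `parent_temps` | 10 values, 30–72 °C | parental TMT10 gradient |
| `hybrid_temps` | 16 values, 30–72 °C | hybrid TMT16 gradient |
| `tm_base_mean`, `tm_base_sd` | 50, 4 °C | *S. uvarum* Tm distribution |
| `species_offset_mean` | 1.6 °C | signed mean interspecies offset |
| `frac_positive` | 0.85 | share of pairs with the *S. cerevisiae* ortholog more stable |
| `hybrid_stabilization_mean`, `_sd` | 1.1, 0.3 °C | hybrid-context stabilization of *S. uvarum* alleles |
| `shared_peptide_frac` | 0.43 | species-ambiguous hybrid peptides |
| `intensity_noise_cv` | 0.1 | multiplicative lognormal reporter noise |
| `psm_per_protein` | mean 6, dispersion 2 | shifted negative binomial, min 1 |

The exact treatment temperatures of any given instrument run are
configuration, not constants; equally spaced 30–72 °C vectors are a
stated assumption. The interspecies offset is drawn as sign ×
folded-normal magnitude, with the sign positive with probability
`frac_positive` and the magnitude location solved numerically so that the
*signed* mean equals `species_offset_mean` — both the direction fraction
and the mean offset are then simultaneously faithful. (With
`frac_positive = 0.5` the signed mean is necessarily 0 and the
configuration is rejected otherwise.) Reporter noise is multiplicative
lognormal with unit mean, reflecting positive, heteroscedastic TMT
intensities. PSM counts have a minimum of 1 and substantial dispersion so
the PSM ≥ 3 and ≥ 8 filters genuinely bite. Per-channel factors are drawn
once per dataset and applied to all peptides including the 30-PSM
spike-in — an abundant purified standard yields many PSMs, and this is
what makes spike standardization both identifiable and quantitatively
clean (a sparse spike would inject a coherent pseudo-batch shift into
every Tm). A replicate-level affine distortion of the generating Tm
(`batch_tm_shift`) exercises renormalization.

What the generator does **not** emulate: raw spectra and chromatography,
isotopic interference and reporter-ion ratio compression, peptide-level
missingness beyond the PSM-count distribution, post-translational
modification effects, and correlated (complex-level) stability. Passing
tests therefore demonstrate correctness of the estimators under the
stated noise model, not robustness to every artifact of real MS data.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed; identical configuration
and seed give byte-identical output, and all fitters are deterministic
given data. The test and acceptance workloads use 150–500 proteins per
simulated dataset, 20-seed detection loops, 200-seed null-calibration
loops at the measurement level, and a 200-profile fitter-versus-grid
oracle comparison — sizes chosen to give stable sampling distributions
for each check while keeping a full run in minutes on a single core.
Under the all-zero-effect null, each divergence test's rejection rate
stays within binomial slack of its nominal α, and with effects at their
defaults the pipeline recovers the generating mean offset to ±0.2 °C,
the direction fraction within binomial error, median per-protein |Tm
error| well under 0.5 °C, and the hybrid stabilization to ±0.15 °C.

## Known limitations

- Percentile bootstrap CIs undercover somewhat at small PSM counts (see
  above); a BCa or studentized interval would be a natural upgrade.
- Regression-based renormalization attenuates under Tm measurement noise
  and partially absorbs differential effects (see above).
- The two-state CD model assumes ΔCp = 0 and reversibility; fitted ΔH is
  an operational van 't Hoff enthalpy.
- Shared-peptide detection is exact string matching; it does not model
  near-isobaric ambiguity or razor-peptide assignment.
- ΔΔG aggregation assumes additivity across sites (no epistasis), and the
  mapping from ΔΔG to ΔTm is deliberately out of scope.
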