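---
title: "Methods: production estimation, temperature scaling, and resource correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: production estimation, temperature scaling, and resource correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamprod)
```

This vignette is the package's own account of the models it implements, the
choices made where the design was genuinely open, and what the synthetic-data
generator does and does not establish about real field data.

## The estimation chain

**Temperature scale.** All temperature dependences are slopes on the
standardized inverse Boltzmann temperature
`x(T) = 1/(k·T_ref) − 1/(k·T)` with `k = 8.62e-5 eV K⁻¹` and
`T_ref = 15 °C`, so `x(15) = 0`, `x` increases with temperature, and an OLS
slope of a log-transformed quantity on `x` is an apparent activation energy
in eV with the conventional sign (positive = increases with warming). The
printed form of this standardization is ambiguous about operator precedence;
we use the only reading under which a rate that accelerates with warming has
a positive slope and biomass (which should decline with warming at fixed
resources) a negative one. `k` is kept at the two-digit literature value
rather than the longer CODATA expansion so results are reproducible against
the ecological literature that uses it.

**Individual growth.** Chamber incubations give
`g = ln(W_{t+Δt}/W_t)/Δt` (d⁻¹). Chambers are aggregated as mean initial
versus mean final mass (individuals are photographed in groups;
per-individual pairing is not assumed). Negative chamber growth is retained
in the raw tables but excluded (and counted) from the log-linear model
`ln g = ln i0 + a·ln M + E_ind·x(T)`, since `ln g` is undefined for
`g ≤ 0`. For synchronous cohorts, growth comes from the shift in
size-frequency distributions: individual masses at the two dates are
resampled with replacement — resample size equal to the observed count on
each date — and the pair is redrawn (up to 1000 attempts per replicate)
whenever the resampled final mean does not exceed the initial mean.
Rejection resampling, rather than truncating masses, preserves the marginal
size distributions; if no valid pair can be drawn the cohort is rejected
with an error rather than silently returning zeros. Input order is
canonicalized (sorted) so the estimate depends only on the multiset of
masses.

**Production.** The instantaneous growth method:
`P = g·Δt·(B_t + B_{t+Δt})/2` per taxon × 0.25 mm size class, summed over
classes, populations, and intervals. Standing biomass at each date is
bootstrapped by resampling the replicate field samples (default five
0.023 m² Surber samples) with replacement; subsample splits (1/2–1/16) are
expanded before resampling, and all taxa share the same resampled set of
field replicates within a bootstrap draw so spatial covariance among taxa
is preserved. A field replicate with zero catch on a date is a genuine
zero, not a missing sample. The alternative resampling unit — individuals
within samples — would understate spatial variance among replicates, which
for aggregated benthic invertebrates is usually the dominant component;
resampling whole replicate samples keeps it.

**The pairing contract.** One bootstrap run assigns a replicate index that
is shared by growth, biomass, production, P:B and everything derived from
them: all arithmetic is replicate-wise, community production is the exact
replicate-wise sum over populations, and annual production the exact sum
over intervals. This makes `P = B × (P:B)` hold replicate by replicate,
and consequently the slope additivity
`E(P) = E(B_corrected) + E(P:B_corrected)` holds exactly per outer
bootstrap replicate (the ±0.25 mass corrections cancel in the product).
The test suite asserts this to 1e-10. Endpoint dates of an interval are
resampled independently; growth distributions measured with a different
replicate count are resampled to the production `n_boot` before pairing.
Intervals are the gaps between consecutive sampling dates (no
back-extrapolation before the first date); gaps over 45 days trigger a
warning, not an error.

**Activation energies.** `fit_activation_energy()` is a double bootstrap:
each of `n_boot` (default 10 000) outer replicates draws one inner
bootstrap replicate of the quantity for every unit (stream, or interval
within a stream) and fits the OLS slope of the log quantity on `x`; the
mean and the 2.5/97.5 percentiles of the slope distribution are reported
(percentile CIs, not BCa, matching how the inner intervals are formed),
with r² taken from the point fit on unit means. Resampling the *units*
themselves is available but off by default: with six streams, unit
resampling frequently produces degenerate draws (few distinct x values)
and is not obviously implied by the procedure being emulated; the switch
`resample_units = TRUE` enables it, and degenerate outer replicates are
then dropped and counted. The inner draws are a deterministic function of
the seed and the unit structure, which is what makes the slope-additivity
identity testable.

**Mass correction.** Community `B` and `P:B` are corrected by the
biomass-weighted mean individual body mass `M_c = Σ(B_i·M_i)/Σ(B_i)`
(computed per replicate from the same bootstrap run) raised to the
theoretical exponents ±0.25. "Correction" here means *removing* the
theoretical mass effect — `B` is divided by `M_c^0.25` and `P:B` multiplied
by it — the direction under which the two corrections cancel in `P` and the
expected sign pattern (negative `E_b`, positive `E_pb`) is coherent. The
opposite direction is available via `direction = "multiply"`, and exponents
other than 0.25 are accepted with a warning.

**Resource models.** Among streams, five OLS candidates
(`null`, `temp`, `chla`, `temp + chla`, `temp × chla`) for log annual
production are ranked by AICc
(`−2·logLik + 2k + 2k(k+1)/(n−k−1)`, `k` counting the residual variance);
selection is repeated (default 1000×) on jointly resampled inner replicates
of production and chlorophyll, with temperature as a fixed covariate. Ties
go to the model with fewer parameters, and a candidate whose AICc
correction is undefined at the given number of streams (`n ≤ k+1`, e.g. the
interaction model with six streams) is ineligible rather than an error —
the competition proceeds among the defined candidates. The apparent
temperature dependence is the `temp` coefficient distribution of the
temperature-only model and the resource-corrected one is the `temp`
coefficient of the additive model, accumulated over the same resampled
fits. Within streams, the response is log daily production per interval and
the candidates are all fixed-effect sub-models of
`temp × ln chla × ln light` that respect marginality (19 structures,
enumerated programmatically), each with a random stream intercept, fit by
maximum likelihood for AICc ranking and refit by REML for coefficients —
ML for comparing fixed-effect structures, REML for final estimates.
Singular or non-converging candidate fits are ineligible within a
replicate; replicates where every candidate fails are dropped and counted,
and more than 10% dropped is an error. Light enters as the interval mean of
the daily series; a configurable floor (half the smallest positive value)
guards `ln(0)` should a zero-light interval occur.

**GPP correction.** `ln GPP ~ x + ln light + ln chla` by OLS on monthly
data from the instrumented streams, with a case bootstrap for the
temperature-coefficient distribution. The within-stream corrected
temperature dependence is `E_p_within − E_gpp_within` by independent draws
from the two distributions. The additive log-linear form is an assumption
(the source analyses of such data sit in supplementary material we do not
reconstruct); interactions are deliberately not included.

## The synthetic-data generator

The generator is first-class, tested code: every downstream estimator is
validated by recovering the parameters stored in the `synthetic_truth`
record, never against published values.

*Conditions.* Six streams with mean annual temperatures
27.2, 17.6, 11.2, 5.8, 5.5 and 5.0 °C; ~monthly sampling (12 dates, 30 d
apart); five 0.023 m² replicate samples; four taxa (two chironomid
morphotypes, a blackfly with synchronous cohorts, a snail) with length–mass
allometries `M = a·L^b` and normal length distributions truncated at the
250 µm mesh; growth truth `ln i0 = −3.5`, `a = −0.25`, `E_ind = 0.65 eV`
with lognormal noise SD 0.4 (chosen so the fitted growth model has
substantial but realistic scatter); chlorophyll truth `E_chla = 0.53 eV`
with stone-level lognormal noise SD 0.3.

*Environment.* Temperature and light are phase-shifted sinusoids over 365
days; light peaks at the summer solstice with multiplicative lognormal
daily noise (SD 0.4) and strong relative amplitude (0.8, appropriate to
high latitude); the temperature phase is solved numerically per stream so
the realized Pearson correlation with light matches the configured target
(defaults spanning 0.67 to −0.09 across streams). The annual mean
temperature is exact by construction (a sinusoid sums to zero over a full
period).

*The resource-only control.* Each stream's true annual production is
`P_ref · (chla_ann/chla_ref)^1.2` — temperature affects production *only*
through chlorophyll. Two features make this control identifiable. First,
annual chlorophyll carries a stream-level lognormal residual (SD 0.6)
around the Boltzmann line, leaving roughly half the among-stream variance
in log chlorophyll unexplained by temperature — without it, production
would be an exact function of temperature and the "temperature or
resources?" question would be ill-posed (and the temperature-only model
would win by parsimony). Second, the within-year production shape is
GPP-like, `exp(E_gpp·x(T_d))·light_d` with `E_gpp = 1.37 eV`, renormalized
to mean one within each stream so that seasonal steepening never leaks into
the among-stream annual pattern. Standing biomass is back-calculated as
production over true growth, so warm streams carry less biomass at equal
production, `Σ g·B` equals stored true production identically, and the
within-stream corrected dependence (`E_p_within − E_gpp`) is centred on
zero by construction. Counts are negative-binomial (dispersion 2; Poisson
available) — replicate-to-replicate spatial variance of benthic samples is
not well constrained by the literature, and the overdispersion default is a
free parameter, flagged here. Records with large expected counts are
binomially thinned to emulate subsampling splits (1/2–1/16).

*Default magnitudes.* `chla_at_ref = 30 mg m⁻²` and
`annual_P_at_ref = 3 g AFDM m⁻² y⁻¹` put simulated annual production in the
range of a few tenths to ~10 g AFDM m⁻² y⁻¹ across the temperature
gradient — the right order for sub-arctic streams, though a narrower range
than the most extreme field gradients, since the generator drives
production through one resource channel only.

*What passing tests do not show.* The generator draws all noise as
lognormal/Gaussian on the log scale with known structure, taxa have
stationary size distributions, no emergence, drift, or mortality pulses,
no taxonomy errors, and chlorophyll is a clean resource proxy. Recovery on
these data demonstrates the estimators are consistent and their CIs honest
*under the stated noise model* — not that field data meet that model. In
particular, the coverage of activation-energy CIs reflects only the noise
sources the bootstrap resamples (field replicates, stones, dates); real
between-stream residual variation beyond these sources widens scatter
without widening the CIs, which is inherent to the procedure being
implemented, not a property of this implementation.

## Problem sizes and numerical choices

Defaults follow the procedure the package implements: 500 replicates for
cohort growth, 1000 for production/biomass, 10 000 for activation-energy
slopes, 1000 for each model-selection exercise. The test suite and
acceptance script scale some of these down — bootstrap sizes of 100–1500,
mixed-model selection replicates of 12–200, recovery studies of 25–100
seeds — sizes at which every Monte-Carlo tolerance in the tests (3
standard errors) is still meaningful. Monte-Carlo assertions use
enumeration oracles (exhaustive expectation over all resampling outcomes on
two-point/tiny instances) rather than frozen random numbers.

Degenerate inputs are errors, not silent results: non-positive masses or
durations, cohorts whose final masses never exceed initial, all-zero
community biomass in a replicate, zero-biomass P:B, fewer than 3 units (4
intervals within-stream) for a slope, missing growth sources (the offending
taxon is named), undefined AICc corrections, and out-of-schema CSV rows
(with row numbers). AICc ties break toward fewer parameters. Exact
identities (community = Σ populations; slope additivity; `W_t·e^{gΔt}`
inversion) are asserted at 1e-10–1e-12, i.e. floating-point accumulation
error only.

## Known limitations

- Within an interval, growth is evaluated at the interval mean temperature;
  no correction for non-constant temperature within intervals.
- Production methods other than instantaneous growth (size-frequency /
  Hynes, removal-summation) are out of scope, as are emergence and drift
  accounting.
- The within-stream resource correction borrows `E_gpp` from two
  instrumented streams and applies it to all; stream-specific resource
  production is not modelled.
- Mixed-model selection with small interval counts per stream can be
  sensitive to singular-fit handling; the replicate-drop accounting makes
  this visible but cannot remove it.
- The deposited field dataset of the study system this package emulates is
  not bundled; all validation is against synthetic truth.
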