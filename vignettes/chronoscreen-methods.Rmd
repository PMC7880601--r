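---
title: "Methods behind chronoscreen: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind chronoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoscreen)
library(dplyr)
```

# The problem

Many anticancer drugs act on targets whose abundance oscillates with the
circadian clock, so their efficacy can depend on the time of day at which
they are delivered. A chrono-pharmacological screen measures this directly:
cultured cells are synchronized with a dexamethasone pulse, groups of
plates are treated with each drug at staggered times after synchronization
(24, 30, 36, 42 and 48 h — five treatment phases at 6-h spacing, with 24 h
and 48 h representing the same circadian phase one cycle apart), and
viability is read out after a fixed incubation. Each drug is arrayed as an
eight-point threefold dilution from 10 µM, giving final doses
10, 3.33, 1.11 µM, 370, 123, 41, 14 and 4.6 nM, with solvent (DMSO) and
positive-kill (doxorubicin) control columns on every plate.

chronoscreen implements the complete analysis of such a screen, plus the
follow-up analyses that typically accompany it (reporter rhythm fitting,
cell-cycle synchrony, tumor growth comparison), and a synthetic-data
generator that emulates the screen design so the whole pipeline is testable
end to end.

# Plate QC and normalization

Each plate is analyzed independently. Assay quality is summarized by the
standard screening-window statistic

$$Z' = 1 - \frac{3(\sigma_{pos} + \sigma_{neg})}{|\mu_{pos} - \mu_{neg}|},$$

with plates accepted when $Z' > 0.5$ (configurable). Control means use a
10% trimmed mean by default so a single stuck well cannot shift the
normalization anchor; the SDs entering $Z'$ are untrimmed. Test wells are
rescaled to normalized percent inhibition,

$$\mathrm{NPI} = \frac{\mu_{solvent} - y}{\mu_{solvent} - \mu_{positive}}
\times 100,$$

which maps solvent-like wells to 0% and full-kill wells to 100%. NPI is
deliberately not clamped: values outside [0, 100] flag fit problems and
carry information about outlying wells. NPI is invariant to affine gain
changes of a plate's reader, which the tests verify.

# Dose–response fitting and capping

Each drug × phase series is fitted with the variable-slope four-parameter
logistic

$$\mathrm{NPI}(c) = b + \frac{t - b}{1 + 10^{(\log_{10}\mathrm{IC}_{50} -
\log_{10} c)\,h}},$$

by bounded Levenberg–Marquardt least squares with five starts spaced
across the tested log-dose range (best residual sum of squares wins; ties
break toward $|h - 1|$ smallest). Bounds — top ∈ [50, 120], bottom ∈
[−20, 50], hill ∈ [0.1, 5], log10 IC50 ∈ [−4, 3] — stabilize fits at the
edges of the dose range. Replicates enter as individual points, so
better-replicated doses carry proportionally more weight.

Estimates that extrapolate outside the tested range are capped: computed
IC50 ≥ 25 µM (or a non-converged curve with mean NPI < 25%) is assigned
25 µM; computed IC50 ≤ 0.001 µM (or a non-converged curve with mean NPI >
75%) is assigned 0.001 µM. A fitted curve whose plateaus separate by less
than 5 NPI points is treated as non-converged, because its midpoint is not
identified by the data. Capping is idempotent and applied after every fit,
so degenerate inputs produce a structured capped result rather than an
exception.

Temporal profiles divide each phase's IC50 by the first-phase (24 h)
value, so every profile starts at exactly 1; missing interior phases are
flagged, never interpolated. The peak-phase bin is the argmax over the
non-anchor phases {30, 36, 42, 48}, ties toward the earlier phase.

## Why rhythm testing uses per-replicate profiles

A single pooled fit per drug × phase yields a five-point profile. For the
five-phase design the exact rank-test null has so few distinguishable
orderings that the smallest attainable Bonferroni-adjusted p is 0.133 —
no drug could ever be called rhythmic from such a profile, regardless of
effect size. The pipeline therefore also fits one curve per replicate,
anchored to that replicate's own first-phase IC50, and tests the
replicated profile (15 observations). The pooled fit remains the reported
IC50 table; the per-replicate profiles feed the rhythm test. This mirrors
how the replicated timed-viability series are tested directly.

# The JTK-Cycle test

The rhythmicity test is a from-scratch implementation of the JTK-Cycle
idea: compare the observed ordering of a time series against phase-shifted
cosine reference orderings using Kendall's S, and take the best lag with a
Bonferroni correction for the lag search.

**Templates.** For period $T$ (default 24 h, configurable), one template
is built per candidate lag on the sampling grid. The reference value at
time $t$ is $\cos(2\pi (t - \ell)/T)$ reduced to ranks; equal reference
values receive tied ranks. Timepoints congruent modulo the period (24 h ≡
48 h) are therefore always tied, as are cosine-symmetric phases (6 h and
18 h at lag 0). Lags half a period apart give exactly reversed orderings,
so both polarities of a rhythm are covered by the grid.

**Statistic.** $S$ = concordant − discordant pairs over all observation
pairs not tied in the template; data ties contribute zero. $S$ depends on
the data only through ranks, making the test invariant under monotone
transformations.

**Exact null.** Under exchangeability, the number of discordances is
distributed as the inversion count of a random multiset permutation whose
multiset is the template's tied-group structure. Its generating function
is the Gaussian q-multinomial, computed here by convolving per-group merge
distributions (each a normalized Gaussian-binomial coefficient vector
obtained from the last-letter recursion $N(a,b) = q^b N(a-1,b) +
N(a,b-1)$). The tests verify this distribution against exhaustive
permutation enumeration for every tied design up to 8 observations, and
its variance against the tie-corrected Kendall formula. Above 30
observations (configurable) a normal approximation with the tie-corrected
variance and a continuity correction is used and flagged in the result.

**Decision.** The best lag maximizes $S$ standardized by its null SD
(ties to the earlier lag); the one-sided exact p at that template is
multiplied by the number of templates (Bonferroni). A series is rhythmic
when the adjusted p falls below α = 0.05. Amplitude is estimated by a
least-squares cosine with period and lag fixed at the selected values —
half the fitted peak-to-trough range, in the series' units — because a
fixed-phase cosinor is transparent and directly testable.

Simulations in the test suite show the type-I error of this procedure at
the screen design (5 phases × 3 replicates) lies in [0.03, 0.06] at
α = 0.05 (2000 null draws): slightly conservative, as expected from the
discrete exact null and the anchor ties in normalized profiles.

# Reporter rhythms

Bioluminescence reporter traces are fitted with a damped cosinor,

$$y(t) = b_0 + b_1 t + b_2 t^2 + A e^{-dt} \cos(2\pi (t - \phi)/T),$$

profiling the linear coefficients at fixed $(T, d)$ and searching the
nonlinear pair from a 1-h period grid over [18, 32] h refined by bounded
quasi-Newton steps. The first 4 h of each trace are discarded by default
(medium-change transient). A trace is rhythmic when the fitted amplitude
exceeds 2 residual SDs and the fit improves on the baseline-only RSS by
more than 20%. The choice of a damped cosinor (rather than spectral
methods such as FFT-NLLS or MESA) keeps one estimator with a clear
contract; period agreement with other rhythm-analysis software is
procedure-level, not numeric. Group comparisons use seeded permutation
tests of the group-mean difference (10⁴ resamples) rather than t-tests:
reporter experiments have small n and no strong normality guarantee.

# FUCCI synchrony

The two FUCCI channels (red = G1, green = S-G2-M) are summarized by: the
dominant period, from the mean-centered red channel's periodogram peak in
the 8–48 h band; the synchrony index, the spectral power at the dominant
frequency divided by total band power (1 for a pure oscillation, near 0
for noise); and the channel phase offset, from the circular
cross-correlation peak. A population is synchronized when the index
reaches 0.5 and the offset is antiphasic within ±25% of the period — the
qualitative criteria made explicit, since published claims are visual.

The generator's desynchronized mode gives each simulated cell a Brownian
phase path whose SD grows by the stated jitter per period. A static
per-cell phase offset would only shrink the population amplitude while
leaving a clean periodic residual; phase diffusion is what actually
destroys spectral coherence, matching how heterogeneous cycle lengths
dephase a real population.

# Tumor growth

Caliper measurements are converted by the standard ellipsoid
approximation, volume = length × width² / 2 (mm³); this quantity is
sometimes labelled "tumor weight" but is treated as a volume here. Each
mouse's volumes are normalized to its day-0 value, and the group rate is
the OLS slope through the pooled normalized points (a per-mouse variant —
slope per mouse, then group mean — is available, since figure legends are
often ambiguous about pooling). The default fits the normalized volumes
on the linear scale, matching the common "linear equation to the
normalized data" convention; `log_scale = TRUE` fits log relative volume
instead, which recovers the exponential growth-rate per day and is the
right scale for rate-ratio recovery (the linear slope through an
exponential arc overestimates both rates and biases their ratio toward
zero through convexity). Group contrasts permute mouse labels (keeping
each mouse's curve intact) with a seeded 10⁴-resample test.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

- **Screen**: 5 phases (24–48 h, 6-h spacing), 8-point threefold dilution
  from 10 µM, 3 replicate wells, 384-well plates with column 1 solvent
  and column 2 positive controls; solvent wells at the full-viability
  mean (100), positive wells at the full-kill mean (5). Test-well expected
  signal follows a 4PL whose log-IC50 oscillates as
  $\mu + a\cos(2\pi(\mathrm{phase} - \mathrm{peak})/24)$.
- **Noise**: multiplicative lognormal with CV 5% for plate signals and
  expression (signals are positive and plate-reader error scales with the
  mean); additive Gaussian for reporter traces; lognormal CV 15% for
  tumor volumes. The raw screen's replicate structure and noise magnitude
  are not published, so these defaults are chosen once as realistic for
  ATP-luminescence readouts and are not tuned.
- **Scenarios**: `wildtype` keeps the drug's programmed rhythm;
  `clock_ko` (BMAL1-null-like) and `cc_arrest` (cell-cycle-arrested)
  force every rhythm amplitude to zero while leaving the dose response
  intact, emulating abolished time-of-day dependence with preserved
  cytotoxicity.

Identical inputs and seed give byte-identical outputs; the pipeline
derives each stage's seed deterministically from one global seed.

What the generator does **not** emulate: spatial plate artifacts (edge
effects, gradients), drug-specific deviations from the 4PL shape,
transcript-to-protein lag between target expression and drug
sensitivity, and any mechanistic clock–cell-cycle coupling — it is
phenomenological by design. Passing tests therefore show the estimators
are correct and well calibrated under the stated statistical structure,
not that real screen data are free of artifacts the generator omits.

# Problem sizes used in the validation suite

The test suite validates calibration claims at sizes chosen to keep a
full run comfortably reproducible on a laptop: 2000 null draws for the
type-I error of the rhythm test, 200 synthetic curves for log-IC50
recovery, 200 seeds for tumor-rate recovery, and a 200-seed scenario
study (100 per arrhythmic scenario, three drugs each) for the
false-rhythmic contract. The exhaustive permutation cross-check of the
exact null covers every tied design up to 8 observations.

# Known limitations

- The exact null assumes no ties among the data values; replicate-anchor
  ties in normalized profiles make the test slightly conservative.
- The Bonferroni adjustment is over lags within one series; no
  multiple-testing correction is applied across a drug panel by default
  (per-series calling at α = 0.05 is the screening convention;
  panel-level FDR can be applied to the returned p-values).
- With only four distinct circadian phases, peak-lag resolution is 6 h;
  phase relations finer than the sampling grid are not identifiable.
- The damped cosinor assumes a single dominant period; traces with
  comparable power at two periods will resolve to whichever fits better.
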