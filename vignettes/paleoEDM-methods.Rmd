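---
title: "Methods: resource-corrected diversity and convergent cross mapping on deep-time series"
author: "paleoEDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resource-corrected diversity and convergent cross mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoEDM)
```

## The problem and the model

Deep-time macroevolutionary series — sampling-standardized marine
invertebrate diversity, organic-carbon burial rates, geodynamic
reconstructions — are short (tens of samples over half a billion years),
autocorrelated, trend-dominated, and digitized from heterogeneous sources.
Plain correlation between two such curves says nothing about direction of
cause. This package implements a complete chain from raw digitized curves to
a directed, surrogate-calibrated causal verdict.

### Time axis and alignment

All series live on an age axis in Myr before present, stored ascending
(0 = today). Dynamical operations need forward time, so series are reversed
internally (oldest first) before embedding; users never handle this.

Series are resampled onto the grid of the coarsest, scientifically central
series — the diversity curve — because interpolation can only be trusted to
*downsample* denser records onto it. Piecewise linear interpolation is the
default estimator; a cubic spline is available to check that the choice of
interpolant does not drive results. Extrapolation is never performed: by
default the base grid is trimmed to the intersection of all spans (with a
warning listing dropped ages), and a strict mode turns non-coverage into an
error naming the offending series.

**Cubic end conditions.** The spline uses Forsythe–Malcolm–Moler end
conditions (the `stats::spline` default): the boundary cubics are fitted
through the four nearest points, so the interpolant reproduces cubic
polynomials exactly. A natural spline (zero second derivative at the ends)
cannot do this — it biases the ends of exactly the short records we care
about — which is why FMM was preferred.

### Partitioning organic-carbon burial

The total organic-C burial rate (from long-term carbon-cycle models) counts
terrestrial burial that marine consumers never see. The sedimentary C/S
weight ratio separates the two realms: sulphate reduction and pyrite
formation accompany marine (especially euxinic) deposition, so low C/S marks
marine-dominated burial, while freshwater systems are sulphate-poor and
leave high C/S. We map C/S linearly onto the terrestrial *fraction* of
total burial,

$$\phi(t) = \phi_{\max}\,
  \frac{C\!/\!S(t) - C\!/\!S_{\min}}{C\!/\!S_{\max} - C\!/\!S_{\min}},
  \qquad
  \mathrm{marine}(t) = \bigl(1 - \phi(t)\bigr)\,\mathrm{total}(t).$$

Mass closure (marine + terrestrial = total) holds exactly by construction
and both components are non-negative for any input.

Two choices deserve flagging:

* **`phi_max`** — the terrestrial share at the C/S maximum is not pinned by
  the C/S anchoring argument itself. It ships as 0.5 (terrestrial burial at
  most on par with marine at its peak, consistent with the modern budget in
  which most organic burial is marine) and should be varied in sensitivity
  runs. Because CCM skill is invariant to monotone rescalings of this kind,
  the causal verdicts are insensitive to `phi_max` in practice; the absolute
  corrected-diversity values are not.
* **Fractional, not absolute, ramp** — terrestrial burial is modelled as a
  fraction of the contemporaneous total rather than an independent absolute
  rate curve. The fractional reading keeps closure and positivity
  automatically; the absolute alternative would need an extra normalization
  constant that nothing in the inputs constrains.

C/S values that interpolation pushes outside the anchor interval are clipped
(with a reported count); the anchors default to the observed extremes of the
C/S series itself.

### Resource-corrected diversity

Corrected diversity is the pointwise quotient `diversity / marine burial`
— lineages supported per unit food supply; what remains is the diversity
signal that a constant-food world would show. The mean-normalized form
(mean exactly 1) feeds the causal tests; max-normalization is provided as a
display convention only. The per-capita classification mean-normalizes
diversity and burial separately and labels each bin `above`/`on`/`below`
the 1:1 line (tolerance 1e-9 on the normalized difference): `above` means
the biota is dominated by lineages with a smaller per-capita food share
than the series average.

## Empirical dynamic modelling core

### Embedding

The shadow manifold of a series is its delay embedding with `E` coordinates
at lags `0, τ, ..., (E-1)τ` of the z-scored series. z-scoring makes
Euclidean distances scale-free; the cross-map skill (a Pearson correlation)
is unaffected. With ~45 samples at ~12 Myr spacing, `τ = 1` step is the only
defensible delay, and `E` is selected by the false-nearest-neighbour test
(`Rtol = 15`, `Atol = 2`, acceptance threshold 1% false neighbours) and
varied over `{2, 3, 4}` as a sensitivity harness. One convention note: some
formulations write lags up to `Eτ` in an (E+1)-dimensional space; this
package follows standard EDM software usage where `E` *is* the number of
coordinates. On pure noise the FNN fraction never reaches the threshold;
the minimizing `E` is returned with an explicit warning rather than a
silent answer.

### Simplex projection

Each query point is predicted as the weighted mean of the target values of
its `E+1` nearest library neighbours, with weights `exp(-d_i/d_1)`
normalized to one (`d_1` = nearest distance). Degenerate cases are pinned
down deterministically: exact matches (`d_1 = 0`) share uniform weight and
all other neighbours get zero; distance ties break toward the lower time
index; a query inside the library is excluded from its own neighbour set
(plain leave-one-out — with so few points no wider temporal exclusion
radius is affordable, and none is needed for maps without strong temporal
smoothness). Every prediction is a convex combination of neighbour targets,
which the tests exploit, and the whole operation is checked against a
brute-force oracle to 1e-12.

### Convergent cross mapping

"A xmap B" estimates B from the manifold of A; substantial, *converging*
skill is evidence that B causally forces A (the forced variable carries the
forcer's information, not vice versa). The library ladder runs from `E+2`
(the smallest usable library) to the full embedding row count in steps of
one; at each rung, 200 libraries are drawn uniformly without replacement
(contiguous-segment sampling is available behind a flag) and the skill is
averaged. At the top rung every without-replacement draw is the full
library, so the value there is deterministic; the implementation computes
it once, which is algebraically identical to averaging identical
replicates. Both the terminal skill (largest library) and the maximum mean
skill over the ladder are reported; the terminal value is the summary
statistic for significance because it is the convergence limit the method
is named after, while the ladder maximum is kept for display comparability.
If a prediction vector is constant (possible at tiny libraries), its skill
is defined as 0 rather than NA.

Identical seeds reproduce every replicate bit-for-bit.

### Surrogate significance

The null model must preserve everything about the series *except* the
claimed dynamical coupling. Ebisuzaki phase randomization does exactly
this: the discrete Fourier amplitudes (hence the full autocorrelation
function) are kept, the phases of all non-DC, non-Nyquist bins are drawn
uniformly with conjugate symmetry, the Nyquist amplitude (even lengths)
keeps a random sign, and the mean is untouched. The *putative cause* — the
cross-mapped target — is surrogated by default, leaving the effect's
manifold intact: this nulls precisely the information CCM claims to
detect while the fixed manifold's neighbour structure is reused across all
draws (a pure speedup, verified equal to the naive loop). Flags allow
surrogating the effect or both series instead. The threshold is the
empirical 95th percentile of 1000 null skills (linear interpolation
between order statistics; with 1000 draws the percentile definition is
immaterial to three decimals), and the verdict is `observed > threshold`.
Both causal directions are always computed in the pipeline, since
directionality is the point of the exercise.

## The synthetic systems: what they emulate, and what not

* `coupled_logistic()` — the standard two-species chaotic benchmark with
  declared coupling; defaults `r_a = 3.8`, `r_b = 3.7`, `beta_ab = 0.3`
  (B forces A), `beta_ba = 0`, n = 45 after a 300-step burn-in. It provides
  exact ground truth for direction recovery at the short record length the
  real analysis faces.
* `phanerozoic_like()` — a 45-point bundle spanning 541–0 Ma (~12.3 Myr
  spacing): a driver with secular trend, ~130 Myr cycle and AR(1) ("red")
  noise; a response that is a one-step-lagged function of the driver plus
  its own red noise (at zero coupling it is independent by construction);
  a positive total-burial curve; and a C/S ratio rising monotonically from
  a low Early-Palaeozoic value to a modern maximum with a late plateau.
  Noise is red rather than white deliberately: geological series are
  strongly autocorrelated, and a white-noise emulator would flatter the
  surrogate test.
* `ar1_null()` — independent AR(1) pairs (default φ = 0.5) for type-I-error
  calibration.

What the emulators do **not** reproduce: mass-extinction spikes,
heteroscedastic digitization error, age-model uncertainty, and any
mechanistic geochemistry. Passing tests on these generators therefore
demonstrate that the machinery is correct and calibrated — not that any
particular real-world causal claim is true.

## Simulation sizes and calibration results

The repeated-trial harnesses use sizes chosen to give useful Monte-Carlo
resolution at interactive cost: 200 trials for size calibration (binomial
95% band around a nominal 5% rate is roughly 2–9% at that count), 50 trials
for power, 200 surrogates per trial in the power harness (1000 in
single-run analyses and in the size harness), and 200 library replicates
per ladder rung. On one CPU the full test suite runs in under a minute.

Two calibration facts computed by the package's own harnesses are worth
stating plainly:

* On independent AR(1) pairs at n = 45 the significance test rejects at
  6–7%, statistically compatible with its nominal 5%.
* On the logistic benchmark at the default coupling 0.3, the true direction
  is declared significant in roughly 55–60% of runs and the false direction
  in well under 20%. The limiting factor is not the skill (the directional
  asymmetry of raw ρ is recovered in ≳95% of runs) but the null: chaotic
  logistic maps are strongly anti-persistent (lag-1 autocorrelation ≈
  −0.7), their surrogates inherit that oscillatory spectrum, and an
  oscillatory target series is partially predictable from any manifold
  sharing its periodicity — so the null 95th percentile sits high. This is
  the surrogate test being honest about spectral confounding, and it is the
  price of a null that cannot be fooled by shared autocorrelation. Power
  rises with coupling (≈80% at 0.5–0.8) and, on the red-noise
  `phanerozoic_like()` bundle, from the nominal rate at zero coupling to
  ≈90% at strong coupling.

## Degenerate inputs and numerical policy

* Constant series: rejected by surrogate generation (no phase content) and
  by FNN (no neighbour structure); embedding of a constant series yields
  zero vectors rather than NaN (z-scoring guards the zero-variance case).
* Non-positive marine burial: a hard error listing the offending ages —
  a corrected diversity with zero food supply is meaningless.
* Duplicate ages, non-numeric rows, and sub-2-row files are rejected at
  read time with the offending row named.
* All file output is written at full double precision (`%.17g`), so runs
  round-trip losslessly and reruns with the same config and seed reproduce
  every output byte-for-byte.

## Known limitations

* With ~45 samples, CCM operates at the edge of its validity; verdicts at
  a single embedding dimension should never be interpreted without the
  E-sensitivity harness, and absence of significance is weak evidence of
  absence.
* The terrestrial-burial `phi_max` is an assumption, not a measurement.
* The per-capita classification depends on mean-normalization of both
  series; it is invariant to rescaling but not to monotone nonlinear
  transforms of either input.
* The pipeline treats its input curves as error-free; digitization and age
  model uncertainty are not propagated.
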