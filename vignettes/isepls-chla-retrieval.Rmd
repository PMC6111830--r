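---
title: "Methods: hyperspectral chlorophyll-a retrieval with ISE-PLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral chlorophyll-a retrieval with ISE-PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperchla)
```

## The retrieval problem

Above-water hyperspectral radiometry yields a water-leaving reflectance
spectrum $R_L(\lambda)$ per station visit, measured at a 1-nm interval over
350–1050 nm, paired with an in-water chlorophyll-*a* (Chl-*a*) measurement
in µg/L. The optical signal of Chl-*a* in productive coastal water sits in
a handful of narrow features — red absorption near 670 nm, a
fluorescence/scattering peak near 685–710 nm that shifts red as
concentration grows, depressed blue reflectance — embedded in a spectrum
dominated by backscatter, CDOM and water absorption. A retrieval model maps
the spectrum to a concentration; this package implements the three model
families usually compared for that task and a common evaluation layer.

## Preprocessing

The measured ends of the grid are noise-dominated, so analysis is
restricted to 400–900 nm inclusive, which at 1 nm is exactly 501 bands.
Spectra are smoothed with a Savitzky–Golay filter (window 15 points,
polynomial order 2). The window length is the common chemometrics setting;
the order is unconstrained by any physical argument, and order 2 is the
default that preserves local curvature while halving white-noise variance.
Both are exposed as arguments. Smoothing is applied **before** trimming, on
the full measured grid, so that filter edge effects fall outside the
analysis range; the two orders differ only within half a window of the trim
boundary (this is tested).

The first derivative reflectance (FDR) uses centered differences at
interior bands and one-sided differences at the two edges. A plain
adjacent-band difference would shorten the grid by one band per
application; the edge stencils keep the 501-band grid intact, so
reflectance and derivative models are selected from, and report
percentages against, the same 501 wavebands.

Remote sensing reflectance is taken as $R_{rs} = R_L / \pi$. The opposite
convention ($\pi R_L$) is seen in the literature; since every model here is
built on band ratios, the constant cancels and predictions are provably
identical under either convention (tested). The multiplied form is
available via `to_rrs(s, "multiply")`.

## The model families

**OC polynomials.** $\log_{10}(\text{Chl-}a) = a_0 + a_1 R + \dots + a_4
R^4$ with $R$ the $\log_{10}$ of the maximum blue/green $R_{rs}$ ratio
(OC2: 490/555; OC3: max(443, 490)/555; OC4: max(443, 490, 510)/555).
Hyperspectral bands are mapped to the nominal SeaWiFS centers by nearest
1-nm band. Recalibration to a local dataset is ordinary least squares of
$\log_{10}$(Chl-*a*) on the quartic polynomial basis — the canonical choice,
and one whose recovery of known coefficients is exactly testable. Samples
with non-positive $R_{rs}$ at a required band are excluded and reported,
never propagated as NaN, because a silent NaN corrupts the max-ratio
selection.

**Band-ratio indices.** The three-band index
$(R_{\lambda_1}^{-1} - R_{\lambda_2}^{-1}) R_{\lambda_3}$ and the NIR/red
ratio $R_{\lambda_{NIR}} / R_{\lambda_{red}}$, both calibrated linearly
against Chl-*a*. Spectral tuning is stagewise: the three-band search scans
$\lambda_1$ over 600–700 nm with $(\lambda_2, \lambda_3)$ initialised at
(700, 750) nm, then $\lambda_2$ over 680–740 nm, then $\lambda_3$ over
700–800 nm; the two-band search scans red over 620–680 nm with NIR
initialised at 705 nm, then NIR over 680–740 nm. Each stage keeps the band
maximising $|r|$ (Pearson, raw index against raw Chl-*a*, matching the
linear calibration that follows). Tuning is a single pass, mirroring the
stagewise procedure the searches are meant to emulate; no iteration to
convergence is attempted. Ties — which in floating point only occur to a
tolerance — resolve to the smallest wavelength, for determinism.

**ISE-PLS.** PLS1 by NIPALS on mean-centered data. Centering without
autoscaling is deliberate: the importance measure
$z_i = |\beta_i| s_i / \sum_i |\beta_i| s_i$ weights each coefficient by
its predictor's standard deviation, which would be meaningless if the
predictors had been scaled to unit variance first. The elimination loop is:
fit PLS on the retained bands, with the number of latent variables (NLV)
re-selected each cycle as the leave-one-out RMSE minimiser over 1..10;
record the cross-validated RMSE; drop the single band with minimum $z_i$;
repeat until 2 bands remain (the jaggedness criterion needs at least two
coefficients; no other stop rule is imposed). The returned band set is the
cycle with the global minimum cross-validated RMSE; ties resolve toward
fewer bands. An alternative reading freezes the NLV from the initial
full-band model; re-selection per cycle is the default here because the
LOO minimum is the in-loop criterion and the jaggedness-penalised choice
below is specific to the final model.

On the selected bands, the final NLV is chosen over candidates $j = 1..10$
by minimising $\mathrm{RMSE}_r + J_r$, where
$J_j = \sum_i (\beta_{ji} - \beta_{j,i-1})^2$ is the jaggedness of the
$j$-component coefficient vector taken in wavelength order over the
retained bands (gaps ignored — zero-filling the full grid would let the
selection pattern, not the coefficients, dominate the penalty), and both
RMSE and $J$ are rescaled to $[0,1]$ over the candidate set by
$(v - v_{\min})/(v_{\max} - v_{\min})$. If all candidates tie on one term,
that term rescales to all zeros (degenerate, logged by the rescaler's
definition). Ties resolve to the smaller count.

## Evaluation conventions

- Validation $R^2$ is the squared Pearson correlation between observed
  values and their leave-one-out predictions; calibration $R^2$ likewise on
  training fits. The $1 - SS_{res}/SS_{tot}$ alternative is computable from
  the returned vectors.
- RMSE uses the $n$ divisor.
- bias $= \mathrm{mean}(\hat{y} - y)$: underestimation is negative.
- RPD $= SD/\mathrm{RMSE}$ with the **population** ($n$ divisor) SD — the
  only form dimensionally consistent with an $n$-divisor RMSE; descriptive
  tables use the sample ($n-1$) SD, as summary tables conventionally do.
  `convert_sd()` moves between the two. RPD classes: $\ge 2$ good,
  $[1.4, 2)$ moderate, $< 1.4$ poor; the class boundaries are assigned
  upward since strict inequalities would leave them undefined.
- Selected-waveband percentages are rounded to one decimal of percent.

## The synthetic campaign generator

No suitable public campaign dataset exists, so the package simulates one.
The forward model per sample is

$$R(\lambda) = \Big[ b(\lambda)\, e^{-c\,(h_r G_{670,6} + h_b G_{443,30})
 - a_{CDOM}(\lambda)} + f\, c\, G_{685 + c, 10} \Big] \cdot w(\lambda)$$

with $c$ the Chl-*a* concentration, $G_{\mu,\sigma}$ unit-height Gaussians,
$b(\lambda)$ a green-peaked baseline (maximum near 580 nm), $a_{CDOM}$ an
exponentially decaying blue absorption, the fluorescence center red-shifting
at 1 nm per µg/L from 685 nm, and $w(\lambda)$ a smooth logistic ramp
suppressing reflectance above ~750 nm. Multiplicative (2%) and additive
($10^{-4}$) Gaussian sensor noise is applied per band and the result is
clipped at zero. Concentrations are drawn log-uniformly over
0.83–14.33 µg/L (59 samples by default, labelled into six station blocks of
12/12/12/12/6/5), giving the right-skewed distribution typical of coastal
campaigns with an expected mean near 4.7 µg/L.

The amplitude constants (red absorption 0.020 per µg/L with $\sigma = 6$
nm, blue 0.050 with $\sigma = 30$ nm, fluorescence $2 \times 10^{-4}$ per
µg/L with $\sigma = 10$ nm) were fixed once so that the generator satisfies
its own design contract: with noise off, the three-band index at
generator-matched bands is strictly increasing in concentration, the
693/666 nm ratio correlates with concentration at $r > 0.9$, and stagewise
tuning recovers the planted red absorption center within ±10 nm. The noise
defaults are small enough that ISE-PLS retains good predictive ability and
large enough to exercise the smoothing step.

**What the generator does not emulate** — and hence what passing tests do
not show about field data: independent variation of suspended sediment,
CDOM and phytoplankton (here a single latent driver, Chl-*a*, plus noise
generates the whole spectrum), bidirectional and sky-glint effects,
radiative-transfer realism of any kind, and inter-station optical
differences. Two consequences deserve emphasis. First, performance numbers
on synthetic campaigns (validation $R^2$ near 1, RPD in the tens) are far
above anything achievable on real coastal data, where RPDs near 2 are
good; the tests assert thresholds ($R^2 > 0.7$, RPD $> 2$), not the
inflated values themselves. Second, because every NIR band carries some
trace of the single driver, the noiseless correlation landscape over
$(\lambda_2, \lambda_3)$ is nearly flat (all $|r| > 0.99$), so while the
tuned $\lambda_1$ and the two-band red band are stable recovery targets,
the tuned NIR bands can drift between near-tied optima when the search is
re-initialised. This is a property of single-driver data, not of the search
code, and it is why the recovery tests pin $\lambda_1$ only.

## Numerical choices and degenerate inputs

- The PLS kernel (C++, Armadillo) stops extracting components when the
  residual weight vector norm falls below $10^{-12} \cdot \|y_c\|$ — i.e.
  when $y$ is numerically exhausted — and replicates the last valid
  coefficient vector for any remaining requested components, so coefficient
  paths stay total; LOO RMSE curves then plateau and the tie rule (smallest
  count within $10^{-9}$ relative tolerance) picks the true rank.
- Leave-one-out folds re-center within the fold; no information from the
  held-out sample reaches its model.
- Constant response, constant index, all-zero importance weights,
  single-band derivative input, non-positive reflectance at model bands,
  misaligned sample ids, non-uniform wavelength grids: all are explicit
  errors or flagged exclusions, never silent propagation.
- Everything downstream of the generator is deterministic; seeds matter
  only in `synthetic_params()`.

## Problem sizes

Tests and the acceptance script run the full pipeline at the campaign's
native size: 59 samples × 501 analysis bands for complete ISE-PLS runs
(about 500 elimination cycles, each with a 59-fold LOO over 10 candidate
NLVs), with smaller grids (e.g. 640–760 nm) for repeated property checks
such as the noise-monotonicity suite, and small random matrices (10–20
samples, 4–8 predictors) for oracle-equivalence tests against a plain-R
NIPALS and per-sample-refit cross-validation.

## Known limitations

- PLS1 only (single response); no PLS2, no uncertainty intervals on
  coefficients.
- The elimination loop drops exactly one band per cycle; with 501 bands
  this is $O(p^2)$ in cross-validations, acceptable here but not for
  10⁴-band instruments.
- OC recalibration fits the quartic in $\log_{10}$ space without
  regularisation; with narrow local ratio ranges the high-order
  coefficients are poorly identified (their predictions inside the observed
  range remain well-behaved, which is all the comparison uses).
- The simulator is a testing instrument, not a radiative-transfer model;
  conclusions about model ranking on real water require real campaigns.
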