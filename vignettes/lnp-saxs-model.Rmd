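---
title: "The core-triple-shell SAXS model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The core-triple-shell SAXS model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnpsaxs)
```

## The model and its assumptions

A lipid nanoparticle is represented as a sphere with a core (radius $R_c$,
scattering length density $\rho_c$) and three concentric shells: the inner
lipid layer ($t_1$, $\rho_1$; ionizable lipid, cholesterol, DSPC tails),
the hydrophilic headgroup layer ($t_2$, $\rho_2$) and the hydrated
PEG corona ($t_3$, $\rho_3$), in a solvent of SLD $\rho_s$. Because the
amplitude of a radially symmetric particle telescopes over its interfaces,

$$A(q) = \sum_{i=1}^{4} \Delta\rho_i \, V(R_i)\, j(qR_i), \qquad
j(x) = \frac{3(\sin x - x\cos x)}{x^3},$$

with $R_1 = R_c$, $R_2 = R_c + t_1$, and so on, and $\Delta\rho_i$ the SLD
step across interface $i$ (outermost step referenced to the solvent). The
forward-scattering delta contribution at $q = 0$ is dropped: all
evaluation grids keep $q > 0$.

For a dilute ensemble the core radius follows a Gaussian distribution
$N(R_c)$ with mean $R_0$ and standard deviation $\sigma$, and

$$I(q) = \mathrm{scale}\int N(R_c)\,A(q;R_c)^2\,\mathrm{d}R_c
        + A_p e^{-(q-C)^2/2W^2} + B_g.$$

Assumptions inherited from this form: isotropic scattering, uniform SLD
per shell, no inter-particle structure factor (dilute limit), no
instrument resolution smearing, and shell thicknesses that ride rigidly on
$R_c$ — only the core is polydisperse, a literal reading of the integrand.
Non-Gaussian size distributions (log-normal, Schulz), aspherical or
multilamellar form factors, and absolute-intensity calibration are out of
scope.

### The quasi-Bragg peak

mRNA complexed with ionizable lipid packs quasi-periodically inside the
core and produces a broad maximum near $q \approx 1.2\ \mathrm{nm^{-1}}$.
It is modelled as a Gaussian in $q$, *additive* to the form-factor
intensity and *before* the background, with $W$ interpreted as the
Gaussian standard deviation (not FWHM) — the common quasi-Bragg convention
in small-angle fitting suites. The repeat distance is $d = 2\pi/C$. The
peak's integrated normalisation is deliberately not factored out:
$A_p$ is the peak height, a free nuisance parameter in fits.

## Parameters, units and defaults

| parameter | meaning | unit | typical / default |
|---|---|---|---|
| $R_0$ | mean core radius | nm | 18–25 |
| $\sigma$ | core-radius spread | nm | 2.5–5 |
| $t_1$ | inner lipid layer | nm | ~2 (free) |
| $t_2$ | headgroup layer | nm | 0.3, fixed |
| $t_3$ | PEG-2000 corona | nm | 4, fixed |
| $\rho_s$ | solvent SLD | arb. | 0, reference |
| $\rho_c$ | core SLD | arb. | 1e-4, pinned reference |
| $\rho_1$ | inner-shell SLD | arb. | negative (hydrophobic) |
| $C$, $W$ | peak center, width | nm$^{-1}$ | 1.2–1.3, 0.26–0.38 |

SLDs are in arbitrary units: relative-intensity data determine only the
*ratios* of contrasts, and the product of squared contrast and number
density is absorbed into one `scale` factor. This creates a strict
identifiability rule enforced at configuration time: `scale` and all five
SLDs may not be simultaneously free. The convention used throughout —
including the built-in presets — pins $\rho_s = 0$ and the core SLD at the
reference magnitude $\rho_c = 10^{-4}$, so that fitted $\rho_1, \rho_2,
\rho_3$ are reported on a common, comparable scale. Fitted tables for
Comirnaty-type formulations conventionally print only $\rho_1, \rho_2,
\rho_3$, which is consistent with exactly this kind of pinned-core
convention.

Units: $q$ in nm$^{-1}$; `read_curve(..., unit = "angstrom")` converts
Å$^{-1}$ input by the factor 10.

## Numerical choices

**Shape function.** $j(x)$ suffers catastrophic cancellation as
$x \to 0$; below $x = 10^{-2}$ the Taylor series
$1 - x^2/10 + x^4/280$ is used (truncation error $< 10^{-16}$ there).

**Polydispersity quadrature.** Fixed Gauss–Legendre with 201 nodes on
$[\max(10^{-3}\,\mathrm{nm}, R_0 - 6\sigma),\ R_0 + 6\sigma]$. The
distribution is *not* renormalised after truncation: the clipped mass is
below $10^{-8}$ for all relevant $\sigma/R_0 \le 0.3$, and renormalising
would silently change the meaning of `scale`. The choice is deterministic
and oracle-checkable: the test suite compares it against brute-force
Riemann sums with $10^4$–$10^5$ nodes (agreement $< 10^{-4}$ relative) and
against the closed-form monodisperse limit. $\sigma = 0$ takes the exact
monodisperse branch; `size_distribution()` rejects $\sigma = 0$ so the
caller cannot integrate over a delta by accident.

**Optimizer.** Bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`), minimising $\sum_i w_i (I_i - m(q_i))^2$.
Weighting: reported uncertainties when the curve has them
($w_i = 1/\mathrm{err}_i^2$), otherwise proportional weighting
($w_i = 1/I_i^2$), which equalises the decades of a curve spanning five
orders of magnitude; unweighted is available but not the default. Default
bounds span all plausible LNP values with margin ($R_0 \in [5, 100]$ nm,
$\sigma \in [0.1, 10]$ nm, $t_1 \in [0.5, 6]$ nm, SLDs
$\in [-0.01, 0.01]$, $C \in [0.8, 2]$ nm$^{-1}$,
$W \in [0.05, 1]$ nm$^{-1}$). Optional multi-start (seeded ±10 %
perturbations of the initial point, best objective wins) guards against
the multimodality of oscillatory form factors. Standard errors come from
the Jacobian-based covariance at the optimum scaled by the reduced
$\chi^2$; experimental error bars produced by other estimators are not
expected to match them. Non-convergence is flagged on the result, never
raised.

**Initial guesses.** The background starts at the median intensity of the
top-$q$ decile. The core radius starts from the first local minimum of
$I q^4$ below 0.5 nm$^{-1}$ mapped through the uniform-sphere first zero
$qR \approx 4.493$; empirically (and by construction: the largest contrast
step sits at the core boundary) this minimum tracks the *core* radius, so
the map is applied directly rather than to the outer radius. Detection
runs on a running-mean-smoothed log curve and demands a strict minimum
within a ±5-point window, so 1 % noise ripple is not mistaken for a
form-factor zero. The peak center starts at the argmax on 1–2 nm$^{-1}$
after subtracting both the background and a Porod $cq^{-4}$ tail whose
scale is estimated from the 0.7–0.95 nm$^{-1}$ flank — without the tail
subtraction the decaying form factor, not the bump, dominates the argmax.
Degenerate curves (no detectable oscillation) fall back to documented
defaults and carry a `low_confidence` flag.

**Tie-breaks and degenerate inputs.** Curves must have strictly
increasing $q > 0$; rows violating this are dropped at the I/O layer with
a reported count. A fit requires more points than free parameters.
Non-finite model values during optimisation are mapped to a large
residual, which steers the optimizer away rather than aborting it.

## What the synthetic generator emulates — and what it does not

`generate_curve()` evaluates the model on the instrument grid
(log-spaced, 400 points over 0.07–4.5 nm$^{-1}$) and applies one of three
noise models. The default for recovery studies is 1 % multiplicative
Gaussian noise, representative of frame-averaged synchrotron 1D data; a
Poisson-like option models count statistics at a configurable effective
count scale. Replicate seeds are derived as `seed + replicate − 1`:
reproducible yet distinct.

What it does *not* emulate: instrument resolution smearing, q-dependent
systematic reduction errors (buffer mismatch, capillary scatter),
inter-particle interference at finite concentration, and radiation-damage
drift across frames. Passing recovery tests therefore demonstrate that
the fitting machinery is unbiased and precise *under the model's own
assumptions*; they do not certify accuracy on measured curves whose
deviations from those assumptions are material.

Preset parameter sets (`preset_params()`) encode representative fitted
values for empty and mRNA-loaded Comirnaty-type LNPs and an N/P-ratio
series. Two preset quantities are conventions rather than measurements,
because relative-intensity fits cannot pin them down and published tables
do not print them: the background is set equal to the form-factor
intensity at $q = 3$ nm$^{-1}$ (so the flat background takes over at high
$q$, as in measured curves), and the peak amplitude is set to twice the
underlying form-factor-plus-background level at the peak center, giving
the clearly visible bump seen in measured mRNA-LNP curves.

## The simulation study

`run_sweep()` reproduces the standard single-parameter simulation study
around the base point $R_0 = 25$ nm, $t_1 = 2$ nm, $t_2 = 0.3$ nm,
$t_3 = 4$ nm, $\rho_c = 0.01$, $\rho_1 = -0.01$, $\rho_2 = 0.01$,
$\rho_3 = 0.001$, $\rho_s = 0$:

* increasing $\sigma$ from 1 to 6 nm progressively washes out the
  form-factor oscillations, which become indistinguishable once
  $\sigma/R_c$ exceeds about 0.2;
* increasing $t_1$ from 1 to 4 nm shifts the first oscillation peak to
  higher $q$ and lowers the forward scattering below 0.1 nm$^{-1}$;
* making $\rho_1$ more negative than about $-0.04$ creates a broad
  maximum near $q \approx 0.1$ nm$^{-1}$.

Because curve *shape*, not absolute level, carries these signatures (the
normalisation of published simulation figures is not stated), the sweep
assertions in the test suite are shape properties: local-maxima counts on
the log-intensity curve (a maximum must be the strict largest within a
±5-point window, robust to float ripple), interpolated forward intensity,
and first-peak positions.

## Frame QC and averaging

Twenty consecutive 1 s exposures of one sample are compared before
averaging to screen for radiation damage. The similarity statistic used
at beamlines is typically unpublished; here it is the Pearson correlation
of $\log_{10}$ intensities (floored at $10^{-3}$ times the smallest
positive intensity), which is standard for frame QC and insensitive to
overall scale. Precisely because it is scale-blind, a supplementary
median-ratio guard (frame median over ensemble median within $[0.5, 2]$)
catches grossly rescaled outliers. Frames failing either rule at the
default mean-similarity threshold 0.99 are excluded and logged; the rest
are averaged pointwise with the standard error of the mean (or exactly
propagated reported errors) as uncertainty. Both the threshold and the
band are exposed as arguments.

## Problem sizes

The test suite and the acceptance script run at the sizes a desk analysis
would use: 400-point curves, 201 quadrature nodes, five replicate fits
per recovery experiment, and oracle comparisons at 40–80 q points against
$10^4$–$10^5$-node Riemann sums. A full recovery experiment (generate,
guess, fit, five replicates) takes on the order of ten seconds on one
core.

## Known limitations

* Only the core radius is polydisperse; real shell thicknesses fluctuate
  too, and fitted $\sigma$ will absorb some of that variability.
* The Gaussian size distribution admits (negligible but nonzero) mass at
  small radii for large $\sigma/R_0$; beyond $\sigma/R_0 \approx 0.3$ the
  truncation-without-renormalisation choice becomes visible and a skewed
  distribution would be more appropriate.
* The quasi-Bragg peak is purely phenomenological: a single Gaussian
  cannot represent higher-order reflections or asymmetric peaks.
* Parameter uncertainties are local (curvature-based); strongly
  correlated parameters (e.g. $\sigma$ with $R_0$ at high polydispersity)
  are better explored by profiling, which this package does not do.
* Fits to measured curves require the model assumptions above to hold;
  lyophilised or otherwise restructured formulations may need a different
  structural model entirely.
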