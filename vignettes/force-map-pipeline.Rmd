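---
title: "Stiffness mapping of cells from AFM force maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stiffness mapping of cells from AFM force maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcemapr)
```

## The measurement and the model

An AFM force map is a rectangular grid of force-distance curves: at each
grid point the cantilever is lowered onto the sample while its deflection
is recorded against piezo height, until the force reaches a *set point*
(1 nN here), and then retracted. Two calibration constants convert the raw
photodiode signal to force: the deflection sensitivity (nm of cantilever
bending per volt, from the contact slope of a curve on the rigid dish) and
the spring constant (from the equipartition theorem applied to the free
thermal fluctuations, `k = kB * T / var(d)`).

For a rigid sphere of radius $R$ indenting an incompressible elastic
half-space, the exact axisymmetric (Sneddon) solution is parameterised by
the contact radius $a$:

$$P = \frac{E}{1-\nu^2}\left[\frac{R^2+a^2}{2}\,
  \ln\frac{R+a}{R-a} - aR\right],\qquad
  \delta = \frac{a}{2}\,\ln\frac{R+a}{R-a},$$

with load $P$, Young's modulus $E$, Poisson ratio $\nu$ (fixed at 0.5 for
cells), and indentation depth $\delta$. The familiar Hertz expression
$P = \tfrac{4}{3}\,\frac{E}{1-\nu^2}\sqrt{R}\,\delta^{3/2}$ is its
parabolic small-depth limit; the package keeps both, and uses the limit as
an internal verification oracle (agreement is within 1% for
$\delta/R \le 0.01$, and the sphere carries *less* load than the
paraboloid at depth, as the blunter shape must).

$\delta(a)$ has no closed-form inverse. `contact_radius_from_indentation()`
inverts it with a bracketed, safeguarded Newton iteration on
$[0, R(1-10^{-12})]$: Newton steps are accepted only inside the current
sign-change bracket and replaced by bisection otherwise, so convergence is
guaranteed on this monotone function despite the logarithmic singularity
at $a = R$; the iteration is vectorised over depths, which is what makes
fitting whole maps affordable in R. Round-trip accuracy is below
$10^{-12}$ relative. Internally the contact model is evaluated in SI units
(m, N, Pa) with explicit boundary conversion to the reporting units (um,
nN, kPa); the identity 1 kPa x 1 um^2 = 1 nN is pinned by a unit test.
Depths beyond $2R$ are accepted mathematically but trigger a warning —
the physical model is meaningless there and the QC cascade removes such
fits anyway.

## Per-curve processing

Each approach segment is processed independently:

1. **Baseline.** A straight line is fitted to the free (non-contact) part
   and subtracted. A linear rather than constant baseline was chosen
   because real photodiode signals drift approximately linearly with
   piezo position; the generator simulates exactly such a baseline.
2. **Contact point, integer scan.** Candidate contact indices are scanned
   exhaustively within a bracket around the first force excursion above
   3x the baseline noise, widened by 10% of the segment length. For each
   candidate the baseline is refitted to its free side and the contact
   model to its contact side, and the candidate is scored by a Huber loss
   of all residuals at a fixed scale set by the free-side noise. The
   fixed scale matters: a median-based score goes blind on dish curves,
   where the true contact region is only ~4 samples — a spurious
   "E near zero" fit then matches the free majority and the median never
   sees the misfit, while the Huber score still counts those four
   samples' systematic error. Ties go to the smallest index.
3. **Contact point, continuous refinement.** The true contact almost never
   falls on a sample. Inside `fit_young_modulus()` the contact height is
   treated as a continuous parameter within one sample spacing and
   profiled against the fit objective (the modulus is closed-form at a
   fixed contact height, so this remains a cheap 1-D search). Without
   this, the 16.7 nm sampling grid biases noise-free modulus estimates by
   several percent.
4. **Modulus fit.** The model is exactly linear in $E$, so least squares
   is closed-form. The default robust estimator is a Huber M-estimator
   (IRLS, scale from the MAD, tuning constant 1.345): ~95% efficient
   under Gaussian noise, bounded influence under gross outliers. The
   robust-estimation literature's median-objective alternatives were
   rejected after measurement: minimising the median absolute residual
   converges like $n^{-1/3}$ and roughly doubled the modulus error at 2%
   deflection noise. The robust estimators built into the desktop
   software traditionally used for such maps are unpublished, so both of
   this package's robust objectives are documented stand-ins, isolated
   behind one internal function each.
5. **QC cascade.** Five independent, idempotent, individually toggleable
   rules, with the thresholds of the original study as defaults: modulus
   above 10 kPa (dish or very thin cell), fitted indentation above 2 um
   (faulty contact point), deepest fitted force below 80% of the set
   point (fit region too small), RMS model deviation above 5% of the set
   point, maximum pointwise deviation above 7% of the set point. A fit is
   accepted exactly when no rule fires.

A fit needs at least 4 contact samples. At the mapping settings used here
(spring constant ~18 mN/m, 2 kHz at 33.3 um/s, i.e. 16.7 nm of travel per
sample) a rigid dish reaches the 1 nN set point after only ~4 contact
samples — the cantilever bends 56 nm while the dish yields nanometres — so
any larger minimum would make dish stiffness unassignable and the 10 kPa
rule inoperative; 4 samples are enough to identify the single linear
parameter. Curves on cells have dozens to hundreds of contact samples and
are unaffected.

## Map assembly and statistics

Accepted moduli form the stiffness map; contact heights form the height
map. A least-squares plane through substrate points (those flagged by the
10 kPa rule) is subtracted so the dish sits at zero; the fit is iterated
once after re-classifying points that lie within the noise floor of the
plane (at least 0.05 um, or 3x the MAD of the substrate residuals). With
fewer than 3 substrate points the zero level falls back to the global
minimum with a warning.

The cell is partitioned at half of the full cell height — the per-map
maximum over the cell mask, since maps here contain one (or few) cells
and no per-component rule is defined. A point exactly at 50% belongs to
the upper (core/nuclear) region; this closed boundary makes the partition
deterministic. Per timepoint the package reports median and mean modulus
over the cell and per region, SEM, a Shapiro-Wilk normality p-value, and
spatial deviation. "Spatial deviation from the median" is ambiguous in
the field (SD? MAD? extreme?); the package reports both MAD/median and
|region median − map median|/map median and documents the choice here.
Time series are normalised to the first timepoint; the headline number is
the maximum relative decrease of the whole-cell median.

## The synthetic generator

Real force-map archives of cryopreserved cells are tens of gigabytes;
every stage of this package is instead exercised against a synthetic
generator with known ground truth. A phantom is a spherical-cap cell on a
rigid dish (substrate modulus 2 MPa, far above the 10 kPa rule) with a
compartmental elasticity field: soft nucleus, stiffer periphery, optional
stiff perinuclear ring and fiber lines — the structure seen in structured,
DMSO-protected cells — and a multiplicative post-thaw relaxation
$E(t) = E_0\,[f + (1-f)e^{-t/\tau}]$ per compartment. Two presets ship
with the package: `"dmso-like"` (nucleus 2 kPa, periphery 4 kPa, ring
6 kPa, fibers 8 kPa; $f = 0.4$, $\tau = 25$ min, i.e. a ~60% median
decrease over 2 h) and `"peg-like"` (homogeneous 3 kPa, taller cap;
$f = 0.8$, $\tau = 40$ min, at most a ~20% decrease). The nucleus radius
(0.55 of the footprint) is chosen so the soft nucleus dominates the
upper height region and the upper-vs-lower median contrast of a
structured cell is reproducible by construction; the ring sits at 0.78 of
the footprint, in the lower region, like the actin ring at the flattening
cell margin.

Curves are simulated through the same contact model the fitter inverts —
but only through it: the generator solves the self-consistent force
balance $\delta + P(\delta)/k = \text{travel}$ per sample (Newton, using
the exact contact stiffness $dP/d\delta = 2aE/(1-\nu^2)$), adds the
linear photodiode baseline and Gaussian deflection noise, and truncates
the approach at the exact set-point crossing, recording that off-grid
trigger sample as real instruments do. Noise enters on the *deflection*
signal, where it arises physically. The fitter never sees the
ground-truth fields; they travel as object attributes and are never
written to the exchange archive. Acquisition defaults mirror a typical
colloidal-probe session: probe radius 3.31 um, sensitivity 15.2 nm/V,
spring constant 18 mN/m, set point 1 nN, Z-length 15 um, 2 kHz at
33.3 um/s, grids up to 64 x 64 over 100 x 100 um. The default deflection
noise is 2% of the set point (20 pN RMS), a realistic liquid-cell level.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: viscoelastic approach-retract hysteresis,
adhesion, thermal drift, finite cell thickness (bottom effect), membrane
and glycocalyx layers, or curve-to-curve variation of the baseline noise.
The phantom establishes that the *pipeline* is correct, not that the
contact model captures everything in a living cell.

## Numerical choices and problem sizes

Tolerances: contact-radius inversion to $10^{-12}$ relative; contact
height profiled to $10^{-6}$ of a sample spacing; IRLS to $10^{-10}$
relative in $E$. Degenerate inputs error early and explicitly: curves
with no contact excursion, no free baseline, fewer than 4 contact
samples, or non-positive modulus estimates; maps with an empty cell mask.
Determinism is part of the contract: archives are written with
17-significant-digit doubles so write/read round trips are bit-exact, and
identical archive, configuration and seed give bit-identical fits and
statistics tables.

The test suite runs its recovery studies at reduced sizes chosen to keep
the full battery in the tens of minutes: 200 noisy curves per modulus
level, 16 x 16 phantom grids for the five-timepoint relaxation series,
and a single full 64 x 64 map for the end-to-end run (which completes in
a few minutes). These sizes were fixed before freezing the expected
values and give comfortable statistical margins; enlarging them is a
matter of changing one constant in the tests.

## Known limitations

Only spherical probes are implemented (no pyramidal/conical tips, no
adhesion or bottom-effect corrections — out of scope by design). The
robust estimators are stand-ins for unpublished ones, as documented
above. The height-based partition assumes a single dominant cell per
map; multi-cell maps are processed but their "full cell height" is the
global maximum. Retract segments are stored but not analysed.
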