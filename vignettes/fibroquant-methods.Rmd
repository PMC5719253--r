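---
title: "Quantifying fibrillar collagen remodelling: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibrillar collagen remodelling: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroquant)
```

fibroquant quantifies four complementary readouts of collagen remodelling in
fibrotic lung tissue — second-harmonic-generation (SHG) fibril maturity,
lysyl-oxidase immunostaining, micro-indentation stiffness, and their
cohort-level interrelationships — and ships synthetic generators with known
ground truth for each, so the whole pipeline can be validated without tissue
images. This vignette documents the models, the conventions adopted where
the underlying protocols are ambiguous, and what the synthetic tests do and
do not demonstrate about real data.

## SHG forward/backward maturity metrics

Fibrillar collagen emits frequency-doubled light with no exogenous label.
The forward-propagated signal arises predominantly from thick, mature,
organized fibrils; the backward signal from thin, immature, disorganized
fibrils. The analysis therefore images both channels with independent
detectors and compares them.

For each channel the background threshold is `mu + sigma` computed over
*all* voxels of the 3D stack; per z-slice, **area** is the number of voxels
strictly above threshold, **density** the mean intensity of those voxels,
and **intensity** their product. Slice values are averaged over the stack
and the three forward/backward (F/B) ratios are ratios of those stack
means. A rising intensity F/B indicates increasing fibril
maturity/thickness.

Conventions adopted (the imaging protocol leaves these open):

* *Strict threshold.* "Above threshold" is `>`, so ties at `mu + sigma`
  count as background and a constant image has zero area.
* *Population standard deviation.* `sigma` uses the divisor `n`; with
  whole-stack statistics the difference from the sample estimator is
  negligible, but fixing it makes the metrics bit-reproducible.
* *Empty slices* contribute area 0 and intensity 0 to their averages but
  are excluded from the density average — a mean intensity over an empty
  voxel set is undefined, and injecting zeros would bias the density
  statistic downward on sparse stacks.
* *Average first, then ratio.* Ratios divide stack means rather than
  averaging per-slice ratios; per-slice ratios are unstable when single
  slices are nearly empty.
* *Per-channel thresholds.* Forward and backward detectors have different
  gains, so `mu + sigma` is computed independently per channel. This makes
  all three ratios invariant to a joint rescaling of both channels and
  makes `fb_density` scale linearly when only one channel is rescaled —
  both properties are tested.

The generator renders straight fibril segments as hard cylinders with a
one-voxel linear falloff at the edge (anti-aliasing that keeps the geometry
oracle-checkable), splits each segment's emission between the channels as
`m : (1 - m)` for maturity `m`, and adds a constant background plus
additive Gaussian noise clipped at zero. Total emission is independent of
`m`, so with equal gains and no noise a field at `m = 0.8` must produce an
intensity F/B of exactly `0.8 / 0.2 = 4` — the sharpest end-to-end check of
the quantification. What the generator does *not* emulate: phase-matching
optics, polarization effects, the point-spread function, and detector
quantization (intensities are continuous, clipped to the 16-bit range).
Passing tests therefore validate the *quantification arithmetic and its
invariances*, not the optical interpretation of forward versus backward
emission in tissue.

Imaging regions are selected as in the acquisition protocol: a 10x10 grid
(5x5 for small decellularized samples) with `n` cells drawn uniformly
without replacement from a seeded generator ([sample_regions()]), tested
for uniformity with a chi-squared test over 100,000 seeds.

## IHC colour deconvolution and DAB quantification

Brightfield immunohistochemistry follows the Beer–Lambert model: with
incident intensity `I0 = 255`, transmitted light in colour channel `c` is
`I0 * 10^(-sum_s A_s V[s, c])` for stain concentrations `A_s` and
unit-norm stain OD vectors `V`. [unmix()] inverts this linearly
(Ruifrok–Johnston colour deconvolution) after the OD transform
`-log10((value + 1/255) / I0)`; the `1/255` offset avoids `log(0)` at
fully absorbed pixels, and ODs driven slightly negative by that offset at
pure white are clipped so a blank pixel unmixes to exactly zero.

The default stain vectors are the published H-DAB/Eosin constants; the
study re-optimized its vectors but did not print them, so absolute
densities from real slides are not reproducible and the defaults are
overridable. OD thresholds likewise default to the triangle method on each
channel's histogram, overridable by fixed values. "Tissue" is the overlay
of the thresholded Eosin and DAB channels; the two reported statistics are
**percentage tissue surface area** (DAB-positive pixels / tissue pixels x
100) and **density**, defined here as the mean DAB OD over *tissue* pixels
— the protocol's phrase "average intensity for the whole tissue" is
ambiguous between tissue pixels and all pixels, and whitespace area varies
with sectioning, so tissue pixels are the stable choice.

The generator draws smooth Gaussian-blob concentration maps with a
per-stain peak of 0.25 OD. That peak is a deliberate design constant: the
inverse of the default basis amplifies per-channel OD errors by up to
~3.45x in the worst case, and 0.25 OD keeps transmitted light bright
enough that 8-bit quantization perturbs recovered concentrations by less
than 2/255 OD — so the mix/unmix round trip is exact up to quantization,
which the tests assert over 50 random maps. Real slides violate several
generator assumptions (scanner vignetting, stain co-localization at high
OD, chromatic nonlinearity at saturation); the round-trip tests validate
the deconvolution algebra, not stain chemistry.

## Hertz contact-model stiffness

A sphere of radius `R` indenting an elastic half-space to depth `delta`
exerts `F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2)`. With `E` in kPa
and lengths in um this yields nN directly (`1 kPa um^2 = 1 nN`), the one
unit convention used everywhere. Defaults mirror the acquisition: `R =
2.5` um, `nu = 0.4`, a 10 um ramp, 500 samples, contact point mid-ramp.

[fit_hertz()] estimates the contact point `z0`, a linear baseline
(intercept and drift slope), and `E` jointly: for fixed `z0` the model
`F = a + b z + C max(z - z0, 0)^(3/2)` is linear in `(a, b, C)`, so `z0`
is found by a coarse 60-point grid search on the mean squared residual
followed by golden-section refinement (the vendor software used for the
original curves does not document its algorithm, so a transparent one is
used instead). Numerical choices:

* The fit is restricted to `delta <= 0.5 x` the post-contact range
  (`max_indentation_fraction`, configurable) — deep indentations on thin
  sections feel the glass substrate, biasing `E` upward.
* `E >= 0` is enforced by refitting with the Hertz term removed when the
  unconstrained coefficient is negative; failures (contact point stuck at
  the search boundary) are flagged via `converged = FALSE`, never coerced
  to zero.
* The objective is the *mean* squared residual because the restricted
  point set varies with the candidate `z0`.
* No finite-thickness (bottom-effect) correction is applied, matching the
  original analysis.

Noiseless synthetic curves across 1.96–60 kPa refit to within 0.1%, and
100 replicates at 1% multiplicative noise recover the median within 5% and
the mean within 2% — the regimes chosen to match reported healthy
(1.96 kPa) and fibrotic (16.52 kPa) lung parenchyma. The generator omits
cantilever dynamics, adhesion, and viscoelastic creep; recovery tests
demonstrate estimator correctness, not instrument realism. Group contrasts
are compared with Kruskal–Wallis plus Dunn's tie-corrected pairwise z
tests under a Bonferroni family correction (the post-hoc family scheme is
not specified in the original analysis beyond "Dunn's correction";
Bonferroni is the classical choice), cross-checked in tests against a
permutation oracle.

## Cohort statistics and factor analysis

Two-group comparisons are gated on the D'Agostino–Pearson omnibus
normality test (implemented from the published formulas and verified to
ten decimals against an independent implementation): both groups normal at
alpha 0.05 gives Student's t, otherwise Mann–Whitney. The omnibus test is
unreliable below `n = 8`, so smaller groups — the study's cohorts of 7–10
subjects sit exactly at this edge — take the nonparametric branch
directly, and the report always states which branch ran and why.
Correlations are Pearson on pairwise-complete, group-pooled data with
`R^2 = r^2` and raw two-tailed p; correlation families are additionally
Benjamini–Hochberg adjusted in the analysis driver.

Factor analysis uses principal axis factoring on the correlation matrix of
listwise-complete subjects: communalities start at squared multiple
correlations, the reduced matrix is eigen-decomposed and communalities
re-estimated until the largest change falls below 0.001. That tolerance —
the convention of mainstream factor-analysis software — matters here: with
only two indicators per factor (the default cohort), loadings are
identified only through their pairwise products, communalities crawl
toward the Heywood boundary, and far tighter tolerances never settle.
Heywood cases are clipped to 1 with a warning. The factor count defaults
to the Kaiser rule (eigenvalues of the correlation matrix >= 1, boundary
inclusive). Promax rotation (varimax pre-rotation, then a sign-preserving
power-`kappa` target transform, `kappa = 4` by convention) returns the
oblique pattern matrix and factor intercorrelations; it is cross-checked
against an independent implementation and on planted structures.

The **weighted relationship-group scores** require a convention the source
protocol never states: here each subject's score on a factor is the
weighted mean of its z-scored variables, with weights equal to the
absolute promax pattern loadings normalized to sum to one within the
factor. Absolute loadings are used because a strongly *negatively* loading
variable contributes as much "strength" to a relationship group as a
positive one; z-scoring prevents variables on large scales from dominating.
This is a stipulation — other defensible constructions (regression factor
scores, signed loadings) would differ in detail, which is why it is
documented prominently and exposed through `weights` on the result.

The default cohort truth is four variables loading 0.8/0.7 on two
orthogonal factors with uniqueness 0.3 and a +1 shift on the factor-1
variables in the second group, echoing the two relationship groups the
study reports among collagen-structure and lysyl-oxidase variables. Tests
confirm the Kaiser rule returns 2 at n = 200, planted loadings are
recovered with Tucker congruence > 0.95 over 20 seeds, and group
separation appears only on the shifted factor. Because the generator is
multivariate normal, these tests say nothing about robustness to the
skewed, small-n data of real cohorts — that is exactly what the
normality-gated branch logic is for.

## Problem sizes and determinism

Test and acceptance workloads are sized for quick, deterministic runs:
16^3-voxel SHG oracle stacks (20 replicates), 32x32 IHC maps (50 round
trips), 500-point force curves (100-replicate noise studies), cohorts of
200–500 subjects (20-seed recovery loops). Every stochastic stage takes an
explicit integer seed, uses it through a local RNG scope that restores the
caller's random state, and is bit-reproducible under a fixed seed.

## Known limitations

* SHG rendering is geometric, not optical; forward/backward splitting by a
  scalar maturity is the *interpretive* model, encoded so the arithmetic
  can be tested against it.
* Stain vectors and OD thresholds of the original study are unpublished;
  only internal consistency of the IHC stage is testable.
* The Hertz fit assumes an elastic half-space; thin-section substrate
  effects are mitigated, not modelled, by the indentation-depth cap.
* The group-score weighting is a documented convention, not a reproduction
  of an unpublished formula.
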