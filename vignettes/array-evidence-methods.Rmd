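---
title: "Scoring and optimising magnetometer-array geometry by model evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and optimising magnetometer-array geometry by model evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opmarray)
```

## The problem

On-scalp optically pumped magnetometers (OPMs) can be placed flexibly, which
makes the usual MEG assumption — that sensor positions and orientations are
known precisely — fragile. Because OPMs sit close to the brain, small errors
in the assumed sensor geometry distort source reconstructions more than they
would for a cryogenic array. `opmarray` implements an empirical-Bayesian
framework that treats each candidate sensor geometry as a *model* of the
recorded field data, scores it by an approximation to log model evidence, and
uses that score to (i) quantify how sensitive a sensor system is to
geometric error and (ii) recover the pose of a rigid array from the data
themselves, using the cortical geometry as spatial support rather than scalp
landmarks.

## Model

The recording is the general linear model `Y = L J + e`, with `Y` the
channels-by-samples field data (tesla), `L` the lead field of the candidate
geometry, `J` the source currents on a cortically constrained source space,
and `e` white Gaussian sensor noise. Two covariance components are estimated
per candidate geometry:

* sensor noise `Q_eps = lambda1 I`;
* an Empirical Bayes Beamformer (EBB) source prior `Q = lambda2 diag(Gamma)`,
  where `Gamma_d = 1 / (l_d' C^-1 l_d)` is the per-source beamformer power
  computed from the sample covariance `C = Y Y' / Nt` (valid when no sources
  are correlated at zero lag). `Gamma` is normalised to unit mean; the EBB
  diagonal-loading `regularization` defaults to 0.

The hyperparameters maximise the penalised Gaussian log-evidence of the
implied model covariance `C_a = lambda1 I + lambda2 L Gamma L'` by Fisher
scoring on log-hyperparameters (prior mean 0, precision `1e-6 I`; effectively
non-informative, but it makes the Occam term well defined). The reported
score is the negative variational free energy

```
F = accuracy - complexity
accuracy   = -Nt/2 [ trace(C_Y C_a^-1) + log|C_a| + Nc log 2pi ]
complexity = 1/2 (h - nu)' Pi (h - nu) - 1/2 log |Sigma_h Pi|
```

with `h` the log-hyperparameters and `Sigma_h` their posterior covariance
from the curvature at the optimum. Since `Sigma_h = (Fisher + Pi)^-1`, the
complexity is non-negative. Only *differences* of `F` between geometries
scoring the same data are meaningful; a difference of 3 nats is an evidence
ratio of `exp(3) ~ 20`, the rejection threshold used throughout. Conventions
that amount to a fixed global scale (the `1/Nt` covariance normaliser, the
absence of a `1/Nt` factor inside `C_a`) therefore cancel; both are exposed
via `covarianceNormalizer` for completeness.

The posterior current estimate is `J = Q L' C_a^-1 Y`, computed by a linear
solve; with the orientation constraint each source contributes one lead-field
column.

## Forward models

`computeLeadfield()` dispatches on the volume conductor:

* **Fitted sphere** (`fitSphere()`, global or local): the closed-form field
  of a current dipole in a homogeneous conducting sphere. Radial dipole
  moments are externally silent; the implementation projects moments onto
  the tangential subspace so that silence is exact in floating point.
  Sphere fitting minimises the geometric loss `sum((|v - c| - r)^2)`
  (algebraic start, Gauss-Newton refinement). The local variant fits a
  vertex subset within a configurable radius (default 40 mm) of a target —
  note that near a pole of an ellipsoidal surface this tracks the osculating
  sphere, whose radius can be smaller than any semi-axis.
* **Corrected sphere ("single shell")**: the fitted-sphere field plus a
  correction `-grad(U)`, `U` a combination of exterior real solid harmonics
  centred at the fitted centre (default order 8), with coefficients chosen
  by least-squares collocation at the shell's face centres so that the
  field component normal to the shell matches the bare-dipole (Biot-Savart)
  normal field. For a spherical conductor that boundary condition is exact
  and the correction vanishes, so the model degenerates to the sphere
  (verified to < 0.5% in the tests). Collocation uses vertex-averaged
  normals interpolated at face centres; flat facet normals inject
  mesh-frequency noise into the boundary residual. The single-centre
  exterior expansion converges slowly (though monotonically) on strongly
  eccentric shells whose surface approaches the expansion's convergence
  radius — the tests assert self-convergence against a high-order
  reference rather than a fixed small change between orders 6 and 10.

## Perturbation curves and their width

`perturbationCurve()` rescores each perturbed copy of the array against fixed
data: independent per-sensor orientation errors of a fixed magnitude about a
random frame axis (roll/pitch/yaw), or rigid arc displacements of the whole
array about the fitted head-sphere centre (arc length divided by the mean
sensor radius gives the rotation angle; default axis: the left-right `x`
axis). Optional per-model multiplicative gain errors `Normal(1, f^2)` model
calibration and cross-talk imperfections. Curves are reported relative to
their maximum; `widthAtThreshold()` interpolates the offsets at which the
mean relative `F` crosses a threshold (default -3 nats, i.e. 20-fold less
likely). Narrow widths mean the system cannot hide geometric error — the
signature of a well-modelled, high-SNR system.

Random draws are *paired across offsets*: repeat `r` re-uses the same axis
and gain draws at every offset, so offset columns differ only in the
perturbation magnitude. This removes spurious argmax displacement caused by
between-column luck; the per-offset dispersion is retained in the returned
repeat matrix. Near the curve top the expected drop is shallow (about -1.7
nats at 2.5 degrees under the default simulation), so with 30 repeats the
empirical argmax can land one 2.5-degree grid step off the truth; the tests
treat "peaks at zero" as peaking within one grid step.

## Pose search and model averaging

`metropolisPoseSearch()` samples the rigid-array pose (translation by
default, a 1D arc mode for illustration) under a flat prior (default a
40 mm cube) with the free energy as log-target: proposals that increase `F`
are always accepted, decreases with probability `exp(dF)`. Proposal scale
starts at a tenth of the prior width and adapts multiplicatively toward a
25-40% acceptance rate during the first 40% of iterations (burn-in), frozen
afterwards. A tenth of the proposals are drawn fresh from the prior: this
independence component is symmetric within the support (the acceptance rule
is unchanged) and is load-bearing — the discrete source space induces local
evidence maxima separated by barriers of tens of nats, and a purely local
random walk reliably gets trapped in them (in development, all four chains
stuck 16 mm from the truth); with the restart component the search recovers
the generating pose to about a millimetre.

`bmaSources()` draws a configurable number of models (default 30) from the
post-burn-in samples with weights proportional to `exp(F)`, inverts each,
and averages the current estimates; `confidenceEllipsoid()` summarises the
evidence-weighted cloud of a tracked sensor position (default: the sensor
closest to the array centroid) as a chi-squared confidence ellipsoid whose
volume quantifies the remaining pose uncertainty relative to the prior box.

A caveat established during development: with nominal sensor noise the
*global* optimum of `F` over 3D translation is itself displaced from the
generating pose by up to several millimetres for some noise realisations
(the two-component model can trade a small signal mismatch against fitting
sampling ripples of the covariance). Millimetre-level pose recovery is
therefore a property of low-noise data; the sampler finds the evidence
optimum either way.

## The synthetic protocol

The generator replaces subject anatomy, which is not distributable, with
parametric surfaces carrying the protocol's printed scalars:

* `makeHead()`: a subdivided-icosahedron inner skull (radius 80 mm, 642
  vertices by default — about 10 mm source spacing, emulating a dense
  cortical sampling at desk scale) with the source space 10 mm interior.
* Source orientations are *pseudo-cortical*: the outward normal plus a
  seeded tangential random field of unit spread, smoothed once over the
  mesh (about 10-15 mm coherence) and renormalised. Two features matter:
  purely radial orientations would be externally silent in a spherical
  conductor (degenerate inverse problem), and spatially incoherent
  orientations would prevent neighbouring sources from absorbing small
  rigid-array displacements, making displacement curves unrealistically
  sharp (sub-millimetre). Real cortical orientation fields are both tilted
  and locally smooth.
* `makeArray()`: 13 point magnetometers in concentric rings over the
  somatosensory target (the MNI-like coordinate (46, -25, 60) mm scaled
  onto the source shell), on the scalp surface (inner skull + 10 mm) at a
  6.5 mm standoff, minimum spacing 25 mm, radially oriented.
* `simulateRecording()`: one 10 Hz sinusoidal dipole of 10 nAm at the
  vertex nearest the target, 1 s single trials at 200 Hz, i.i.d. Gaussian
  sensor noise of 100 fT RMS (divided by `sqrt(nTrials)` under trial
  averaging).

What passing tests on this substitute do and do not show: the evidence
machinery, its oracles, and the qualitative behaviour (peak at the true
geometry, blunting under gain error, posterior-volume collapse) transfer to
real data; the *numerical* curve widths do not transfer exactly, because
they depend on anatomy-dependent factors the parametric head lacks —
notably the displacement-compensation capacity of real cortical geometry.
Under the frozen defaults the orientation half-width at -3 nats is about
4 degrees; the arc-displacement half-width is about 2 mm, an order of
magnitude tighter than on real anatomy, and per-model gain error blunts the
orientation curve only mildly (about 4 to 5 degrees), with the true geometry
remaining the most likely throughout.

## Numerical choices

* Internal units are SI (metres, teslas, radians); file and CLI surfaces use
  millimetres and degrees.
* Hyperparameter optimisation: damped Fisher scoring on log-hyperparameters,
  components pre-scaled to equal trace, start at half data variance each,
  at most 128 iterations, stop when the objective changes by < 1e-4 nats;
  non-convergence returns the best iterate with a warning and a flag.
* EBB with exactly noiseless data: the sample covariance is rank-deficient
  and the unregularised beamformer weights are undefined; raise
  `regularization` (the zero-noise tests use 0.05).
* Externally silent sources (zero lead-field norm) receive zero prior
  weight rather than an infinite one.
* The correction-basis least squares is solved by SVD with a relative
  tolerance of 1e-8; a rank-deficient basis triggers a warning and a
  reduced-subspace solve.
* All randomness is seed-controlled per call; curves and searches derive
  independent sub-streams from the master seed so that runs are exactly
  reproducible.

## Problem sizes

The default analyses were sized for a single CPU: 642-vertex source spaces,
17-offset curves with 30 models per offset (510 inversions per curve, a few
seconds), and 4 chains of 600 Metropolis iterations (2400 inversions, under
half a minute). All scale linearly in the number of sources and offsets.

## Known limitations

* Point-magnetometer sensor model: no integration over the vapour cell, no
  cross-talk, no gradiometer baselines.
* Volume conductors are limited to fitted spheres and the corrected-sphere
  shell; no BEM/FEM, no anisotropy, no CSF compartment.
* The EBB prior assumes zero-lag-uncorrelated sources; correlated-source
  configurations will mis-estimate `Gamma`.
* The pose search covers rigid translation (and a 1D arc); full 6-parameter
  rigid search uses the same machinery but is not exercised by the shipped
  experiments.
* Free energies are comparable only across models of the *same* data.
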