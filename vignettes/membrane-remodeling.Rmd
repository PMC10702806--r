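---
title: "Quantifying local membrane remodeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying local membrane remodeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memlens)
```

## The problem

Large membrane-protein complexes such as the Sec61 translocon with its
associated TRAP complex locally deform the bilayer that hosts them: the
membrane curves, thins and disorders in their vicinity ("membrane lensing").
Quantifying this requires turning two very different kinds of raw data into
the same set of local descriptors:

* **leaflet point clouds** — scattered 3D positions of each leaflet, e.g.
  segmented from a cryo-electron tomogram or taken as time-averaged lipid
  phosphate positions from a molecular-dynamics trajectory; and
* **lipid trajectories** — per-frame coordinates of annotated lipids, from
  which chain order, flip-flop events, helix distances and hydrogen bonds
  are measured.

memlens reconstructs smooth leaflet surfaces from the point clouds, derives
curvature and thickness maps from them, and implements the trajectory-side
statistics. Every stage can be driven by a synthetic generator whose ground
truth is known analytically, so the whole pipeline is testable without any
external data.

## Surface reconstruction

`fit_leaflet()` is the canonical two-step operation:

1. **Scattered interpolation.** The lateral positions $(x, y)$ are Delaunay
   triangulated and $z$ is interpolated piecewise-linearly onto a regular
   grid (`interpolate_scattered()`, backed by the `interp` package). Grid
   cells outside the convex hull are marked invalid. Linear interpolation is
   exact on planes; on curved surfaces its error is bounded by
   $h^2/8 \cdot \max\lVert \mathrm{Hess}\, z\rVert$ for triangle diameter
   $h$, which the tests verify against a brute-force per-triangle oracle.
2. **LOESS smoothing.** At each grid node a bivariate polynomial of degree
   2 (configurable to 1) is fitted by weighted least squares to the
   $k = \lceil \text{span} \cdot N \rceil$ nearest gridded samples, with
   tricube weights $w = (1 - (d/d_{\max})^3)^3$, and evaluated at the node.
   The defaults — span 0.20 and quadratic polynomials — follow the
   established membrane-surface protocol for cryo-ET leaflet data. The
   neighborhood is defined by point count, not radius, matching classical
   LOESS. Degree-2 LOESS is exact on global quadratics (tested to
   $10^{-6}$ Å), and at span 1 with noise-free quadratic data it coincides
   with a single global least-squares fit.

Numerical choices: the local normal equations are solved by Cholesky via
`solve()`; if the degree-2 normal matrix has a reciprocal condition number
below $10^{-10}$ (typical at hull edges where the neighborhood is
one-sided), the fit is downgraded to degree 1; a node whose system is still
singular is marked invalid rather than failing the run. The farthest
neighbor's tricube weight is exactly zero; if fewer points than coefficients
carry positive weight, a tiny uniform weight is added so the system stays
determined. The default grid spacing is 4 Å, about the voxel scale of a
binned tomogram; all tolerances scale with this choice and it is
configurable everywhere.

LOESS is applied to the gridded interpolated samples (interpolate first,
then smooth); a points-direct mode is exposed through `loess_smooth()` for
callers who want to skip gridding.

## Curvature, radii and sphere fits

On a height field $z(x,y)$, mean and Gaussian curvature are computed with
central finite differences (one-sided stencils at valid-mask borders):

$$H = \frac{(1+z_x^2)z_{yy} - 2 z_x z_y z_{xy} + (1+z_y^2)z_{xx}}
          {2\,(1+z_x^2+z_y^2)^{3/2}}, \qquad
  K = \frac{z_{xx}z_{yy} - z_{xy}^2}{(1+z_x^2+z_y^2)^2}.$$

The normal is fixed toward $+z$ (the cytosolic side), so a bulge toward the
cytosol has negative $H$ at its apex and a sphere cap of radius $R$ gives
$H = -1/R$. A regional radius of curvature is extracted as
$R = 1/\lvert\langle H\rangle_{\text{region}}\rvert$ — the region-averaged
$H$ is inverted, rather than averaging $1/\lvert H\rvert$, because the mean
is stable when $H$ fluctuates around small values while the pointwise
inverse diverges. Both the signed mean $H$ and the radius are reported. For
free-floating, strongly curved patches (bicelles) a direct least-squares
sphere fit is provided instead: the algebraic Coope formulation (a linear
system in the center and radius) refined by one Gauss-Newton pass on the
geometric residuals $\lVert p - c\rVert - R$.

Default protein-vicinity region: a 40 Å radius around a caller-supplied
lateral center. The center must be supplied because it encodes where the
protein sits, which the point cloud alone does not know.

## Thickness and mixture statistics

Thickness is the vertical difference of the two leaflet fields,
$t = z_{\text{up}} - z_{\text{lo}}$, valid where both are; fields on
different grids are bilinearly resampled first. The vertical (rather than
surface-normal) difference is the field's standard definition for
leaflet-pair height fields and is antisymmetric under leaflet exchange;
normal-projected thickness would differ only at second order in the slope
for the gentle curvatures considered here.

Thickness (and order) distributions are summarized by a one-dimensional
Gaussian mixture fitted with EM (`fit_gaussian_mixture()`): k-means++
seeding of the means, closed-form M-steps, a monotone log-likelihood
asserted at every iteration, convergence when the increase drops below
`tol`, and pruning of components whose standard deviation collapses below
$10^{-6}$ times the data SD. On unimodal data a forced $k = 2$ fit
legitimately degenerates (near-identical means or a vanishing weight); when
the number of populations is genuinely unknown, `fit_gaussian_mixture_auto()`
selects $k$ by BIC rather than asserting bimodality.

## Order parameters and events

The deuterium order parameter per chain carbon is
$S_{CD} = \langle (3\cos^2\theta - 1)/2 \rangle$ over lipids, frames and
hydrogen partners, with $\theta$ the C–H angle to the membrane normal
($z$). Values are bounded by $[-0.5, 1]$; the chain average over carbons
2–15 is reported as a magnitude with the sign kept in
`S_CD_signed`, matching the convention of plotting $|S_{CD}|$.
`local_order_map()` bins the same per-bond samples by the head-group's
lateral grid cell.

Flip-flops are detected from head-particle $z$ with hysteresis: a lipid's
leaflet label changes only when its head crosses beyond the midplane
$\pm$ gap/2. The default gap of 10 Å (about half a leaflet) suppresses
spurious events from thermal jitter near the midplane while completing
genuine translocations; widening the gap can only reduce the event count
(tested). The midplane is recomputed per frame as the mean head height,
which makes the detector robust to slow box drift.

Superposition RMSD uses the Kabsch algorithm (SVD with the determinant sign
corrected, so reflections are never returned); the implementation is
cross-checked against `bio3d::rmsd()` in the tests, which also verify the
$\sigma\sqrt{3}$ law for isotropic Gaussian displacements. Hydrogen-bond
occupancy uses a donor–acceptor distance cutoff of 3.5 Å and, when an
explicit hydrogen is present, a D–H···A angle cutoff of 150°; with
heavy atoms only, the distance criterion alone applies. The default
reporting threshold for "significant" occupancy is 0.10 — a reporting
convention, not a physical constant.

Buried interface area between two subunit groups is
$[\mathrm{SASA}(A) + \mathrm{SASA}(B) - \mathrm{SASA}(A \cup B)]$, with the
conventional single-side value (half the total) reported first and the
total alongside, since either convention appears in the literature. SASA
itself is Shrake–Rupley with a Fibonacci-lattice point set (default 960
points, probe 1.4 Å) over Bondi-style van der Waals radii; hydrogens are
ignored by default because deposited models often lack them.

## The synthetic generator

`gen_surface_cloud()` samples lateral positions uniformly at random (not on
a lattice) to mimic the irregularity of segmentation voxels — this
deliberately stresses the scattered-interpolation step. Heights are
analytic (plane, sphere cap, Gaussian bump, or a microsome patch: a
1,300 Å background sphere carrying a local bump) plus Gaussian noise of 1 Å
by default, the scale of segmentation jitter at tomogram voxel sizes.
`surface_height()` and `surface_mean_curvature()` expose the exact surface
and its exact curvature as independent oracles.

`gen_lipid_trajectory()` draws C–H orientations fresh each frame from a
two-state mixture — perfectly aligned with the normal versus isotropic —
whose aligned fraction equals the target $S_{CD}$, the simplest exactly
solvable order model (for negative targets the aligned state is replaced by
an in-plane, $S_{CD} = -1/2$, state with fraction $-2 S_{CD}$). Flip-flops
are instantaneous head jumps across the midplane drawn per lipid per frame
with the prescribed rate, and the true event log is returned with the
trajectory, so the detector can be graded exactly. Default conditions: a
34 Å bilayer (head planes at ±17 Å), 1 Å head jitter, 16 chain carbons with
two hydrogens each; flip-flop studies use 200 lipids × 2,000 frames at a
rate of $2.5 \times 10^{-4}$ per lipid per frame (about 100 expected
events), heads-only since the detector consumes only head positions; order
studies use 500 lipids × 100 frames.

What the generator does **not** emulate: lateral diffusion and lipid
mixing, transit states during flip-flops (jumps are instantaneous by
design, so detection can be exact), collective undulations, anisotropic
segmentation noise, and missing-wedge artifacts of tomography. Passing the
recovery tests therefore demonstrates the correctness of the estimators on
their stated model, not the segmentation quality of any particular
experimental map.

## Problem sizes and reproducibility

The bundled checks run at desk scale, chosen so each stage still has
non-trivial statistics: ~5,600 points for the sphere-cap radius recovery,
9,000 for the two-scale microsome patch, $10^5$ samples for the mixture
fits, 500 × 100 lipid-frames for order parameters, 200 × 2,000 for
flip-flops. All stochastic operations take explicit integer seeds and equal
seeds give bit-identical outputs; the pipeline summaries embed a hash of
their configuration. `scripts/acceptance.R` re-runs all of these from
scratch for any seed.

## Known limitations

* Curvature is computed on height fields only; strongly overhanging
  membranes (not representable as $z(x,y)$) need an external
  reparameterization first.
* One-sided difference stencils at mask borders are first-order accurate;
  regional radii should be read a few cells away from the rim, and the
  far-field microsome radius carries a few-percent upward bias from LOESS
  flattening at practical point densities.
* The two-leaflet split of a single membrane segmentation is the caller's
  responsibility (upstream segmentation tools provide it); `mask_to_points()`
  converts one mask to one cloud and the segmentation threshold is a
  required argument, as no universal default exists.
* EM mixture fits assume Gaussian components; heavy-tailed thickness
  distributions will inflate the broad component's weight.
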