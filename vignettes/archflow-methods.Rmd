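---
title: "Methods: wall shear stress, OSI, projection maps and PWV from 4D flow velocity fields"
author: "archflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wall shear stress, OSI, projection maps and PWV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the numerical methods, the tunable parameters,
and the design decisions behind `archflow`, in the order the pipeline
runs them. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The physical model

Blood is treated as a Newtonian fluid with dynamic viscosity
η = 0.004 Pa·s (configurable; the default is the standard assumption for
mouse blood at body temperature). The traction the flowing blood exerts
on the vessel wall is τ = 2 η ε̇ n, with ε̇ the symmetrized velocity
gradient and n the unit normal pointing from the wall into the fluid.
With this orientation the longitudinal component of τ points along the
flow and a component directed at the vessel center is positive — the
sign convention used for "radial strain" throughout. Components are
**stored signed**; statistics run on signed values, and magnitude
summaries can be formed trivially where a display calls for them.

## The synthetic phantom and what it does (not) emulate

`generate_phantom()` voxelizes a straight tube or a 180° torus arch
(lumen radius 0.6 mm, arch radius 1.5 mm by default — murine aortic
dimensions) at 100 µm isotropic resolution, with 20 frames per cardiac
cycle in WSS mode or 200 in PWV mode and a 120 ms heart period, matching
the acquisition regime of high-field murine 4D flow imaging. Inside the
lumen the axial velocity is parabolic, `v(r) = v_max(t) (1 − (r/R)²)`
with a 100 cm/s default peak; an optional azimuthal component
`v_φ(r) = v_c(t) (r/R)²` emulates helical flow. The pulsatile waveform
is a half-sine over the systolic 30 % of the cycle on a 5 % diastolic
baseline, which gives the flow curve an unambiguous foot; pulse
propagation is a pure time shift by arc-length/wave-speed, so the
prescribed wave speed *is* the ground-truth PWV with no dispersion.
Gaussian velocity noise (seeded, never applied to the mask) emulates
measurement noise. Closed-form truth accompanies each phantom: wall WSS
2ηv_max/R and ηv_c/R (both cross-checked in the tests against numerical
differentiation of the analytic profiles), flow πR²v_max/2, volume πR²L,
OSI and PWV.

The phantom deliberately does **not** emulate: Womersley (unsteady
Bessel-profile) flow, wall motion or compliance, partial-volume and
phase-noise characteristics of reconstruction, displacement artifacts,
or branch vessels. Passing the phantom suite therefore validates the
geometric and numerical machinery — not robustness to every artifact of
in vivo data.

## Surface extraction

The lumen surface is the 0.5-level isosurface of the (optionally
time-averaged) segmentation after Gaussian smoothing (σ = 1 voxel by
default), triangulated by marching tetrahedra on the Kuhn 6-tetrahedra
cube subdivision — consistent face diagonals between neighboring cubes
make the mesh watertight. Smoothing removes the voxelization staircase so
that node positions and mesh area track the underlying smooth surface
(sphere area within 5 % at 10 voxels radius). Node normals come from the
smoothed occupancy gradient and orient the faces outward. Only the
largest connected component is meshed; a secondary component holding
more than 10 % of the foreground raises an error rather than silently
meshing debris.

## Centerline extraction

The segmentation tool chain this replaces was interactive, so the
algorithm is specified here in full. Lumen voxels are ordered by a
double breadth-first-search geodesic coordinate and collapsed to slab
centroids, weighted by squared erosion depth to pull the (corner-biased)
BFS end slabs toward the tube core. The curve is then refined twice:
voxels are re-slabbed by their projection onto the current curve — slabs
perpendicular to the axis have unbiased centroids wherever they are
complete cross-sections — and voxels near the tube ends are mirrored
across the estimated end-cap planes so the end slabs *are* complete.
Each coordinate is smoothed against cumulative chord length by local
quadratic regression (loess, 1.5 mm window), resampled at even 50 µm arc
spacing; the last ~2.5 lumen radii, which inherit residual bias from the
initial coordinate, are cut and regrown as the circle fitted to the
adjacent clean interior (an exact continuation for arch-like geometry,
a straight line for tubes). Finally the curve is cropped to the arc
range actually occupied by lumen voxels. Two refinement cycles reach
voxel-level accuracy on the phantoms; more mainly lets the end estimates
wander, which is why `refine_iter = 2` is the default. The approach
assumes an unbranched, roughly tubular lumen at least ~4 radii long;
side branches should be excluded from the mask (or flagged via
`branch_flags`) beforehand.

The extraction cannot know which end is proximal; `orient_by_flow()`
flips the curve so arc length increases downstream, which fixes the sign
of the longitudinal WSS and the handedness of θ.

## Wall frames and the θ convention

Each mesh node takes its arc-length coordinate z from the nearest point
of the densely resampled centerline (ties resolved to the smaller z).
The frame is l̂ = local tangent, r̂ = unit vector from the node toward
its foot point orthogonalized against l̂ (inward positive), and
ĉ = l̂ × r̂. θ is measured from a reference direction transported along
the centerline by projecting out the tangent at each step (parallel
transport). Transport is the decisive choice here: projecting a fixed
anatomical axis directly degenerates where the vessel bends strongly
(the top of the arch), whereas the transported frame stays continuous;
the anatomical labels are recovered by choosing the reference so that
θ = 0 is posterior, which for the arch phantom (bend in the x–z plane)
is the plane normal +y, and then θ = 90°/270° land on the outer/inner
curvature automatically.

## WSS gradient estimation

The decisive numerical step. At each node the full velocity gradient is
reconstructed from three directional derivatives along the orthonormal
triad (n̂ and two tangents):

* **Normal derivative.** Velocities are sampled by trilinear
  interpolation at depths {0.5, 1, 1.5, 2, 2.5, 3} voxels along the
  inward normal. A sample is kept only if its entire 8-voxel
  interpolation stencil lies inside the lumen — near-wall samples
  contaminated by zero-filled exterior voxels would otherwise bias the
  fit. A **quadratic** polynomial in depth is fitted per velocity
  component (nodes need at least 3 clean depths to be valid) and its
  slope is evaluated at the wall. A straight-line fit — the simpler
  choice — estimates the derivative at the mean sampling depth instead
  of at the wall and systematically underestimates a parabolic profile
  by ≈ 2 d̄/R (≈ 20 % at 100 µm voxels for R = 0.6 mm); the quadratic is
  exact for parabolic near-wall profiles at any subset of depths, which
  is what makes the oracle recovery at 100 µm possible. The wall *value*
  of the fit is discarded: measured data violate no-slip, so only slopes
  are used.
* **Tangential derivatives.** Central differences of mask-aware
  trilinear samples (exterior stencil weights renormalized away) offset
  ±0.5 voxel along each tangent at depth 1 voxel.

The gradient is assembled as G = Σ_dir (D_dir v) ⊗ dir, symmetrized, and
contracted with the into-the-fluid normal. On the steady Poiseuille
phantom the spatial mean |τ| is within 3.3 % of 2ηv_max/R at 100 µm and
the error falls monotonically at 50 and 25 µm (1.9 %, 0.7 %); on the
helical phantom the circumferential component — which requires the
tangential term ∂v_φ/∂φ, i.e. the −v_φ/r correction — lands within 12 %
of ηv_c/R while the longitudinal component simultaneously matches its
oracle.

OSI is computed per node from the frame-resolved τ; an all-zero series
maps to OSI = 0 (the defining ratio is 0/0 there, and no flow is treated
as non-oscillatory).

## Projection maps

Nodes carry (z, θ, value) triples. Interpolation onto the regular grid
(0.5° × 1 µm by default, the native reporting grid) is two-stage: nodes
are grouped into thin z slabs (80 µm), each slab is linearly
interpolated around the periodic θ axis (point cloud replicated at
±360°), and the slab profiles are linearly interpolated along z at the
slab mean-z positions. This is effectively bilinear interpolation on a
quasi-grid: continuous, exactly constant-preserving, with no overshoot
at coverage borders. A cell is valid if a node lies within a ±3° × ±60 µm
box (evaluated by coarse binning); branch ostium flags propagate to
invalid cells. Maps of different animals are aligned by resampling each
so its landmark row sits `prox_mm` into a common 7 mm window (3 mm
proximal + 4 mm distal — the standard length normalization between the
brachiocephalic and left subclavian landmarks). Group statistics may run
on a block-averaged coarsening of the native grid (`coarsen_map()`);
the phantom validation runs the reconstruction check on the native grid.

## Flow, PWV and volume

Through-plane flow rasterizes a plane orthogonal to the centerline at
half-voxel pitch, samples the velocity trilinearly, and sums v·n̂ over
in-lumen pixels. Upstroke feet are the intersection of a baseline line
(fitted to the ~10 % of frames preceding the foot candidate, itself the
last sub-10 %-amplitude sample before the rise) and an upstroke line
(fitted between the 20 % and 80 % amplitude crossings — standard
transit-time windows; threshold crossings rather than monotone runs keep
the windows stable under noise). The curve is treated as one period of a
cyclic signal: it is rotated so the peak sits past mid-cycle before
detection, and arrival times are recentered circularly before the
regression, because the transit across 7 mm is a small fraction of the
cycle. Arrival time is regressed **on** position — detection errors live
in the time estimates — and PWV = 1/slope in m/s; a non-positive or
near-zero slope is reported as unresolvable rather than as a number.
Volume is exact voxel counting (branch-flagged voxels excluded) on the
mask cropped to the analysis window by signed arc position.

## Group statistics

Pixel-wise comparisons default to the unpaired two-sided Welch t-test:
per-pixel normality testing at 4–6 animals is uninformative, and Welch
avoids assuming equal variances between e.g. control and diseased
groups. A Mann–Whitney option exists. No multiple-testing correction is
applied on maps — pixels are thresholded at raw p < 0.05, as is
conventional for these significance maps — but the fraction of
significant pixels is always reported so users can gauge inflation.
Zero-variance pixels carry an undefined (NA) p rather than 0 or 1.
Under a null simulation (both groups i.i.d. normal, n = 5 vs 5, 10⁴
pixels) the significant fraction is calibrated to the nominal 5 % rate.
Within-group comparisons across timepoints are treated as **unpaired**
(matching the scalar testing cascade); a paired alternative would gain
power but is not what the cascade specifies. Scalar tests run iterative
Grubbs outlier exclusion first (α = 0.05, capped at two removals per
group to guard small samples), gate on Shapiro–Wilk per group, and then
use unpaired t / ANOVA or Mann–Whitney / Kruskal–Wallis; groups too
small for the gate fall back to the non-parametric branch, and the
chosen branch is always returned for audit.

## Problem sizes and numerical guardrails

The validation suite uses short cylinders (3 mm at 100/50/25 µm for the
WSS convergence ladder, 9 mm at 100 µm elsewhere), 50 flow planes with
200 frames for PWV, 100 noise repetitions at 5 % of peak flow, and 10⁴
pixels for the null calibration — sizes chosen so every closed-form
comparison is well-resolved while the whole suite runs in minutes on one
core. Degenerate inputs fail loudly: empty or multi-component masks,
single-voxel masks, planes that miss the lumen, flat flow curves,
simultaneous upstrokes, zero-variance correlations. Frame orthonormality
is enforced to 10⁻⁶, the component decomposition conserves |τ|² to
10⁻⁹ relative, and identical configuration plus seed reproduces pipeline
output byte-for-byte (outputs deliberately contain no timestamps).

## Known limitations

Newtonian viscosity only; no correction for displacement artifacts or
partial-volume effects at the wall; the centerline assumes an unbranched
tubular mask and degrades on stubby segments shorter than ~4 radii;
landmark-based z alignment is the only inter-animal registration (no
nonrigid surface matching); per-pixel significance is uncorrected for
multiplicity by design.
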