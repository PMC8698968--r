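# archflow

Hemodynamic mapping of the murine aortic arch from 4D flow (phase-contrast
MRI) velocity fields: wall shear stress vectors and their anatomical
components, oscillatory shear index, 2D projection maps with pixel-wise
group statistics, transit-time pulse wave velocity, and time-resolved lumen
volume — with a synthetic flow phantom that carries analytic ground truth
for every stage.

## Who this is for

Preclinical cardiovascular imaging groups that acquire time-resolved
three-component velocity fields of small vessels (typically the mouse
aortic arch at ~100 µm isotropic resolution, 20 frames per cardiac cycle)
together with a binary lumen segmentation, and want spatially resolved,
statistically comparable wall-shear readouts rather than global means.

## The model

The wall shear stress vector at a point on the lumen surface is

    τ = 2 η ε̇ n,        ε̇ᵢⱼ = ½ (∂vᵢ/∂xⱼ + ∂vⱼ/∂xᵢ)

with η the dynamic blood viscosity (0.004 Pa·s by default), ε̇ the
symmetrized velocity-gradient tensor estimated at the wall, and n the
surface normal pointing into the fluid. τ is computed per cardiac frame,
averaged over the cycle as a vector, and decomposed in a centerline-based
cylindrical frame into a longitudinal component (along the flow), a
circumferential component (helical flow), and a radial component
("radial strain", positive toward the vessel center). The oscillatory
shear index summarizes temporal direction/magnitude changes:

    OSI [%] = ½ (1 − |Σᵢ τ(i)| / Σᵢ |τ(i)|) · 100      (0–50 %)

Per-node values are unwrapped to regular (z, θ) maps — z the centerline
arc length, θ the circumferential angle (0° posterior, 90° outer
curvature, 180° anterior, 270° inner curvature) — on a 0.5° × 1 µm grid,
aligned across animals at an anatomical landmark, and compared pixel-wise
(difference, p-value and significance maps; inter-animal dispersion
summaries). Pulse wave velocity comes from the transit-time method: the
systolic upstroke foot of the through-plane flow curve is detected at ~50
planes along the vessel by a two-line (baseline × upstroke) intersection
and arrival time is regressed on plane position, PWV = Δx/Δt.

## Worked example

```r
library(archflow)

# a steady Poiseuille tube phantom: R = 0.6 mm, 100 µm voxels, 100 cm/s peak
spec <- phantom_spec("straight_cylinder", radius = 0.6, length = 9,
                     voxel_size = 0.1, n_frames = 1, v_max_axial = 100)
ph <- generate_phantom(spec)
ph$truth$wss_long_wall          # analytic wall WSS, 2 η v_max / R
#> [1] 13.33333

mesh <- extract_surface(ph$mask)
cl   <- orient_by_flow(extract_centerline(ph$mask), ph$velocity, ph$mask)
ne   <- normalize_extent(cl, mesh, landmark_z = 4)  # 7 mm analysis window
fr   <- build_wall_frames(ne$mesh, ne$centerline)

tab <- wall_mechanics_table(ph$velocity, ph$mask, ne$mesh, fr)
summary(tab$long_wss[tab$valid])
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   12.17   12.39   12.86   12.90   13.48   13.62

mp <- project_to_map(tab$long_wss, fr, theta_step = 2, z_step = 0.02,
                     z_range = c(0, 7))
mp
#> projection_map: 351 x 180 (z x theta), 100 % valid, range 12.17 .. 13.61

extract_strip(mp, center_theta = 270, half_width = 30)   # inner-curvature strip
#> [1] 12.60978
```

The recovered longitudinal WSS (mean 12.90 Pa) sits ~3 % below the
analytic 13.33 Pa at 100 µm voxels; the error shrinks monotonically at
finer resolution (see the methods vignette). `run_pipeline()` chains the
same stages over a manifest of animals, writes per-animal node tables and
maps plus group difference/p-value maps, volumes, and (in 200-frame mode)
PWV fits, all as CSV/JSON. A thin command-line wrapper lives at
`inst/cli/archflow.R` (`phantom` and `pipeline` subcommands).

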