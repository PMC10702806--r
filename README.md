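# memlens

Quantitative analysis of local membrane remodeling around membrane-protein
complexes, in R.

Large complexes such as the Sec61 translocon with the TRAP complex "lens"
the bilayer around them: the membrane locally curves, thins and disorders.
memlens provides the full analysis chain used to quantify this from two
kinds of data — scattered leaflet point clouds (e.g. segmented from a
cryo-electron tomogram, or time-averaged lipid phosphate positions from a
simulation) and lipid trajectories — together with a synthetic-membrane
generator that supplies analytic ground truth for every stage.

## What it computes

**Surfaces.** Scattered leaflet points → smooth height fields by Delaunay
piecewise-linear interpolation onto a regular grid followed by LOESS local
regression (default: 20 % of the data points per local fit, quadratic
polynomials, tricube weights):

z(x, y) fitted per grid node from its k = ⌈span·N⌉ nearest samples with
weights w = (1 − (d/d_max)³)³.

**Geometry.** Mean curvature
H = [(1+z_x²)z_yy − 2 z_x z_y z_xy + (1+z_y²)z_xx] / [2(1+z_x²+z_y²)^{3/2}]
and Gaussian curvature K by finite differences; regional radius of
curvature R = 1/|⟨H⟩|; least-squares sphere fits (Coope + Gauss–Newton).

**Thickness & statistics.** Thickness maps t = z_upper − z_lower, axis
profiles, and two-component Gaussian-mixture decompositions of thickness or
order distributions by EM (k-means++ init, monotone log-likelihood, BIC
model selection).

**Trajectories.** Deuterium order parameters S_CD = ⟨(3cos²θ − 1)/2⟩ per
chain carbon and as local lateral maps; lipid flip-flop detection with
hysteresis and cumulative event curves; lateral-gate (helix-pair)
center-of-geometry distances; Kabsch superposition RMSD; hydrogen-bond
occupancy (3.5 Å / 150° criteria).

**Structures.** Shrake–Rupley SASA and buried interface areas between
subunit groups.

**I/O.** MRC2014 volumes (with `mask_to_points()` for segmentation masks),
PDB/mmCIF via bio3d, multi-frame GRO/XYZ trajectories, CSV point tables and
gridded maps. All coordinates in Ångström.

## Worked example

Reconstruct a lensed bilayer with known ground truth and recover its
geometry:

```r
library(memlens)

# synthetic microsome-like leaflets: flat-ish upper, bulged lower,
# nominal thickness 34 A, 5 A thinning at the bump, 1 A noise
up <- surface_spec("plane", extent = 200, density = 0.1, noise_sd = 1,
                   z0 = 17, seed = 3)
lo <- surface_spec("gaussian_bump", extent = 200, density = 0.1,
                   noise_sd = 1, z0 = -17, A = 5, sigma = 40, seed = 4)
bl <- gen_lensed_bilayer(bilayer_spec(up, lo, nominal_thickness = 34))

g  <- grid_for_points(bl$upper, spacing = 4, shrink = 5)
th <- thickness_map(fit_leaflet(bl$upper, g), fit_leaflet(bl$lower, g))

xy <- field_xy(th); r <- sqrt(xy$x^2 + xy$y^2)
round(th$z[which.min(r)], 2)              # thickness at the bump center
#> [1] 28.97
round(mean(th$z[th$valid & r > 120]), 2)  # far-field thickness
#> [1] 33.92
```

The map reports the built-in thinning from 34 Å to ~29 Å at the bump. The
same `fit_leaflet()` output feeds `mean_curvature_map()` and
`radius_of_curvature()`:

```r
sp <- surface_spec("sphere_cap", extent = 150, density = 0.25,
                   noise_sd = 1, R = 320, seed = 1)
cl <- gen_surface_cloud(sp)
H  <- mean_curvature_map(fit_leaflet(cl, grid_for_points(cl, 4, shrink = 4)))
radius_of_curvature(H, center = c(0, 0), radius = 40)$radius
#> [1] 316.5084
```

i.e. the 320 Å radius is recovered within a few percent from noisy points.
See `vignettes/membrane-remodeling.Rmd` for the model, conventions and
design decisions, and `inst/cli/memlens.R` for a thin command-line front
end (`simulate`, `fit-surface`, `run-cryoet`, `run-md`).

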