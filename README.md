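# msimclink

Linking MALDI mass spectrometry imaging (MSI) pixel grids to imaging
mass cytometry (IMC) single-cell data through a chain of brightfield
microscopy images — with registration quality control and spatial
statistical models of analyte–cell-type association.

## Who this is for

MSI measures glycans, lipids and metabolites at 10–100 µm pixels; IMC
resolves individual cells at 1 µm but only sees antibody-taggable
targets. Groups running both modalities on the same or adjacent tissue
slices need to (i) register the MSI ablation grid onto the IMC cell
segmentation via the slide scans taken before/after each acquisition
(`MSI → PostMSI ← PreMSI ← PreIMC ← PostIMC ← IMC`), (ii) quantify how
precise each registration link is, and (iii) model which analytes
co-localize with which cell types despite the resolution gap. This
package implements that workflow as composable R functions plus a thin
command-line front end (`inst/cli/msimclink.R`).

## The statistical core

For each sample and m/z channel, the per-pixel analyte intensity is
modelled with a spatial-lag (simultaneous autoregressive, SAR)
regression

```
y = ρ W y + X β + ε,   ε ~ N(0, σ² I)
```

where `W` is the row-standardized pixel neighbour matrix, `X` holds the
per-cell-type area fractions inside each MSI pixel (from exact polygon
overlap of registered cell masks with the pixel squares), `ρ` captures
spatial autocorrelation, and `β` are the analyte–cell-type
associations. Fitting is by maximum likelihood with an eigenvalue
log-determinant. A second stage regresses per-sample `β̂` on sample
metadata with inverse-variance weights (`1/SE²`), optionally with a
patient random intercept, and controls FDR across channels. Aggregate
alternatives (compositional pivot-coordinate regression, tissue-domain
pseudobulk tests) are included.

## Worked example

Simulate a tissue (cells with per-type analyte rates aggregated onto a
30 µm MSI grid with 24 µm spots), then fit the pixel model:

```r
library(msimclink)

sim <- simulate_dataset(sim_config(field_um = 500, n_per_type = 60,
                                   noise_meanlog = NULL, grf_error_max = 0,
                                   smooth_lambda = 0), seed = 2)
covs <- grep("^frac_", names(sim$grid), value = TRUE)
fit  <- fit_pixel_model(sim$grid, sim$grid$y, covs)
fit
#> Spatial lag (SAR) fit: n = 256 pixels, rho = -0.0157, sigma2 = 798.5
#>          (Intercept)    frac_1   frac_2   frac_3
#> estimate      1.8833 2529.9584 978.0756 537.2868
#> se            3.5339   30.6721  34.8935  54.1258
```

The three `frac_*` coefficients estimate each type's analyte rate times
the pixel area; the simulated truth here is `2663 / 980 / 594`
(`sim$true_rate_mean * 24^2`), so the fit recovers the per-type rates
to within a few standard errors on a single 256-pixel sample.
The intercept is near zero because uncovered pixel area carries no
analyte. `tidy(fit)` and `glance(fit)` return the usual tidy summaries.

Registration works the same way on rendered fixtures:

```r
fx <- render_postmsi_fixture(n_col = 10, n_row = 10, stepsize_um = 30,
                             mark_radius_um = 10, jitter_sd_um = 1, seed = 3)
p  <- detection_params(w = 0.5, t = 0.15, disk_radius_px = 5,
                       area_bounds_um2 = pi * 100 * c(0.5, 1.6))
mk <- detect_marks(enhance_marks(fx$image, p), p, stepsize_um = 30)
reg <- register_msi_grid(mk, fx$truth$col, fx$truth$row, stepsize_um = 30)
median(reg$assignment$residual_um, na.rm = TRUE)
#> [1] 1.242613
```

The median residual of ~1.24 µm is essentially the Rayleigh median of
the planted 1 µm jitter (1.18 µm) — the registration itself contributes
almost nothing on top of the mark placement noise.

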