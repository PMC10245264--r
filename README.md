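# lwlrattrib

Nonlinear attribution of vegetation-index dynamics to climate and human
activity, for monthly gridded NDVI / temperature / precipitation records.

Global ("RESTREND"-style) regressions assume the climate–vegetation
relationship is constant over a 20-year record; it rarely is.  This package
implements a locally weighted linear regression (LWLR) whose coefficients
are re-estimated at every month,

    N(t) = β₀(t) + β₁(t)·T(t) + β₂(t)·T²(t) + β₃(t)·P(t) + β₄(t)·P²(t) + ε(t),

using an asymmetric Gaussian kernel in time: months before the focal month
decay with bandwidth h₁, later months with h₂, so the ratio Rh = h₂/h₁
carries lead–lag information between NDVI and its climate drivers.  The pair
(h₁, h₂) is chosen per cell by exhaustive leave-one-out cross-validation.
The time-varying intercept β₀(t) collects the non-climatic signal and is
interpreted as the anthropogenic contribution.

On top of the fit the package provides:

* **contribution series** — temperature f̂(t) = β̂₁T + β̂₂T², precipitation
  ĝ(t), anthropogenic β̂₀(t), their time averages (APNC), and the share
  R_ac = β̄₀/(f̄+ḡ+β̄₀);
* **changing trends** — STL-detrended climate contribution and cubic-fit
  mean derivatives α (climate) and α₀ (anthropogenic), the relative
  contribution ratios Ra = α₀/(α₀+α), Rc = 1−Ra, and a driver
  classification;
* **diagnostics** — kernel-weighted variance inflation factors,
  Durbin–Watson with Cochrane–Orcutt AR(1) correction, and a residual
  normality test (ΔP: maximum KDE-vs-normal density discrepancy) with a
  Monte-Carlo calibrated threshold τ = 0.04;
* **a synthetic generator** — seasonal, trending, AR(1)-noisy climate and
  NDVI built from known coefficient functions, with full ground truth for
  recovery testing;
* **a batch pipeline and CLI** — mask → select → fit → diagnose →
  attribute over a grid of cells, CSV/JSON in and out.

## Worked example

```r
library(lwlrattrib)

# a 20-year synthetic cell whose anthropogenic term rises by 2.5e-4 NDVI/month
sim <- make_cell(synthetic_truth(beta0 = linear_coef(0.20, 2.5e-4), seed = 7),
                 M = 240)
out <- run_cell(sim$cell, run_config())
out
#> <cell_outcome> synthetic-1: fitted
#>   h = (24, 24), Rlg = 1.013, DW = 2.10, Delta-P = 0.052
#>   APNC f = 0.126, g = 0.045, b0 = 0.230;  Ra = 1.04 (anthropogenic-promotes-climate-degrades)
```

Reading the output: cross-validation picked a symmetric 24-month kernel;
the local model explains 1.3 % more variance than the global one
(Rlg = 1.013); residuals show no autocorrelation (DW ≈ 2).  Human activity
contributes the largest average share of fitted NDVI (b̄₀ = 0.230 vs
f̄+ḡ = 0.171), and the changing trend is almost entirely anthropogenic
(Ra ≈ 1, matching the generating slope on β₀ with trendless climate).

The same works batch-wise:

```r
grid <- make_grid(10, "mixed", seed = 1, M = 120)
res <- run_grid(grid, run_config(cv_grid = default_bandwidth_grid(c(2, 6, 12, 24, 48))))
res
#> <grid_result> 10 cells: 8 fitted, 2 masked, 0 failed
#>   Rlg bins:
#> 1.00-1.10 1.11-1.20 1.21-1.30 1.31-1.40 1.41-1.50     >1.50
#>         7         0         0         0         0         1
#>   mean Ra = 0.380, mean Rc = 0.620, Delta-P pass = 0.50
write_outputs(res, "results/")
```

The two masked cells are the grid's "no-vegetation" cells (mean NDVI
≤ 0.15).  From a shell, the same pipeline is:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "lwlr-attrib.R", package = "lwlrattrib"))') \
    sim --n-cells 25 --seed 1 --out cells.csv
Rscript $(Rscript -e 'cat(system.file("cli", "lwlr-attrib.R", package = "lwlrattrib"))') \
    run --input cells.csv --out results/
```

## Documentation

The methods vignette (`vignettes/lwlr-attribution.Rmd`) describes the
model and its assumptions, every tunable parameter with units and
defaults, the diagnostics and their calibration, what the synthetic
generator does and does not emulate, and the package's numerical choices
and known limitations.
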