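# megabiota

Metabolic scaling theory (MST) applied to the **megabiota** — the largest
trees and animals in an ecosystem — for macroecologists and ecosystem
modellers who want the size-scaling arguments about extinction risk,
carbon stocks, resource flux, and soil fertility as tested, reusable
code rather than back-of-envelope algebra.

## What it computes

Body size enters everywhere through power laws:

- **Extinction risk**: `E ∝ m^(b+c+d)` from mortality risk (`m^b`),
  inverse fecundity (`m^c`), and minimum habitat area (`m^d`); with the
  headline composite exponent 2.5, a 10× larger organism is ~316× more
  extinction-prone.
- **Stocks**: with the stem spectrum `f(r) = c_n r^-2` and tree mass
  `m = c_m r^(8/3)`, total forest biomass is
  `M_tot ≈ (3/5) c_n c_m r_max^(5/3)`, i.e. `∝ m_max^(5/8)`; animal
  trophic biomass with `f(m) = c_a m^(-3/4)` gives
  `M_tot ≈ (4/5) c_a m_max^(5/4)`.
- **Flows**: plant resource flux `J_tot ∝ r_max` (10× radius → 10× carbon
  assimilation); heterotrophic flux `∝ m_max^(5/4)` (10× mass → ~18×
  flux); `NPP ∝ M_tot^(3/5)`.
- **Fertility**: per-herbivore lateral nutrient diffusivity
  `φ(m) = k m^1.17`, aggregated over a community into `Φ` (calibrated to
  4.4 km² yr⁻¹ for the intact reference fauna) and fed into the
  steady-state diffusion–loss equation `∇·(Φ∇P) = λP` on a gridded
  basin with a floodplain source, to ask how size-selective extinctions
  degrade soil phosphorus.

Log–log power-law fitting (OLS and standardized major axis, analytic or
bootstrap CIs) and seed-reproducible synthetic-data generators (forest
plot inventories, Pleistocene-like herbivore communities, basin-like
grids) make every stage testable without external data.

## Worked example

```r
library(megabiota)

# rule-of-thumb predictions
extinction_risk_ratio(extinction_scaling(), 10)
#> [1] 316.2278
p1  <- plant_size_spectrum(r_min = 1e-6, r_max = 1)
p10 <- plant_size_spectrum(r_min = 1e-6, r_max = 10)
plant_total_biomass(p10) / plant_total_biomass(p1)    # ~47x the carbon
#> [1] 46.41589

# synthetic forest inventory: recover the 5/8 biomass exponent
plots <- generate_forest_plots(generator_config(seed = 1))
fit_power_law(plots$m_max, plots$m_tot)
#> Power-law fit (OLS, analytic CI): exponent = 0.6285 [0.6078, 0.6492],
#>   intercept = 6.8612, n = 200

# fauna downsizing vs basin fertility
fauna <- pleistocene_community()
model <- calibrate_model(fauna, target_phi = 4.4)
dom   <- generate_amazon_like_grid()
run_threshold_experiment(dom, sim_config(), fauna, model,
                         c(Inf, 5623, 89, 3))
#>   threshold_kg phi_km2_yr percent_of_baseline
#> 1          Inf  4.4000000           100.00000
#> 2         5623  3.1847338            84.99775
#> 3           89  0.4165234            29.24307
#> 4            3  0.0000000             0.00000
```

The fitted exponent sits on the theoretical 5/8 = 0.625 with a covering
confidence interval; the sweep shows fertility falling monotonically —
removing animals above ~5.6 t already costs 15% of steady-state soil P
on the synthetic fixture, and a world with no wild herbivores loses the
entire diffusive subsidy.

## Analyses

Three narrative drivers reproduce the package's analyses end to end and
write delimited tables under `results/`:

```sh
Rscript analysis/01_mst_predictions.R    # ratios & exponents table
Rscript analysis/02_forest_scaling.R     # plot generation + exponent fit
Rscript analysis/03_amazon_fertility.R   # calibration, PDE, threshold sweep
```

`run_full_pipeline()` runs the same stages as one seeded, manifest-logged
call.

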