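# equaflux

Turbulent nitrate supply to the equatorial surface ocean: dissipation-rate
estimation from microstructure shear, diapycnal diffusivity and diffusive
nitrate flux, Equatorial Undercurrent (EUC) core-relative composites,
Richardson-number fields, and seasonal climatologies with full uncertainty
propagation — together with a synthetic-data generator that makes the whole
chain verifiable end to end.

## The problem

Productivity in the eastern equatorial ocean hinges on nitrate crossing
from the thermocline into the sunlit layer. Whether that happens depends on
the vertical arrangement of three features: the surface mixed layer
(`D_ML`), the nitracline — well proxied by the 20 °C isotherm
(`D_20C`) — and the core of the eastward Equatorial Undercurrent
(`D_EUC`), below a strongly sheared, turbulent "deep cycle" layer. Nitrate
is mixed upward only when the nitracline sits inside that turbulent layer
above the EUC core.

The package implements the standard observational chain that quantifies
this:

* **Dissipation rate** ε from microstructure shear, by band-limited
  integration of the wavenumber spectrum of 2-s segments under isotropy
  (`ε = 7.5 ν ⟨u_z′²⟩`), with iterative correction for unresolved variance
  against the universal **Nasmyth spectrum**, plus saturation and
  noise-floor quality flags.
* **Osborn diffusivity** `K_ρ = Γ ε / N²` (Γ = 0.2) and **upward nitrate
  flux** `F_NO3 = K_ρ ∂NO3/∂z`, on 15-m depth bins relative to the EUC
  core, excluding the mixed layer plus 10 m.
* **Feature detectors**: mixed-layer depth (0.125 kg m⁻³ density
  threshold), 20 °C isotherm (linear interpolation), EUC core (discrete
  argmax refined by a quadratic fit over a 32-m window), N² (10-dbar
  running window), Sh² and Ri on modified-Akima-regridded velocities.
* **Seasonal climatologies**: mooring composites on a 15-day phase grid
  with effective-sample-size standard errors (decorrelation from the
  autocorrelation e-folding), the three-step Gaussian-distance-weighted
  profile-cloud regression (ellipse selection, IQR outlier filter, WLS
  with 200-km weighting), the Richardson-number climatology as a ratio of
  climatologies, and monthly moored-ε composites with bootstrap CL95.
* **Synthetic data** with known truth: cruise sections (tanh thermocline,
  monotone temperature–nitrate relation, Gaussian jet, planted ε field),
  Nasmyth-spectrum shear records (random-phase Fourier synthesis), mooring
  series (harmonics + AR(1) noise), and Argo-like profile clouds.

## Worked example

Two synthetic cruise scenarios encode the seasonal extremes of the
equatorial Atlantic: an April-like regime (fast, shallow EUC core at 53 m,
nitracline far below at 110 m) and a July/September-like regime (deep
91-m core with the nitracline at 60 m, inside the turbulent layer above
the core).

```r
library(equaflux)

ap <- run_section_pipeline(scenario_april(n_stations = 6), seed = 1)
ap
#> <section_pipeline> 6 stations; mean core 53.2 m at 1.00 m/s; 11 EUC-relative bins

round(ap$stations[, c("lon", "d_ml", "d_20", "d_euc", "core_speed")], 2)
#>     lon  d_ml   d_20 d_euc core_speed
#> 1 -35.0 19.54 109.98 54.18       1.01
#> 2 -27.6 18.85 110.04 53.13       0.98
#> 3 -20.2 19.03 109.94 52.72       0.99
#> 4 -12.8 19.29 110.03 52.47       1.01
#> 5  -5.4 19.19 109.96 52.98       1.00
#> 6   2.0 18.73 110.02 53.78       1.01
```

The detector recovers the planted mixed layer (~19 m), nitracline (110 m)
and core (53 m at 1.0 m s⁻¹) at every station. The same pipeline on the
deep-core regime, looking at the EUC-relative composite around the core:

```r
jl <- run_section_pipeline(scenario_september(n_stations = 6), seed = 1)
subset(jl$composite, bin_center <= 15 & bin_center >= -30,
       c(bin_center, epsilon, k_rho, gradient, flux))
#>   bin_center  epsilon    k_rho gradient     flux
#> 3        -30 1.53e-07 2.67e-05   0.6780 1.81e-05
#> 4        -15 2.69e-07 1.18e-04   0.4420 5.23e-05
#> 5          0 5.89e-08 1.22e-04   0.0667 8.13e-06
#> 6         15 1.19e-07 7.56e-04   0.0110 8.31e-06
```

Each row is a 15-m bin relative to the core (negative = above). Dissipation
peaks in the deep-cycle layer (bin −15: ε ≈ 2.7 × 10⁻⁷ W kg⁻¹, estimated
from synthesized shear spectra, not copied from the truth field), the
nitrate gradient is large there because the nitracline lies above the
core, and the upward flux `K_ρ · ∂NO3/∂z` reaches ≈ 5 × 10⁻⁵ µmol kg⁻¹
m s⁻¹. In the April regime the same bins carry near-zero flux — the
nitracline is below the core, so the turbulence stirs nitrate-free water.

A single dissipation estimate closes the loop on a synthesized record:

```r
rec <- make_shear_record(1e-9, duration = 30, seed = 7)  # truth: 1e-9 W/kg
epsilon_from_record(rec)$epsilon
#> [1] 9.09e-10
```

The mooring pipeline composites six years of synthetic daily records into
the seasonal cycle of `D_EUC − D_20C` (positive when the core is below the
nitracline — the configuration that allows upward nitrate flux):

```r
pl <- run_mooring_pipeline(mooring_scenario(seed = 1))
pl
#> <mooring_pipeline> depth difference peaks at day 226 (35.4 m); 25 Ri entries
```

The difference peaks in August (day 226) at +35 m and is negative in
boreal winter/spring, and the Richardson-number climatology drops below
0.25 in the mid-year entries — the phasing that concentrates nitrate
supply, and hence productivity, in boreal summer.

## Package layout

| Area | Files |
|---|---|
| Equation of state, depth/pressure | `R/eos.R` |
| Profile detectors, N², regridding | `R/hydrography.R` |
| EUC core, shear, Richardson number | `R/currents.R` |
| Nasmyth spectrum, ε estimation, K_ρ, flux | `R/turbulence.R` |
| Seasonal climatologies | `R/climatology.R` |
| Effective n, SE/CL95, bootstrap | `R/uncertainty.R` |
| Synthetic generators | `R/synthetic.R` |
| CSV/JSON I/O, pipeline drivers | `R/io.R`, `R/pipelines.R` |

The methods vignette (`vignettes/equatorial-nitrate-flux.Rmd`) documents
the model assumptions, parameter choices, the statistics behind the
uncertainty machinery, and what the synthetic tests do and do not
demonstrate about real data.
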