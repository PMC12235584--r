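# mimicscope

Characterization toolkit for **extracellular-vesicle (EV) mimics** — hollow
organosilica nanocapsules (NCs) coated with a designed lipid bilayer that
emulates the surface of natural EVs. It is aimed at groups building or
benchmarking such mimics who need the bespoke calculations of that workflow
as tested, reusable code:

1. **Coating stoichiometry budget** — how much lipid does a single-bilayer
   coat need? The capsule is a hollow sphere,
   `m_NC(d) = (4/3)π(r_o³ − (r_o − t)³)·ρ` (wall `t = 3.68` nm, silica
   density `ρ = 1.87` g/cm³), and the coat is a two-leaflet area model,
   `N(d) = [4π(d/2)² + 4π(d/2 + t_b)²] / a_eff`, converted to grams through
   the mole-fraction-weighted molar mass of the formulation. Per-diameter
   ratios `m_NC/m_lip` over 45–125 nm are weighted by a truncated-normal
   (79.4 ± 11.6 nm) capsule size distribution to a single comprehensive
   NC:lipid mass ratio.
2. **sPAINT polarity analysis** — spectrally resolved single-molecule
   localization with Nile Red, whose emission blue-shifts in apolar lipid
   environments: Gaussian PSF detection and fitting, redundant
   cross-correlation drift correction, density filtering, grating dispersion
   calibration, per-localization spectrum extraction with Gaussian peak
   fitting, the literal quality filter (uncertainty > 40 nm or
   < 300 spectral photons rejected), flat-kernel mean-shift clustering into
   particles, bright/dark-time kinetics, and population comparison via
   zero-lag Pearson cross-correlation of wavelength histograms
   (similarity threshold 0.9).
3. **Membrane metrics** — from head-group trajectories: area per lipid
   (`APL = Lx·Ly/n_leaflet`, sampled every 10 ns), head-to-head thickness
   `D_HH` from z-density peaks, area compressibility
   `K_A = k_B·T·APL/σ_APL` (as printed; a conventional variance-based mode
   is included), and lateral diffusivity from `MSD = 2dDτ` (`d = 2`) fitted
   over 8–72.5% of the trajectory span.

A seeded synthetic-data module generates ground-truthed sPAINT movie stacks
(blinking kinetics, photon-split grating optics, Poisson noise), TEM-like
size distributions, and periodic Brownian bilayer trajectories, so every
estimator is validated against known truth.

## Worked example

```r
library(mimicscope)

## How much lipid for a CE Mimic 3 coat, and is 2:1 the right call?
budget_report(load_formulation("ce-mimic-3"))
#> Coating budget for CE Mimic 3
#>   per-diameter NC:lipid ratio (uniform area): 1.72 - 2.15
#>   weighted ratio: 1.982 (uniform) / 1.412 (per-species)
```

Per-diameter ratios stay inside the theoretical 1.4–2.6 window and the
size-weighted ratio rounds to **2 : 1** — the mass ratio at which coated
capsules assemble best experimentally. The per-species figure uses distinct
molecular areas per lipid instead of one effective area; both are reported
so the sensitivity to that choice is visible.

```r
## membrane dynamics of a simulated bilayer patch
tr <- simulate_trajectory(n_heads = 100, D_true = 5, n_steps = 2000,
                          dt = 10, seed = 1)
membrane_metrics(tr)
#> Membrane metrics
#>   APL: 0.4199 +/- 0.0001 nm^2 (stderr, n = 2000)
#>   D_HH: 4.014 nm
#>   K_A: 4.332e-19 J (as-printed relation) | 2088 mN/m (variance)
#> Lateral diffusivity: D = 5.405 +/- 0.013 um^2/s (R^2 = 0.9993)
#>   fitted over tau = 1.6e+03 - 1.45e+04 ns
```

The generator used `D_true = 5 µm²/s` and leaflets at ±2 nm: the Einstein
fit and density-peak thickness recover both (the ~8% high D here reflects
the short 100-head trajectory; at the validation scale of 500 heads ×
10⁴ steps the estimator sits within 5%).

An imaging walk-through (simulate → localize → spectra → QC → cluster →
compare) is in the test suite and the methods vignette
(`vignettes/mimicscope-methods.Rmd`); a command-line front end for the
budget report is installed as `exec/mimicscope`:

```sh
Rscript inst/exec/mimicscope budget --formulation ce-mimic-3 --out report.csv
```

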