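---
title: "Models and estimators in mimicscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators in mimicscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimicscope)
```

`mimicscope` characterizes extracellular-vesicle (EV) mimics: hollow
organosilica nanocapsules (NCs) coated with a designed lipid bilayer. It
covers three workflows — the coating stoichiometry budget, a spectrally
resolved single-molecule (sPAINT) analysis chain with Nile Red polarity
read-out, and membrane structure/dynamics estimators for head-group
trajectories — plus a seeded synthetic-data module that provides ground
truth for all of them. This vignette explains the models, the defaults,
and what the validation does and does not show.

## Coating stoichiometry budget

The capsule is modeled as a perfect hollow sphere of outer radius
$r_o = d/2$, wall thickness $t$ and silica density $\rho$:

$$ m_{\mathrm{NC}}(d) = \tfrac{4}{3}\pi\!\left(r_o^3 - (r_o - t)^3\right)\rho. $$

Defaults are the TEM estimates $t = 3.68$ nm and a sol–gel silica density
$\rho = 1.87$ g/cm³. At the mean capsule diameter of 79.4 nm this gives
$m_{\mathrm{NC}} \approx 1.24\times10^{-16}$ g. (A widely quoted single-NC
weight of $1.3\times10^{-6}$ g for this geometry carries an obvious
exponent typo — it is ten orders of magnitude above what the stated volume
and density can produce; we implement the formula.)

The lipid mass of a single-bilayer coat uses a closed-form two-leaflet
area model in place of a bead-level vesicle builder: the inner leaflet
tiles the sphere of radius $d/2$, the outer one the sphere at
$d/2 + t_b$ (bilayer thickness $t_b = 4$ nm, a typical fluid-bilayer
value), and both are divided by an effective per-molecule area $a_{\rm eff}$:

$$ N(d) = \frac{4\pi (d/2)^2 + 4\pi (d/2+t_b)^2}{a_{\rm eff}}, \qquad
   m_{\mathrm{lip}}(d) = N(d)\,\frac{\bar M}{N_A}, $$

with $\bar M$ the mole-fraction-weighted molar mass (mole fractions derive
from the tabulated mass fractions via $x_i \propto w_i / M_i$; molar
masses are supplier-catalog constants shipped in
`inst/extdata/lipid_catalog.yaml`). The default is a uniform
$a_{\rm eff} = 0.72$ nm², calibrated once so that the per-diameter ratios
for the six mimic formulations reproduce the published [1.4, 2.6]
envelope; a per-species mode (distinct areas for cholesterol and each
phospholipid) is available through `area_mode = "per_species"` and is
reported alongside in `budget_report()` for transparency. The budget is
deliberately deterministic and dependency-free; it is a mass bookkeeping
device, not a thermodynamic prediction of coating success.

The comprehensive ratio weights each diameter's ratio by its frequency in
the capsule size distribution. The default size model is a truncated
normal (mean 79.4 nm, sd 11.6 nm, support 45–125 nm, 5 nm bins) with
analytic bin masses, so `weighted_ratio()` is seed-independent. With these
defaults the weighted ratio for the cholesterol-enriched candidates lands
near 1.9–2.0 and rounds to the experimentally adopted 2:1.

```{r budget}
rep3 <- budget_report(load_formulation("ce-mimic-3"))
rep3
```

## Synthetic sPAINT data

`sim_config()` fixes the imaging model: 90 nm camera pixels, 50 ms
exposure, a symmetric Gaussian PSF with $\sigma = 130$ nm
($\approx \lambda/2\mathrm{NA}$ for a 1.49 NA objective at 590 nm), a
grating that sends 41% of emitted photons to the zeroth-order (spatial)
image and 32% to the first order (spectral), an affine dispersion default
of 3.2 nm of wavelength per pixel, and a Gaussian spectral footprint of
45 nm FWHM (Nile Red emission is broad; a Gaussian matches the downstream
fitting model). Kinetic rates and photon budgets are not published for
this dye/buffer combination; the defaults (on-rate 0.06/frame, off-rate
0.85/frame, 2000 photons per bright frame over a 2 count/px background)
are order-of-magnitude choices exposed in the config.

Blinking is a frame-level two-state Markov chain started from its
stationary distribution, so bright stretches are geometric with mean
$1/k_{\mathrm{off}}$ frames — matching the frame-quantized bright/dark
extraction downstream. Binding positions are uniform on each particle's
projected disc; per-event wavelengths are Normal with a particle-specific
mean and intra-particle sd. Rendering integrates the PSF over pixels
(photon-conserving), then adds Poisson shot noise and background unless
`noise = FALSE`. Events whose first-order footprint leaves the chip are
dropped and logged in the truth table.

The generator emulates blinking kinetics, photon statistics, the grating
photon split and dispersion geometry, TEM-like size distributions and
periodic Brownian head-group motion. It does *not* emulate astigmatism,
chromatic aberration, EMCCD gain statistics, sample drift (unless
injected), asymmetric Nile Red lineshapes, or particle mobility during
acquisition — so passing tests validate the estimators under the stated
model, not instrument-specific behavior on real data.

## Localization

Detection smooths each frame with a PSF-matched Gaussian kernel and takes
8-neighborhood local maxima above a robust threshold (median + k·MAD of
the smoothed frame, default k = 5; on a shot-noise-limited camera the
matched filter concentrates the signal so a high k costs no real events
while suppressing false maxima). Candidates are refined by
Levenberg–Marquardt least squares of a pixel-integrated symmetric 2D
Gaussian with offset on a 7×7 px window. Coordinates are continuous nm
with the origin at the top-left pixel corner, x right / y down, frames
1-based; tables round-trip through THUNDERSTORM-style CSV.

The reported per-axis precision is the Thompson-style shot-noise formula
with the least-squares correction factor,
$\sigma_{loc}^2 = (s_a^2/N)\,(16/9 + 8\pi s_a^2 b^2 / (N a^2))$ with
$s_a^2 = s^2 + a^2/12$; on synthetic data the observed error sd matches
it to ~10% and localization errors are zero-mean.

Drift correction renders temporal bins as 2D histograms (30 nm pixels),
cross-correlates all bin pairs by FFT with parabolic sub-pixel refinement,
reduces the redundant pairwise shifts by least squares (first bin pinned
at zero), and interpolates per frame with a natural cubic spline. It
preserves within-frame relative positions exactly and falls back to the
identity (with a warning) when bins are too sparse. The density filter
keeps localizations with ≥ 3 neighbors within 100 nm by default; both
parameter sets are unpublished in the source protocol and are exposed as
arguments.

## Spectral analysis

`calibrate_dispersion()` fits wavelength against spatial-to-spectral pixel
distance with an affine or quadratic polynomial (default order 2, matching
a three-line lamp calibration at 435/586/763 nm, which it interpolates
with zero residuals) and refuses mappings that are not strictly monotone
over the 550–700 nm Nile Red working range.

`extract_spectrum()` sums the spectral image over a 5 px transverse
window, subtracts a per-column background (median over off-spectrum rows,
scaled to the window height), converts pixel distance to wavelength, and
keeps the 550–700 nm support. The 5 px window clips about 8% of the
transverse PSF tails; spectral photon counts are reported as measured
(the QC threshold applies to measured counts). `fit_peak()` fits a 1D
Gaussian; the *peak uncertainty* is the standard error of the fitted
center (the width-based alternative is available via
`qc_filter(use_width = TRUE)`, since published "uncertainty" wording is
ambiguous between the two).

The QC filter is read literally from its published statement: spectra
with uncertainty **> 40 nm** or spectral photons **< 300** are removed,
so records exactly at 40 nm or 300 photons survive. Off-chip spectra and
non-converged fits never pass. The filter never alters wavelengths.

## Particle clustering and kinetics

Clustering is flat-kernel mean shift on (x, y): every point iterates to
the mean of input points within the bandwidth (default 100 nm ≈ expected
particle radius plus localization precision) until the shift falls below
0.1 nm; modes closer than half a bandwidth merge by single linkage;
every localization is assigned to exactly one cluster and labels are
ordered by mode position, making the result invariant to input order.

Event linking treats consecutive-frame runs (gap tolerance 0 by default;
1 tolerates single-frame blinking dropouts) as one binding event of
bright time (run length × exposure); inter-run gaps give dark times.
Cluster summaries report mean ± sd of bright/dark times, peak and
centroid wavelengths and spatial/spectral photons, the event count, a
diameter defined as $2\sqrt{2}$ × RMS member distance from the centroid
(unbiased for a uniform disc), and the aspect ratio
$\sqrt{\lambda_1/\lambda_2}$ of the position covariance. Clusters with ≥ 5
events are `validated` (the source criterion is unpublished; 5 events make
sd estimates meaningful).

## Population comparison

Wavelength histograms use 2 nm bins on 550–700 nm, normalized to unit
integral, at localization or cluster-mean level (peak wavelengths by
default; centroid mode available — the published figures do not specify
which). "Cross-correlation" is operationalized as the zero-lag Pearson
correlation of matched-bin densities: 1 for identical shapes, ≤ 0 for
disjoint supports, invariant to common rescaling; coefficients above 0.9
are flagged as significantly similar. Heterogeneity is reported as the sd
of validated-cluster mean wavelengths (inter-particle) and the median of
within-cluster sds (intra-particle); on synthetic variance-component data
both recover their generator values within 10%.

## Membrane metrics

For trajectories of lipid phosphate head groups with per-time box
dimensions:

- **APL**: $L_x L_y / n_{\rm leaflet}$, sampled every 10 ns, with mean,
  sd and standard error.
- **D$_{HH}$**: distance between the two head-group z-density peaks
  (0.05 nm histogram bins, parabolic peak refinement); unimodal densities
  raise an error rather than return a number.
- **K$_A$**: the default `"literal"` mode evaluates
  $k_B T \,\overline{\mathrm{APL}} / \sigma_{\mathrm{APL}}$ exactly as
  printed in the source description, which carries units of energy;
  because the conventional fluctuation estimator divides by the *variance*
  of the total area, a clearly named `"variance"` mode
  ($k_B T \langle A\rangle / \mathrm{Var}(A)$, in mN/m) is provided as the
  alternative. Faithful-first, correct-optional; both error out on a
  zero-variance series, where the estimator diverges.
- **Lateral D**: ensemble MSD over all time origins after minimum-image
  unwrapping, fitted linearly over 8–72.5% of the trajectory span
  (mirroring a 1.6–14.5 µs window on a 20 µs production run);
  $D = \mathrm{slope}/(2d)$ with $d = 2$. Fits with low R² *or* a
  log-log diffusive exponent far from 1 (band 0.7–1.3) are flagged
  `poor_fit` — an R² threshold alone cannot flag ballistic motion, whose
  quadratic MSD still fits a line with R² ≈ 0.96 over this window.

```{r membrane}
tr <- simulate_trajectory(n_heads = 100, D_true = 5, n_steps = 2000,
                          dt = 10, seed = 1)
membrane_metrics(tr)
```

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty frames localize to empty
tables; empty fit tables cluster to empty lists; single-member clusters
report sd 0 with a flag; a single validated cluster reports inter-particle
sd as not available; identical points form one zero-diameter cluster.
Gaussian fits that do not converge are dropped (detection) or marked
failed (spectra) and counted, never silently imputed.

The validation suite simulates at desk scale chosen to keep the full run
in minutes while leaving comfortable statistical margin: the two-population
imaging check uses 50 particles over 1500 frames on a 192 px field
(~5000 events); trajectory checks use 500 heads × 10⁴ stored steps,
giving the lateral-D estimator a ~3% (1 sd) spread against its 5%
tolerance; variance-component checks use 200 clusters × 100 events. All
stochastic tests run under one fixed seed. Estimates at other seeds vary
within those statistical margins.

## Limitations

The budget model ignores PEG-corona geometry, lipid asymmetry between
leaflets and any gap between silica and the inner leaflet (the source
protocol does not state one). The imaging model omits instrument
aberrations, and spectral extraction assumes one emitter per transverse
band — simultaneous same-row emitters are not unmixed. The diffusivity is
reported without finite-size corrections, matching the practice it
reimplements; it is a comparative mobility measure, not an absolute one.
Bulk-instrument quantities (DLS sizes, zeta potentials, flow-cytometry
percentages) are out of scope: they require instrument data that cannot
be regenerated computationally.
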