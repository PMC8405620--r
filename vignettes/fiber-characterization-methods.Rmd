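---
title: "Methods: quantitative characterization of protein polymer fibers"
author: "fiberlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative characterization of protein polymer fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberlab)
```

fiberlab implements the complete quantitative analysis chain used to
characterize semi-crystalline protein fibers — such as fibers wet-spun
from ultra-high-molecular-weight titin produced by in-vivo protein
polymerization — from four instrument modalities: analytical
size-exclusion chromatography (SEC), FTIR and polarized Raman
spectroscopy, wide-angle X-ray fiber diffraction (WAXD), and uniaxial
tensile/cyclic mechanical testing. Every modality has a seeded forward
model with attached ground truth, so each estimator is validated by
parameter recovery rather than by comparison to opaque reference output.
This vignette documents the models, the tunable parameters, the numerical
choices, and the known limits of each stage.

## Molecular weights from SEC

**Model.** In-vivo ligation of identical protein subunits by a split
intein is, statistically, a step-growth polymerization: after an extent of
reaction $p$, the number fraction of $i$-mers follows the most-probable
distribution $n_i = (1-p)\,p^{\,i-1}$, with closed-form averages
$M_n = M_0/(1-p)$ and $M_w = M_0(1+p)/(1-p)$, so the dispersity is $1+p$.
`gen_flory_distribution()` truncates the distribution at a degree chosen
so that less than `mass_tol` (default $10^{-8}$) of the mass is discarded;
at that tolerance the truncated sums agree with the closed forms to better
than $10^{-6}$ relative, which is what the test suite asserts. A 43 kDa
monomer reaches $M_w = 2.4$ MDa at $p \approx 0.9648$.

**Calibration.** SEC calibration fits $M = a\,e^{b\,V_r/V_0}$ by least
squares on $\log M$ ($V_0$ = void volume from an excluded tracer). The
log-linear fit is exact for exact data, interpolates two standards
exactly, and is the natural error model for masses with multiplicative
noise. Masses beyond the standards' range are extrapolated by the fitted
exponential and counted in `n_extrapolated`, since the integration window
deliberately extends to 5 MDa, above typical standards.

**Averages.** `compute_mn_mw()` evaluates, over chromatogram grid points
whose calibrated mass lies within the 1 kDa–5 MDa window,

$$M_n = \frac{\sum_i M_i N_i}{\sum_i N_i}, \qquad
  M_w = \frac{\sum_i N_i M_i^2}{\sum_i N_i M_i},$$

with $N_i$ the measured A280 absorbance (negative values clamped to
zero). This is deliberately the instrument-level definition: A280 weighs
*mass*, not number, so the estimator's "$M_n$" is in truth a
mass-weighted average. `species_mw_oracle()` reports both the
signal-weighted values the estimator should reproduce (the fair oracle,
windowed identically) and the true number-weighted averages, making the
inherent bias visible instead of hiding it: at the 2.4 MDa operating
point the windowed chromatogram $M_w$ is $\approx 2.75$ MDa while the
distribution's true $M_w$ is 2.4 MDa. About 20 % of the mass of that
distribution lies above the 5 MDa window limit, which is why the window
matters and is always recorded in the result.

## FTIR amide-I deconvolution

The amide-I band (1600–1700 cm$^{-1}$) is modeled as eleven Lorentzians
with *fixed* centers at 1610, 1618.5, 1624.5, 1632.5, 1642, 1651, 1659,
1666.5, 1678, 1690.5 and 1700 cm$^{-1}$. The center-to-class map (see
`amide_assignment()`) follows standard amide-I correlation ranges:
β-sheet for the low- (1610–1632.5) and high-wavenumber (1690.5, 1700)
components, random coil at 1642, α-helix at 1651/1659, β-turn at
1666.5/1678. The map is data, not code — any named `center -> class`
vector can be substituted.

**Fitting.** With centers fixed, the model is linear in the component
areas and nonlinear only in the widths. `deconvolve_amide_I()` exploits
this by variable projection: box-constrained quasi-Newton iteration over
the eleven FWHMs (bounded to the physical range 5–40 cm$^{-1}$), with the
non-negative areas solved exactly by NNLS at every iterate; three width
starts (20, 12, 30 cm$^{-1}$) guard against local minima. On noiseless
synthetic bands the fit is exact to the optimizer tolerance (relative
residual below $10^{-6}$). Fractions are *analytic* Lorentzian areas
summed per class; integrating numerically over only 1600–1700 instead
would change the class percentages by a few percent because of the
truncated wings — the analytic convention is used consistently on both
the generator and analysis sides.

**Baseline.** `convex_hull_baseline()` subtracts the lower convex hull of
the spectrum (the rubber band), evaluated by linear interpolation between
hull vertices. The operation is idempotent and the corrected signal is
non-negative to round-off. Two properties matter in practice: the hull
removes any convex baseline exactly, and it inevitably clips some of the
Lorentzian wings under the band. Applying the band over the full recorded
range (1415–1780 cm$^{-1}$) rather than a narrow window around amide-I
minimizes the clipping; with the default generator (28 % β-sheet truth)
the recovered β fraction is 26.8 % full-range versus 25.4 % with a
narrow-window hull. Both are inside the 3-percentage-point recovery
tolerance the tests enforce, and the residual deficit is a property of
rubber-band baselines generally, not of this implementation.

## Polarized Raman orientation ratio

Spectra acquired with the fiber perpendicular ($Y$) and parallel ($X$) to
the laser polarization are each normalized to the maximum intensity
within 1450 ± 10 cm$^{-1}$ (CH$_2$ bending, conformation-insensitive);
the orientation ratio is $I = Y/X$ evaluated on the amide-I peak located
as the maximum within 1670 ± 10 cm$^{-1}$ (same window for both spectra).
Peak *height* after normalization is used, not area. The ratio is exactly
invariant to any positive rescaling of either spectrum. The generator
builds both spectra from Gaussian bands, whose negligible cross-band
tails let the constructed ratio be recovered to well under 1 %.

## Wide-angle fiber diffraction

**Geometry.** For a flat detector at distance $L$ with pixel radius $r$
from the beam center: $2\theta = \arctan(r/L)$,
$q = 4\pi\sin\theta/\lambda$, and the azimuth $\chi$ is measured from the
equator ($\chi = 0$ perpendicular to the configured meridian/fiber axis).
Defaults are $\lambda = 0.886$ Å, $L = 200$ mm, 172 µm pixels, beam
center at the image center, meridian vertical — all overridable, and all
carried in a plain-text sidecar next to the image file.

**Profiles.** Radial profiles average background-subtracted counts into
$q$ bins (default 0.005 Å$^{-1}$) over an equatorial or meridional wedge
(default full width 25°, the middle of the conventional 20–30° range),
combining both Friedel-related wedges. Azimuthal profiles average counts
into $\chi$ bins (default 2°) over a radial band, by default the fitted
reflection's center ± FWHM/4 — a compromise between capturing the
reflection and excluding the neighboring amorphous halo. A recorded air
background is subtracted pixel-wise when available; otherwise a constant
estimated from the image corners is used, and any negative net counts are
clamped and flagged.

**Radial deconvolution.** The equatorial profile is fit with four
Gaussians — (200) and (120) crystalline reflections plus two amorphous
halos — by bounded nonlinear least squares (the meridional model adds a
free-center (002)). Crystalline centers are initialized at $2\pi/d$ for
$d = 1.08$ and 0.46 nm (inter-sheet and inter-strand spacings of a
β-sheet lattice in an orthorhombic indexing) and bounded within ±15 %;
crystalline FWHMs are bounded in [0.05, 0.65] Å$^{-1}$ and amorphous
FWHMs in [0.6, 2.5] Å$^{-1}$, so a crystalline/amorphous width swap is
excluded by construction; a fit that still ends inverted is refit from a
perturbed start and rejected if the inversion persists.

**Derived metrics.**

* Crystallinity: integrated *area* ratio
  $(I_{200} + I_{120}) / (I_{200} + I_{120} + I_{am1} + I_{am2})$ of the
  equatorial components. Area (not height) is the standard convention for
  relative intensity here.
* d-spacing: $d = 2\pi/\mathrm{PC}$, exactly.
* Scherrer size: $\theta = \arcsin(\lambda\,\mathrm{PC}/4\pi)$,
  $\beta = 2\arcsin(\lambda\,\mathrm{FWHM}/4\pi)$,
  $D = K\lambda/(\beta\cos\theta)$ with $K = 0.9$. A vanishing FWHM is
  reported as an error (unresolvable, effectively infinite crystallite).
* Herman's orientation: from the azimuthal crystalline FWHMs of the two
  equatorial reflections,
  $\langle\cos^2\varphi\rangle = 1 - 0.8\sin^2(0.4\,\mathrm{FWHM}_{200})
  - 1.2\sin^2(0.4\,\mathrm{FWHM}_{120})$ and
  $f = (3\langle\cos^2\varphi\rangle - 1)/2$. The $0.4\times$FWHM
  arguments are evaluated **in degrees**: the empirical constants of this
  relation are tied to degree-valued widths, and a radian reading drives
  $\langle\cos^2\varphi\rangle$ negative for ordinary widths. A result
  outside $[-0.5, 1]$ raises an error as a unit-misuse guard rather than
  being silently clipped.

**Azimuthal deconvolution.** Each azimuthal profile is fit with an
equator-centered narrow (crystalline) Gaussian lobe pair plus a broad
(amorphous) pair and a constant, with optional symmetric satellites for
residual (201) intensity. Near isotropy the model is weakly identified:
at $f = 0.02$ the crystalline width ($\approx 87°$) abuts the narrow/broad
boundary (89°/90°) and trades off against the broad-plus-constant terms,
so only qualitative recovery ($|f|$ small) is possible there. At the
oriented operating point ($f = 0.76$, width $\approx 41°$) recovery is
well-conditioned and the tests require $|f_\mathrm{rec} - f| < 0.05$.

**Forward model.** `gen_waxd_image()` Poisson-samples the analytic
surface — radial Gaussians whose widths come from inverting the Scherrer
chain for the requested crystallite sizes, multiplied (for crystalline
components) by an azimuthal Gaussian pair whose width inverts Herman's
relation for the requested $f$ (equal widths assumed for both
reflections), plus isotropic amorphous halos and a flat air background
that is also delivered as a separately sampled background exposure.
Amplitudes are scaled so that the *measured* crystallinity at the
reference sector width equals the requested value. Because generator and
fit share the Gaussian line shape, round-trip recovery is a well-posed
check of the reduction chain, not of line-shape physics. The default
truth (d 1.08/0.46 nm, D 1.08/2.91 nm, 18 % crystallinity, $f = 0.76$,
halos at 0.80 and 1.60 Å$^{-1}$ with 0.9 Å$^{-1}$ widths, area ratio
10:8:40:42) describes a moderately crystalline, well-oriented β-sheet
fiber.

## Tensile and cyclic mechanics

Engineering stress is force over the initial cross-section
$A = \pi(d/2)^2$ from the averaged diameter measurements; engineering
strain is crosshead displacement over the gauge length (default 5 mm).
Because MPa $\times$ strain $=$ MJ/m$^3$, all energy densities are plain
areas under stress-strain curves; the tests assert this identity on
closed-form curves.

* **Modulus**: least-squares slope over the elastic window, default
  0.2–1.5 % strain — inside the linear-elastic regime that extends to
  about 1.6 % strain in such fibers, while skipping the earliest
  grip-settling points. The window is configurable and recorded.
* **Breaking strain**: the first point after the stress peak where stress
  falls below 10 % of the peak (the 90 %-drop rule). Absent such a drop
  the result is censored and flagged.
* **Toughness**: trapezoidal $\int\sigma\,d\varepsilon$ from zero to the
  detected break — including the post-peak region up to the 90 %-drop
  point, with negative transients clamped to zero. Integrating only to
  the peak is a configurable alternative (pass the truncated curve).
* **Damping**: each cycle is split at the maximum-strain sample (first
  occurrence on ties); damping capacity is
  $100\,(A_\mathrm{load} - A_\mathrm{unload})/A_\mathrm{load}$ and
  damping energy $A_\mathrm{load} - A_\mathrm{unload}$. An unload branch
  above the load branch produces a flagged, out-of-range capacity with a
  warning instead of silent clipping.

**Forward model.** Loading is linear elastic to $\varepsilon_y$ then
power-law hardening $\sigma_y + h(\varepsilon-\varepsilon_y)^m$;
unloading is linear with modulus $E_u$, leaving a permanent set that an
optional `recovery_fraction` rescales between cycles — a phenomenological
stand-in for humidity-driven recovery, with no mechanistic claim. The
defaults ($E = 4.2$ GPa, elastic to 1.6 %, break at 47 % with 378 MPa,
$m = 0.5$) describe the target fiber class; toughness then evaluates to
$\approx 125$ MJ/m$^3$. $E_u$ must be $\ge E$ (otherwise the elastic
unload would sit above the load path); the default 5.12 GPa makes the
purely elastic cycle dissipate $1 - E/E_u \approx 18\,\%$ — the observed
low-strain damping capacity of such fibers — and yields $\approx 85\,\%$
capacity and $\approx 57$ MJ/m$^3$ at 30 % strain. A single constant
unload modulus cannot simultaneously match both the low-strain and the
high-strain damping of a real fiber exactly; this one-parameter
compromise favors the low-strain (resilient) regime where the linear
model is most meaningful.

## Reproducibility and problem sizes

Every generator is a pure function of its parameters and seed (the global
RNG state is saved and restored around each draw), so identical
configurations give bit-identical datasets and reports. The test suite
runs its diffraction round trips at 512–768 pixel images and the
acceptance script at 1024 — sizes at which the recovered quantities are
comfortably inside their tolerances while a full run stays around a
minute; all other stages are sub-second. `roundtrip_check()` packages the
truth-versus-recovered comparison (2 % on molecular weights, 3 points on
structure fractions, 1 % on the Raman ratio, 1 %/5 %/2 points/0.05 on
d/D/crystallinity/f, 2 % on tensile metrics, 0.5 % on damping) as a
single table.

## What passing tests do and do not show

The synthetic generators share their line shapes and noise models with
the fitting stages. Passing round trips therefore demonstrate that the
reduction chains are implemented correctly and are numerically stable at
realistic signal levels — they do not validate the physical
approximations themselves (Gaussian peak shapes, the empirical Herman
relation's constants, the linear unload path, ideal step-growth
statistics) against real instruments. Known limitations: no detector
point-spread, polarization or absorption corrections; no multi-detector
(light-scattering) molecular weights; no Rietveld-style full-pattern
refinement; no viscoelastic rate dependence or compliance correction; and
the humid-air recovery is a single rescaling parameter, not a mechanism.
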