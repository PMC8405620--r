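# fiberlab

Quantitative characterization of semi-crystalline protein polymer fibers —
the complete analysis chain used to study fibers wet-spun from
ultra-high-molecular-weight (megadalton) proteins produced by in-vivo
polymerization, such as titin built from repeating immunoglobulin (Ig)
domains.

fiberlab covers five instrument modalities end to end, and every one of
them ships with a seeded synthetic-data generator carrying exact ground
truth, so each estimator is validated by parameter recovery:

| Stage | Input | What is computed |
|---|---|---|
| SEC | chromatogram + standards | exponential calibration `M = a·exp(b·Vr/V0)`; `Mn = ΣMiNi/ΣNi`, `Mw = ΣNiMi²/ΣNiMi` over a 1 kDa–5 MDa window |
| FTIR | amide-I band | rubber-band baseline; 11 fixed-center Lorentzians (1610–1700 cm⁻¹); secondary-structure fractions from analytic areas |
| Raman | polarized pair | `I = Y/X` of amide-I (1670 cm⁻¹) heights, each normalized to the 1450 cm⁻¹ band |
| WAXD | 2D diffraction image | sector/azimuthal integration; Gaussian deconvolution; crystallinity; `d = 2π/PC`; Scherrer `D = Kλ/(β cos θ)`; Herman's `f = (3⟨cos²φ⟩−1)/2` |
| Mechanics | force–displacement traces | modulus, ultimate strength, breaking strain (90 %-drop rule), toughness; cyclic damping capacity and energy |

The synthetic side models a step-growth (Flory most-probable) chain-length
distribution read out through SEC band broadening, amide-I bands as
Lorentzian mixtures, oriented semi-crystalline fiber diffraction with
Poisson counting statistics, and elastic–plastic stress–strain loops with
permanent set and humidity-style recovery.

## Worked example

Simulate a megadalton polymer, measure it by SEC, analyze a synthetic
fiber diffraction pattern, and run a pull test:

```r
library(fiberlab)

## step-growth polymer reaching Mw = 2.4 MDa from a 43 kDa monomer
d <- gen_flory_distribution(0.9648, 43)
d
#> Flory distribution: p = 0.9648, M0 = 43 kDa, i_max = 601
#>   Mn = 1222 kDa, Mw = 2400 kDa, dispersity = 1.9648

standards <- data.frame(mass_kDa = c(2000, 670, 158, 44, 17, 1.35),
                        Vr_mL    = c(9, 11, 13.5, 15.5, 17, 19.5))
calib <- fit_calibration(standards, void_volume = 8)
chrom <- gen_sec_chromatogram(d, calib, broadening_sd = 0.02, dv = 0.005)
compute_mn_mw(chrom, calib)
#> Mn = 2050 kDa, Mw = 2745 kDa, dispersity = 1.339 (1453 points)

## diffraction: 18 % crystalline, well-oriented beta-sheet fiber
img <- gen_waxd_image(waxd_truth(seed = 7), detector_geometry(),
                      dim = c(768L, 768L))
waxd_analyze(img)
#> WAXD analysis:
#>   crystallinity  18.8 %
#>   d200 = 1.080 nm, d120 = 0.460 nm
#>   Da   = 1.06 nm, Db   = 2.91 nm (Scherrer, K = 0.9)
#>   f_crystal = 0.761 (azimuthal FWHM 41.0 / 41.1 deg)

## mechanics: stiff, extensible fiber with hysteretic damping
p <- mech_params()
tensile_summary(to_stress_strain(gen_tensile_trace(p)))
#> tensile: E = 4.2 GPa, UTS = 378 MPa, breaking strain = 0.471,
#>          toughness = 125.2 MJ/m3
for (tr in gen_cyclic_traces(p, c(0.016, 0.30)))
  print(cycle_damping(to_stress_strain(tr)))
#> cycle to 0.016 strain: DC = 18.0 %, DE = 0.0966 MJ/m3, set = 0.00287
#> cycle to 0.3 strain: DC = 85.5 %, DE = 55.8 MJ/m3, set = 0.239
```

Reading the numbers: the SEC estimate (2745 kDa) exceeds the
distribution's true `Mw` (2400 kDa) because A280 absorbance weighs mass
rather than number — `species_mw_oracle()` quantifies exactly this bias.
The diffraction analysis recovers the generating truth (d-spacings
1.08/0.46 nm, crystallite sizes 1.08/2.91 nm, crystallinity 18 %,
orientation 0.76) within its stated tolerances, and the equality of the
a-axis crystallite size with its d-spacing is the signature of crystals
only two β-sheets thick — one folded Ig-like domain. The cyclic loops show
the characteristic transition from a resilient regime (18 % damping
capacity at 1.6 % strain) to a strongly dissipative one (~86 % at 30 %
strain).

`roundtrip_check()` runs every modality's simulate→analyze loop and
tabulates truth versus recovered values at the package tolerances;
`run_pipeline(run_config(), out_dir = "out")` writes a consolidated JSON
report with provenance.

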