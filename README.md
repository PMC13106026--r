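# decbct

Dual-energy cone-beam CT (DE-CBCT) simulation, virtual monoenergetic image
(VMI) synthesis, and air-kerma-based imaging-dose estimation — a desk-scale R
test bench for the physics and protocol-design questions of image-guided
radiation therapy.

**Who it is for.** Medical physicists and imaging-algorithm developers who
want to study dual-energy CBCT protocol trade-offs (dose split, framerate,
VMI energy) on a fully synthetic, reproducible digital phantom, without
scanner access.

## What it computes

A sequential DE-CBCT scan pair (80 and 140 kVp) of a digital Catphan-style
sensitometry phantom is simulated with a polyenergetic fan-beam forward model
and Poisson noise. Each ray's pair of log attenuations is decomposed into
equivalent thicknesses of an aluminum/PMMA basis by damped Newton inversion
of the exact spectral forward model

    L_s = -ln [ Σ_E S_s(E) w(E) exp(-μ_Al(E) t_Al - μ_PMMA(E) t_PMMA)
                / Σ_E S_s(E) w(E) ],   s ∈ {80, 140},

and the two thickness sinograms are reconstructed once by fan-beam filtered
backprojection into basis-weight images w_Al, w_PMMA. Because FBP is linear,
a VMI at *any* energy E is the voxel-wise combination

    μ_E(x) = μ_Al(E) w_Al(x) + μ_PMMA(E) w_PMMA(x),
    HU_E(x) = 1000 (μ_E(x) - μ_w(E)) / μ_w(E),

identical to reconstructing each energy from scratch but two orders of
magnitude cheaper for a 40–150 keV sweep: two reconstructions instead of one
per keV. On top of that sit the standard image-quality metrics — per-insert
CNR `(HU_i - HU_bkg)/√((σ_i² + σ_bkg²)/2)`, rCNR against a single-energy
reference scan, HU accuracy against theoretical insert values, HU uniformity
(center minus periphery) — and a CNR-optimal energy search.

The dosimetry module implements the K_air surrogate framework: linear
regressions of free-in-air kerma against cumulative mAs per tube potential
(and of CBDI/CBDIw against K_air), chamber-charge conversion, the 1/3 + 2/3
weighted dose index, the 2.34 body-to-head phantom conversion, and combined
dual-energy dose estimates relative to the clinical reference protocol.

## Worked example

```r
library(decbct)
res <- runPipeline(runConfig(run = 2, seed = 1))   # matched-dose DE pair, 15 /s
print(res)
#> <pipeline result: run 2>  optimal energy 61 keV
#> <metrics report @ 60 keV>
#>   mean rCNR        1.17 +/- 0.28
#>   HU accuracy      2.4 +/- 4.7 HU (max |dHU| 13.0)
#>   HU uniformity    -0.2 HU (reference -20.5 HU)
#> <dose estimate>  80 kVp 67.5 + 140 kVp 67.8 = 135.3 mGy (100% of reference)  [extrapolated]
```

Reading the numbers: run 2 splits the reference protocol's air kerma across
the two tube potentials (relative dose 100%). Its 60 keV VMI has higher
insert CNR than the single-energy reference (mean rCNR 1.17), every insert
lands within 13 HU of its theoretical value, and the beam-hardening cupping
of the reference (−20.5 HU center-to-periphery) collapses to −0.2 HU in the
VMI. The CNR-optimal energy found by the 40–150 keV sweep is 61 keV for this
noise realization. The `[extrapolated]` flag records that 4046 mAs lies above
the fitted calibration range — estimates are flagged, never refused.

A thin CLI wraps the same functions
(`Rscript inst/cli/decbct.R run-all --run 2 --seed 1 --out out/`), with
subcommands for simulation, decomposition, sweeps, dose fits and fixture
generation.

## Layout

- `R/` — materials & spectra, phantom, acquisition, decomposition,
  reconstruction, VMI synthesis, QA metrics, dosimetry, pipeline/IO
- `inst/extdata/` — embedded attenuation tables, material compositions,
  default spectra, kerma validation table (plain CSV)
- `inst/cli/decbct.R` — command-line front end
- `vignettes/dual-energy-cbct.Rmd` — model assumptions, parameter rationale,
  numerical choices and limitations
- `tests/testthat/` — unit, property and end-to-end acceptance suites
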