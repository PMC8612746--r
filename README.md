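# fdhddot

Simulation study of how the source **modulation frequency** (continuous
wave to 1000 MHz) affects image quality in **frequency-domain high-density
diffuse optical tomography (FD-HD-DOT)** of the human head.

HD-DOT reconstructs maps of hemoglobin changes from many overlapping
near-infrared source-detector measurements on the scalp. A continuous-wave
(CW) system measures only intensity attenuation; a frequency-domain system
modulates its sources sinusoidally and also measures the phase delay of the
detected photon-density wave. Phase carries relatively more deep-tissue
information, but phase noise grows with modulation frequency — so image
quality as a function of frequency is a trade-off, and this package
quantifies it.

## The model in brief

* **Forward problem.** Frequency-domain photon diffusion
  `(-div(D grad) + mua - i*omega/v) Phi = Q`, `D = 1/[3(mua + musp)]`,
  discretized by flux balance on a voxelized five-layer head slab (scalp /
  skull / CSF / gray / white, literature optics at 690 and 850 nm) with
  Robin boundaries and a fast spectral solver for the layered geometry,
  validated against the closed-form kernel
  `exp(-k r)/(4 pi D r)`, `k = sqrt((mua - i omega/v)/D)`.
* **Sensitivity.** Rytov linearization: channel data split into
  log-intensity and phase rows; adjoint-form Jacobian
  `-h^3 Phi_s(r_j) Phi_d(r_j) / Phi_s(r_d)` per voxel, pinned to 1% by a
  brute-force perturbation oracle.
* **Inversion.** Tikhonov-regularized pseudo-inverse with spatially
  variant voxel scaling,
  `A# = L^-1 (Ahat^T Ahat + lambda1 I)^-1 Ahat^T`, `Ahat = A L^-1`,
  evaluated in measurement space; `lambda1 = 0.01`, `lambda2 = 0.1`
  (relative), per-wavelength inversion and spectral recombination to HbO2.
* **Noise.** Empirical model
  `N(r, f) = (a e^{br} + c e^{dr}) * 10^{g(f - 140)}` per wavelength and
  datum type (percent / degrees), coupled intensity-phase draws; the
  injected amplitude carries one documented global calibration (see the
  methods vignette).
* **Metrics.** Point-spread functions from single-voxel +3.8/-1.8 uM
  HbO2/HbR perturbations at ~1400 seed voxels: localization error (LE),
  FWHM, FVHM, depth-resolved success rate with the 8 mm cutoff, the 50%
  success depth (`sr50`, the reliable-imaging boundary), and the brain
  volume successfully imaged relative to CW (FBT ratio), plus Wilcoxon
  signed-rank FD-vs-CW comparisons.

## Worked example

```r
library(fdhddot)

ph <- build_layered_slab()
print(ph)
#> Layered slab phantom: 60 x 60 x 30 voxels @ 2 mm
#>   extent: 120 x 120 x 60 mm
#>   z-layers per tissue: scalp=2, skull=3, CSF=1, gray=2, white=22

arr <- place_checkerboard_array(13, 7, 7, ph)
print(arr)
#> Checkerboard optode array: 25 sources, 24 detectors, pitch 13 mm
table(enumerate_channels(arr, 4)$nn)
#>   1   2   3   4
#>  84 120  56  80

g <- greens_homogeneous(get_tissue_property("gray", 850), r = 29, frequency = 300)
sprintf("|phi| = %.3e, phase lag = %.1f deg", Mod(g), Arg(g) * 180 / pi)
#> "|phi| = 1.511e-05, phase lag = 74.2 deg"

# a reduced sweep: 5x5 array, three frequencies, strong-dynamic-range set
cfg <- sweep_config(frequencies = c(0, 300, 800),
                    phantom = list(lateral_extent = 90, depth_extent = 40),
                    array = list(n_rows = 5, n_cols = 5), nn_sets = 4)
sw <- run_sweep(cfg, quiet = TRUE)
sw$sr50
#>  frequency nn noise sr50_depth censored
#>          0  4   off   18.75000    FALSE
#>          0  4    on   16.50000    FALSE
#>        300  4   off   20.91667    FALSE
#>        300  4    on   15.83333    FALSE
#>        800  4   off   22.91667    FALSE
#>        800  4    on   14.36667    FALSE
```

`sr50_depth` is the depth (mm below the surface) to which at least half of
the simulated point activations are recovered within 8 mm localization
error. In this reduced example the noise-free boundary deepens with
modulation frequency (18.8 -> 22.9 mm from CW to 800 MHz) while noise pulls
it back down at high frequency (16.5 -> 14.4 mm) — the trade-off the full
study maps over 11 frequencies and both measurement sets.

## The analysis workflow

The numbered drivers under `analysis/` reproduce the study and write all
tables under `results/`:

| script | what it does |
|---|---|
| `01_phantom_geometry.R` | phantom, optode array, channel sets, ROI tables |
| `02_forward_validation.R` | solver vs closed-form Green's functions, reciprocity |
| `03_noise_model.R` | noise curves and the matched-filter SNR analysis |
| `04_frequency_sweep.R` | the full 11-frequency sweep and all summary tables |
| `05_noise_scale_sensitivity.R` | how the noise-added optimum moves with the injection scale |

Run them from the repository root, e.g.
`Rscript analysis/04_frequency_sweep.R 1` (the argument is the master
seed).

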