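# doctk — dynamic OCT contrasts and speckle phantom simulation

Label-free **dynamic optical coherence tomography (DOCT)** reveals tissue
function by statistics of temporal speckle fluctuation: metabolically
active structures decorrelate the complex OCT field, static tissue does
not. In kidney imaging this turns renal tubules — invisible in plain
scattering OCT — into bright convoluted pipe-like structures, and
distinguishes functional from obstruction-damaged tissue without any
contrast agent.

`doctk` is an R implementation of that analysis for people who need a
*testable* pipeline: it simulates 4D complex OCT speckle data of
kidney-like phantoms with known per-voxel ground truth, and runs the full
processing chain on them.

## The two contrasts

**LIV** (logarithmic intensity variance), sensitive to second-scale
dynamics — the population variance of the dB-scale intensity over N
repeated frames at one location:

    LIV(x,z) = (1/N) Σᵢ [ I_dB(x,z,tᵢ) − ⟨I_dB(x,z)⟩ ]² ,

computed from 16 frames 409.6 ms apart (6.14 s window), no noise
correction.

**Fast-DOCT**, sensitive to millisecond-scale dynamics — one minus the
magnitude of the noise-corrected complex correlation of consecutive
frames 12.8 ms apart (39 ms window), spatially kernel-averaged, after
bulk phase-offset correction:

    ρ = |Σ_K Σ_pairs Aᵢ* Aᵢ₊₁| / √( max(Σ|Aᵢ|² − E_n, δ) · max(Σ|Aᵢ₊₁|² − E_n, δ) )
    Fast-DOCT = clip(1 − ρ, 0, 1),   E_n = |K| · n_pairs · σ_n²

Low-SNR pixels whose corrected energy falls below the guard are flagged
invalid instead of masquerading as decorrelation.

The package also provides the two scan protocols that drive frame timing
(block-repeating raster for LIV: 2048 frames / 128 locations / 26.2 s;
fast raster: 512 frames / 6.55 s), tissue-surface segmentation,
surface-following slab average projections (default 100 px = 724 µm),
pseudo-color HSV compositing (hue = LIV red→green, value = dB intensity),
and metrics: FWHM structure diameters, region contrast ratios, phenotype
reports, and correlation-time (τ) map recovery.

## Worked example

```r
library(doctk)

liv_protocol()
#> raster_protocol (block_repeat): 4 block(s) x 32 location(s) x 16 repeat(s)
#>   repeat interval 0.4096 s, 512 A-lines @ 50000 Hz, FOV 3 mm
#>   frames/volume 2048, window 6.144 s, total 26.21 s

res <- run_pipeline(run_config(preset = "normal", seed = 7))
res$volumes$liv
#> oct_volume [LIV]: 64 x 128 x 48 (z,x,y), pitch 7.24/5.86/5.86 um
res$surface
#> surface_map: 128 x 48 columns, 100.0% valid, height 7..15
res$phenotype[, c("preset", "tubule_contrast_ratio", "tubule_visibility_liv",
                  "fdoct_wall_mean", "fdoct_tubule_visible")]
#>   preset tubule_contrast_ratio tubule_visibility_liv fdoct_wall_mean fdoct_tubule_visible
#> 1 normal              4.682535       clearly visible       0.1870878                FALSE
```

Read: the tubule walls are 4.7× brighter than parenchyma in the LIV slab
projection ("clearly visible" pipe-like structures), while their mean
Fast-DOCT decorrelation of 0.19 sits below the 0.25 visibility threshold
— with the default 50 ms wall correlation time, tubules are a
LIV-only finding. Re-running with
`phantom = list(wall_tau_scale = 0.4)` (≈ 20 ms walls) flips
`fdoct_tubule_visible` to `TRUE`; `preset = "obstructed_2w"` removes the
tubules and reports a superficial shell ratio ≥ 3 instead. Passing
`out_dir =` writes TIFF volumes, PNG composites, the YAML config, a
phenotype JSON and an MD5 manifest; reruns with the same seed are
bit-identical.

A thin CLI over the same functions ships in `inst/cli/doctk.R`:

```sh
Rscript inst/cli/doctk.R all --preset normal --seed 7 --out results/
```

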