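# dualcest

Dual-power deep-learning denoising of low-power CEST MRI Z-spectra.

## The problem

Low-power (0.25 µT) CEST Z-spectra resolve individual exchange pools —
amide (APT, +3.5 ppm), phosphocreatine (+2.6 ppm), guanidine (+2 ppm),
NOE(−1.6), NOE(−3.5) — far better than high-power spectra, because weak
saturation narrows the peaks and suppresses the direct-saturation and
semisolid-MT backgrounds. The price is a severe loss of contrast-to-noise.
`dualcest` denoises low-power Z-spectra by exploiting a *second* spectrum
acquired at higher power (1 µT) in the same session:

1. **Feature preparation** — within windows of 3 and 5 consecutive offsets
   (plain and half-shifted tilings, averaged), each high-power (HP) signal
   has its window mean replaced by the low-power (LP) window mean:
   `out = hp − mean(hp|window) + mean(lp|window)`. The transformed HP
   spectrum follows the LP trajectory while keeping the steeper, more
   noise-robust HP local slopes.
2. **Autoencoder** — a small 1-D convolutional autoencoder (conv/ELU/
   max-pool encoder, transposed-conv decoder, linear output) maps the
   (LP, transformed-HP) pair to a denoised LP spectrum. It is trained on
   Bloch-McConnell-simulated four-pool spectra spanning slow-to-fast
   exchange, with Gaussian noise (2.5–3% of S0, equal for both powers),
   B0 shifts up to ±0.4 ppm and B1 scalings 0.8–1.2.
3. **Fine-tuning** — an iterative context-learning loop nudges the
   prediction toward a PCA(8) reconstruction of the acquired LP stack
   (scaling the difference spectrum by 1.01 or 0.99, at most five cycles)
   to bound prediction bias without collapsing onto the PCA result.
4. **Quantification** — a two-pool (water + MT) Lorentzian reference is
   fitted on CEST-free offset ranges (±10…±6.25 and ±0.5 ppm) and the
   apparent exchange-dependent relaxation
   `AREX(Δω) = (1/S_lab − 1/S_ref) · R1w` (s⁻¹) yields per-pool peak maps.

Everything is exercised on synthetic data: an N-pool Bloch-McConnell
simulator (compiled matrix-exponential core, verified against an
independent stiff-ODE integration to 1e-6) and a 23×23 brain-mimicking
digital phantom with noise-free ground truth.

## Worked example

```r
library(dualcest)

sched <- build_offset_schedule()          # 89 offsets, ±10 ppm, control 500 ppm

# an amide + MT system at 4.7 T
sys <- pool_system(
  water   = pool(0, 1, 0, T1_s = 1.7, T2_s = 0.07),
  solutes = list(pool(3.5, 0.002, 50, 1.5, 0.002)),
  mt      = pool(-2.5, 0.07, 30, 1.3, 1e-5)
)
z_clean <- simulate_zspectrum(sys, power_uT = 0.25)         # ground truth

# the acquisition is miscalibrated: B0 off by +0.2 ppm, B1 10% low
acq  <- sequence_params(B0_shift_ppm = 0.2, B1_scale = 0.9)
z_lp <- simulate_zspectrum(sys, 0.25, sched, acq)
z_hp <- simulate_zspectrum(sys, 1, sched, acq)

# dual-power training set and a small denoiser (~2 min on one CPU)
pairs <- training_grid(60, seed = 1) |>
  generate_training_pairs(seed = 2) |>
  prepare_features()
model <- build_denoiser(seed = 3) |>
  train_denoiser(pairs, train_config(learning_rate = 3e-3, epochs = 60,
                                     batch_size = 64, seed = 4))

# denoise one noisy realization of the miscalibrated acquisition
set.seed(5)
lp_noisy <- z_lp$values + rnorm(89, sd = 0.025)
hp_noisy <- z_hp$values + rnorm(89, sd = 0.025)
den <- predict(model, lp_noisy, build_transformed_hp(lp_noisy, hp_noisy))
round(c(noisy = mse(lp_noisy, z_clean$values),
        denoised = mse(den, z_clean$values)), 5)
#>    noisy denoised
#>  0.01014  0.00092

# quantify: LD reference fit + AREX peak amplitudes of the clean spectrum
ld <- ld_analysis(z_clean, R1w_per_s = sys$R1w_per_s)
tidy(ld)
#> # A tibble: 5 × 2
#>   pool      arex_peak_per_s
#>   <chr>               <dbl>
#> 1 apt             0.0121
#> 2 pcr             0.00348
#> 3 guanidine       0.00146
#> 4 noe_m1.6       -0.000314
#> 5 noe_m3.5        0.0000356
```

The denoised spectrum is ~11× closer (in MSE) to the noise-free,
calibration-true spectrum than the raw acquisition — the model removes
noise *and* most of the B0/B1 miscalibration. The LD/AREX analysis of the
clean spectrum shows the amide peak (0.012 s⁻¹) standing an order of
magnitude above the residual background in the other pool windows, as
expected for a system whose only solute is amide.

The full image-domain pipeline (phantom simulation → feature preparation →
training → volume denoising with fine-tuning → quantification → report)
runs via `run_pipeline(pipeline_config(), out_dir, seed)` or the CLI at
`inst/cli/cest-dpdl.R` (`simulate | featureprep | train | denoise |
quantify | evaluate | run`).

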