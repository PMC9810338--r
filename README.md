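# confinedfcs

In-silico fluorescence correlation spectroscopy (FCS) for diffusion in
confined bacterial cytoplasm.

## The problem

FCS measures how fast fluorescent molecules move by correlating intensity
fluctuations in a confocal detection volume. Inside a bacterium the cell
width (0.8–0.9 µm) is comparable to the detection volume itself, and the
cell wall cuts off long molecular excursions. Autocorrelation functions
(ACFs) of *purely Brownian* molecules confined this way, fitted with the
standard 3D anomalous-diffusion model

G(τ) = G∞ + (1/N) · B(τ) · [1 + (τ/τ_D)^α]⁻¹ · [1 + (τ/τ_D)^α/S²]^(−1/2)

return an apparent anomalous exponent α ≈ 0.8–0.9 — easily mistaken for
genuine subdiffusion. This package simulates the full experiment (Brownian
or fractional Brownian emitters in a spherocylindrical cell, Gaussian
confocal detection, blinking, photobleaching detrending) and fits ACFs
both with the anomalous model and with an Ornstein–Uhlenbeck (OU)
confined-diffusion model, in which motion across the cell width is Brownian
diffusion trapped in a harmonic potential of width σ ≈ d/2. The OU fit
recovers the true diffusion coefficient to within about ±5% at bacterial
cell widths, turning the confinement artifact into a correction.

Downstream analyses cover the size dependence of cytoplasmic diffusion —
the inverse power law D = A·MM^(−β) across GFP fusion constructs, with
Stokes–Einstein (β = 0.4) and linked two-bead (dumbbell) reference
models — and buoyant-density estimation from sedimentation profiles via
1/Z₀ = Δρ·V·g/k_BT.

It is aimed at people analyzing (or sanity-checking) FCS measurements in
small confined geometries: bacteria, organelles, microfluidic traps.

## Worked example

Simulate one FCS measurement on a cell of diameter 0.85 µm — six 20-s
acquisitions of 50 emitters diffusing at D = 10 µm²/s, sampled at 10 µs —
then correlate, apply the blinking factor, and fit:

```r
library(confinedfcs)

cfg <- simulation_config(
  n_particles = 50, dt = 1e-5, duration = 20,
  geometry = cell_geometry(L = 5, d = 0.85),
  motion   = motion_model("brownian", D = 10),
  seed     = 11)

cell <- simulate_cell(cfg, n_acquisitions = 6,
                      model = "anomalous", fixed = list(S = 4))
m <- cell$measurement
cat(sprintf("anomalous fit: alpha = %.3f +- %.3f, tau_D = %.0f us\n",
            m$alpha$mean, m$alpha$sem, 1e6 * m$tau_D$mean))

ou <- simulate_cell(cfg, n_acquisitions = 6, model = "ou",
                    fixed = list(omega0 = 0.2, S = 4, sigma = 0.85 / 2))
cat(sprintf("OU fit:        D = %.2f +- %.2f um^2/s (ansatz 10)\n",
            ou$measurement$D$mean, ou$measurement$D$sem))
```

```
anomalous fit: alpha = 0.830 +- 0.017, tau_D = 885 us
OU fit:        D = 10.03 +- 0.13 um^2/s (ansatz 10)
```

The particles are purely Brownian, yet the anomalous model reports
α ≈ 0.83 — the confinement artifact. The OU model, with the confinement
width fixed to half the cell diameter, recovers the true D = 10 µm²/s
within 1%.

The mass-scaling fit over the packaged construct table (18 freely
diffusing GFP fusions, 26.9–163 kDa):

```r
tab <- read_construct_table()
sub <- tab[!is.na(tab$d_fcs_um2_s), ]
fit_power_law(sub$mm_kda, sub$d_fcs_um2_s, sub$d_fcs_sem_um2_s)
```

```
Power law D = A * MM^(-beta): beta = 0.546 +- 0.041, A = 86.7 (weighted, n = 18)
```

The `analysis/` directory holds numbered drivers that run the full set of
analyses (confinement α scan over cell diameters, OU validation and σ
calibration, fBm α mapping, mass scaling, sedimentation) and write tidy
CSVs under `results/`.

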