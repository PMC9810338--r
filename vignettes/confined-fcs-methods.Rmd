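---
title: "Measuring protein diffusion in confined bacterial cytoplasm by in-silico FCS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring protein diffusion in confined bacterial cytoplasm by in-silico FCS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confinedfcs)
```

## The problem

Fluorescence correlation spectroscopy (FCS) infers molecular mobility from
the decay of the autocorrelation function (ACF) of intensity fluctuations in
a femtoliter confocal volume. In a bacterium the confocal volume is
comparable to the cell itself: the width of an *E. coli* cell (0.8–0.9 µm)
is similar to the axial extent of the detection volume, and the cell wall
truncates long molecular excursions. ACFs of *purely Brownian* molecules
confined this way, fitted with the standard 3D anomalous-diffusion model,
return an anomalous exponent α well below 1 — an artifact that is easily
mistaken for genuine subdiffusion. This package provides the machinery to
quantify and correct that artifact:

1. an in-silico FCS experiment — Brownian or fractional Brownian point
   emitters confined in a spherocylindrical (capsule) cell, observed through
   a 3D Gaussian detection volume;
2. ACF estimation on a logarithmic lag grid, with photobleaching detrending
   and a chromophore-blinking multiplier;
3. model fitting: the 3D anomalous-diffusion ACF and an Ornstein–Uhlenbeck
   (OU) confined-diffusion ACF that estimates the true diffusion
   coefficient directly;
4. downstream analyses: the diffusion-vs-molecular-mass power law with
   Stokes–Einstein and linked two-bead (dumbbell) reference models, and
   buoyant-density estimation from sedimentation profiles.

## The simulated experiment

The cell is a capsule: a cylinder of diameter $d$ and length $L-d$ closed
by hemispherical caps (long axis $x$, centered at the origin). Defaults
emulate a cephalexin-elongated cell, $L = 5$ µm and $d = 0.85$ µm. $N = 50$
point emitters start uniformly distributed over the capsule — the
stationary law of confined diffusion, so no burn-in is needed — and move
with per-axis Gaussian steps of standard deviation $\sqrt{2D\,\Delta t}$.
Steps that would leave the capsule are redrawn (up to 100 times, after
which the particle stays put and a diagnostic counter is incremented);
specular reflection is available as an alternative and yields statistically
indistinguishable occupancies, which the test suite asserts.

Detection is a 3D Gaussian profile
$I_G(\mathbf r) = \exp[-2(\Delta x^2+\Delta y^2)/\omega_0^2 - 2\Delta z^2/z_0^2]$
with $\omega_0 = 0.2$ µm and $z_0 = 0.8$ µm, centered on the cell axis 1 µm
from one pole (the experimental placement near the polar region, away from
the nucleoid). The recorded trace is the summed PSF intensity of all
emitters at every step.

Two deliberate scalings keep problem sizes tractable without changing the
physics probed: the simulation step is $\Delta t = 10^{-5}$ s (the transit
time through the beam waist at $D = 10$ µm²/s is $\tau_D = \omega_0^2/4D =
1$ ms, so each transit is still resolved by ~100 steps), and each
measurement consists of six 20-s acquisitions, matching the experimental
per-cell protocol.

### Subdiffusive motion

Fractional Brownian motion is generated from fractional Gaussian noise with
per-axis increment covariance
$\gamma(k) = \tfrac{\Gamma_\alpha}{2}\Delta t^\alpha\left(|k+1|^\alpha + |k-1|^\alpha - 2|k|^\alpha\right)$,
giving unconfined per-axis MSD $\Gamma_\alpha t^\alpha$. Increments are
synthesized by circulant embedding (Davies–Harte): the covariance sequence
is embedded in a circulant matrix whose eigenvalues come from one FFT, and
paths are colored complex white noise — the real and imaginary parts of one
synthesis are two independent paths, halving the cost. The embedding
spectrum is provably nonnegative for fGn; the generator still checks and
fails loudly if eigenvalues go negative beyond tolerance. Confinement for
fBm uses reflective (specular-fold) boundaries; redraw is not offered
because redrawing correlated increments would break the increment
covariance. When comparing fBm at exponent $\alpha$ with Brownian motion at
coefficient $D$, $\Gamma_\alpha$ is chosen so the MSDs agree at
$t = 1$ ms — the beam-transit timescale, where the ACF is most informative.

### Blinking and bleaching

GFP-family chromophores blink on a ~25 µs protonation timescale. As in the
experimental analysis pipeline being emulated, blinking is applied at the
ACF level: simulated ACFs are multiplied by
$1 + \tfrac{0.1}{1.1}e^{-\tau/\tau_H}$ with $\tau_H = 25$ µs, algebraically
identical to the models' blinking term with dark fraction $F_P = 1/12$.

Photobleaching plumbing (`bleach_rate`) exists to exercise the detrending
correction: each emitter goes irreversibly dark with per-step probability
proportional to its instantaneous excitation intensity. Bleaching decisions
draw from a dedicated RNG substream, so a bleached and an unbleached run at
the same seed share identical trajectories — which is what makes the
"detrending restores the bleach-free ACF" test a paired comparison rather
than a statistical one. It is off by default.

## ACF estimation

The estimator is the symmetrically normalized correlator
$C(\delta t) = \langle I(t+\delta t)I(t)\rangle / (\langle I(t+\delta t)\rangle\langle I(t)\rangle) - 1$
with means over the overlapping segment, evaluated on a log-spaced grid (16
points per decade, the density of typical hardware correlators) from one
sample up to a tenth of the trace duration. Symmetric normalization makes
the estimator invariant under intensity rescaling and tolerant of residual
slow trends. Simulated traces carry no afterpulsing, so the grid starts at
one sample; experimental photon traces conventionally start at 2 µs.

Photobleaching detrending fits a continuous piecewise-linear trend $f(t)$
(two segments by default; the interior knot is grid-searched over coarse
bin boundaries, with the bin count exposed because the reference
implementation does not document it) and applies the variance-preserving
square-root correction
$I_c(t) = I(t)/\sqrt{f(t)/f(0)} + f(0)\left(1-\sqrt{f(t)/f(0)}\right)$,
which restores both the mean and the fluctuation amplitude of a stationary
process under multiplicative intensity loss. The exact correction formula
of the original plugin is unpublished; the contract is therefore
tolerance-based (the corrected ACF matches the matched bleach-free ACF
within 10%), consistent with the reported near-identity of two independent
detrending methods.

## The ACF models

**Anomalous diffusion** (the standard 3D model with one blinking and one
diffusive component):
$$G(\tau) = G_\infty + \frac1N\,
\frac{1-F_P+F_P e^{-\tau/\tau_P}}{1-F_P}\,
\frac{1}{1+(\tau/\tau_D)^\alpha}\,
\frac{1}{\sqrt{1+(\tau/\tau_D)^\alpha/S^2}}$$
with $S = z_0/\omega_0$. $\alpha = 1$ recovers the unconfined Brownian
model; $D = \omega_0^2/(4\tau_D)$ converts the diffusion time to a
diffusion coefficient.

**OU confined diffusion.** Motion across the cell width is approximated by
an OU process — diffusion at coefficient $D$ in a harmonic potential whose
stationary standard deviation is $\sigma$. With
$E(\tau) = 1 - e^{-2D\tau/\sigma^2}$ and $\tau_D = \omega_0^2/(4D)$:
$$G(\tau) = G_\infty + \frac{B(\tau)}N
\left[1+\frac{2\sigma^2}{\omega_0^2}\,\frac{E(\tau)}{1+\omega_0^2/8\sigma^2}\right]^{-1/2}
\left[1+\frac{\tau}{\tau_D}\right]^{-1/2}
\left[1+\frac{2\sigma^2}{S^2\omega_0^2}\,\frac{E(\tau)}{1+S^2\omega_0^2/8\sigma^2}\right]^{-1/2}$$
one confined factor per transverse axis (waists $\omega_0$ and
$S\omega_0$), one free factor for the long axis. The parsing of this
expression is pinned by three requirements enforced in the test suite:
both confined axes share the same $E(\tau)$ (same $\sigma$, same $D$); the
$\sigma \to \infty$ limit reduces each confined factor to its unconfined
counterpart, collapsing the model onto the 3D Brownian ACF (asserted to
$10^{-9}$ relative over seven decades of lag); and the axial factor is the
lateral one under $\omega_0 \to S\omega_0$.

Calibration against hard-wall simulations fixes the only non-instrumental
parameter: scanning $\sigma$ with every other parameter held at its ansatz
value — $D$, $\omega_0$, $S$, $G_\infty = 0$, $F_P = 1/12$, and the
amplitude $N = N_p\langle I_G\rangle^2/\mathrm{var}(I_G)$, the zero-lag
contrast of the summed-PSF signal under uniform occupancy — the
residual-sum-of-squares minimum falls at $\sigma \approx d/2$. Fixing all
parameters is essential: with $D$ free the model reabsorbs $\sigma$ through
$D$ and the SSR minimum shifts to ~$0.35\,d$. The minimum's location is
also sensitive to the boundary discretization at the 10-µs step used here:
the redraw rule rejects outward moves near the wall and depletes occupancy
within $O(\sqrt{2D\Delta t})$ of it, pulling the minimum to ~$0.44\,d$,
whereas specular reflection preserves the uniform law and yields
$\sigma^\ast = 0.49\,d$ (at a 1-µs step the two boundary rules agree, as
expected). The calibration scan therefore runs on reflective-boundary
simulations. With $\sigma = d/2$ fixed, the OU fit recovers the ansatz $D$
to within about ±5% at bacterial cell widths: high-replication runs put
the systematic error near +3% for $D = 10{-}15$ µm²/s, while the slowest
condition tested ($D = 5$ µm²/s) sits at the edge of that band — partly
because 20-s acquisitions under-sample the slowest (cell-length)
relaxations, partly intrinsic to the harmonic approximation. Recovery
accuracy is the method's figure of merit and is re-measured, not assumed,
by the acceptance analyses.

## Fitting conventions

Fits are Levenberg–Marquardt least squares (via minpack.lm), unweighted by
default (per-lag SEM weights are available for averaged curves). Starting
values are data-driven: amplitude from the first lags, $\tau_D$ from the
half-amplitude lag, $\alpha = 0.85$, $F_P = 0.1$. Bounds:
$\alpha \in [0.3, 1.3]$, $F_P \in [0, 0.5]$. Convergence uses relative
tolerances of $10^{-12}$ with bound-hitting parameters flagged; the
original software's criteria are unknown, so tight tolerances and a
convergence flag are the conservative choice.

Fixed-parameter conventions follow the procedure being emulated:
$\tau_P = 25$ µs always; for *experimental* curves $S = 8$,
$\omega_0 = 0.19$ µm and $\sigma = 0.42$ µm (half the typical cell width).
For *simulated* curves the optical parameters are fixed to the values of
the simulated instrument — $\omega_0 = 0.2$ µm, $z_0 = 0.8$ µm, hence
$S = 4$ — because, as in the validation of the OU fit, the optics are
measured independently and only mobility parameters are unknown. This is a
deliberate deviation from naively reusing the experimental $S = 8$ with
simulated data, where the mismatched axial geometry biases the fitted
$\alpha$ upward by ~0.03–0.04.

$F_P$ is left free when fitting simulated curves even though the blinking
multiplier is known exactly, mirroring the experimental procedure (a
documented `fixed = list(F_P = 1/12)` switch pins it). Per-measurement
aggregation averages the six per-acquisition fits (arithmetic mean and SEM
over the converged ones). Model comparison uses
$\mathrm{AIC} = n\log(\mathrm{SSR}/n) + 2(k+1)$; the reference analysis
compared fits qualitatively, so AIC is this package's choice for an
automatable ranking. Group comparisons use Welch's two-tailed
heteroscedastic *t*-test.

A two-component anomalous fit (fast species fully fixed — weight, $\tau_D$,
$\alpha$ — slow species free) reproduces the control for a contaminating
fraction of free fluorophore from partially degraded fusions.

## Mass scaling and the dumbbell model

The mass dependence of the OU-derived diffusion coefficients across the
freely diffusing constructs is fitted as $D = A\,\mathrm{MM}^{-\beta}$ by
weighted ($1/\mathrm{SEM}^2$) nonlinear least squares on per-construct
means — matching how the data are plotted; whether the reference analysis
pooled cells or construct means is unstated, so the unweighted option is
retained and both land in the same exponent band. The subset fitted is
defined operationally as the rows of the packaged construct table with a
populated FCS diffusion coefficient (18 records).

Reference curves: the Stokes–Einstein prediction
$D \propto \mathrm{MM}^{-\beta}$ with $\beta = 0.4$ (the radius–mass
exponent of imperfectly compact globular proteins, empirically 0.35–0.43),
and a linked two-bead (dumbbell) model for fusion proteins — tag and target
as tethered beads with radii scaling as $\mathrm{MM}^{0.4}$. The dumbbell
formula implemented is the package's own Kirkwood/Oseen-level model for a
rigid pair,
$D = D_1\,\frac{a_1}{a_1+a_2}\left(1 + \frac{3\,a_1 a_2}{2\,(a_1+a_2)\,r}\right)$,
chosen to satisfy the three properties that define the modeling intent: it
reduces to the single-sphere value as the partner vanishes, decreases
monotonically in either radius, and lies between the no-coupling pair and
the isolated tag. The linker gap defaults to zero (touching beads) and is
exposed.

## Sedimentation

Cells in a density-matched fluid at sedimentation–diffusion equilibrium
follow the barometric profile $n(z) = n_0 e^{-z/Z_0}$ with
$1/Z_0 = \Delta\rho\,V g/k_BT$. The decay length is fitted in the interior
window $[0.25, 0.8] \times$ channel height (50 µm) to avoid boundary
artifacts. The decay is exactly log-linear, so the estimator is Poisson
regression with a log link — the maximum-likelihood choice for counted
cells (quasi-family, so fractional bin values are accepted and the standard
error absorbs dispersion); a plain log-linear least-squares option is
retained. A nonlinear fit weighted by *observed* counts was rejected:
weights that correlate with the noise bias the fitted rate downward. Flat
or inverted profiles return the $Z_0 = \infty$ flag ($\Delta\rho = 0$)
instead of diverging. Units: $k_BT = 4.11$ pN·nm (25 °C),
$g = 9.81$ m/s², $V$ in µm³ from the capsule volume formula
$V = \pi d^3/6 + (L-d)\pi d^2/4$; $\Delta\rho$ emerges in kg/m³ ≡ g/L.
The synthetic-profile generator draws multinomial counts per 1-µm bin (the
imaging z-step) from the barometric expectation; note that estimating
$\Delta\rho \propto 1/Z_0$ is linear in the fitted rate, so the round trip
is unbiased even though $Z_0$ itself is heavy-tailed for near-flat
profiles.

## Numerical choices

* RNG: a self-contained xoshiro256++ generator with a ziggurat normal
  sampler in the compiled kernels; per-particle substreams are derived
  deterministically from the acquisition seed, so traces are bit-identical
  across platforms for a given configuration. R-level helpers use R's RNG
  and respect `set.seed()`.
* fGn synthesis pads the circulant to the next power of two and uses a
  radix-2 FFT in the kernel (validated against R's `fft` in the tests).
* PSF evaluations are skipped when the Gaussian exponent exceeds 30
  (contribution < $10^{-13}$), which prunes ~two-thirds of the
  exponentials in a 5-µm cell.
* Capsule reflection folds radially about the nearest point of the axis
  segment — exact for both the cylindrical wall and the caps; pathological
  steps (longer than the cell width, never produced at the default
  $\Delta t$) are clamped just inside after 100 folds.
* Degenerate inputs are rejected loudly: all-zero traces (undefined
  normalization), nonpositive fitted bleaching trends, ACFs with fewer
  than 10 points or under two decades of lag span, $F_P = 1$, flat
  sedimentation ranges.

## What the generator does and does not emulate

The simulator reproduces the geometry, optics, particle numbers, blinking
and acquisition protocol of the experiment it models, and it is the basis
of every quantitative claim the tests make. It does not emulate photon
statistics (intensities are noiseless sums of PSF values, not Poisson
counts), detector afterpulsing, the nucleoid or any intracellular
structure, polydispersity or interactions between emitters, or vendor
hardware correlators. Passing tests therefore demonstrate correctness of
the estimation and correction pipeline under the stated physical model —
confinement effects, fitting conventions, unit handling — not robustness
to every artifact of a real detector.

## Problem sizes used by the checks

The acceptance analyses use six 20-s acquisitions per condition at
$\Delta t = 10^{-5}$ s with 50 particles (2×10⁶ samples per trace),
diffusion coefficients 5–15 µm²/s, diameters 0.7–1.0 µm, and six fBm
acquisitions at ansatz $\alpha = 0.95$; unit tests use shorter traces of
the same construction. These sizes give per-condition SEMs of ~0.01–0.03
on $\alpha$ and ~1–3% on $D$, comfortably resolving the effects under
test.

## Known limitations

* The OU approximation treats the two confined axes independently and
  ignores the axial inhomogeneity of confinement along the caps; it is
  validated only for $d$ in the 0.7–1 µm range scanned.
* The anomalous-model $\alpha$ for confined Brownian motion depends on the
  fixed aspect ratio used in the fit (see Fitting conventions).
* The dumbbell model is a far-field, rigid-pair approximation; it is a
  reference curve, not a hydrodynamic boundary-element calculation.
* Experimental per-construct values shipped in the construct table are
  fixture data for the loader and scaling fit; they cannot be regenerated
  in silico.
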