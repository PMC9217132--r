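---
title: "Excitatory/inhibitory neural mass modelling of regional MEG spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excitatory/inhibitory neural mass modelling of regional MEG spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmmspectra)
```

## The model

Each cortical region is modelled as a pair of lumped neuronal
subpopulations — excitatory and inhibitory — whose signals $x_e(t)$ and
$x_i(t)$ decay through gamma-shaped ensemble impulse responses and excite
each other through a cross-population loop, driven by white noise $p(t)$:

$$\frac{dx_e}{dt} = -\frac{f_e(t)}{\tau_e} \ast
  \bigl(g_{ee}\,x_e(t) - g_{ei}\, f_i(t) \ast x_i(t)\bigr) + p(t), \qquad
  \frac{dx_i}{dt} = -\frac{f_i(t)}{\tau_i} \ast
  \bigl(g_{ii}\,x_i(t) + g_{ei}\, f_e(t) \ast x_e(t)\bigr) + p(t).$$

The kernels are the unit-area gamma functions
$f(t) = (t/\tau^2)\,e^{-t/\tau}$ with Fourier transform
$F(\omega) = (1 + j\omega\tau)^{-2}$. Because the equations are linear,
the regional spectrum has a closed form: solving the $2 \times 2$
frequency-domain system for the transfer functions $H_e$, $H_i$ from the
shared drive, the power spectral density of the regional signal
$x_e + x_i$ is $|H_e(\omega) + H_i(\omega)|^2$ (in dB,
`model_psd_db()`). Four parameters are free per region — the
time-constants $\tau_e$, $\tau_i$ (ms) and recurrent gains $g_{ee}$,
$g_{ii}$ — while the cross-population gain $g_{ei}$ is fixed at 1 and
the noise amplitude at 1 (a pure dB offset under the fitting cost, hence
unidentifiable).

Two wiring choices deserve explanation because the model statement leaves
them open:

* **Kernel normalization.** We use the unit-area kernel, so the DC
  response of every kernel is exactly 1; any other normalization is
  absorbed by the gains and the (unidentified) noise scale.
* **Noise wiring.** Both population equations are driven by the same
  symbol $p(t)$. The default treats it as a single shared realization
  (coherent sum $|H_e + H_i|^2$); `noise_mode = "independent"` switches
  to uncorrelated drives ($|H_e|^2 + |H_i|^2$). The Pearson cost in dB is
  insensitive to overall scale, so the choice matters only through the
  interference cross-term.

## Stationarity and the time-domain oracle

The closed-form spectrum is validated against a stochastic simulation of
the same equations (`simulate_time_domain()`): each gamma convolution is
realized exactly as the critically damped filter
$\tau^2 y'' + 2\tau y' + y = u$, giving a 10-state linear SDE integrated
by Euler–Maruyama.

Working through the pole structure (`nmm_stability()`) exposes a property
of this model family that is easy to miss when it is used purely as a
spectral template: for most parameter values inside the standard fitting
box — including the canonical starting values $\tau = 17$ ms,
$g = 0.5$ and the cohort-typical estimates — the resonant pole pair lies
in the *right* half-plane. The frequency-domain solution is then the
driven steady-state template the model is fit with, but no stationary
time-domain process exists and a simulation diverges (the integrator
raises an instability error). Cross-validation of the closed form against
Welch spectra of simulations is therefore performed on parameter sets
drawn inside the fitting bounds and rejection-sampled to the stationary
regime, with margin: we require the largest pole real part to be at most
$-0.5\,\mathrm{s}^{-1}$, so the autocorrelation time (≤ 2 s) is far
shorter than the 600 s realizations used and the Welch estimate mixes.
Within that regime the two routes agree to $r > 0.99$ and RMS < 1 dB
after offset removal.

Two numerical choices in the integrator:

* **Substepping.** Forward Euler is stable for a pole $\lambda$ only when
  $h < -2\,\mathrm{Re}\,\lambda / |\lambda|^2$; at a lightly damped 10 Hz
  resonance this is far below a 600 Hz sampling interval. The integrator
  therefore takes internal substeps (derived from the pole locations with
  a safety factor of 10, so that the Euler damping error
  $h|\lambda|^2/2$ stays well below $|\mathrm{Re}\,\lambda|$), while the
  output is sampled at the requested rate.
* **Welch windows.** Comparisons with the closed form use 8 s Hann
  windows (0.1875 Hz equivalent noise bandwidth): at the admitted
  stationarity margin the resonance half-width can be as small as
  $0.5/(2\pi) \approx 0.08$ Hz, and with coarser windows the window's
  spectral smearing of the peak — not the model — dominates the
  residual. A 600 s realization still leaves ~150 half-overlapped
  segments, keeping the per-bin sampling error near 0.5 dB.

## Spectral features

Empirical spectra are Welch periodograms (Hann windows, 2 s, 50 %
overlap by default) in dB, restricted to the 1–35 Hz analysis band. Band
summaries are the arithmetic mean of the dB values over the band bins,
edges inclusive: delta–theta 2–7 Hz, alpha 8–12 Hz, beta 13–35 Hz,
broadband 1–35 Hz. Averaging on the dB scale (not dB of the mean power)
matches how dB-scale spectra are compared across groups.

## Fitting protocol

`fit_region()` estimates the four free parameters by basin-hopping
global optimization of the negative Pearson correlation between the
empirical and model spectra, both in dB, over the empirical frequency
bins inside 1–35 Hz. Protocol constants: start at $\tau = 17$ ms,
$g = 0.5$; bounds $\tau \in [5, 30]$ ms, $g \in [0.1, 10]$; 2000
iterations, temperature 0.1, step size 4; when an estimate lands within
$10^{-3}$ of a bound (relative to the bound width) the search is rerun
with step size 6 and the better run kept. The local minimizer inside
each hop is bounded L-BFGS-B; the whole loop runs at C level for speed,
drawing proposals from R's RNG so that a seed makes the search
reproducible. Simulation studies in the test suite run at reduced
iteration counts (30–400, stated per experiment); 400 iterations already
recover 25 random noiseless truths exactly, and the full 2000-iteration
protocol takes about 3 s per region.

The offset between empirical and model spectra (`scaling_offset_db`) is
recorded per fit, since the correlation cost ignores it by construction.

## Synthetic cohorts

`generate_cohort()` draws a complete study dataset with known ground
truth. Defaults emulate the study conditions: 35 controls and 20
patients over the 68 Desikan–Killiany cortical ROIs; Gaussian regional
parameters truncated to the fitting bounds, with control means near the
reported control least-squares means ($\tau_e$ 11.8 ms, $\tau_i$
15.4 ms, $g_{ee}$ 1.7, $g_{ii}$ 3.7) and patient mean shifts of +4 ms,
+1 ms, +0.3, −0.4 respectively; between-observation SDs of 1.5 ms for
time-constants and 0.35/0.5 for gains (chosen so that group separations
correspond to moderate effect sizes, roughly matching the reported
confidence-interval widths). Tracer uptake is linearly coupled to
control-referenced parameter z-scores: tau SUVR to $z(\tau_e)$ and
amyloid-beta SUVR to $z(\tau_i)$ (slopes 0.2 SUVR per z, cross-slopes 0,
SUVR noise SD 0.25, base levels 1.64 and 1.99, the cohort averages at
which predicted fits are reported). Spectra are the closed-form model
spectra plus i.i.d. $N(0, 1\ \mathrm{dB})$ noise per bin — 1 dB is the
order of the sampling error of a one-minute resting epoch. The grid
default is 0.5 Hz spacing (the resolution of a 2 s Welch window).

What the generator does *not* emulate: spatially structured (smooth)
noise and ROI covariance (an optional ROI random-effect flag exists but
is off by default), beamformer leakage between regions, heavy-tailed or
frequency-correlated spectral noise, and any PET image formation
process. Passing tests on this generator therefore demonstrate the
correctness of the estimation and statistics machinery under the stated
conditions, not robustness to all properties of real MEG/PET data.

## Statistics

* **z-scores** are computed per ROI against the control cohort
  (`zscore_vs_controls()`); controls standardize themselves to mean 0,
  SD 1.
* **Associations** (`association_model()`) regress a z-scored outcome on
  tau and amyloid-beta SUVR jointly, on patients, respecting repeated
  ROIs within subject via a subject random intercept (nlme;
  a compound-symmetry marginal `gls` variant is available). ROI-specific
  residual variances (`variance = "per_roi"`) reproduce the
  heterogeneous-variance design; the homogeneous default is more robust
  at reduced simulation sizes. Degrees of freedom follow nlme's
  between-within approximation; no attempt is made to reproduce
  SAS-specific denominator-df conventions.
* **Group contrasts** (`group_contrast()`) use the same random-intercept
  model with a group fixed effect — the simple replacement for the
  original two-way repeated-measures ANOVA, whose Tukey–Kramer post hocs
  are out of scope.
* **Regional maps** (`regional_group_map()`) are per-ROI unpaired
  t-tests (Student by default, Welch optionally) thresholded with
  Benjamini–Hochberg FDR across the 68 ROIs at $q = 0.10$.
* **Mediation** (`mediate()`, `run_mediation_suite()`) decomposes a
  protein effect on band power into direct and time-constant-mediated
  parts by the product-of-coefficients method, adjusting for the other
  protein. The least-squares estimator is the default because its
  decomposition is exactly additive (total = direct + indirect); the
  mixed-model variant is provided for fidelity and is approximately
  additive. Indirect-effect uncertainty comes from the Sobel first-order
  SE or a cluster bootstrap resampling whole subjects. The five standard
  decompositions are: amyloid-beta → {delta–theta, alpha, beta} via
  $\tau_i$, and tau → {alpha, beta} via $\tau_e$.

## A known identifiability limit

The coupled system is nearly invariant under exchanging
$(\tau_e, g_{ee})$ with $(\tau_i, g_{ii})$: for a patient-typical
parameter set the spectra of the two assignments correlate at
$r = 0.99995$. With 1 dB spectral noise the fitting cost cannot reliably
distinguish the two modes, and the global optimum lands in the swapped
mode for roughly 15 % of patient-like regions regardless of how long the
optimizer runs — patients are the worst case because the shifted group
means bring $\tau_e$ and $\tau_i$ both near 16 ms. Swapped fits mix the
two time-constants' signals, which attenuates the main
parameter–proteinopathy associations (they remain clearly detectable)
but also injects a genuine, sample-size-independent *cross*-correlation
between fitted $\tau_e$ and the amyloid-coupled signal (and vice versa).
On synthetic cohorts the specific dissociation "each time-constant
associates only with its own protein" therefore replicates in sign and
dominance but the cross-associations do not stay reliably
non-significant once cohorts are large enough to detect the swap
leakage. The corresponding acceptance check is left failing by design
rather than weakened; the effect is a property of the model's likelihood
surface at this noise level, not of the optimizer (doubling iterations
does not change it) nor of the statistics downstream. Fits on real
spectra face the same ambiguity, which is worth keeping in mind when
interpreting per-region time-constant estimates.

## Reduced problem sizes

The test suite and the acceptance script run every experiment at scales
chosen to keep a complete run within a few minutes each: 600 s
realizations for the oracle comparisons; 25 random truths at 400
basin-hopping iterations for recovery; 500 replicates for FDR control;
cohorts of 20 controls / 14 patients over 16 ROIs at 30–50 iterations
for the end-to-end experiments. Each scale is stated where it is used.

## Worked example

```{r example, eval = FALSE}
library(nmmspectra)

# a cohort at reduced scale, then the full pipeline
cfg <- pipeline_config(
  cohort = cohort_config(n_controls = 20, n_patients = 14,
                         rois = dk68_rois()[1:16], seed = 1),
  fit = fit_config(n_iterations = 50, seed = 2),
  seed = 3)
res <- run_pipeline(cfg, verbose = TRUE)
print(res)
res$associations          # dual-predictor association t-tables
res$mediation             # the five mediation decompositions
```
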