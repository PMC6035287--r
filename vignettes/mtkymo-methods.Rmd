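---
title: "Models and methods in mtkymo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mtkymo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtkymo)
```

mtkymo analyses the growing plus ends of microtubules (MTs) as they appear
in fluorescence kymographs: noisy, diffraction-limited 1D intensity
profiles of a 25 nm-wide polymer whose 13 protofilaments are unresolved.
Everything in the package revolves around four quantitative questions: where
is the tip (to sub-pixel precision), what is the nanoscale shape of the tip
(how many protofilaments are missing, and how long is the eroded region),
how variable is growth (drift vs. diffusion of the tip position), and how
often do catastrophes, rescues and tip-repair events occur.

## Intensity models

All models act on 1D line profiles with the lattice at low *x* and the tip
at high *x*; coordinates are in nm, pixels are 65 nm unless configured
otherwise.

**Tip edge.** A homogeneously labeled lattice ending at $x_c$, imaged with
a Gaussian point spread function (PSF), gives

$$I(x) = I_{BG} + \tfrac12 I_{AMP}\,\mathrm{erfc}\!\left(\frac{x - x_c}{\sqrt2\,\sigma}\right),$$

where $\sigma$ is the PSF width convolved with any tip taper. `fit_tip_erf()`
fits this by least squares: the linear parameters $(I_{BG}, I_{AMP})$ are
profiled out analytically and $(x_c, \log\sigma)$ optimized by a multi-start
Nelder–Mead simplex (starts at the steepest intensity drop and at the
supplied approximate tip). This variable-projection form is what makes the
Monte-Carlo taper search below affordable: the same compiled fitter runs a
few hundred thousand times per grid search. Fits with non-positive
amplitude, $\sigma$ pinned at its bounds, or a tip position outside the fit
window are flagged and excluded from averaging.

**EB comet.** End-binding proteins decorate a region that decays
exponentially behind the tip. Convolved with the PSF this is an
exponentially modified Gaussian, evaluated in `comet_emg()` via
`pnorm(log.p = TRUE)` so that no parameter combination overflows (relative
error against direct quadrature is below $10^{-8}$; the test suite checks
this). The fitted $x_c$ is the position of maximum molecule density, i.e.
the start of the decay, and `lambda` is the decay *length* in nm.

**Tip-tracker accumulation.** A point-like accumulation near the tip on top
of lattice binding is a complementary error function plus a Gaussian of
fixed width $\sigma_{PSF}$ (default 97.5 nm = 1.5 pixels):
`tog2_step_peak()` / `fit_tog2_step_peak()`. The offset `x_peak` is reported
relative to the fitted lattice edge; negative values lie behind the tip.
The edge width is bounded below at $0.8\,\sigma_{PSF}$: an edge is the PSF
convolved with taper and cannot be sharper than the PSF, and without the
bound the model has a near-degenerate solution (sharp edge plus a displaced
peak) that destabilizes the fit at realistic noise. The peak-to-lattice
ratio $I_{peak}\sqrt{2\pi}\sigma_{PSF} / (I_{lattice}\cdot\text{pixel})$
corrects for the different convolutions of a delta and a step; expressed
with $\sigma_{PSF}$ in pixels it is dimensionless, and the `> 1` value used
as an inclusion filter corresponds to a point accumulation at least as
bright per pixel as the lattice.

A known limitation, quantified on synthetic data: at a signal-to-noise
ratio of 7 the six-parameter step+peak fit shows a small-sample bias that
pulls the fitted lattice edge backwards by roughly 15–20 nm. The bias
cancels in the *within-channel* offset `x_peak` (edge and peak move
together), which is why offsets referenced to the fit's own channel are
recovered accurately, but it propagates into any *cross-channel* distance
that uses the step+peak fit's absolute positions, such as the distance
between the accumulation and a comet peak fitted in a second channel. The
bias scales with the square of the noise and is present at the global
least-squares optimum, so it is a property of the estimator at these
conditions, not of the optimizer.

## Averaging

`align_and_average()` reproduces the two-level averaging used for
experimental profiles: each accepted profile is shifted by a tip position
(its own fitted $x_c$, or the partner channel's for two-color data),
background-subtracted, normalized (by $I_{AMP}$, $I_{lattice}$, or the
profile maximum), linearly interpolated onto a common half-pixel grid
(32.5 nm), averaged per kymograph, and then averaged across kymographs with
the SEM taken at that second level. No extrapolation is performed: a grid
point survives only where all profiles of a kymograph, and then all
kymographs, cover it.

## Synthetic data generator

The generator exists so that every analysis stage can be exercised against
known ground truth; its defaults are the imaging conditions the analyses
assume.

* **Lattice**: 13 protofilaments, 8 nm axial dimer spacing, projected onto
  one axial coordinate (the transverse width is far below the PSF).
* **Tip erosion**: Model A removes the same length $d$ from each of $N$
  eroded protofilaments (sharp); Model B draws the missing lengths i.i.d.
  from an exponential with mean $d$ (gradual). Lengths are rounded to the
  8 nm dimer grid; Model B draws are truncated at the lattice length
  (for $d$ far below the lattice length the truncated mass is negligible,
  so no renormalization is applied).
* **Labeling**: each present dimer is labeled independently with
  probability 0.09.
* **Rendering**: each labeled dimer contributes a unit Gaussian mass of SD
  122 nm, integrated over 65 nm pixels as a CDF difference (not sampled at
  pixel centers). Gaussian noise is added with SD = plateau mean / SNR,
  with SNR 7 by default. The plateau is measured on pixels at least
  $4\sigma$ behind the most eroded tip; whether an experimental SNR refers
  to the plateau mean or amplitude is not fixed by convention, so this
  choice is configurable.
* **Trajectories**: tip increments per frame are $v_g\,dt + \sqrt{2 D_p dt}\,\xi$
  with independent per-frame measurement noise of SD $\sigma_{err}$ added
  to every sample; default sampling 0.7 s for 5 min (429 samples). Note the
  increment between two noisy frames carries $2\sigma_{err}^2$; the MSD fit
  absorbs this in a single constant.
* **Dynamic instability**: a continuous-time telegraph process with
  catastrophe and rescue rates in min$^{-1}$ and a reflecting floor at the
  stable seed.
* **Outgrowth**: per-seed Bernoulli draws from a Hill sigmoid
  $p_{max} c^h / (c_{50}^h + c^h)$.

What the generator does *not* emulate: photobleaching, camera EM gain
statistics, 2D/3D optics, drift, or chromatic offsets between channels.
Passing tests therefore demonstrate the correctness and calibration of the
estimators under the stated statistical model, not robustness to every
artifact of real microscopy.

## Monte-Carlo taper inference

`simulate_averaged_model_profile()` renders one noisy profile per
experimental microtubule length, fits each with the same erf edge fit used
for data, normalizes, aligns and averages on the half-pixel grid, and
repeats for 50 iterations whose mean is the model profile. Flagged fits are
excluded; an iteration in which every fit is rejected is an error. Fits
whose tip lands more than 500 nm from the steepest intensity drop are also
rejected — a single runaway fit would otherwise truncate the common support
of the whole ensemble average.

`grid_search_taper()` evaluates the sum of squared differences between the
simulated and reference averaged profiles over every $(N, d)$ cell of the
grid (default $N \in 0..13$, $d \in 50..1500$ nm in 50 nm steps — chosen to
bracket both reported erosion regimes, roughly 0.2–0.3 µm and 0.9–1.2 µm).
Because the residual must be comparable across cells, the common-support
SSD is rescaled to the size of the reference support, and a cell whose
simulation covers less than 80% of the reference support scores an infinite
residual; `profile_residual()` itself reports the plain SSD. Each cell uses
an RNG stream derived from the master seed and the cell's $(N, d)$, so
surfaces are bit-reproducible and repeats are honest replicates. The
experimental-profile SEMs do not weight the residual.

The residual surface has a shallow valley along which $N$ and $d$ trade
off; a single search can land one or two cells away from the generating
parameters. The end-to-end recovery experiment therefore repeats the whole
search three times and averages the surfaces before taking the argmin —
the same repeat protocol as the published fits — and `compare_models()`
summarizes repeated searches per model, selecting the lower mean minimal
residual with ties broken toward the structurally simpler Model A.

## Growth variability (MSD)

`fit_msd()` computes the ensemble mean squared displacement of length
increments over all overlapping start points and fits

$$\langle\Delta L^2\rangle(\tau) = v_g^2\tau^2 + 2 D_p \tau + \text{const}.$$

Delays are capped at 25% of the trajectory duration by default (the long-lag
tail of an overlapping-increment MSD is strongly correlated and noisy). The
fit uses generalized least-squares weights $1/(\text{MSD}_k^2\,k)$, the
standard approximation to the relative variance of the MSD estimator at lag
$k$; this matters — the unweighted fit's diffusion coefficient has an order
of magnitude larger sampling variance at these trajectory counts because
the drift term dominates the long lags. `weights = "none"` restores the
unweighted fit. A negative fitted $D_p$ is clamped to zero and flagged.
Per-trajectory diffusion constants (`per_trajectory = TRUE`) are fitted
with the drift speed shared from the ensemble fit, since a 5-minute
trajectory constrains $v_g^2\tau^2$ poorly on its own.

## Event statistics

`segment_piecewise_linear()` finds breakpoints by exact dynamic programming
on per-segment least-squares line costs with a per-segment penalty
(default: a BIC-style $2\hat\sigma^2\log n$ with $\hat\sigma$ from second
differences), then refines each breakpoint locally under a continuous
piecewise-linear (hinge) model, which localizes slope changes to within a
couple of samples at realistic noise. This penalized change-point approach
stands in for multiscale trend analysis used historically for the same
purpose. `classify_events()` labels segments growth / shrinkage / pause by
slope thresholds (default 8.3 nm/s ≈ 0.5 µm/min in both directions — the
thresholds are explicit parameters, since published event calls came from
in-house tooling with unpublished rules), and counts transitions:
growth-or-pause into shrinkage is a catastrophe, shrinkage into
growth-or-pause a rescue. Tip-repair events require a paired lagging-comet
track and are supplied as split/merge intervals.

`frequency_estimates()` divides counts by the time in the relevant phase
(per minute). The catastrophe and repair SE is $f/\sqrt{N}$. The rescue SE
propagates the standard error of the mean shortening time
($SE = f\,SE_{t_{sh}}/\bar t_{sh}$); with $N_r \le 10$ rescues the counts
are treated as Poisson and $SE = f/\sqrt{N_r}$ is used. A calibration test
verifies 90–98% empirical coverage of $f \pm 1.96\,SE$ over hundreds of
simulated ensembles.

## Outgrowth dose-response

`fit_outgrowth_sigmoid()` fits the Hill sigmoid to outgrowth fractions by
iterated generalized least squares with binomial-variance weights
$n_i/(p_i(1-p_i))$ — the least-squares analogue of the binomial likelihood,
noticeably more efficient than seed-count weighting when several
concentrations sit near saturation. $p_{max}$ can be fixed or fitted with
an upper bound of 1. The recovery experiments use eight log-spaced
concentrations spanning 1–12 µM (log spacing is the standard dose-response
design and keeps both published parameter regimes identifiable with one
design).

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed, all randomness flows
through R's RNG (including the compiled Monte-Carlo core), and repeated
calls with the same seed are bit-identical. `run_recovery()` drives the
end-to-end experiments: simulate at the published values as ground truth,
analyse with the package, report the recovered quantity. The experiments
use the published problem sizes (17 profiles and 50 iterations for the
taper search; 88 and 183 trajectories for the MSD fits; the published
per-concentration seed counts; 1000 profiles for the peak-offset
recoveries). Test-suite simulations are smaller (tens of profiles, hundreds
of replicates) — sizes chosen so each check is statistically decisive for
the property it tests.
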