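---
title: "Models and methods behind smvsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smvsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smvsim)
```

smvsim simulates the videos produced by camera-based single-molecule FRET
(smFRET) experiments — surface-immobilised donor/acceptor-labelled
molecules imaged through a TIRF microscope onto an EMCCD — and scores
spot-detection algorithms against the simulated ground truth. This
vignette explains the models, the defaults and the numerical choices, in
the order the pipeline runs them.

## Kinetic model

A molecule switches between `J` conformational states, each with a mean
FRET efficiency, following first-order kinetics with rate matrix
`k[i,j]` (s^-1). Over one camera frame of duration `1/f` the chain has
staying probability `p[i,i] = exp(-sum(k[i,-i])/f)` and the escape mass
`1 - p[i,i]` is split across destinations in proportion to their rates;
a state with no outgoing rates is absorbing (`p[i,i] = 1`). Rows of the
matrix therefore sum to 1 by construction (the summation excludes the
diagonal, which is forced to zero).

Two simulators generate trajectories:

* **Bin-wise** (`simulate_binwise()`): one state per frame, drawn by
  inverse-CDF sampling on the current row. Frames are never mixtures;
  this is the natural choice for kinetics slower than the frame time.
* **Dwell-time** (`simulate_dwelltime()`): kinetic Monte Carlo on the
  continuous time axis. From state `i` the dwell is exponential with the
  total exit rate `sum(k[i,-i])` and the destination is drawn from the
  embedded chain (off-diagonal rates normalised to one). Dwells are
  concatenated until they cover the trace; the last dwell is truncated
  at the trace end. Frames crossed by a transition get a time-weighted
  average FRET value — this is what produces the apparent intermediate
  ("averaged") states seen whenever exchange rates approach or exceed
  the frame rate.

The initial state is the state with the largest staying probability,
ties broken towards the lowest index — a deterministic rule that makes
trajectories reproducible under a fixed seed. Dwells live on the
half-open axis `[0, L/f)` with frame `l` covering `[l/f, (l+1)/f)`;
frame indices are 0-based. Time-weights are computed once per
trajectory (`bin_weights()`) and reused for every quantity derived from
it, so bin averaging is exactly invariant under subdividing a dwell
into sub-dwells of the same state.

Photobleaching truncates trajectories at an exponentially distributed
time with user-set mean. The frame containing the bleach time is
partially lit (scaled by the lit fraction of the bin); `bleach_frame`
records the first fully dark frame.

## Photophysics

With `E(l)` the frame's (possibly time-averaged) FRET efficiency, the
ideal channel intensities are

```
I_DD(l) = I_tot0 * (1 - E(l))        # donor channel
I_DA(l) = I_tot0 * gamma * E(l)      # acceptor channel
```

in photon counts per frame. The gamma factor enters multiplicatively on
the acceptor channel; at `gamma = 1` the intensity-based estimator
`I_DA / (I_DD + I_DA)` inverts the forward model exactly, which the
tests exploit as a round-trip identity. When not set explicitly, gamma
defaults to `(eta_A * QY_A) / (eta_D * QY_D)` from the configured
quantum yields and detection efficiencies (about 1.92 for the default
Cy3/Cy5-like values).

Detected intensities add spectral bleed-through and direct acceptor
excitation on top of the ideal channels:

```
I_DA,det = I_DA + bt_D * I_DD + dE_A * I_tot0
I_DD,det = I_DD + bt_A * I_DA
```

Defaults: `bt_D = 7 %`, `bt_A = 0`, `dE_A = 2 %`,
`I_tot0 = 100 pc/frame`, `eta_D = 0.95`, `eta_A = 0.91`, `QY_D = 0.15`,
`QY_A = 0.3`. Direct excitation uses the donor-side total intensity for
the acceptor as well (no separate acceptor brightness is modelled).

Molecule-to-molecule variability is Gaussian on `I_tot0`, gamma and the
per-state FRET values. Draws are clipped (FRET to `[0, 1]`, intensity
floored at 0, gamma at 0.01) rather than redrawn, so a request for `N`
molecules always yields exactly `N`; clipping is visible in the ground
truth. Per-frame averages use the molecule's *drawn* state FRET values,
preserving heterogeneity through fast-exchange averaging. Triplet
blinking and explicit orientation dynamics are not modelled separately;
they are part of what the Gaussian variability stands in for.

## Imaging

The default geometry is a 512 x 512 sensor with 16 um pixels, 2 x 2
hardware binning and 150-fold magnification, split into donor and
acceptor channels of 256 x 128 superpixels; one superpixel then covers
`2 * 16 / 150 = 0.213 um` in object space. Coordinates are 0-based and
continuous; pixel `(i, j)` covers `[i, i+1) x [j, j+1)`. Molecules are
placed either on a regular lattice (non-overlapping spots, as with
nanopatterned surfaces) or uniformly at random with sub-pixel accuracy;
for a surface density rho the molecule count is
`round(rho * channel object-space area)`.

The PSF is a unit-integral symmetric 2D Gaussian whose pixel values are
the *exact* integral over each pixel (products of `pnorm` differences),
not a centre-point evaluation — sub-pixel position tests are exact this
way. `w_det` is the Gaussian sigma by default (1.5 px), with an optional
FWHM interpretation (`FWHM = 2.355 sigma`) selectable because the two
conventions coexist in the field. Rendering is windowed at 8 sigma; the
neglected mass is below 1e-14, far inside the 1e-8 conservation
tolerance the tests enforce against a quadrature oracle. Focal drift
can optionally broaden the width as
`w * sqrt(1 + (z0(t)/z_scale)^2)` with `z0(t) = m*t + z0`; it is off by
default, and a static scene renders bit-identical frames.

The background follows the excitation profile: either uniform or an
asymmetric 2D Gaussian (widths 60/150 px by default) evaluated at pixel
centres — it varies slowly relative to a pixel, so pixel integration
would change values by less than 1e-3 while costing a quadrature per
pixel. Its amplitude (photons/pixel/frame at the profile maximum) has
no published default; 1 pc/px/frame was chosen once as a typical
TIRF background under the default brightness, and is a plain config
field. Acceptor-channel coordinates equal the donor coordinates within
their channel, plus an optional lateral chromatic offset (default 0).

## Camera noise

Three noise models convert expected photons per pixel into image
counts, sharing the parameter set `eta` (detection efficiency), `g` (EM
gain), `s` (e/image count), `K = g/s`, `sigma_d` (readout noise, in
electrons), `mu_ic_dark` (bias offset) and the clock-induced-charge
(CIC) description:

* **PGN** (`apply_pgn()`): `Poisson(eta*I + CIC)` input electrons, a
  `Gamma(shape = n_ie, scale = g)` EM cascade (zero stays zero; at
  `g = 1` the register is a pass-through, so the chain degenerates to
  exact Poisson statistics), then Gaussian readout noise and the offset
  after division by `s`. The Gamma cascade reproduces the EM
  excess-noise factor: the output variance is `2 K^2 (eta*I + CIC)`
  plus readout terms, about twice the single-K photon-transfer
  relation. The tests check PGN against this exact closed form; the
  single-K relation is exact only for the Normal model.
* **NExpN** (`apply_nexpn()`): a mixture — with probability
  `1 - A_CIC` a Normal with variance equal to its mean (electron
  units), otherwise an exponential CIC spike of scale `tau_CIC` — then
  readout noise and offset. The exponential operates in electron units,
  before division by `s`. Dark frames show the characteristic
  exponential right tail above the Gaussian core.
* **Normal** (`apply_normal()`): the high-signal limit,
  `Normal(mu_ic, sigma_ic^2)` with `mu_ic = mu_ic_dark + K eta mu_ph`
  and `sigma_ic^2 = K^2 sigma_d^2 + sigma_q^2 + K (mu_ic - mu_ic_dark)`.

Quantisation noise `sigma_q` is kept as a field but defaults to 0.
All models round half-to-even (unbiased) and clip to the digitiser
range `[0, 2^BR - 1]` — 16383 counts at the default 14 bit. The SNR
helper implements
`eta mu_ph / sqrt(sigma_d^2 + sigma_q^2/K^2 + eta mu_ph)`, bounded by
the ideal-sensor `sqrt(mu_ph)`.

Default camera parameters (`K = 57.7` ic/e, `mu_ic_dark = 113`,
`sigma_d = 0.067` e, `CIC = 0.02` e, `A_CIC = 0.02`, `tau_CIC = 205`)
describe a realistic back-illuminated EMCCD at gain 300 and are used as
generator settings in the calibration recovery tests; they are not
themselves desk-reproducible measurements.

Two calibration fitters close the loop. `fit_photon_transfer()`
regresses variance on mean over a series of illumination levels
(weights `1/variance^2`, i.e. constant relative error of a sample
variance); the slope is `K`, the lowest-mean point is treated as the
dark frame, and the readout noise follows from the intercept.
`fit_dark_histogram()` fits the NExpN dark mixture by maximum
likelihood — Gaussian core plus an exponentially modified Gaussian
tail, evaluated with a log-erfc formulation for numerical stability —
over a logit/log-transformed parameter space with Nelder-Mead. Seeded
recovery tests hold to 5 % on `K`, 30 % on `A_CIC` and 15 % on
`tau_CIC` at 5e4 dark samples.

## Detection benchmarking

`detect_iss()` is an in-series-screening detector: pick the global
maximum above the intensity threshold, zero its suppression
neighbourhood (`NhoodSize`, odd), repeat until the threshold or the
spot cap is reached. The cap should sit above the true molecule count
so false positives can surface.

`match_greedy()` classifies detections in decreasing-intensity order:
a detection is a true positive if its nearest *unmatched* ground-truth
coordinate lies within the tolerance radius (consuming it), otherwise a
false positive; leftovers are false negatives. This makes
`TP + FN = |GT|` and `TP + FP = |detections|` structural invariants,
verified against a literal re-enactment of the policy on random
instances. Distances run from the detected pixel centre to the
continuous ground-truth coordinate. The default tolerance is
`max(1.5, w_det)` pixels and is always recorded. Scores use the 0/0 = 0
convention, with raw counts reported so other conventions can be
re-derived. Stable-marriage (Gale-Shapley) matching is deliberately out
of scope; the matcher interface accepts external detection tables so
third-party algorithms can be scored.

`optimize_grid()` maps recall, precision and accuracy over a full
`I_thresh x NhoodSize` grid and reports every maximising parameter
combination per measure (the optimum is typically a region, not a
point). `rank_methods()` awards 1..n points per condition and measure,
ties sharing the mean of the tied span.

### The reference benchmark

`benchmark_config()` pins down the standard evaluation scene: 288
molecules on a regular 12 x 24 lattice (10.7 px spacing) in one
256 x 128 channel, PSF sigma 1 px, a static FRET-0.5 state,
`I_tot0 = 40 pc/frame`, default photophysics, uniform background of
1 pc/px/frame per channel, full PGN camera chain, 100 frames at 10 Hz.
`benchmark_spot_detection()` time-averages the video, converts image
counts back to photons, sums the two spatially aligned channels
(molecules are colocalised across channels, so the sum maximises the
usable signal without changing positions) and scans the default
7 x 5 = 35 parameter combinations. Under these conditions the grid
optimum reaches recall = precision = accuracy = 1; the margin is
comfortable (peak pixels around 9-12 pc against a summed background
near 2 pc after averaging), so the result is stable across seeds.

## Reproducibility and I/O

A single integer seed, set once at the start of `simulate_video()`,
drives every stochastic stage; identical configurations and seeds
produce byte-identical TIFF stacks and trace tables. `run_simulation()`
writes the two-channel video (16-bit TIFF for quantised output; 32-bit
float scaled by `2^BR - 1` for expectation stacks, scale recorded),
per-channel trace tables (CSV, rows = frames, columns = molecules), and
a JSON sidecar holding the resolved configuration, package version,
seed, complete per-molecule ground truth and an MD5-checksummed file
inventory — sufficient to re-run the simulation exactly or to audit any
published benchmark video. Configurations are YAML with unknown keys
rejected. The `smvsim` command-line script (installed under
`inst/cli/`) wraps `simulate`, `evaluate` and `calibrate`.

## Problem sizes and limitations

The test suite runs its statistical checks at 1e5 draws (noise-model
moments, occupancy, dwell statistics) and the benchmark at
256 x 128 x 100 frames — sizes chosen so each distributional test has
at least 3-sigma resolution on the quantity it checks while the whole
suite stays interactive.

What passing tests do *not* show: real videos contain fixed-pattern
dark structure, sCMOS-specific per-pixel gain, molecule motion,
aberrations beyond a Gaussian PSF, and acceptor-only bleaching
pathways — all deliberately outside the model. The simulator's
Gaussian cross-sample variability folds several physical mechanisms
(quantum-yield fluctuations, orientation effects) into one knob, so
recovering a configured SD says nothing about which mechanism dominates
in an experiment. ALEX excitation schemes are not simulated.
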