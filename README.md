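# smvsim

Camera-based single-molecule FRET (smFRET) experiments record hundreds of
surface-immobilised donor/acceptor-labelled molecules as noisy grayscale
videos. Evaluating the software that processes such videos — spot
detectors, background estimators, trace extractors — requires data with a
known ground truth, which real recordings cannot provide. **smvsim**
generates such data: it simulates the complete imaging chain from the
molecular kinetics to the digitised camera frames, annotates every output
with its full ground truth, and scores spot-detection algorithms against
it.

The pipeline, for each molecule `n` and frame `l`:

1. **Kinetics** — a Markov chain over `J` FRET states with rate matrix
   `k_ij` (s⁻¹). Per-frame transition probabilities are
   `p_ii = exp(-Σ_{j≠i} k_ij / f)` with the escape mass split by rates.
   Trajectories are simulated bin-wise or dwell-time-wise (kinetic Monte
   Carlo); dwells shorter than a frame yield time-averaged FRET values,
   and an exponential photobleaching time truncates the trace.
2. **Photophysics** — channel intensities
   `I_DD = I_tot,0 (1 − E)`, `I_DA = I_tot,0 γ E` (photon counts/frame),
   plus spectral bleed-through `bt_D/A` and direct acceptor excitation
   `dE_A`. Cross-sample variability is Gaussian on `I_tot,0`, `γ` and the
   state FRET values. The Förster relation
   `E(r, R₀) = 1 / (1 + (r/R₀)⁶)` is available for distance-based setups.
3. **Imaging** — molecules placed on a grid or uniformly at random with
   sub-pixel accuracy in a 256×128-superpixel channel; a unit-mass 2D
   Gaussian PSF integrated exactly over pixels; a uniform or
   Gaussian-profile excitation background.
4. **Camera** — EMCCD noise as Poisson–Gamma–Normal (PGN), its
   Normal–Exponential–Normal (NExpN) approximation with exponential
   clock-induced-charge spikes, or a plain Normal model; linear response
   `μ_ic = μ_ic,dark + K η μ_ph`, photon-transfer variance
   `σ_ic² = K²σ_d² + K(μ_ic − μ_ic,dark)`, and `BR`-bit saturation.
   Calibration fitters recover `K`, `σ_d`, `μ_ic,dark` from a
   photon-transfer series and the CIC mixture from a dark histogram.
5. **Evaluation** — an in-series-screening (ISS) peak detector, greedy
   tolerance-radius matching into TP/FP/FN, `recall = TP/(TP+FN)`,
   `precision = TP/(TP+FP)`, `accuracy = (TP+TN)/(TP+TN+FP+FN)`,
   method-parameter grid optimisation, and method ranking.

## Worked example

Simulate a small two-state video, write it to disk, and score the ISS
detector on the time-averaged image:

```r
library(smvsim)

cfg <- simulation_config(list(
  seed = 42, n_frames = 50,
  kinetics = list(fret_mean = c(0.2, 0.7),
                  rates = rbind(c(0, 1), c(1, 0)), frame_rate = 10),
  photophysics = list(itot_mean = 40),
  imaging = list(layout = list(x_res = 128, y_res = 128, binning = 1),
                 psf = list(w_det_d = 1, w_det_a = 1),
                 background = list(kind = "uniform", bg_d = 1, bg_a = 1),
                 placement = list(mode = "grid", rows = 4, cols = 8))))

sim <- run_simulation(cfg, "example_out")
avg <- ic_to_pc(time_average_video(sim$donor), cfg$cam) +
       ic_to_pc(time_average_video(sim$acceptor), cfg$cam)
res <- optimize_grid(avg, sim$ensemble$params[, c("x", "y")],
                     i_thresh_grid = c(2, 6, 10, 14),
                     nhood_grid = c(3, 5), tol = 1.5)
res$max
#>    recall precision  accuracy
#>         1         1         1
res$scores[res$scores$nhood_size == 3, c(1, 3:8)]
#>  i_thresh  recall precision accuracy tp fp fn
#>         2 1.00000  0.500000 0.500000 32 32  0
#>         6 1.00000  0.969697 0.969697 32  1  0
#>        10 0.21875  1.000000 0.218750  7  0 25
#>        14 0.00000  0.000000 0.000000  0  0 32
```

The table shows the characteristic trade-off: a threshold at the
background level (2 pc here, for a summed background of ~2 pc/px) finds
every molecule but fills the detection cap with false positives; a
threshold above the dimmest time-averaged peak (10 pc) is clean but
blind. In between, and at the wider suppression neighbourhood (where all
three measures reach 1), detection is essentially perfect.
The `metadata.json` sidecar in
`example_out/` carries the resolved configuration, the seed, every
molecule's coordinates, brightness, γ, drawn state FRET values and bleach
frame, plus MD5 checksums of all written files — re-running with the same
seed reproduces every byte.

The command-line wrapper drives the same machinery:

```sh
Rscript inst/cli/smvsim.R simulate -c config.yml -o outdir
Rscript inst/cli/smvsim.R evaluate --video outdir/video.tif \
    --truth outdir/metadata.json --out scores.csv
Rscript inst/cli/smvsim.R calibrate --ptc meanvar.csv --out camera.yml
```

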