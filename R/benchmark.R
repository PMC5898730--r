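#' Configuration of the spot-detection benchmark video
#'
#' Builds the configuration of the reference benchmark: molecules on a
#' regular grid in one 256 x 128 channel, a narrow PSF, a static
#' mid-range FRET state, default photophysics and the full EMCCD noise
#' chain. These are the conditions under which a well-parameterised
#' detector should reach perfect recall, precision and accuracy.
#'
#' @param seed Simulation seed (mandatory).
#' @param itot Total emitted intensity `I_tot,0` (pc/frame; default 40).
#' @param w_det PSF Gaussian width (pixels; default 1).
#' @param n_frames Video length (frames; default 100).
#' @param rows,cols Placement grid (default 12 x 24 = 288 molecules).
#' @param noise_model Camera noise model (default `"pgn"`).
#' @return A resolved `simulation_config`.
#' @export
benchmark_config <- function(seed, itot = 40, w_det = 1, n_frames = 100,
                             rows = 12, cols = 24, noise_model = "pgn") {
  simulation_config(list(
    seed = seed,
    n_frames = n_frames,
    kinetics = list(fret_mean = 0.5, fret_sd = 0,
                    rates = matrix(0, 1, 1), frame_rate = 10,
                    method = "binwise"),
    photophysics = list(itot_mean = itot, itot_sd = 0),
    imaging = list(
      psf = list(w_det_d = w_det, w_det_a = w_det),
      background = list(kind = "uniform", bg_d = 1, bg_a = 1),
      placement = list(mode = "grid", rows = rows, cols = cols)),
    camera = list(noise_model = noise_model)))
}

#' End-to-end spot-detection benchmark on a simulated video
#'
#' Simulates a grid-placed single-molecule video, converts the
#' time-averaged image back to photon units, sums the spatially aligned
#' donor and acceptor channels (molecules are colocalised across
#' channels, so the sum maximises the usable signal), runs the ISS
#' detector over a full grid of intensity thresholds and suppression
#' neighbourhood sizes, matches detections greedily against the
#' ground-truth coordinates within the configured tolerance radius, and
#' reports the score map together with the maxima of recall, precision
#' and accuracy over the grid.
#'
#' @param config A `simulation_config`, typically from
#'   [benchmark_config()].
#' @param i_thresh_grid,nhood_grid Method-parameter grids; default to the
#'   configuration's `evaluation` section (7 thresholds x 5 sizes = 35
#'   combinations).
#' @return List with `scores`, `best`, `max` (see [optimize_grid()]),
#'   plus `gt`, `frame` (the detection image, photon units) and `tol`.
#' @export
benchmark_spot_detection <- function(config,
                                     i_thresh_grid = NULL,
                                     nhood_grid = NULL) {
  if (!inherits(config, "simulation_config"))
    config <- simulation_config(config)
  if (is.null(i_thresh_grid)) i_thresh_grid <- config$evaluation$i_thresh_grid
  if (is.null(nhood_grid)) nhood_grid <- config$evaluation$nhood_grid
  sim <- simulate_video(config)
  in_ic <- !config$cam$noise_model %in% c("none", "poisson")
  avg_d <- time_average_video(sim$donor)
  avg_a <- time_average_video(sim$acceptor)
  if (in_ic) {
    avg_d <- ic_to_pc(avg_d, config$cam)
    avg_a <- ic_to_pc(avg_a, config$cam)
  }
  frame <- avg_d + avg_a
  gt <- sim$ensemble$params[, c("x", "y")]
  tol <- config$evaluation$tolerance
  res <- optimize_grid(frame, gt, i_thresh_grid, nhood_grid, tol,
                       max_spots = 2 * nrow(gt))
  res$gt <- gt
  res$frame <- frame
  res$tol <- tol
  res
}
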