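#' Simulate a two-channel single-molecule video in memory
#'
#' Executes the full pipeline for a resolved configuration: state
#' trajectories (bin-wise or dwell-time kinetic Monte Carlo) with optional
#' photobleaching, per-molecule parameter draws, ideal channel traces,
#' crosstalk, sub-pixel PSF rendering with background, and the configured
#' camera noise model. The global R random number generator is seeded
#' from `config$seed`, so the output is a deterministic function of the
#' configuration.
#'
#' @param config A `simulation_config` (or a list accepted by
#'   [simulation_config()]).
#' @return List with `expected` (the noise-free `photon_video`), `donor`
#'   and `acceptor` (noisy `ny x nx x L` stacks in the units of the noise
#'   model), `traces_detected` (list of per-molecule detected
#'   `intensity_traces`), `ensemble`, and the resolved `config`.
#' @export
simulate_video <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- simulation_config(config)
  set.seed(config$seed)
  L <- config$n_frames
  pl <- config$imaging$placement
  coords <- if (pl$mode == "grid")
    place_grid(pl$rows, pl$cols, config$layout, margin = pl$margin)
  else
    place_random(config$layout, n = pl$n, density = pl$density)
  n <- nrow(coords)
  if (n == 0L) stop("placement produced zero molecules")
  ens <- draw_ensemble(n, config$pair, config$model)
  ens$params$x <- coords$x
  ens$params$y <- coords$y
  simulate_one <- switch(config$kinetics$method,
                         binwise = simulate_binwise,
                         dwelltime = simulate_dwelltime)
  traces <- vector("list", n)
  for (m in seq_len(n)) {
    traj <- simulate_one(config$model, L)
    traj <- apply_bleaching(traj, config$kinetics$tau_bleach)
    tr <- traces_from_states(traj, itot = ens$params$itot[m],
                             gamma = ens$params$gamma[m],
                             state_fret = ens$state_fret[m, ])
    traces[[m]] <- apply_crosstalk(tr, config$pair)
    ens$params$bleach_frame[m] <- if (is.na(traj$bleach_frame))
      NA_integer_ else traj$bleach_frame
  }
  video <- render_video(coords, traces, config$layout, config$psf,
                        config$background,
                        chromatic_offset = config$imaging$chromatic_offset)
  don <- apply_noise(video$donor, config$cam)
  acc <- apply_noise(video$acceptor, config$cam)
  list(expected = video, donor = don, acceptor = acc,
       traces_detected = traces, ensemble = ens, config = config)
}
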