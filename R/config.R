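## Configuration schema: nested sections mirroring the module types.
## Unknown keys are rejected so typos cannot silently fall back to defaults.

config_defaults <- function() {
  list(
    seed = NULL,
    n_frames = 100,
    kinetics = list(
      fret_mean = c(0.2, 0.7),
      fret_sd = c(0, 0),
      rates = rbind(c(0, 1), c(1, 0)),
      frame_rate = 10,
      method = "dwelltime",
      tau_bleach = NULL),
    photophysics = list(
      itot_mean = 100, itot_sd = 0,
      gamma_mean = NULL, gamma_sd = 0,
      bt_d = 0.07, bt_a = 0, de_a = 0.02,
      qy_d = 0.15, qy_a = 0.3, eta_d = 0.95, eta_a = 0.91,
      r0 = NULL),
    imaging = list(
      layout = list(x_res = 512, y_res = 512, d_pix = 16, binning = 2,
                    magnification = 150, split_axis = "y"),
      psf = list(w_det_d = 1.5, w_det_a = 1.5, width_is_fwhm = FALSE,
                 z0_d = 0, z0_a = 0, drift_rate = 0, z_scale = NULL),
      background = list(kind = "gaussian", bg_d = 1, bg_a = 1,
                        w_ex_x = 60, w_ex_y = 150, center = NULL),
      placement = list(mode = "random", density = 0.05, n = NULL,
                       rows = NULL, cols = NULL, margin = 0),
      chromatic_offset = c(0, 0)),
    camera = list(
      eta = 0.95, g = 300, s = NULL, K = 57.7,
      sigma_d = 0.067, mu_ic_dark = 113,
      cic = 0.02, a_cic = 0.02, tau_cic = 205, sigma_q = 0,
      bit_rate = 14, noise_model = "pgn"),
    evaluation = list(
      tolerance = NULL,      # NULL: max(1.5, w_det_d)
      i_thresh_grid = seq(2, 26, by = 4),
      nhood_grid = c(1, 3, 5, 7, 9)))
}

## recursive default filling with unknown-key rejection
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) return(user)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop(sprintf("unknown configuration key%s: %s",
                 if (length(extra) > 1) "s" else "",
                 paste0(path, extra, collapse = ", ")))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "/"))
    else user[[k]]
  }
  defaults
}

#' Build and validate a simulation configuration
#'
#' Fills user-supplied values into the default configuration tree
#' (sections `kinetics`, `photophysics`, `imaging`, `camera`,
#' `evaluation`, plus the global `seed` and `n_frames`), rejects unknown
#' keys, and validates every section by constructing the corresponding
#' module objects. A seed is mandatory: together with the resolved
#' configuration it fully determines every simulated byte.
#'
#' @param config Named list (possibly nested) of overrides, e.g. parsed
#'   from a YAML file via [read_config()].
#' @return A resolved `simulation_config` with the constructed module
#'   objects attached (`$model`, `$pair`, `$layout`, `$psf`,
#'   `$background`, `$cam`).
#' @export
simulation_config <- function(config = list()) {
  cfg <- merge_config(config_defaults(), config)
  if (is.null(cfg$seed))
    stop("a seed is mandatory for reproducible simulations")
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$n_frames < 1) stop("n_frames must be >= 1")
  kin <- cfg$kinetics
  if (is.list(kin$rates)) kin$rates <- do.call(rbind, kin$rates)
  if (!kin$method %in% c("binwise", "dwelltime"))
    stop("kinetics method must be 'binwise' or 'dwelltime'")
  cfg$model <- kinetic_model(kin$fret_mean, kin$rates, kin$frame_rate,
                             kin$fret_sd)
  cfg$kinetics$rates <- cfg$model$rates
  ph <- cfg$photophysics
  cfg$pair <- fret_pair_config(ph$itot_mean, ph$itot_sd, ph$gamma_mean,
                               ph$gamma_sd, ph$bt_d, ph$bt_a, ph$de_a,
                               ph$qy_d, ph$qy_a, ph$eta_d, ph$eta_a, ph$r0)
  im <- cfg$imaging
  cfg$layout <- do.call(field_layout, im$layout)
  cfg$psf <- do.call(psf_model, im$psf)
  cfg$background <- do.call(background_model, im$background)
  if (!im$placement$mode %in% c("grid", "random"))
    stop("placement mode must be 'grid' or 'random'")
  cam <- cfg$camera
  cfg$cam <- camera_model(cam$eta, cam$g, cam$s, cam$K, cam$sigma_d,
                          cam$mu_ic_dark, cam$cic, cam$a_cic, cam$tau_cic,
                          cam$sigma_q, cam$bit_rate, cam$noise_model)
  if (is.null(cfg$evaluation$tolerance))
    cfg$evaluation$tolerance <- max(1.5, im$psf$w_det_d)
  class(cfg) <- "simulation_config"
  cfg
}

#' Read a YAML configuration file
#'
#' @param path Path to a YAML file whose keys follow
#'   [simulation_config()].
#' @return A resolved `simulation_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("configuration file not found: %s", path))
  simulation_config(yaml::read_yaml(path))
}
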