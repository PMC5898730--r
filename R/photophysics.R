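#' Photophysical configuration of a FRET pair
#'
#' Bundles the fluorophore and detection parameters of a donor/acceptor
#' pair: quantum yields, channel detection efficiencies, the gamma
#' correction factor (with cross-sample SD), spectral bleed-through
#' fractions, the direct-acceptor-excitation fraction, and the total
#' emitted donor-side intensity `I_tot,0` (photon counts per frame, with
#' cross-sample SD). Defaults are typical Cy3/Cy5 values; if `gamma_mean`
#' is omitted it is derived from the yields and efficiencies as
#' `(eta_a * qy_a) / (eta_d * qy_d)`.
#'
#' @param itot_mean,itot_sd Total emitted donor-side intensity `I_tot,0`
#'   and its cross-sample SD (pc/frame).
#' @param gamma_mean,gamma_sd Gamma correction factor and cross-sample SD.
#' @param bt_d Donor bleed-through fraction into the acceptor channel.
#' @param bt_a Acceptor bleed-through fraction into the donor channel.
#' @param de_a Direct acceptor excitation, as a fraction of `I_tot,0`.
#' @param qy_d,qy_a Donor/acceptor fluorescence quantum yields.
#' @param eta_d,eta_a Donor/acceptor channel detection efficiencies.
#' @param r0 Foerster radius in nm (optional, only used by
#'   [fret_efficiency()]).
#' @return An object of class `fret_pair_config`.
#' @export
fret_pair_config <- function(itot_mean = 100, itot_sd = 0,
                             gamma_mean = NULL, gamma_sd = 0,
                             bt_d = 0.07, bt_a = 0, de_a = 0.02,
                             qy_d = 0.15, qy_a = 0.3,
                             eta_d = 0.95, eta_a = 0.91,
                             r0 = NULL) {
  for (fr in c(bt_d = bt_d, bt_a = bt_a, de_a = de_a))
    if (fr < 0 || fr > 1) stop("crosstalk fractions must lie in [0, 1]")
  if (itot_mean <= 0) stop("itot_mean must be positive")
  if (itot_sd < 0 || gamma_sd < 0) stop("SDs must be >= 0")
  if (any(c(eta_d, eta_a) <= 0) || any(c(eta_d, eta_a) > 1))
    stop("detection efficiencies must lie in (0, 1]")
  if (is.null(gamma_mean)) gamma_mean <- (eta_a * qy_a) / (eta_d * qy_d)
  if (gamma_mean <= 0) stop("gamma_mean must be positive")
  structure(
    list(itot_mean = itot_mean, itot_sd = itot_sd,
         gamma_mean = gamma_mean, gamma_sd = gamma_sd,
         bt_d = bt_d, bt_a = bt_a, de_a = de_a,
         qy_d = qy_d, qy_a = qy_a, eta_d = eta_d, eta_a = eta_a,
         r0 = r0),
    class = "fret_pair_config")
}

#' FRET efficiency from the Foerster relation
#'
#' `E(r, R0) = 1 / (1 + (r/R0)^6)`: the transfer efficiency falls with the
#' inverse sixth power of the inter-dye distance and equals 1/2 at the
#' Foerster radius.
#'
#' @param r Inter-dye distance (nm, > 0); vectorised.
#' @param r0 Foerster radius (nm, > 0).
#' @return Efficiency in (0, 1], strictly decreasing in `r`.
#' @examples
#' fret_efficiency(5, 5)    # 0.5
#' fret_efficiency(10, 5)   # 1/65
#' @export
fret_efficiency <- function(r, r0) {
  if (any(r <= 0)) stop("distance r must be positive")
  if (length(r0) != 1L || r0 <= 0) stop("Foerster radius r0 must be positive")
  1 / (1 + (r / r0)^6)
}

#' Apparent FRET efficiency from channel intensities
#'
#' The intensity-based estimator `I_DA / (I_DD + I_DA)` applied frame-wise.
#' On noiseless, crosstalk-free, gamma = 1 traces it inverts
#' [traces_from_states()] exactly.
#'
#' @param i_dd Donor-channel intensity trace (pc/frame).
#' @param i_da Acceptor-channel intensity trace (pc/frame).
#' @return Apparent FRET per frame; frames with zero total intensity give
#'   `NA`.
#' @export
fret_apparent <- function(i_dd, i_da) {
  tot <- i_dd + i_da
  ifelse(tot > 0, i_da / tot, NA_real_)
}

#' Draw per-molecule photophysical parameters
#'
#' Cross-sample variability is modelled as Gaussian: each molecule draws
#' its total intensity `I_tot,0`, its gamma factor, and its per-state FRET
#' values around the configured means. Draws are clipped rather than
#' redrawn (FRET to `[0, 1]`, intensity floored at 0, gamma floored at
#' 0.01) so the sample size is deterministic.
#'
#' @param n Number of molecules.
#' @param pair A [fret_pair_config()].
#' @param model A [kinetic_model()] (supplies per-state FRET means/SDs).
#' @return A `molecule_ensemble`: data frame `params` with columns
#'   `index`, `x`, `y`, `itot`, `gamma`, `bleach_frame` and a `n x J`
#'   matrix `state_fret` of drawn per-state FRET values.
#' @export
draw_ensemble <- function(n, pair, model) {
  stopifnot(n >= 1)
  itot <- pmax(stats::rnorm(n, pair$itot_mean, pair$itot_sd), 0)
  gam <- pmax(stats::rnorm(n, pair$gamma_mean, pair$gamma_sd), 0.01)
  sf <- matrix(stats::rnorm(n * model$J,
                            mean = rep(model$fret_mean, each = n),
                            sd = rep(model$fret_sd, each = n)),
               n, model$J)
  sf <- pmin(pmax(sf, 0), 1)
  structure(
    list(params = data.frame(index = seq_len(n), x = NA_real_, y = NA_real_,
                             itot = itot, gamma = gam,
                             bleach_frame = NA_integer_),
         state_fret = sf),
    class = "molecule_ensemble")
}

#' Ideal donor/acceptor intensity traces of one molecule
#'
#' Converts a state trajectory into per-frame channel intensities using the
#' molecule's drawn parameters: with `E_l` the dwell-weighted average of
#' the molecule's own per-state FRET values in frame `l`,
#' `I_DD = itot * (1 - E_l)` and `I_DA = itot * gamma * E_l`. Frames at or
#' after the bleach time are zero; the frame containing the bleach time is
#' scaled by the lit fraction of the bin.
#'
#' @param traj A `state_trajectory`.
#' @param itot Total emitted intensity of the molecule (pc/frame).
#' @param gamma Gamma correction factor of the molecule.
#' @param state_fret Drawn per-state FRET values (length `J`); defaults to
#'   the model means.
#' @return An `intensity_traces` object: vectors `i_dd`, `i_da`, the
#'   per-frame lit fraction `alive`, and `itot`.
#' @export
traces_from_states <- function(traj, itot, gamma = 1, state_fret = NULL) {
  stopifnot(inherits(traj, "state_trajectory"))
  if (is.null(state_fret)) state_fret <- traj$model$fret_mean
  if (length(state_fret) != traj$model$J)
    stop("state_fret length does not match the number of states")
  e <- as.numeric(traj$weights %*% state_fret)
  alive <- alive_fraction(traj)
  i_dd <- itot * (1 - e) * alive
  i_da <- itot * gamma * e * alive
  structure(list(i_dd = i_dd, i_da = i_da, alive = alive, itot = itot),
            class = "intensity_traces")
}

#' Apply spectral crosstalk and direct acceptor excitation
#'
#' Maps ideal channel intensities to detected ones: the acceptor channel
#' gains the donor bleed-through `bt_d * I_DD` and the direct-excitation
#' term `de_a * itot` (on the lit part of each frame); the donor channel
#' gains the acceptor bleed-through `bt_a * I_DA`.
#'
#' @param traces An `intensity_traces` object.
#' @param pair A [fret_pair_config()].
#' @return An `intensity_traces` object with detected intensities.
#' @export
apply_crosstalk <- function(traces, pair) {
  stopifnot(inherits(traces, "intensity_traces"))
  det_da <- traces$i_da + pair$bt_d * traces$i_dd +
    pair$de_a * traces$itot * traces$alive
  det_dd <- traces$i_dd + pair$bt_a * traces$i_da
  structure(list(i_dd = det_dd, i_da = det_da, alive = traces$alive,
                 itot = traces$itot),
            class = "intensity_traces")
}
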