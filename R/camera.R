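#' EMCCD camera model
#'
#' Parameters of the detector chain: detection efficiency `eta`, EM gain
#' `g` (output electrons per input electron), amplifier sensitivity `s`
#' (electrons per image count) and the overall system gain `K = g / s`
#' (image counts per photoelectron); readout noise `sigma_d` (electrons),
#' bias offset `mu_ic_dark` (image counts), clock-induced charge as either
#' a Poisson mean `cic` (electrons/pixel/frame, used by the PGN model) or
#' an exponential mixture (`a_cic`, `tau_cic`, used by the NExpN model),
#' the digitiser bit rate, and the noise model applied by
#' [apply_noise()]. Exactly two of `g`, `s`, `K` determine the third;
#' supplying all three requires consistency.
#'
#' Defaults follow a photon-transfer and dark-frame characterisation of a
#' back-illuminated EMCCD at EM gain 300 (`K = 57.7` ic/e,
#' `mu_ic_dark = 113` ic, `sigma_d = 0.067` e, `cic = 0.02` e,
#' `a_cic = 0.02`, `tau_cic = 205`).
#'
#' @param eta Detection efficiency in (0, 1].
#' @param g EM gain (e/e).
#' @param s Amplifier sensitivity (e per image count).
#' @param K Overall system gain (image counts per photoelectron).
#' @param sigma_d Readout noise SD in electrons.
#' @param mu_ic_dark Bias offset in image counts.
#' @param cic Mean spurious charge (electrons/pixel/frame), PGN model.
#' @param a_cic,tau_cic CIC mixture weight and exponential scale
#'   (electrons), NExpN model.
#' @param sigma_q Quantisation noise (image counts); kept for completeness
#'   of the variance and SNR relations, 0 by default.
#' @param bit_rate Digitiser bit rate `BR` (bits, >= 1).
#' @param noise_model One of `"none"`, `"poisson"`, `"pgn"`, `"nexpn"`,
#'   `"normal"`.
#' @return A `camera_model`.
#' @export
camera_model <- function(eta = 0.95, g = 300, s = NULL, K = 57.7,
                         sigma_d = 0.067, mu_ic_dark = 113,
                         cic = 0.02, a_cic = 0.02, tau_cic = 205,
                         sigma_q = 0, bit_rate = 14,
                         noise_model = c("pgn", "nexpn", "normal",
                                         "poisson", "none")) {
  noise_model <- match.arg(noise_model)
  given <- c(g = !is.null(g), s = !is.null(s), K = !is.null(K))
  if (sum(given) < 2L) stop("give at least two of g, s, K")
  if (is.null(s)) s <- g / K
  else if (is.null(K)) K <- g / s
  else if (is.null(g)) g <- K * s
  else if (abs(K - g / s) > 1e-9 * K) stop("inconsistent g, s, K: K must equal g/s")
  if (eta <= 0 || eta > 1) stop("eta must lie in (0, 1]")
  if (any(c(g, s, K) <= 0)) stop("g, s, K must be positive")
  if (any(c(sigma_d, mu_ic_dark, cic, a_cic, tau_cic, sigma_q) < 0))
    stop("noise parameters must be >= 0")
  if (a_cic > 1) stop("a_cic is a mixture weight and must be <= 1")
  if (bit_rate < 1) stop("bit_rate must be >= 1")
  structure(
    list(eta = eta, g = g, s = s, K = K, sigma_d = sigma_d,
         mu_ic_dark = mu_ic_dark, cic = cic, a_cic = a_cic,
         tau_cic = tau_cic, sigma_q = sigma_q, bit_rate = bit_rate,
         noise_model = noise_model),
    class = "camera_model")
}

#' Photon shot noise
#'
#' Independent Poisson draw per pixel with the pixel's expected photon
#' count as mean.
#'
#' @param frame Matrix/array of expected photon counts (>= 0).
#' @return Integer-valued object of the same shape.
#' @export
shot_noise <- function(frame) {
  if (any(frame < 0)) stop("photon expectations must be >= 0")
  out <- stats::rpois(length(frame), frame)
  array(out, dim = dim(frame) %||% length(frame))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Poisson-Gamma-Normal EMCCD noise
#'
#' The full stochastic detector chain: input electrons
#' `n_ie ~ Poisson(eta * I + CIC)`, electron-multiplication output
#' `n_oe ~ Gamma(shape = n_ie, scale = g)` (0 when `n_ie = 0`), and
#' digitisation `n_ic ~ Normal(mu_ic_dark + n_oe / s, K * sigma_d)`
#' rounded to integer image counts. The Gamma cascade reproduces the EM
#' excess-noise factor (about doubled variance at large gain). At unit
#' gain the EM register is a pass-through (`n_oe = n_ie`), so the chain
#' degenerates to plain Poisson statistics.
#'
#' @param frame Matrix/array of expected photon counts per pixel.
#' @param cam A [camera_model()].
#' @return Integer image-count frame of the same shape.
#' @export
apply_pgn <- function(frame, cam) {
  if (any(frame < 0)) stop("photon expectations must be >= 0")
  n <- length(frame)
  n_ie <- stats::rpois(n, cam$eta * as.numeric(frame) + cam$cic)
  if (cam$g == 1) {
    n_oe <- n_ie                   # EM register off: no amplification noise
  } else {
    n_oe <- numeric(n)
    pos <- n_ie > 0L
    if (any(pos)) n_oe[pos] <- stats::rgamma(sum(pos), shape = n_ie[pos],
                                             scale = cam$g)
  }
  ic <- stats::rnorm(n, mean = cam$mu_ic_dark + n_oe / cam$s,
                     sd = cam$K * cam$sigma_d)
  array(round(ic), dim = dim(frame) %||% n)
}

#' Normal-Exponential-Normal EMCCD noise
#'
#' Approximates the PGN chain: with probability `1 - a_cic` the amplified
#' signal (in electrons) is `Normal(mean = eta * I * g, variance = mean)`,
#' otherwise an exponential clock-induced-charge spike of scale `tau_cic`;
#' the result is divided by the sensitivity `s`, and readout noise
#' (`K * sigma_d` image counts) plus the bias offset are added before
#' rounding.
#'
#' @inheritParams apply_pgn
#' @return Integer image-count frame of the same shape.
#' @export
apply_nexpn <- function(frame, cam) {
  if (any(frame < 0)) stop("photon expectations must be >= 0")
  if (cam$a_cic > 1) stop("a_cic must be <= 1")
  n <- length(frame)
  mu_oe <- cam$eta * as.numeric(frame) * cam$g
  spike <- stats::runif(n) < cam$a_cic
  v <- stats::rnorm(n, mean = mu_oe, sd = sqrt(mu_oe))
  if (any(spike)) v[spike] <- stats::rexp(sum(spike), rate = 1 / cam$tau_cic)
  ic <- v / cam$s +
    stats::rnorm(n, mean = cam$mu_ic_dark, sd = cam$K * cam$sigma_d)
  array(round(ic), dim = dim(frame) %||% n)
}

#' Plain Normal camera noise
#'
#' High-signal limit: each pixel is drawn from a Normal distribution with
#' mean [pc_to_ic()] and variance [variance_model()], then rounded.
#'
#' @inheritParams apply_pgn
#' @return Integer image-count frame of the same shape.
#' @export
apply_normal <- function(frame, cam) {
  if (any(frame < 0)) stop("photon expectations must be >= 0")
  mu_ic <- pc_to_ic(as.numeric(frame), cam)
  ic <- stats::rnorm(length(frame), mean = mu_ic,
                     sd = sqrt(variance_model(mu_ic, cam)))
  array(round(ic), dim = dim(frame) %||% length(frame))
}

#' Apply the configured noise model and digitise
#'
#' Dispatches on `cam$noise_model` (`"none"` returns the expectation frame
#' unchanged and unquantised; `"poisson"` is photon shot noise only, in
#' photon units) and applies [quantize_saturate()] to the camera models.
#'
#' @inheritParams apply_pgn
#' @return Frame in image counts (pgn/nexpn/normal), photons (poisson), or
#'   expected photons (none).
#' @export
apply_noise <- function(frame, cam) {
  switch(cam$noise_model,
         none = frame,
         poisson = shot_noise(frame),
         pgn = quantize_saturate(apply_pgn(frame, cam), cam),
         nexpn = quantize_saturate(apply_nexpn(frame, cam), cam),
         normal = quantize_saturate(apply_normal(frame, cam), cam))
}

#' Convert mean photon counts to mean image counts
#'
#' `mu_ic = mu_ic_dark + K * eta * mu_ph`: the linear detector response.
#'
#' @param mu_ph Mean photon counts (>= 0); vectorised.
#' @param cam A [camera_model()].
#' @return Mean image counts.
#' @export
pc_to_ic <- function(mu_ph, cam) {
  cam$mu_ic_dark + cam$K * cam$eta * mu_ph
}

#' Convert mean image counts back to mean photon counts
#'
#' Inverse of [pc_to_ic()].
#'
#' @param mu_ic Mean image counts; vectorised.
#' @param cam A [camera_model()].
#' @return Mean photon counts.
#' @export
ic_to_pc <- function(mu_ic, cam) {
  (mu_ic - cam$mu_ic_dark) / (cam$K * cam$eta)
}

#' Image-count variance of the camera signal
#'
#' The photon-transfer relation
#' `sigma_ic^2 = K^2 sigma_d^2 + sigma_q^2 + K (mu_ic - mu_ic_dark)`:
#' readout and quantisation noise plus shot noise amplified by the system
#' gain. Valid above the bias offset.
#'
#' @param mu_ic Mean image counts (>= `mu_ic_dark`); vectorised.
#' @param cam A [camera_model()].
#' @return Variance in image counts squared.
#' @export
variance_model <- function(mu_ic, cam) {
  if (any(mu_ic < cam$mu_ic_dark - 1e-9))
    stop("mu_ic below the bias offset mu_ic_dark")
  cam$K^2 * cam$sigma_d^2 + cam$sigma_q^2 + cam$K * (mu_ic - cam$mu_ic_dark)
}

#' Signal-to-noise ratio of the camera signal
#'
#' `SNR = eta mu_ph / sqrt(sigma_d^2 + sigma_q^2 / K^2 + eta mu_ph)`.
#' An ideal sensor (`eta = 1`, `sigma_d = sigma_q = 0`) gives
#' `sqrt(mu_ph)`, the shot-noise limit that bounds every configuration.
#'
#' @param mu_ph Mean photon counts (>= 0); vectorised.
#' @param cam A [camera_model()].
#' @return Unitless SNR (0 at zero signal).
#' @export
snr <- function(mu_ph, cam) {
  if (any(mu_ph < 0)) stop("mu_ph must be >= 0")
  sig <- cam$eta * mu_ph
  den <- sqrt(cam$sigma_d^2 + cam$sigma_q^2 / cam$K^2 + sig)
  ifelse(sig > 0, sig / den, 0)
}

#' Round and clip a frame to the digitiser range
#'
#' Values are rounded half-to-even and clipped to `[0, 2^BR - 1]`, the
#' saturation ceiling of a `BR`-bit digitiser (16383 counts at 14 bit).
#'
#' @param frame Numeric frame.
#' @param cam A [camera_model()] (supplies `bit_rate`).
#' @return Integer-valued frame within the digitiser range.
#' @export
quantize_saturate <- function(frame, cam) {
  ceiling_ic <- 2^cam$bit_rate - 1
  out <- pmin(pmax(round(frame), 0), ceiling_ic)
  array(out, dim = dim(frame) %||% length(frame))
}
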