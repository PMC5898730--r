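#' Photon-transfer calibration of the system gain
#'
#' Estimates the overall system gain `K`, the readout noise `sigma_d` and
#' the bias offset `mu_ic_dark` from a photon-transfer series: per-pixel
#' temporal means and variances of the image-count signal recorded at
#' several illumination levels. The photon-transfer relation
#' `sigma_ic^2 = (K^2 sigma_d^2 - K mu_ic_dark) + K mu_ic` is linear in
#' the mean, so a weighted least-squares line yields `K` from the slope;
#' the lowest-mean point is treated as the dark frame and supplies
#' `mu_ic_dark`, from which `sigma_d` follows from the intercept.
#'
#' @param mean_series Mean image counts at each illumination level
#'   (length >= 3, spanning a range).
#' @param variance_series Corresponding image-count variances.
#' @param weights Regression weights; defaults to `1 / variance^2`
#'   (constant relative error of a sample variance).
#' @return List with elements `K`, `mu_ic_dark`, `sigma_d` and a data
#'   frame `se` of standard errors for slope and intercept.
#' @export
fit_photon_transfer <- function(mean_series, variance_series,
                                weights = NULL) {
  if (length(mean_series) != length(variance_series))
    stop("mean and variance series must have equal length")
  if (length(mean_series) < 3L)
    stop("at least 3 (mean, variance) pairs are required")
  if (diff(range(mean_series)) <= 0)
    stop("degenerate series: means do not span a range of illuminations")
  if (is.null(weights)) weights <- 1 / pmax(variance_series, 1e-12)^2
  fit <- stats::lm(variance_series ~ mean_series, weights = weights)
  co <- stats::coef(fit)
  K <- unname(co[2])
  if (K <= 0) stop("non-positive fitted slope: series is not a photon-transfer curve")
  mu_dark <- mean_series[which.min(mean_series)]
  sd2 <- (unname(co[1]) + K * mu_dark) / K^2
  list(K = K, mu_ic_dark = mu_dark,
       sigma_d = sqrt(max(sd2, 0)),
       se = data.frame(term = c("intercept", "slope"),
                       se = suppressWarnings(      # exact fits have zero RSS
                         unname(sqrt(diag(stats::vcov(fit)))))))
}

## internal: log density of an exponentially modified Gaussian
## (Normal(mu, sigma) + Exp(scale tau)), numerically stable via log-erfc.
dexpgauss_log <- function(x, mu, sigma, tau) {
  z <- (mu + sigma^2 / tau - x) / (sqrt(2) * sigma)
  -log(tau) + (mu - x) / tau + sigma^2 / (2 * tau^2) +
    log(2) + stats::pnorm(z * sqrt(2), lower.tail = FALSE, log.p = TRUE) -
    log(2)
}

#' Fit the NExpN model to a dark-frame histogram
#'
#' Maximum-likelihood fit of the dark-signal mixture to raw dark-pixel
#' image counts: with probability `1 - a_cic` a pixel carries only the
#' Gaussian readout core (`Normal(mu_ic_dark, K sigma_d)`), otherwise an
#' exponential clock-induced-charge spike convolved with the same
#' readout Gaussian (an exponentially modified Gaussian tail). Returns
#' the mixture weight, the exponential scale, and the core parameters;
#' electron-unit equivalents are attached when a camera model supplies
#' `K` and `s`.
#'
#' @param counts Vector of dark-pixel image counts (>= 1e4 recommended).
#' @param cam Optional [camera_model()] used only to convert the fitted
#'   image-count scales back to electron units (`sigma_d`, `tau_cic`).
#' @return List with `a_cic`, `tau_cic_ic` (image counts), `mu_ic_dark`,
#'   `sigma_ic` (image counts), `convergence`, and, when `cam` is given,
#'   `tau_cic` and `sigma_d` in electrons.
#' @export
fit_dark_histogram <- function(counts, cam = NULL) {
  if (length(counts) == 0L) stop("empty dark-count input")
  mu0 <- stats::median(counts)
  sd0 <- stats::mad(counts)
  if (sd0 <= 0) sd0 <- max(stats::sd(counts), 1e-3)
  tail0 <- max(mean(pmax(counts - mu0, 0)[counts > mu0 + 3 * sd0]), 5 * sd0)
  nll <- function(par) {
    a <- stats::plogis(par[1])
    mu <- par[2]; sigma <- exp(par[3]); tau <- exp(par[4])
    lg <- stats::dnorm(counts, mu, sigma, log = TRUE)
    le <- dexpgauss_log(counts, mu, sigma, tau)
    m <- pmax(lg, le)
    -sum(m + log((1 - a) * exp(lg - m) + a * exp(le - m)))
  }
  start <- c(stats::qlogis(0.02), mu0, log(sd0), log(tail0))
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  if (opt$convergence != 0)
    warning(sprintf("dark-histogram fit did not fully converge (code %d, nll %.3f)",
                    opt$convergence, opt$value))
  res <- list(a_cic = stats::plogis(opt$par[1]),
              mu_ic_dark = opt$par[2],
              sigma_ic = exp(opt$par[3]),
              tau_cic_ic = exp(opt$par[4]),
              convergence = opt$convergence,
              logLik = -opt$value)
  if (!is.null(cam)) {
    res$sigma_d <- res$sigma_ic / cam$K
    res$tau_cic <- res$tau_cic_ic * cam$s
  }
  res
}
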