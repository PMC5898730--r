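cam_default <- function(...) camera_model(...)

test_that("the camera model ties K = g/s and validates its parameters", {
  cam <- camera_model(g = 300, K = 57.7, s = NULL)
  expect_equal(cam$s, 300 / 57.7)
  cam2 <- camera_model(g = 300, s = 5, K = NULL)
  expect_equal(cam2$K, 60)
  expect_error(camera_model(g = 300, s = 5, K = 57.7), "K must equal g/s")
  expect_error(camera_model(eta = 1.2), "eta")
  expect_error(camera_model(a_cic = 1.5), "a_cic")
})

test_that("photon shot noise has Poisson moments and independent pixels", {
  expect_equal(shot_noise(matrix(0, 3, 3)), matrix(0, 3, 3))
  set.seed(401)
  draws <- shot_noise(array(100, c(1e5)))
  se_mean <- sqrt(100 / 1e5)
  expect_lt(abs(mean(draws) - 100), 3 * se_mean)
  se_var <- stats::sd((draws - 100)^2) / sqrt(1e5)
  expect_lt(abs(stats::var(draws) - 100), 3 * se_var)
  two <- matrix(shot_noise(array(50, c(2e5))), ncol = 2)
  expect_lt(abs(stats::cor(two[, 1], two[, 2])), 0.01)
  expect_error(shot_noise(matrix(-1, 2, 2)), ">= 0")
})

test_that("PGN dark pixels centre on the offset plus amplified spurious charge", {
  set.seed(402)
  cam <- camera_model()   # K = 57.7, dark = 113, CIC = 0.02
  draws <- apply_pgn(array(0, 5e4), cam)
  expected <- 113 + 57.7 * 0.02
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("the PGN mean follows the law of total expectation", {
  set.seed(403)
  cam <- camera_model(sigma_d = 0, cic = 0)
  mu <- 20
  draws <- apply_pgn(array(mu, 1e5), cam)
  expected <- cam$mu_ic_dark + cam$K * cam$eta * mu
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("PGN variance matches its exact closed form (EM excess noise included)", {
  set.seed(404)
  cam <- camera_model()
  mu <- 50
  draws <- apply_pgn(array(mu, 1e5), cam)
  lam <- cam$eta * mu + cam$cic
  v_expect <- 2 * cam$K^2 * lam + cam$K^2 * cam$sigma_d^2 + 1 / 12
  expect_lt(abs(stats::var(draws) - v_expect) / v_expect, 0.05)
})

test_that("degenerate PGN parameters reduce to pure Poisson statistics", {
  set.seed(405)
  cam <- camera_model(g = 1, s = 1, K = NULL, sigma_d = 0, cic = 0,
                      mu_ic_dark = 0)
  mu <- 7
  draws <- apply_pgn(array(mu, 1e5), cam)
  expect_true(all(draws >= 0 & draws == round(draws)))
  # with the EM register off the chain is exactly Poisson(eta * mu)
  lam <- cam$eta * mu
  expect_lt(abs(mean(draws) - lam), 3 * sqrt(lam / 1e5))
  se_var <- stats::sd((draws - lam)^2) / sqrt(1e5)
  expect_lt(abs(stats::var(draws) - lam), 3 * se_var)
  p_ks <- suppressWarnings(
    stats::ks.test(draws, stats::rpois(1e5, lam)))$p.value
  expect_gt(p_ks, 0.01)
})

test_that("NExpN reproduces the mixture moments and the CIC tail", {
  cam <- camera_model()
  # mixture mean: (1-a) * eta I g / s + a * tau / s + dark
  set.seed(406)
  mu <- 30
  draws <- apply_nexpn(array(mu, 1e5), cam)
  m_expect <- (1 - cam$a_cic) * cam$eta * mu * cam$g / cam$s +
    cam$a_cic * cam$tau_cic / cam$s + cam$mu_ic_dark
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - m_expect), 3 * se)

  # dark frame: exponential right tail above the Gaussian core
  set.seed(407)
  dark <- apply_nexpn(array(0, 5e4), cam)
  sigma_core <- cam$K * cam$sigma_d
  n_above <- sum(dark > cam$mu_ic_dark + 6 * sigma_core)
  # Gaussian-only expectation is ~ 5e4 * 1e-9; the CIC tail dominates
  expect_gt(n_above, 0.5 * cam$a_cic * 5e4 *
              exp(-6 * sigma_core / (cam$tau_cic / cam$s)))
  expect_gt(n_above, 50)

  # weight degeneracy: a_cic = 0 at large signal equals the Normal model
  set.seed(408)
  cam0 <- camera_model(a_cic = 0)
  mu2 <- 200
  d_nexpn <- apply_nexpn(array(mu2, 1e5), cam0)
  m_norm <- pc_to_ic(mu2, cam0)
  se2 <- stats::sd(d_nexpn) / sqrt(1e5)
  expect_lt(abs(mean(d_nexpn) - m_norm), 3 * se2)
})

test_that("the Normal model matches the linear mean and variance relations", {
  set.seed(409)
  cam <- camera_model(noise_model = "normal")
  mu <- 80
  draws <- apply_normal(array(mu, 1e5), cam)
  m_expect <- pc_to_ic(mu, cam)
  v_expect <- variance_model(m_expect, cam) + 1 / 12   # + rounding variance
  se_m <- sqrt(v_expect / 1e5)
  expect_lt(abs(mean(draws) - m_expect), 3 * se_m)
  se_v <- stats::sd((draws - m_expect)^2) / sqrt(1e5)
  expect_lt(abs(stats::var(draws) - v_expect), 3 * se_v)

  # zero signal, zero readout noise: every draw sits at the offset
  cam0 <- camera_model(sigma_d = 0)
  expect_true(all(apply_normal(array(0, 100), cam0) == cam0$mu_ic_dark))

  # variance grows linearly in the signal
  v <- variance_model(pc_to_ic(c(0, 10, 20), cam), cam)
  expect_true(all(diff(v) > 0))
  expect_equal(diff(v), rep(cam$K^2 * cam$eta * 10, 2), tolerance = 1e-9)
})

test_that("photon/image-count conversion is the linear detector response", {
  cam <- camera_model()
  expect_equal(pc_to_ic(0, cam), 113)
  cam2 <- camera_model(eta = 0.95, K = 57.7, g = 300, mu_ic_dark = 113)
  expect_equal(pc_to_ic(100, cam2), 113 + 57.7 * 95)
  x <- c(0, 1.7, 42, 1e4)
  expect_equal(ic_to_pc(pc_to_ic(x, cam), cam), x, tolerance = 1e-12)
})

test_that("the photon-transfer variance relation evaluates correctly", {
  cam <- camera_model(K = 57.7, g = 300, sigma_d = 0.067)
  expect_equal(variance_model(cam$mu_ic_dark, cam), 57.7^2 * 0.067^2)
  expect_equal(variance_model(cam$mu_ic_dark + 1000, cam),
               57.7^2 * 0.067^2 + 57.7 * 1000)
  expect_error(variance_model(0, cam), "below")
})

test_that("SNR reaches the ideal square-root bound only for a perfect sensor", {
  ideal <- camera_model(eta = 1, sigma_d = 0, sigma_q = 0)
  expect_equal(snr(100, ideal), 10)
  cam <- camera_model()
  expect_identical(snr(0, cam), 0)
  mu <- c(0.5, 1, 5, 10, 100, 1000)
  expect_true(all(diff(snr(mu, cam)) > 0))
  expect_true(all(snr(mu, cam) <= sqrt(mu)))
})

test_that("quantisation rounds half-to-even and saturates at the bit ceiling", {
  cam <- camera_model(bit_rate = 14)
  expect_equal(as.numeric(quantize_saturate(20000, cam)), 16383)
  expect_equal(as.numeric(quantize_saturate(-3.2, cam)), 0)
  expect_equal(as.numeric(quantize_saturate(100.4, cam)), 100)
  expect_equal(as.numeric(quantize_saturate(c(0.5, 1.5, 2.5), cam)),
               c(0, 2, 2))
})
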