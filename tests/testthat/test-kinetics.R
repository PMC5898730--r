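test_that("per-frame transition probabilities follow the rate-matrix closed form", {
  m <- two_state_model(k12 = 1, k21 = 1, f = 10)
  M <- build_transition_matrix(m)
  expect_equal(diag(M), rep(exp(-0.1), 2))
  expect_equal(M[1, 2], 1 - exp(-0.1))
  expect_equal(rowSums(M), c(1, 1), tolerance = 1e-12)

  # no transitions: identity
  m0 <- kinetic_model(c(0.1, 0.5, 0.9), matrix(0, 3, 3), 10)
  expect_equal(build_transition_matrix(m0), diag(3))

  # arbitrary positive rates stay row-stochastic
  set.seed(11)
  for (rep in 1:20) {
    J <- sample(2:5, 1)
    k <- matrix(stats::runif(J * J, 0, 50), J, J)
    m3 <- kinetic_model(stats::runif(J), k, stats::runif(1, 1, 100))
    M3 <- build_transition_matrix(m3)
    expect_equal(rowSums(M3), rep(1, J), tolerance = 1e-12)
    expect_true(all(M3 >= 0 & M3 <= 1))
  }
})

test_that("invalid kinetic models are rejected with the offending entry named", {
  expect_error(kinetic_model(c(0.2, 0.7), rbind(c(0, -1), c(1, 0)), 10),
               "k\\[1,2\\]")
  expect_error(kinetic_model(0.5, matrix(0, 1, 1), 0), "frame_rate")
  expect_error(kinetic_model(1.2, matrix(0, 1, 1), 10), "\\[0, 1\\]")
})

test_that("the initial state maximises the staying probability, ties to the lowest index", {
  expect_identical(initial_state(diag(c(0.99, 0.90))), 1L)
  expect_identical(initial_state(diag(c(0.5, 0.5))), 1L)
  expect_identical(initial_state(diag(4)), 1L)
  expect_identical(initial_state(rbind(c(0.3, 0.7), c(0.05, 0.95))), 2L)
})

test_that("bin-wise trajectories reproduce the stationary occupancy of the chain", {
  set.seed(101)
  L <- 1e5
  m <- two_state_model(k12 = 2, k21 = 1, f = 10)
  M <- build_transition_matrix(m)
  pi0 <- stationary_dist(M)
  tr <- simulate_binwise(m, L)
  occ <- colSums(tr$weights) / L
  # consecutive bins are correlated; the Monte-Carlo SE uses the
  # AR(1)-style inflation factor of a two-state chain
  rho <- sum(diag(M)) - 1
  se <- sqrt(pi0[1] * (1 - pi0[1]) / L * (1 + rho) / (1 - rho))
  expect_lt(abs(occ[1] - pi0[1]), 3 * se)

  # thinned to near-independent samples, occupancy passes a chi-squared test
  states <- apply(tr$weights, 1, which.max)
  thin <- states[seq(1, L, by = 100)]
  p <- stats::chisq.test(table(factor(thin, levels = 1:2)), p = pi0)$p.value
  expect_gt(p, 0.01)
})

test_that("bin-wise run lengths are geometric with mean 1/(1 - p_ii)", {
  set.seed(102)
  m <- two_state_model(k12 = 1, k21 = 1, f = 10)
  M <- build_transition_matrix(m)
  tr <- simulate_binwise(m, 1e5)
  runs <- tr$dwells$duration * m$frame_rate     # run lengths in frames
  runs <- runs[-length(runs)]                   # last run is truncated
  expected <- 1 / (1 - M[1, 1])
  se <- stats::sd(runs) / sqrt(length(runs))
  expect_lt(abs(mean(runs) - expected), 3 * se)
})

test_that("no transitions give a constant trajectory at the initial state", {
  m <- kinetic_model(c(0.1, 0.9), matrix(0, 2, 2), 10)
  tr <- simulate_binwise(m, 50)
  expect_equal(tr$avg_fret, rep(0.1, 50))
  expect_equal(nrow(tr$dwells), 1L)
})

test_that("dwell-time simulation draws exponential dwells at the total exit rate", {
  set.seed(103)
  m <- two_state_model(k12 = 2, k21 = 2, f = 10)   # exit rate 2 everywhere
  tr <- simulate_dwelltime(m, 5e4)
  d <- tr$dwells$duration
  d <- d[-length(d)]                               # drop truncated tail
  expect_gt(length(d), 5000)
  # ML estimate of an exponential rate is 1/mean; SE = rate/sqrt(n)
  rate_hat <- 1 / mean(d)
  se <- rate_hat / sqrt(length(d))
  expect_lt(abs(rate_hat - 2), 3 * se)
})

test_that("a state without exits dwells for exactly the whole trace", {
  m <- static_model(0.8, f = 10)
  tr <- simulate_dwelltime(m, 25)
  expect_equal(tr$dwells$duration, 2.5)
  expect_equal(tr$avg_fret, rep(0.8, 25))
})

test_that("bin-wise and dwell-time simulators agree on state occupancy", {
  set.seed(104)
  m <- two_state_model(k12 = 1.5, k21 = 0.5, f = 10)
  L <- 4e4
  occ_b <- colSums(simulate_binwise(m, L)$weights)[1]
  occ_d <- colSums(simulate_dwelltime(m, L)$weights)[1]
  # compare thinned hard-state counts with a two-sample proportion test
  thin <- seq(1, L, by = 100)
  sb <- apply(simulate_binwise(m, L)$weights[thin, ], 1, which.max)
  sd_ <- apply(simulate_dwelltime(m, L)$weights[thin, ], 1, which.max)
  p <- stats::prop.test(c(sum(sb == 1), sum(sd_ == 1)),
                        c(length(sb), length(sd_)))$p.value
  expect_gt(p, 0.01)
  expect_lt(abs(occ_b - occ_d) / L, 0.05)
})

test_that("bin averaging weights states by their time inside each bin", {
  # one dwell spanning everything
  d1 <- data.frame(state = 1, duration = 1)
  expect_equal(bin_average(d1, f = 10, L = 10, fret = 0.8), rep(0.8, 10))
  # 50/50 split bin
  d2 <- data.frame(state = c(1, 2), duration = c(0.05, 0.05))
  expect_equal(bin_average(d2, f = 10, L = 1, fret = c(0.2, 0.8)), 0.5)
  # three segments 0.25/0.50/0.25 of one bin
  d3 <- data.frame(state = c(1, 2, 3), duration = c(0.025, 0.05, 0.025))
  expect_equal(bin_average(d3, f = 10, L = 1, fret = c(0.1, 0.5, 0.9)), 0.5)
})

test_that("bin averaging is invariant under subdivision of a dwell", {
  set.seed(105)
  fret <- c(0.15, 0.85)
  d <- data.frame(state = c(1, 2, 1), duration = c(0.37, 0.91, 0.72))
  base <- bin_average(d, f = 10, L = 20, fret = fret)
  # split each dwell into random contiguous sub-dwells of the same state
  split_dwell <- function(state, duration) {
    k <- sample(1:4, 1)
    u <- diff(c(0, sort(stats::runif(k - 1)), 1)) * duration
    data.frame(state = state, duration = u)
  }
  d_sub <- do.call(rbind, Map(split_dwell, d$state, d$duration))
  expect_equal(bin_average(d_sub, f = 10, L = 20, fret = fret), base,
               tolerance = 1e-12)
})

test_that("defective dwell lists are rejected", {
  short <- data.frame(state = 1, duration = 0.5)
  expect_error(bin_average(short, f = 10, L = 10, fret = 0.5), "gap")
  neg <- data.frame(state = c(1, 2), duration = c(1.2, -0.2))
  expect_error(bin_weights(neg, f = 10, L = 10, J = 2), "negative")
})

test_that("fast exchange produces time-averaged FRET between the state extremes", {
  set.seed(106)
  m <- two_state_model(k12 = 20, k21 = 20, f = 10)   # k_ij >= f
  tr <- simulate_dwelltime(m, 200)
  mid <- tr$avg_fret > 0.2 + 1e-9 & tr$avg_fret < 0.7 - 1e-9
  expect_gt(sum(mid), 0)
  expect_true(all(tr$avg_fret >= 0.2 - 1e-12 & tr$avg_fret <= 0.7 + 1e-12))
})

test_that("photobleaching times are exponential with the configured mean", {
  m <- static_model()
  tr <- simulate_binwise(m, 10)
  expect_identical(apply_bleaching(tr, NULL)$bleach_frame, NA_integer_)

  set.seed(107)
  tb <- replicate(1e4, apply_bleaching(tr, 2)$bleach_time)
  se <- stats::sd(tb) / sqrt(length(tb))
  expect_lt(abs(mean(tb) - 2), 3 * se)

  # mean bleach time far below the bin time: dark from frame 0 or 1
  set.seed(108)
  bf <- replicate(200, apply_bleaching(tr, 1e-4)$bleach_frame)
  expect_true(all(bf <= 1))
})
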