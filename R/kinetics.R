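#' Define a kinetic Markov model of FRET states
#'
#' A molecular system with `J` conformational states is described by a mean
#' FRET efficiency per state, an optional cross-sample standard deviation of
#' that efficiency, and a dense `J x J` matrix of first-order transition
#' rates in s^-1. The diagonal of the rate matrix is forced to zero; the
#' camera frame rate `f` (Hz) fixes the bin duration `1/f` used throughout
#' the simulation.
#'
#' @param fret_mean Numeric vector of per-state mean FRET efficiencies,
#'   each in `[0, 1]`.
#' @param rates `J x J` numeric matrix of transition rates `k_ij` (s^-1),
#'   non-negative off the diagonal. A scalar 0 is allowed for `J = 1`.
#' @param frame_rate Frame rate `f` in Hz (> 0).
#' @param fret_sd Per-state cross-sample SD of the FRET efficiency
#'   (recycled; default 0, i.e. no molecule-to-molecule heterogeneity).
#'
#' @return An object of class `kinetic_model` with elements `J`,
#'   `fret_mean`, `fret_sd`, `rates`, `frame_rate`.
#' @examples
#' kinetic_model(c(0.2, 0.7), rbind(c(0, 1), c(1, 0)), frame_rate = 10)
#' @export
kinetic_model <- function(fret_mean, rates, frame_rate, fret_sd = 0) {
  J <- length(fret_mean)
  if (J < 1L) stop("at least one FRET state is required")
  if (any(!is.finite(fret_mean)) || any(fret_mean < 0) || any(fret_mean > 1))
    stop("fret_mean values must lie in [0, 1]")
  rates <- as.matrix(rates)
  if (J == 1L && length(rates) == 1L) rates <- matrix(rates, 1L, 1L)
  if (!all(dim(rates) == c(J, J)))
    stop(sprintf("rates must be a %d x %d matrix", J, J))
  bad <- which(rates < 0 & row(rates) != col(rates), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative transition rate k[%d,%d] = %g",
                 bad[1, 1], bad[1, 2], rates[bad[1, , drop = FALSE]]))
  diag(rates) <- 0
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("frame_rate must be a single positive number (Hz)")
  fret_sd <- rep_len(fret_sd, J)
  if (any(fret_sd < 0)) stop("fret_sd must be >= 0")
  structure(
    list(J = J, fret_mean = as.numeric(fret_mean), fret_sd = fret_sd,
         rates = rates, frame_rate = frame_rate),
    class = "kinetic_model")
}

#' Per-frame transition probability matrix of a kinetic model
#'
#' Converts transition rates `k_ij` (s^-1) and the frame rate `f` into the
#' row-stochastic matrix of per-frame transition probabilities: the
#' probability of staying in state `i` over one frame is
#' `p_ii = exp(-sum_{j != i} k_ij / f)`, and the remaining probability mass
#' `1 - p_ii` is split over the destination states in proportion to their
#' rates. A state without outgoing rates gets `p_ii = 1`.
#'
#' @param model A [kinetic_model()].
#' @return A `J x J` row-stochastic matrix.
#' @examples
#' m <- kinetic_model(c(0.2, 0.7), rbind(c(0, 1), c(1, 0)), frame_rate = 10)
#' build_transition_matrix(m)   # diagonal exp(-0.1)
#' @export
build_transition_matrix <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  J <- model$J
  k <- model$rates
  f <- model$frame_rate
  out_rate <- rowSums(k)
  p <- matrix(0, J, J)
  diag(p) <- exp(-out_rate / f)
  for (i in seq_len(J)) {
    if (out_rate[i] > 0)
      p[i, -i] <- (1 - p[i, i]) * k[i, -i] / out_rate[i]
  }
  p
}

#' Deterministic initial state of a trajectory
#'
#' The initial state is the state with the highest probability of remaining
#' in itself over one frame, i.e. the argmax of the diagonal of the
#' transition matrix. Ties are broken towards the lowest state index.
#'
#' @param M Row-stochastic transition matrix from
#'   [build_transition_matrix()].
#' @return Integer state index (1-based).
#' @export
initial_state <- function(M) {
  which.max(diag(M))
}

## internal: StateTrajectory constructor. Dwells live on a continuous time
## axis [0, L/f); bin l (0-based) covers [l/f, (l+1)/f).
new_state_trajectory <- function(model, L, dwells, bleach_time = NA_real_) {
  w <- bin_weights(dwells, model$frame_rate, L, model$J)
  avg <- as.numeric(w %*% model$fret_mean)
  bleach_frame <- if (is.na(bleach_time)) NA_integer_ else
    as.integer(ceiling(bleach_time * model$frame_rate))
  structure(
    list(model = model, L = as.integer(L), dwells = dwells,
         weights = w, avg_fret = avg,
         bleach_time = bleach_time, bleach_frame = bleach_frame),
    class = "state_trajectory")
}

#' Simulate a state trajectory bin-by-bin
#'
#' Draws one state per frame by inverse-CDF sampling on the current row of
#' the per-frame transition matrix, starting from [initial_state()]. Each
#' bin is occupied by exactly one state (no sub-frame averaging); the dwell
#' list is reconstructed from runs of identical states.
#'
#' @param model A [kinetic_model()].
#' @param L Number of frames (>= 1).
#' @return A `state_trajectory`: per-bin state-occupancy weights,
#'   per-bin average FRET (`avg_fret`), and the dwell list
#'   (`state`, `duration` in seconds).
#' @export
simulate_binwise <- function(model, L) {
  stopifnot(L >= 1)
  M <- build_transition_matrix(model)
  cum <- t(apply(M, 1L, cumsum))
  if (model$J == 1L) cum <- matrix(1, 1L, 1L)
  states <- integer(L)
  s <- initial_state(M)
  u <- stats::runif(L)
  for (l in seq_len(L)) {
    states[l] <- s
    s <- 1L + sum(u[l] > cum[s, ])
  }
  r <- rle(states)
  dwells <- data.frame(state = r$values,
                       duration = r$lengths / model$frame_rate)
  new_state_trajectory(model, L, dwells)
}

#' Simulate a state trajectory dwell-by-dwell
#'
#' Kinetic Monte Carlo on the continuous time axis: from state `i`, the
#' dwell duration is exponential with rate `sum_{j != i} k_ij` and the
#' destination is drawn from the off-diagonal rates normalised to 1 (the
#' embedded chain). Dwells are concatenated until the trace length `L/f` is
#' covered; the last dwell is truncated to the trace end. Bins crossed by a
#' transition receive a time-weighted average FRET value.
#'
#' @inheritParams simulate_binwise
#' @return A `state_trajectory`.
#' @export
simulate_dwelltime <- function(model, L) {
  stopifnot(L >= 1)
  M <- build_transition_matrix(model)
  f <- model$frame_rate
  total <- L / f
  s <- initial_state(M)
  out_rate <- rowSums(model$rates)
  t_now <- 0
  cap <- 256L
  st <- integer(cap); du <- numeric(cap); nd <- 0L
  push <- function(state, duration) {
    nd <<- nd + 1L
    if (nd > cap) {            # amortised growth for long traces
      cap <<- cap * 2L
      length(st) <<- cap; length(du) <<- cap
    }
    st[nd] <<- state; du[nd] <<- duration
  }
  while (t_now < total) {
    if (out_rate[s] <= 0) {          # absorbing: dwell to the end
      push(s, total - t_now)
      break
    }
    d <- stats::rexp(1L, rate = out_rate[s])
    if (t_now + d > total) d <- total - t_now
    push(s, d)
    t_now <- t_now + d
    if (t_now >= total) break
    p <- model$rates[s, ] / out_rate[s]
    s <- 1L + sum(stats::runif(1L) > cumsum(p))
  }
  new_state_trajectory(model, L,
                       data.frame(state = st[seq_len(nd)],
                                  duration = du[seq_len(nd)]))
}

#' Fractional state occupancy of each frame
#'
#' Lays the dwell list on the continuous time axis `[0, L/f)` and computes,
#' for each frame, the fraction of the bin duration spent in each state.
#' This is the weight matrix behind all sub-frame time averaging.
#'
#' @param dwells Data frame with columns `state` (1-based index) and
#'   `duration` (seconds), covering `[0, L/f]` without gap or overlap.
#' @param f Frame rate (Hz).
#' @param L Number of frames.
#' @param J Number of states.
#' @return `L x J` matrix; each row sums to 1.
#' @export
bin_weights <- function(dwells, f, L, J) {
  dur <- dwells$duration
  if (any(dur < 0)) stop("negative dwell duration")
  ends <- cumsum(dur)
  starts <- c(0, ends[-length(ends)])
  total <- L / f
  # floating tolerance scaled to the accumulation error of long dwell lists
  tol <- 1e-9 * max(length(dur), 1000)
  if (ends[length(ends)] < total * (1 - tol) - tol / f)
    stop("dwell list does not cover the trace (gap at the end)")
  w <- matrix(0, L, J)
  for (d in seq_along(dur)) {
    if (dur[d] <= 0) next
    a <- starts[d] * f; b <- min(ends[d] * f, L)  # in units of bins
    if (a >= L) break
    l0 <- floor(a); l1 <- ceiling(b) - 1
    for (l in l0:l1) {
      ov <- min(b, l + 1) - max(a, l)
      if (ov > 0) w[l + 1, dwells$state[d]] <- w[l + 1, dwells$state[d]] + ov
    }
  }
  rs <- rowSums(w)
  if (any(abs(rs - 1) > tol))
    stop("dwell list has a gap or overlap inside the trace")
  w / rs
}

#' Time-weighted average FRET per frame
#'
#' @inheritParams bin_weights
#' @param fret Per-state FRET values used for the average (length `J`).
#' @return Numeric vector of length `L`; frames fully inside one dwell
#'   carry that state's FRET value exactly.
#' @examples
#' d <- data.frame(state = c(1, 2), duration = c(0.05, 0.05))
#' bin_average(d, f = 10, L = 1, fret = c(0.2, 0.8))  # 0.5
#' @export
bin_average <- function(dwells, f, L, fret) {
  as.numeric(bin_weights(dwells, f, L, length(fret)) %*% fret)
}

#' Truncate a trajectory with an exponential photobleaching time
#'
#' Draws a photobleaching time from an exponential distribution with the
#' given mean and records it on the trajectory. Frames starting at or after
#' the bleach time emit no molecular photons; the frame containing the
#' bleach time is partially lit (handled downstream by
#' [traces_from_states()]). `bleach_frame` is the first fully dark frame
#' (0-based).
#'
#' @param traj A `state_trajectory`.
#' @param tau_bleach Mean photobleaching time in seconds, or `NULL` to
#'   disable bleaching.
#' @return The trajectory with `bleach_time`/`bleach_frame` set.
#' @export
apply_bleaching <- function(traj, tau_bleach = NULL) {
  stopifnot(inherits(traj, "state_trajectory"))
  if (is.null(tau_bleach)) return(traj)
  if (tau_bleach <= 0) stop("tau_bleach must be positive (or NULL)")
  tb <- stats::rexp(1L, rate = 1 / tau_bleach)
  traj$bleach_time <- tb
  traj$bleach_frame <- as.integer(ceiling(tb * traj$model$frame_rate))
  traj
}

## internal: per-frame fraction of the bin during which the molecule is
## still emitting (1 before bleach, 0 after, partial in the bleach bin).
alive_fraction <- function(traj) {
  L <- traj$L
  if (is.na(traj$bleach_time)) return(rep(1, L))
  f <- traj$model$frame_rate
  tb_bins <- traj$bleach_time * f
  frac <- pmin(pmax(tb_bins - (seq_len(L) - 1), 0), 1)
  frac
}
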