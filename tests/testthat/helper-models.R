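# Shared fixtures, built in code.

two_state_model <- function(k12 = 1, k21 = 1, f = 10,
                            fret = c(0.2, 0.7), fret_sd = 0) {
  kinetic_model(fret, rbind(c(0, k12), c(k21, 0)), f, fret_sd)
}

static_model <- function(fret = 0.5, f = 10) {
  kinetic_model(fret, matrix(0, 1, 1), f)
}

small_layout <- function() {
  field_layout(x_res = 64, y_res = 64, d_pix = 16, binning = 1,
               magnification = 150, split_axis = "y")  # 64 x 32 channel
}

# stationary distribution of a row-stochastic matrix (left eigenvector),
# used as the independent oracle for occupancy tests
stationary_dist <- function(M) {
  e <- eigen(t(M))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# literal re-enactment of the greedy policy, written independently of
# match_greedy: plain loops, no vectorised distance shortcuts
greedy_oracle <- function(det, gt, tol) {
  ord <- order(-det$intensity, seq_len(nrow(det)))
  used <- rep(FALSE, nrow(gt))
  tp <- 0L
  for (i in ord) {
    best <- NA_integer_; bestd <- Inf
    for (j in seq_len(nrow(gt))) {
      if (used[j]) next
      dd <- sqrt((det$x[i] - gt$x[j])^2 + (det$y[i] - gt$y[j])^2)
      if (dd < bestd) { bestd <- dd; best <- j }
    }
    if (!is.na(best) && bestd <= tol) {
      used[best] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = nrow(det) - tp, fn = nrow(gt) - tp)
}
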