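#' Time-average a frame stack
#'
#' Pixel-wise arithmetic mean across all frames; averaging reduces the
#' per-pixel noise variance roughly by the number of frames, which is why
#' spot detection is usually run on the averaged image.
#'
#' @param video `ny x nx x L` array (or a `ny x nx` matrix, returned
#'   as-is).
#' @return `ny x nx` matrix.
#' @export
time_average_video <- function(video) {
  if (is.matrix(video)) return(video)
  d <- dim(video)
  if (is.null(d) || length(d) != 3L || d[3] < 1L)
    stop("video must be a ny x nx x L array with at least one frame")
  rowMeans(video, dims = 2L)
}

#' In-series screening (ISS) spot detector
#'
#' Iterative peak picking: select the brightest pixel above the intensity
#' threshold, record it as a detection, zero the suppression neighbourhood
#' (`nhood_size x nhood_size` pixels centred on the peak) and repeat until
#' no pixel exceeds the threshold or the maximum number of spots is
#' reached. Detections come out ordered by decreasing peak intensity.
#'
#' @param frame Image matrix (any intensity unit; the threshold is in the
#'   same unit).
#' @param i_thresh Intensity threshold: only pixels strictly above it can
#'   seed a detection.
#' @param nhood_size Odd suppression neighbourhood edge (pixels).
#' @param max_spots Upper bound on detections; set it above the expected
#'   number of true molecules so false positives can surface.
#' @return A `detection_set`: data frame `detections` with columns `x`,
#'   `y` (continuous coordinates of the peak pixel centre), `px`, `py`
#'   (integer pixel indices, 1-based), `intensity`; plus the parameters
#'   used.
#' @export
detect_iss <- function(frame, i_thresh, nhood_size = 5, max_spots = Inf) {
  if (nhood_size %% 2 != 1) stop("nhood_size must be odd")
  work <- frame
  ny <- nrow(work); nx <- ncol(work)
  h <- (nhood_size - 1) / 2
  px <- integer(0); py <- integer(0); val <- numeric(0)
  while (length(px) < max_spots) {
    i <- which.max(work)
    v <- work[i]
    if (!length(v) || v <= i_thresh) break
    r <- (i - 1L) %% ny + 1L
    c <- (i - 1L) %/% ny + 1L
    px <- c(px, c); py <- c(py, r); val <- c(val, v)
    work[max(1L, r - h):min(ny, r + h), max(1L, c - h):min(nx, c + h)] <- -Inf
  }
  structure(
    list(detections = data.frame(x = px - 0.5, y = py - 0.5,
                                 px = px, py = py, intensity = val),
         detector = "iss",
         params = list(i_thresh = i_thresh, nhood_size = nhood_size,
                       max_spots = max_spots)),
    class = "detection_set")
}

#' Greedy tolerance-radius classification of detections
#'
#' Detections are processed in order of decreasing intensity (ties by
#' scan order). Each detection is a true positive if its nearest
#' still-unmatched ground-truth coordinate lies within the tolerance
#' radius — that coordinate is then consumed — and a false positive
#' otherwise; unconsumed ground-truth coordinates are false negatives.
#' Distances run from the detection coordinate (the pixel centre for
#' pixel-level detectors) to the continuous ground-truth position.
#'
#' @param det A `detection_set` or a data frame with columns `x`, `y` and
#'   optionally `intensity`.
#' @param gt Data frame of true coordinates `x`, `y` (sub-pixel).
#' @param tol Tolerance radius in pixels (> 0).
#' @return A `match_result`: counts `tp`, `fp`, `fn`, the assignment
#'   (`gt_index` per detection, `NA` for false positives), and `tol`.
#' @export
match_greedy <- function(det, gt, tol) {
  if (tol <= 0) stop("tolerance radius must be positive")
  d <- if (inherits(det, "detection_set")) det$detections else det
  nd <- nrow(d)
  ngt <- nrow(gt)
  ord <- if (nd && !is.null(d$intensity))
    order(-d$intensity, seq_len(nd)) else seq_len(nd)
  assigned <- rep(NA_integer_, nd)
  free <- rep(TRUE, ngt)
  for (i in ord) {
    if (!any(free)) break
    dx <- gt$x[free] - d$x[i]
    dy <- gt$y[free] - d$y[i]
    dist2 <- dx * dx + dy * dy
    j <- which.min(dist2)
    if (dist2[j] <= tol^2) {
      idx <- which(free)[j]
      assigned[i] <- idx
      free[idx] <- FALSE
    }
  }
  tp <- sum(!is.na(assigned))
  structure(
    list(tp = tp, fp = nd - tp, fn = ngt - tp,
         gt_index = assigned, n_true = ngt, n_detected = nd, tol = tol),
    class = "match_result")
}

#' Recall, precision and accuracy of a matching
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`,
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`. Spot detectors produce no
#' true-negative class, so `TN = 0` unless supplied. Undefined ratios
#' (0/0) are reported as 0 by convention; the raw counts are returned so
#' other conventions can be re-derived.
#'
#' @param match A `match_result` (or any list with `tp`, `fp`, `fn`).
#' @param tn True-negative count (default 0).
#' @return List with `recall`, `precision`, `accuracy`, `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
compute_scores <- function(match, tn = 0) {
  tp <- match$tp; fp <- match$fp; fn <- match$fn
  if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be >= 0")
  rat <- function(num, den) if (den > 0) num / den else 0
  list(recall = rat(tp, tp + fn),
       precision = rat(tp, tp + fp),
       accuracy = rat(tp + tn, tp + tn + fp + fn),
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Grid optimisation of detector method parameters
#'
#' Runs a detector over a full grid of intensity thresholds and
#' neighbourhood sizes on one (typically time-averaged) frame, matches
#' each detection set greedily against the ground truth and scores it.
#' Returns the complete score map and, per measure, every grid point
#' achieving the maximum (the maximising region may be a set, not a
#' point).
#'
#' @param frame Image matrix the detector runs on.
#' @param gt Ground-truth coordinates (data frame `x`, `y`).
#' @param i_thresh_grid,nhood_grid Parameter grids (non-empty; all
#'   `nhood_grid` values odd).
#' @param tol Tolerance radius for matching (pixels).
#' @param max_spots Detection cap passed to [detect_iss()].
#' @param detector Detection function with the [detect_iss()] signature.
#' @return List with `scores` (data frame: `i_thresh`, `nhood_size`,
#'   `recall`, `precision`, `accuracy`, `tp`, `fp`, `fn`), `best` (named
#'   list of maximising sub-data-frames per measure) and `max` (named
#'   vector of the three maxima).
#' @export
optimize_grid <- function(frame, gt, i_thresh_grid, nhood_grid, tol,
                          max_spots = 2 * nrow(gt), detector = detect_iss) {
  if (!length(i_thresh_grid) || !length(nhood_grid))
    stop("parameter grids must be non-empty")
  grid <- expand.grid(i_thresh = i_thresh_grid, nhood_size = nhood_grid)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    det <- detector(frame, i_thresh = grid$i_thresh[g],
                    nhood_size = grid$nhood_size[g], max_spots = max_spots)
    sc <- compute_scores(match_greedy(det, gt, tol))
    cbind(grid[g, , drop = FALSE], as.data.frame(sc))
  })
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  measures <- c("recall", "precision", "accuracy")
  mx <- vapply(measures, function(m) max(scores[[m]]), numeric(1))
  best <- lapply(measures, function(m)
    scores[scores[[m]] >= mx[[m]] - 1e-12,
           c("i_thresh", "nhood_size", m)])
  names(best) <- measures
  list(scores = scores, best = best, max = mx)
}

#' Rank detection methods across conditions
#'
#' For every condition and evaluation measure, methods are awarded 1 to
#' `n_methods` ranking points (best = most points); exact ties share the
#' mean of the tied point span.
#'
#' @param scores Data frame with columns `method`, `condition`, `measure`,
#'   `score` (>= 2 methods).
#' @return The input with a `points` column appended, plus an aggregate
#'   attribute `"totals"` (sum of points per method and measure).
#' @export
rank_methods <- function(scores) {
  need <- c("method", "condition", "measure", "score")
  if (!all(need %in% names(scores)))
    stop("scores needs columns method, condition, measure, score")
  if (length(unique(scores$method)) < 2L)
    stop("ranking needs at least two methods")
  scores$points <- stats::ave(scores$score,
                              scores$condition, scores$measure,
                              FUN = function(x) rank(x, ties.method = "average"))
  totals <- stats::aggregate(points ~ method + measure, scores, sum)
  attr(scores, "totals") <- totals
  scores
}
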