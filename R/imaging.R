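#' Sensor and field-of-view geometry
#'
#' Describes the camera sensor (`x_res x y_res` physical pixels of edge
#' `d_pix` micrometres), optional `p x p` hardware binning, the optical
#' magnification, and the axis along which the sensor is split into the
#' donor and acceptor spectral channels. All image-space coordinates used
#' by the simulator are expressed in binned (super)pixels of one spectral
#' channel; pixel `(i, j)` covers `[i, i+1) x [j, j+1)` with its centre at
#' `(i + 0.5, j + 0.5)` (0-based, continuous).
#'
#' @param x_res,y_res Sensor divisions in x (columns) and y (rows).
#' @param d_pix Physical pixel edge (micrometres).
#' @param binning Hardware binning factor `p` (integer >= 1); `x_res` and
#'   `y_res` must be divisible by `p`.
#' @param magnification Total optical magnification `M`.
#' @param split_axis `"y"` (default) splits the binned sensor into a top
#'   (donor) and bottom (acceptor) half; `"x"` splits left/right.
#' @return A `field_layout` with per-channel dimensions `nx`, `ny`
#'   (superpixels), the object-space superpixel edge (`px_obj`, um) and
#'   per-channel object-space area (`area_obj`, um^2).
#' @examples
#' field_layout()  # 512x512, 2x2 binning, 150x: two 256x128 channels
#' @export
field_layout <- function(x_res = 512, y_res = 512, d_pix = 16,
                         binning = 2, magnification = 150,
                         split_axis = c("y", "x")) {
  split_axis <- match.arg(split_axis)
  binning <- as.integer(binning)
  if (binning < 1L) stop("binning must be a positive integer")
  if (x_res %% binning || y_res %% binning)
    stop("x_res and y_res must be divisible by the binning factor")
  if (magnification <= 0 || d_pix <= 0) stop("d_pix and magnification must be positive")
  nx <- x_res %/% binning
  ny <- y_res %/% binning
  if (split_axis == "y") {
    if (ny %% 2L) stop("binned y dimension must be even to split channels")
    ny <- ny %/% 2L
  } else {
    if (nx %% 2L) stop("binned x dimension must be even to split channels")
    nx <- nx %/% 2L
  }
  px_obj <- binning * d_pix / magnification
  structure(
    list(x_res = x_res, y_res = y_res, d_pix = d_pix, binning = binning,
         magnification = magnification, split_axis = split_axis,
         nx = nx, ny = ny, px_obj = px_obj,
         area_obj = nx * ny * px_obj^2),
    class = "field_layout")
}

#' Gaussian point-spread-function model
#'
#' The diffraction-limited image of a point emitter is approximated by a
#' symmetric 2D Gaussian of unit integral. `w_det` is the Gaussian
#' standard deviation in channel pixels by default; set
#' `width_is_fwhm = TRUE` to interpret the widths as FWHM instead
#' (`FWHM = 2 sqrt(2 log 2) sigma`). An optional linear focal drift
#' `z0(t) = m t + z0` broadens the effective width as
#' `w * sqrt(1 + (z0(t)/z_scale)^2)`; it is disabled by default.
#'
#' @param w_det_d,w_det_a Gaussian width per channel (pixels, > 0).
#' @param width_is_fwhm Interpret widths as FWHM instead of sigma.
#' @param z0_d,z0_a Longitudinal chromatic offsets (same units as
#'   `z_scale`).
#' @param drift_rate Focal drift rate `m` per frame (0 disables drift).
#' @param z_scale Axial scale converting defocus into relative width
#'   broadening; `NULL` (default) disables defocus broadening entirely.
#' @return A `psf_model`.
#' @export
psf_model <- function(w_det_d = 1.5, w_det_a = w_det_d,
                      width_is_fwhm = FALSE,
                      z0_d = 0, z0_a = 0, drift_rate = 0, z_scale = NULL) {
  if (w_det_d <= 0 || w_det_a <= 0) stop("PSF widths must be positive")
  k <- if (width_is_fwhm) 1 / (2 * sqrt(2 * log(2))) else 1
  structure(
    list(sigma_d = w_det_d * k, sigma_a = w_det_a * k,
         width_is_fwhm = width_is_fwhm,
         z0_d = z0_d, z0_a = z0_a, drift_rate = drift_rate,
         z_scale = z_scale),
    class = "psf_model")
}

## internal: effective sigma of one channel at frame l (0-based)
psf_sigma_at <- function(psf, channel = c("donor", "acceptor"), frame = 0) {
  channel <- match.arg(channel)
  sigma <- if (channel == "donor") psf$sigma_d else psf$sigma_a
  if (is.null(psf$z_scale)) return(sigma)
  z0 <- if (channel == "donor") psf$z0_d else psf$z0_a
  z <- psf$drift_rate * frame + z0
  sigma * sqrt(1 + (z / psf$z_scale)^2)
}

#' Background (excitation-profile) model
#'
#' The background is proportional to the excitation intensity. A
#' `"uniform"` background is constant; a `"gaussian"` background follows
#' an asymmetric 2D Gaussian excitation profile with its maximum
#' (`bg_d` / `bg_a` photons/pixel/frame) at the profile centre, which
#' defaults to the channel centre.
#'
#' @param kind `"uniform"` or `"gaussian"`.
#' @param bg_d,bg_a Background amplitude per channel
#'   (photons/pixel/frame at the profile maximum).
#' @param w_ex_x,w_ex_y Excitation profile Gaussian widths (pixels).
#' @param center Profile centre `(x_c, y_c)` in channel pixels, or `NULL`
#'   for the channel centre.
#' @return A `background_model`.
#' @export
background_model <- function(kind = c("uniform", "gaussian"),
                             bg_d = 1, bg_a = bg_d,
                             w_ex_x = 60, w_ex_y = 150, center = NULL) {
  kind <- match.arg(kind)
  if (bg_d < 0 || bg_a < 0) stop("background amplitudes must be >= 0")
  if (kind == "gaussian" && (w_ex_x <= 0 || w_ex_y <= 0))
    stop("excitation profile widths must be positive")
  structure(list(kind = kind, bg_d = bg_d, bg_a = bg_a,
                 w_ex_x = w_ex_x, w_ex_y = w_ex_y, center = center),
            class = "background_model")
}

#' Place molecules on a regular grid
#'
#' Evenly spaced lattice inside one spectral channel, emulating
#' nanopatterned immobilisation; with a spacing above about six PSF widths
#' the rendered spots do not overlap.
#'
#' @param rows,cols Lattice dimensions.
#' @param layout A [field_layout()].
#' @param margin Margin kept free around the lattice (pixels).
#' @return Data frame of continuous channel coordinates `x`, `y`
#'   (`rows * cols` molecules, row-major).
#' @export
place_grid <- function(rows, cols, layout, margin = 0) {
  stopifnot(inherits(layout, "field_layout"), rows >= 1, cols >= 1)
  wx <- layout$nx - 2 * margin
  wy <- layout$ny - 2 * margin
  if (wx < cols || wy < rows)
    stop("grid does not fit inside the channel with the requested margin")
  sx <- wx / cols
  sy <- wy / rows
  g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  data.frame(x = margin + (g$col - 0.5) * sx,
             y = margin + (g$row - 0.5) * sy)
}

#' Place molecules uniformly at random with sub-pixel accuracy
#'
#' Either an explicit molecule count or a surface density `rho` (um^-2,
#' object space) may be given; in the latter case
#' `N = round(rho * channel object-space area)`.
#'
#' @param layout A [field_layout()].
#' @param n Explicit number of molecules (overrides `density`).
#' @param density Surface density `rho` in molecules per um^2.
#' @return Data frame of continuous channel coordinates `x`, `y`.
#' @export
place_random <- function(layout, n = NULL, density = NULL) {
  stopifnot(inherits(layout, "field_layout"))
  if (is.null(n)) {
    if (is.null(density)) stop("give either n or density")
    n <- round(density * layout$area_obj)
  }
  n <- as.integer(n)
  if (n == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  data.frame(x = stats::runif(n, 0, layout$nx),
             y = stats::runif(n, 0, layout$ny))
}

#' Render molecules into a pixel-integrated photon frame
#'
#' Each molecule deposits its frame intensity according to the exact
#' integral of a unit-mass symmetric 2D Gaussian over each pixel:
#' the weight of pixel column `x` is
#' `pnorm((x + 1 - x_n)/sigma) - pnorm((x - x_n)/sigma)` and likewise in
#' `y`, so the total rendered count equals the intensity minus the mass
#' falling outside the field of view. Rendering is restricted to a window
#' of `cutoff` sigmas around each molecule (the neglected mass at the
#' default 8 sigma is below 1e-14).
#'
#' @param coords Data frame with columns `x`, `y` (continuous channel
#'   pixels).
#' @param intensities Per-molecule intensities (pc/frame), recycled.
#' @param sigma Gaussian PSF standard deviation in pixels.
#' @param nx,ny Frame dimensions (pixels).
#' @param cutoff Support radius in sigmas (`Inf` renders over the full
#'   frame).
#' @return `ny x nx` numeric matrix of expected photon counts.
#' @export
render_psf <- function(coords, intensities, sigma, nx, ny, cutoff = 8) {
  frame <- matrix(0, ny, nx)
  n <- nrow(coords)
  if (n == 0L) return(frame)
  intensities <- rep_len(intensities, n)
  for (m in seq_len(n)) {
    if (intensities[m] == 0) next
    xm <- coords$x[m]; ym <- coords$y[m]
    if (is.finite(cutoff)) {
      cx0 <- max(0L, floor(xm - cutoff * sigma))
      cx1 <- min(nx - 1L, ceiling(xm + cutoff * sigma) - 1L)
      cy0 <- max(0L, floor(ym - cutoff * sigma))
      cy1 <- min(ny - 1L, ceiling(ym + cutoff * sigma) - 1L)
      if (cx0 > cx1 || cy0 > cy1) next
    } else {
      cx0 <- 0L; cx1 <- nx - 1L; cy0 <- 0L; cy1 <- ny - 1L
    }
    ex <- stats::pnorm((seq.int(cx0, cx1 + 1L) - xm) / sigma)
    ey <- stats::pnorm((seq.int(cy0, cy1 + 1L) - ym) / sigma)
    wx <- diff(ex); wy <- diff(ey)
    frame[(cy0 + 1L):(cy1 + 1L), (cx0 + 1L):(cx1 + 1L)] <-
      frame[(cy0 + 1L):(cy1 + 1L), (cx0 + 1L):(cx1 + 1L)] +
      intensities[m] * tcrossprod(wy, wx)
  }
  frame
}

#' Background photon frame of one channel
#'
#' Uniform kind: a constant frame at the amplitude. Gaussian kind: the
#' amplitude modulated by the excitation profile
#' `exp(-(x - x_c)^2 / (2 w_x^2) - (y - y_c)^2 / (2 w_y^2))`, evaluated at
#' pixel centres (the profile varies slowly relative to a pixel), with its
#' maximum equal to the amplitude at the centre.
#'
#' @param bg A [background_model()].
#' @param layout A [field_layout()].
#' @param channel `"donor"` or `"acceptor"` (selects the amplitude).
#' @return `ny x nx` matrix of expected background photons/pixel/frame.
#' @export
background_frame <- function(bg, layout, channel = c("donor", "acceptor")) {
  channel <- match.arg(channel)
  amp <- if (channel == "donor") bg$bg_d else bg$bg_a
  nx <- layout$nx; ny <- layout$ny
  if (bg$kind == "uniform") return(matrix(amp, ny, nx))
  ctr <- if (is.null(bg$center)) c(nx / 2, ny / 2) else bg$center
  xs <- seq_len(nx) - 0.5
  ys <- seq_len(ny) - 0.5
  gx <- exp(-(xs - ctr[1])^2 / (2 * bg$w_ex_x^2))
  gy <- exp(-(ys - ctr[2])^2 / (2 * bg$w_ex_y^2))
  amp * tcrossprod(gy, gx)
}

#' Pixel-wise composition of molecular signal and background
#'
#' @param molecular,background Equal-sized photon frames.
#' @return Their pixel-wise sum.
#' @export
compose_frame <- function(molecular, background) {
  if (!all(dim(molecular) == dim(background)))
    stop("frame dimensions do not match")
  molecular + background
}

#' Diffraction-limited spot size after magnification
#'
#' Abbe's relation: a point emitter of emission wavelength `lambda_em`
#' imaged through an objective of numerical aperture `NA` produces a spot
#' of size `lambda_em / (2 NA)` in object space, magnified `M`-fold onto
#' the sensor. Returned in micrometres (image space).
#'
#' @param lambda_em Emission wavelength (nm).
#' @param na Numerical aperture (> 0).
#' @param magnification Total magnification `M`.
#' @return Spot size in micrometres.
#' @examples
#' abbe_spot_size(600, 1.2, 60)  # 15 um, matching a 16 um camera pixel
#' @export
abbe_spot_size <- function(lambda_em, na, magnification) {
  if (na <= 0) stop("numerical aperture must be positive")
  if (lambda_em <= 0 || magnification <= 0)
    stop("wavelength and magnification must be positive")
  (lambda_em / (2 * na)) * magnification / 1000
}

#' Render a two-channel photon-expectation video
#'
#' Assembles per-frame expected-photon images for the donor and acceptor
#' channels from per-molecule detected intensity traces: molecules are
#' rendered at their (time-invariant) sub-pixel coordinates with the
#' channel PSF, the background frame is added, and the complete ground
#' truth (coordinates, traces, drawn parameters) is attached. Acceptor
#' coordinates equal the donor coordinates mapped into the acceptor
#' channel, plus an optional lateral chromatic offset.
#'
#' @param coords Data frame of donor-channel coordinates `x`, `y`.
#' @param traces List of `intensity_traces`, one per molecule (equal
#'   length `L`).
#' @param layout A [field_layout()].
#' @param psf A [psf_model()].
#' @param bg A [background_model()] (or `NULL` for none).
#' @param chromatic_offset Acceptor-channel lateral offset `c(dx, dy)` in
#'   pixels.
#' @return A `photon_video`: 3D arrays `donor` and `acceptor`
#'   (`ny x nx x L`, expected pc/pixel/frame) and a `ground_truth` list.
#' @export
render_video <- function(coords, traces, layout, psf, bg = NULL,
                         chromatic_offset = c(0, 0)) {
  stopifnot(inherits(layout, "field_layout"), inherits(psf, "psf_model"))
  n <- nrow(coords)
  if (length(traces) != n) stop("one trace per molecule is required")
  L <- if (n > 0) length(traces[[1]]$i_dd) else
    stop("render_video needs at least one molecule; use background_frame for empty scenes")
  idd <- vapply(traces, function(tr) tr$i_dd, numeric(L))
  ida <- vapply(traces, function(tr) tr$i_da, numeric(L))
  if (L == 1L) { idd <- matrix(idd, 1L); ida <- matrix(ida, 1L) }
  acc_coords <- data.frame(x = coords$x + chromatic_offset[1],
                           y = coords$y + chromatic_offset[2])
  nx <- layout$nx; ny <- layout$ny
  bg_d <- if (is.null(bg)) matrix(0, ny, nx) else
    background_frame(bg, layout, "donor")
  bg_a <- if (is.null(bg)) matrix(0, ny, nx) else
    background_frame(bg, layout, "acceptor")
  don <- array(0, c(ny, nx, L))
  acc <- array(0, c(ny, nx, L))
  for (l in seq_len(L)) {
    sd_l <- psf_sigma_at(psf, "donor", l - 1)
    sa_l <- psf_sigma_at(psf, "acceptor", l - 1)
    don[, , l] <- render_psf(coords, idd[l, ], sd_l, nx, ny) + bg_d
    acc[, , l] <- render_psf(acc_coords, ida[l, ], sa_l, nx, ny) + bg_a
  }
  structure(
    list(donor = don, acceptor = acc,
         ground_truth = list(
           coords = coords, acceptor_coords = acc_coords,
           traces = traces,
           bleach_frame = vapply(traces, function(tr)
             if (all(tr$alive == 1)) NA_integer_ else sum(tr$alive > 0),
             integer(1)),
           layout = layout, psf = psf, background = bg)),
    class = "photon_video")
}
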