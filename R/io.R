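## Video, trace-table and metadata-sidecar I/O.
##
## Videos are multi-page grayscale TIFF stacks: each page holds both
## spectral channels side by side along the configured split axis (donor
## first). Quantised stacks are 16-bit unsigned and round-trip
## bit-exactly; expectation stacks (noise model "none") are 32-bit float,
## stored scaled by 2^BR - 1 with the scale recorded in the sidecar.

## internal: combine donor/acceptor stacks page-wise
combine_channels <- function(donor, acceptor, split_axis) {
  L <- dim(donor)[3]
  lapply(seq_len(L), function(l) {
    if (split_axis == "y") rbind(donor[, , l], acceptor[, , l])
    else cbind(donor[, , l], acceptor[, , l])
  })
}

write_video_tiff <- function(donor, acceptor, path, split_axis = "y",
                             float = FALSE, bit_rate = 14) {
  pages <- combine_channels(donor, acceptor, split_axis)
  if (float) {
    scale <- 2^bit_rate - 1
    pages <- lapply(pages, function(p) pmin(p / scale, 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
    return(invisible(scale))
  }
  if (max(vapply(pages, max, numeric(1))) > 65535)
    stop("integer stack exceeds the 16-bit TIFF range")
  pages <- lapply(pages, function(p) p / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, reduce = FALSE)
  invisible(1)
}

## internal: single-channel stack writer (same encoding rules)
write_stack_tiff <- function(stack, path, float = FALSE, bit_rate = 14) {
  L <- dim(stack)[3]
  pages <- lapply(seq_len(L), function(l) stack[, , l])
  if (float) {
    scale <- 2^bit_rate - 1
    pages <- lapply(pages, function(p) pmin(p / scale, 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
    return(invisible(scale))
  }
  pages <- lapply(pages, function(p) p / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, reduce = FALSE)
  invisible(1)
}

## internal: trace table, rows = frames, columns = molecules
write_trace_table <- function(traces, field, path) {
  tab <- vapply(traces, function(tr) tr[[field]],
                numeric(length(traces[[1]][[field]])))
  tab <- matrix(tab, nrow = length(traces[[1]][[field]]))
  colnames(tab) <- sprintf("mol%03d", seq_along(traces))
  utils::write.csv(tab, path, row.names = FALSE)
}

#' Run a simulation and write all artifacts to disk
#'
#' Executes [simulate_video()] and exports: the two-channel video stack
#' (`video.tif`), optional per-channel stacks, one trace table per
#' channel (`traces_donor.csv`, `traces_acceptor.csv`; rows = frames,
#' columns = molecules, photon counts per frame), and a JSON metadata
#' sidecar (`metadata.json`) holding the fully resolved configuration,
#' the package version, the seed, the per-molecule ground truth and a
#' checksummed file inventory — everything needed to re-run the
#' simulation bit-identically. A failed stage aborts before writing;
#' partially written outputs are removed.
#'
#' @param config A `simulation_config`, a list of overrides, or a path to
#'   a YAML configuration file.
#' @param outdir Output directory (created if missing).
#' @param per_channel Also write `donor.tif` / `acceptor.tif`.
#' @return Invisibly, the [simulate_video()] result with `$files`
#'   appended.
#' @export
run_simulation <- function(config, outdir, per_channel = FALSE) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "simulation_config"))
    config <- simulation_config(config)
  sim <- simulate_video(config)     # fails before any file is touched
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(outdir, c(video = "video.tif",
                               traces_donor = "traces_donor.csv",
                               traces_acceptor = "traces_acceptor.csv",
                               metadata = "metadata.json"))
  names(files) <- c("video", "traces_donor", "traces_acceptor", "metadata")
  on_fail <- function(e) {
    unlink(files[file.exists(files)])
    stop(e)
  }
  tryCatch({
    float <- config$cam$noise_model == "none"
    scale <- write_video_tiff(sim$donor, sim$acceptor, files[["video"]],
                              split_axis = config$layout$split_axis,
                              float = float, bit_rate = config$cam$bit_rate)
    if (per_channel) {
      for (ch in c("donor", "acceptor"))
        write_stack_tiff(sim[[ch]], file.path(outdir, paste0(ch, ".tif")),
                         float = float, bit_rate = config$cam$bit_rate)
    }
    write_trace_table(sim$traces_detected, "i_dd", files[["traces_donor"]])
    write_trace_table(sim$traces_detected, "i_da", files[["traces_acceptor"]])
    write_sidecar(sim, files, scale)
  }, error = on_fail)
  sim$files <- files
  invisible(sim)
}

## internal: serialisable copy of the resolved config (module objects and
## non-scalar helpers dropped; matrices flattened to row lists)
config_for_export <- function(config) {
  cfg <- unclass(config)
  cfg$model <- cfg$pair <- cfg$layout <- cfg$psf <- NULL
  cfg$background <- cfg$cam <- NULL
  cfg$kinetics$rates <- lapply(seq_len(nrow(cfg$kinetics$rates)),
                               function(i) as.numeric(cfg$kinetics$rates[i, ]))
  cfg
}

write_sidecar <- function(sim, files, scale) {
  cfg <- sim$config
  gt <- sim$ensemble$params
  meta <- list(
    software = list(package = "smvsim",
                    version = as.character(utils::packageVersion("smvsim"))),
    seed = cfg$seed,
    config = config_for_export(cfg),
    video = list(
      layout = list(nx = cfg$layout$nx, ny = cfg$layout$ny,
                    split_axis = cfg$layout$split_axis,
                    channel_order = c("donor", "acceptor")),
      units = if (cfg$cam$noise_model %in% c("none", "poisson"))
        "photon counts / frame" else "image counts / frame",
      n_frames = cfg$n_frames,
      float_scale = scale),
    ground_truth = list(
      n_molecules = nrow(gt),
      coords = gt[, c("x", "y")],
      itot = gt$itot, gamma = gt$gamma,
      state_fret = lapply(seq_len(nrow(gt)), function(i)
        as.numeric(sim$ensemble$state_fret[i, ])),
      bleach_frame = gt$bleach_frame))
  body <- files[names(files) != "metadata"]
  meta$files <- data.frame(
    name = basename(unname(body)),
    checksum_md5 = unname(tools::md5sum(unname(body))),
    row.names = NULL)
  jsonlite::write_json(meta, files[["metadata"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
}

#' Read a simulated (or foreign) video stack
#'
#' Reads a multi-page grayscale TIFF. If a `metadata.json` sidecar
#' written by [run_simulation()] sits next to the file, it is parsed, the
#' page layout is split back into the two spectral channels, and float
#' stacks are rescaled to photon units; otherwise the raw frames are
#' returned with `metadata = NULL`.
#'
#' @param path Path to the TIFF stack.
#' @return List with `frames` (`ny x nx x L` array; the full page when no
#'   sidecar describes a split), optional `donor` / `acceptor` arrays,
#'   and `metadata`.
#' @export
read_video <- function(path) {
  if (!file.exists(path)) stop(sprintf("video not found: %s", path))
  first <- tryCatch(tiff::readTIFF(path, info = TRUE),
                    error = function(e)
                      stop(sprintf("failed to read TIFF '%s': %s",
                                   path, conditionMessage(e))))
  is_float <- identical(attr(first, "bits.per.sample"), 32L) ||
    identical(attr(first, "sample.format"), "float")
  # integer stacks are read raw (bit-exact); float stacks keep their values
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = !is_float),
                    error = function(e)
                      stop(sprintf("failed to read TIFF '%s': %s",
                                   path, conditionMessage(e))))
  if (!length(pages)) stop(sprintf("no pages in TIFF '%s'", path))
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  side <- file.path(dirname(path), "metadata.json")
  if (!file.exists(side))
    return(list(frames = arr, metadata = NULL))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!is.null(meta$video$float_scale) && meta$video$float_scale != 1)
    arr <- arr * meta$video$float_scale
  lay <- meta$video$layout
  if (lay$split_axis == "y") {
    ny <- lay$ny
    don <- arr[seq_len(ny), , , drop = FALSE]
    acc <- arr[ny + seq_len(ny), , , drop = FALSE]
  } else {
    nx <- lay$nx
    don <- arr[, seq_len(nx), , drop = FALSE]
    acc <- arr[, nx + seq_len(nx), , drop = FALSE]
  }
  list(frames = arr, donor = don, acceptor = acc, metadata = meta)
}

#' Read/write detection tables
#'
#' Detections travel as delimited text with columns
#' `frame`, `x`, `y`, `intensity`, so external detectors can be scored
#' with [match_greedy()].
#'
#' @param det A `detection_set` or data frame.
#' @param path File path.
#' @param frame Frame index to record (0 for a time-averaged image).
#' @return `write_detections` invisibly returns `path`;
#'   `read_detections` returns a data frame.
#' @export
write_detections <- function(det, path, frame = 0) {
  d <- if (inherits(det, "detection_set")) det$detections else det
  out <- data.frame(frame = frame, x = d$x, y = d$y,
                    intensity = if (is.null(d$intensity)) NA else d$intensity)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  utils::read.csv(path)
}
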