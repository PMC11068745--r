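#' Rendering configuration
#'
#' Converts simulated trajectories into DAPI-like fluorescence frames.
#' Nuclei are drawn as isotropic Gaussian blobs on a constant background
#' with additive Gaussian noise. The default pixel size (0.65 um/px,
#' typical of a CCD behind a 10x objective) is a configurable placeholder:
#' real acquisitions must supply their calibrated value.
#'
#' @param pixel_size um per pixel, > 0.
#' @param blob_sigma Gaussian blob SD (um), > 0.
#' @param peak_intensity blob peak amplitude (arbitrary units).
#' @param background_mean constant background level.
#' @param noise_sd additive Gaussian noise SD, >= 0.
#' @param image_shape integer length-2, image size in pixels (nx, ny).
#' @return Object of class `render_config`.
#' @export
render_config <- function(pixel_size = 0.65, blob_sigma = 3,
                          peak_intensity = 100, background_mean = 10,
                          noise_sd = 2, image_shape = c(256, 256)) {
  stopifnot(pixel_size > 0, blob_sigma > 0, noise_sd >= 0,
            length(image_shape) == 2, all(image_shape >= 4))
  structure(
    list(pixel_size = pixel_size, blob_sigma = blob_sigma,
         peak_intensity = peak_intensity, background_mean = background_mean,
         noise_sd = noise_sd, image_shape = as.integer(image_shape)),
    class = "render_config"
  )
}

#' Render tracks into a synthetic time-lapse
#'
#' Each track position becomes an isotropic Gaussian blob; one frame per
#' time point. Image arrays are indexed `[x, y]` with 0-based pixel
#' centres, so a cell at `x_um` sits at pixel coordinate
#' `x_um / pixel_size`. The number of blobs in a frame equals the number
#' of tracks alive at that frame.
#'
#' @param tracks track table (positions in um).
#' @param render a [render_config()].
#' @param seed RNG seed for the noise field.
#' @return Object of class `frame_stack`: list with `frames` (array
#'   `nx x ny x n_frames`), `pixel_size` (um/px) and `frame_interval`
#'   (min).
#' @export
render_movie <- function(tracks, render, seed = 1L) {
  stopifnot(inherits(render, "render_config"))
  nx <- render$image_shape[1]; ny <- render$image_shape[2]
  frames_idx <- if (nrow(tracks) > 0) sort(unique(tracks$frame)) else 0L
  n_frames <- length(frames_idx)
  dtv <- if (nrow(tracks) > 0) diff(sort(unique(tracks$t_min))) else 1
  frame_interval <- if (length(dtv)) dtv[1] else 1

  set.seed(seed)
  stack <- array(stats::rnorm(nx * ny * n_frames, render$background_mean,
                              render$noise_sd),
                 dim = c(nx, ny, n_frames))

  sig <- render$blob_sigma / render$pixel_size    # px
  half <- ceiling(4 * sig)
  for (fi in seq_along(frames_idx)) {
    rows <- tracks[tracks$frame == frames_idx[fi], , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      cx <- rows$x_um[r] / render$pixel_size
      cy <- rows$y_um[r] / render$pixel_size
      if (cx < 0 || cx > nx - 1 || cy < 0 || cy > ny - 1)
        stop(sprintf("track %s, frame %s: position (%.1f, %.1f) px outside the %d x %d image",
                     rows$track_id[r], frames_idx[fi], cx, cy, nx, ny))
      xs <- max(0, floor(cx - half)):min(nx - 1, ceiling(cx + half))
      ys <- max(0, floor(cy - half)):min(ny - 1, ceiling(cy + half))
      g <- render$peak_intensity *
        exp(-outer((xs - cx)^2, (ys - cy)^2, "+") / (2 * sig^2))
      stack[xs + 1, ys + 1, fi] <- stack[xs + 1, ys + 1, fi] + g
    }
  }
  structure(list(frames = stack, pixel_size = render$pixel_size,
                 frame_interval = frame_interval),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack: %d frames of %d x %d px, %g um/px, %g min/frame>\n",
              d[3], d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Write / read a frame stack as multi-page TIFF
#'
#' Frames are written as 16-bit multi-page TIFF. Physical metadata (pixel
#' size in um, frame interval in min) and the intensity scale are stored
#' in a YAML sidecar next to the image (`<path>.yml`) and recovered on
#' read; without the sidecar, `read_movie()` requires `pixel_size` and
#' `frame_interval` explicitly.
#'
#' @param stack a `frame_stack`.
#' @param path output path.
#' @export
write_movie <- function(stack, path) {
  lo <- min(stack$frames); hi <- max(stack$frames)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(i)
    t((stack$frames[, , i] - lo) / scale))    # tiff expects row-major [y, x]
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  yaml::write_yaml(
    list(physical_size_x_um = stack$pixel_size,
         physical_size_y_um = stack$pixel_size,
         time_increment_min = stack$frame_interval,
         intensity_offset = lo, intensity_scale = scale),
    paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_movie
#' @param pixel_size,frame_interval fall-backs when the file has no
#'   metadata sidecar.
#' @export
read_movie <- function(path, pixel_size = NULL, frame_interval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- if (file.exists(paste0(path, ".yml")))
    yaml::read_yaml(paste0(path, ".yml")) else list()
  px <- meta$physical_size_x_um %||% pixel_size
  dt <- meta$time_increment_min %||% frame_interval
  if (is.null(px) || is.null(dt))
    stop("pixel_size / frame_interval not found in metadata; pass them explicitly")
  off <- meta$intensity_offset %||% 0
  scl <- meta$intensity_scale %||% 1
  arr <- array(NA_real_, dim = c(ncol(pages[[1]]), nrow(pages[[1]]),
                                 length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- t(pages[[i]]) * scl + off
  structure(list(frames = arr, pixel_size = px, frame_interval = dt),
            class = "frame_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
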