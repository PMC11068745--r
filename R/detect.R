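#' Detect nuclei in a single frame
#'
#' Segments bright blobs on a dark background: Gaussian smoothing, Otsu (or
#' fixed) threshold, connected components, and an intensity-weighted
#' centre of mass per component (weights are the above-threshold part of
#' the raw signal, so the centroid is sub-pixel). The frame is an array
#' indexed `[x, y]`, pixel centres at 0-based indices.
#'
#' @param frame numeric matrix `[x, y]`, finite values.
#' @param pixel_size um per pixel.
#' @param min_area minimum component area (px).
#' @param smoothing_sigma Gaussian smoothing SD (px); 0 disables.
#' @param threshold `"otsu"` or a fixed numeric threshold on the raw
#'   intensity scale.
#' @return Data frame with one row per detection: `x_px`, `y_px`
#'   (sub-pixel, 0-based), `x_um`, `y_um`, `area_px`, `mean_intensity`.
#'   A uniform frame yields zero rows.
#' @export
detect_nuclei <- function(frame, pixel_size, min_area = 4,
                          smoothing_sigma = 2, threshold = "otsu") {
  if (!is.matrix(frame) || length(frame) == 0)
    stop("frame must be a non-empty matrix")
  if (any(!is.finite(frame))) stop("frame contains non-finite pixels")

  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      area_px = integer(0), mean_intensity = numeric(0))
  rng <- range(frame)
  if (rng[1] == rng[2]) return(empty)     # flat frame: nothing to find

  norm <- (frame - rng[1]) / (rng[2] - rng[1])
  sm <- if (smoothing_sigma > 0)
    as.matrix(EBImage::gblur(EBImage::Image(norm), sigma = smoothing_sigma))
  else norm

  th <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(pmin(pmax(sm, 0), 1)))
  } else {
    (threshold - rng[1]) / (rng[2] - rng[1])
  }
  mask <- sm > th
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.matrix(lab)

  th_raw <- th * (rng[2] - rng[1]) + rng[1]
  ids <- setdiff(unique(as.vector(lab)), 0)
  res <- lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < min_area) return(NULL)
    vals <- frame[idx]
    w <- pmax(vals - th_raw, 0)
    if (sum(w) == 0) w <- rep(1, length(vals))
    data.frame(x_px = sum((idx[, 1] - 1) * w) / sum(w),
               y_px = sum((idx[, 2] - 1) * w) / sum(w),
               area_px = nrow(idx), mean_intensity = mean(vals))
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty)
  res$x_um <- res$x_px * pixel_size
  res$y_um <- res$y_px * pixel_size
  res[, c("x_px", "y_px", "x_um", "y_um", "area_px", "mean_intensity")]
}

#' Detect nuclei in every frame of a stack
#'
#' @param stack a `frame_stack` (see [render_movie()] / [read_movie()]).
#' @param ... passed to [detect_nuclei()].
#' @return Data frame of detections with a `frame` column (0-based).
#' @export
detect_stack <- function(stack, ...) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- dim(stack$frames)[3]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    d <- detect_nuclei(stack$frames[, , i], pixel_size = stack$pixel_size, ...)
    if (nrow(d)) d$frame <- i - 1L
    out[[i]] <- d
  }
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (!length(out))
    return(data.frame(frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), x_um = numeric(0),
                      y_um = numeric(0), area_px = integer(0),
                      mean_intensity = numeric(0)))
  do.call(rbind, out)
}

#' Link per-frame detections into tracks
#'
#' Greedy mutual-nearest-neighbour linking: for each new frame, candidate
#' links between open track ends and detections are assigned in order of
#' increasing displacement (ties broken by smaller track id), discarding
#' links longer than `max_disp`. Unmatched detections start new tracks;
#' tracks not extended for more than `max_gap` frames are closed; tracks
#' with fewer than `min_track_length` points are dropped.
#'
#' @param detections data frame with `frame`, `x_um`, `y_um` (as returned
#'   by [detect_stack()]).
#' @param frame_interval minutes between consecutive frames.
#' @param max_disp maximum link displacement (um), > 0.
#' @param max_gap frames a track may skip and still be linkable (default 0:
#'   no gap closing).
#' @param min_track_length minimum number of points to keep a track.
#' @return Track table (see [as_tracks()]).
#' @export
link_tracks <- function(detections, frame_interval, max_disp,
                        max_gap = 0L, min_track_length = 2L) {
  if (!is.finite(max_disp) || max_disp <= 0)
    stop("max_disp must be a positive displacement in um")
  if (nrow(detections) == 0)
    return(as_tracks(data.frame(track_id = integer(0), frame = integer(0),
                                t_min = numeric(0), x_um = numeric(0),
                                y_um = numeric(0))))
  detections <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(detections$frame))

  # open tracks: list of (id, last_frame, last_xy, rows)
  tracks <- list(); next_id <- 1L
  for (f in frames) {
    det <- detections[detections$frame == f, , drop = FALSE]
    open <- which(vapply(tracks, function(tr)
      f - tr$last_frame >= 1 && f - tr$last_frame <= 1 + max_gap,
      logical(1)))
    assigned_det <- rep(FALSE, nrow(det))
    if (length(open) && nrow(det)) {
      ends <- t(vapply(tracks[open], function(tr) tr$last_xy, numeric(2)))
      dmat <- sqrt(outer(ends[, 1], det$x_um, "-")^2 +
                   outer(ends[, 2], det$y_um, "-")^2)
      dmat[dmat > max_disp] <- Inf
      # greedy: repeatedly take the globally smallest displacement, which
      # is always a mutual nearest neighbour of the remaining sets
      repeat {
        if (!any(is.finite(dmat))) break
        m <- which(dmat == min(dmat), arr.ind = TRUE)
        # tie-break: smaller track id (rows are in id order), then first det
        m <- m[order(m[, 1], m[, 2]), , drop = FALSE][1, ]
        ti <- open[m[1]]; di <- m[2]
        tracks[[ti]]$rows[[length(tracks[[ti]]$rows) + 1]] <-
          c(f, det$x_um[di], det$y_um[di])
        tracks[[ti]]$last_frame <- f
        tracks[[ti]]$last_xy <- c(det$x_um[di], det$y_um[di])
        assigned_det[di] <- TRUE
        dmat[m[1], ] <- Inf
        dmat[, m[2]] <- Inf
      }
    }
    for (di in which(!assigned_det)) {
      tracks[[length(tracks) + 1]] <- list(
        id = next_id, last_frame = f,
        last_xy = c(det$x_um[di], det$y_um[di]),
        rows = list(c(f, det$x_um[di], det$y_um[di])))
      next_id <- next_id + 1L
    }
  }
  keep <- Filter(function(tr) length(tr$rows) >= min_track_length, tracks)
  if (!length(keep))
    return(as_tracks(data.frame(track_id = integer(0), frame = integer(0),
                                t_min = numeric(0), x_um = numeric(0),
                                y_um = numeric(0))))
  out <- do.call(rbind, lapply(keep, function(tr) {
    m <- do.call(rbind, tr$rows)
    data.frame(track_id = tr$id, frame = as.integer(m[, 1]),
               t_min = m[, 1] * frame_interval,
               x_um = m[, 2], y_um = m[, 3])
  }))
  as_tracks(out)
}

#' Track a movie end-to-end
#'
#' Convenience wrapper: [detect_stack()] then [link_tracks()].
#'
#' @inheritParams detect_stack
#' @inheritParams link_tracks
#' @export
track_movie <- function(stack, max_disp, min_track_length = 2L,
                        max_gap = 0L, ...) {
  det <- detect_stack(stack, ...)
  link_tracks(det, frame_interval = stack$frame_interval,
              max_disp = max_disp, max_gap = max_gap,
              min_track_length = min_track_length)
}
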