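#' Track tables
#'
#' Throughout the package a set of cell trajectories is a plain data frame
#' with columns `track_id`, `frame` (0-based), `t_min`, `x_um`, `y_um`,
#' ordered by track and time. `as_tracks()` validates and normalises such a
#' table (class `tracks` is added for printing only; every function accepts
#' a plain data frame with the same columns).
#'
#' @param df data frame with columns `track_id`, `frame`, `t_min`,
#'   `x_um`, `y_um`.
#' @return The validated table with class `c("tracks", "data.frame")`.
#' @export
as_tracks <- function(df) {
  needed <- c("track_id", "frame", "t_min", "x_um", "y_um")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("track table is missing columns: ", paste(missing, collapse = ", "))
  df <- df[order(df$track_id, df$t_min), needed, drop = FALSE]
  for (id in unique(df$track_id)) {
    t <- df$t_min[df$track_id == id]
    if (any(diff(t) <= 0))
      stop("track ", id, ": timestamps must be strictly increasing")
  }
  class(df) <- c("tracks", "data.frame")
  df
}

#' @export
print.tracks <- function(x, ...) {
  cat(sprintf("Tracks: %d cells, %d positions, t in [%g, %g] min\n",
              length(unique(x$track_id)), nrow(x), min(x$t_min), max(x$t_min)))
  NextMethod()
}

#' Split a track table into per-track data frames
#'
#' @param tracks a track table (see [as_tracks()]).
#' @return Named list of single-track data frames, ordered by time.
#' @export
split_tracks <- function(tracks) {
  tracks <- tracks[order(tracks$track_id, tracks$t_min), , drop = FALSE]
  split(as.data.frame(tracks), tracks$track_id)
}

#' Read / write track CSV
#'
#' The on-disk schema is `track_id,frame,t_min,x_um,y_um`.
#'
#' @param path file path.
#' @export
read_tracks <- function(path) {
  as_tracks(utils::read.csv(path))
}

#' @param tracks track table.
#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' Plot trajectories in x-y coordinates
#'
#' Draws each track as a polyline, optionally recentred to its starting
#' point (the usual presentation for pillar-chamber trajectories).
#'
#' @param x a track table.
#' @param recenter if TRUE, shift each track to start at the origin.
#' @param col vector of colours recycled over tracks.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tracks <- function(x, recenter = FALSE, col = NULL, ...) {
  per <- split_tracks(x)
  if (recenter)
    per <- lapply(per, function(tr) {
      tr$x_um <- tr$x_um - tr$x_um[1]
      tr$y_um <- tr$y_um - tr$y_um[1]
      tr
    })
  xs <- unlist(lapply(per, `[[`, "x_um"))
  ys <- unlist(lapply(per, `[[`, "y_um"))
  if (is.null(col)) col <- grDevices::hcl.colors(max(length(per), 2), "Dark 3")
  col <- rep_len(col, length(per))
  graphics::plot(range(xs), range(ys), type = "n",
                 xlab = "x (um)", ylab = "y (um)", asp = 1, ...)
  for (i in seq_along(per))
    graphics::lines(per[[i]]$x_um, per[[i]]$y_um, col = col[i])
  invisible(x)
}
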