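#' Axial coordinate of a track within a channel
#'
#' Channels run along x; the axial coordinate is distance past the
#' entrance (negative while a cell waits outside).
#'
#' @param track single-track data frame.
#' @param geometry a [channel_geometry()].
#' @return Numeric vector of axial positions (um).
#' @export
axial_position <- function(track, geometry) {
  track$x_um - geometry$entrance_x
}

#' Assign tracks to channels by lateral band majority
#'
#' A track is assigned to the channel whose lateral band (centre +/-
#' width/2 + `lateral_tol`) contains the majority (> 50%) of its
#' positions; otherwise it is unassigned (NA).
#'
#' @param tracks track table.
#' @param geometries list of [channel_geometry()] with distinct bands.
#' @param lateral_tol extra tolerance on each side of the band (um),
#'   absorbing detection jitter.
#' @return Data frame `track_id`, `channel_id` (NA when unassigned).
#' @export
assign_to_channels <- function(tracks, geometries, lateral_tol = 1) {
  if (inherits(geometries, "channel_geometry")) geometries <- list(geometries)
  lo <- vapply(geometries, function(g) g$center_y - g$width / 2 - lateral_tol,
               numeric(1))
  hi <- vapply(geometries, function(g) g$center_y + g$width / 2 + lateral_tol,
               numeric(1))
  o <- order(lo)
  if (length(o) > 1 && any(hi[o][-length(o)] > lo[o][-1]))
    stop("channel lateral bands overlap")
  per <- split_tracks(tracks)
  res <- lapply(per, function(tr) {
    counts <- vapply(seq_along(geometries), function(i)
      sum(tr$y_um >= lo[i] & tr$y_um <= hi[i]), numeric(1))
    best <- which.max(counts)
    ch <- if (counts[best] > nrow(tr) / 2)
      geometries[[best]]$channel_id else NA_integer_
    data.frame(track_id = tr$track_id[1], channel_id = ch)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Instantaneous speeds along a track
#'
#' Finite-difference speed per step: displacement between consecutive
#' positions over the elapsed time. In channels the axial component is
#' used (lateral motion is confined to the 4 um width); elsewhere the full
#' planar displacement.
#'
#' @param track single-track data frame, >= 2 positions.
#' @param component `"xy"` (planar) or `"axial"` (x only).
#' @return Numeric vector of speeds (um/min), length `n - 1`.
#' @export
instantaneous_speeds <- function(track, component = c("xy", "axial")) {
  component <- match.arg(component)
  if (nrow(track) < 2) return(numeric(0))
  dt <- diff(track$t_min)
  if (any(dt <= 0)) stop("duplicate or non-increasing timestamps")
  disp <- if (component == "axial") abs(diff(track$x_um))
          else sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  disp / dt
}

#' Per-track speed fluctuation
#'
#' Sample standard deviation (n - 1 denominator) of the instantaneous
#' speeds, the per-cell "variation in speed" readout of the microchannel
#' assay. With `cv = TRUE` the coefficient of variation (SD / mean) is
#' returned instead.
#'
#' @inheritParams instantaneous_speeds
#' @param cv return the coefficient of variation instead of the SD.
#' @return um/min (or unitless for `cv = TRUE`); NA when fewer than two
#'   speeds are available.
#' @export
speed_fluctuation <- function(track, component = c("xy", "axial"),
                              cv = FALSE) {
  v <- instantaneous_speeds(track, component)
  if (length(v) < 2) return(NA_real_)
  s <- stats::sd(v)
  if (cv) {
    m <- mean(v)
    if (m == 0) return(NA_real_)
    s / m
  } else s
}

#' Per-cell microchannel summary
#'
#' For every track: whether the cell entered the channel (crossed the
#' entrance from outside and penetrated at least `entry_margin`), the
#' frame of first crossing, mean axial speed, speed fluctuation and the
#' furthest axial distance reached.
#'
#' @param tracks track table (assumed assigned to this channel).
#' @param geometry a [channel_geometry()].
#' @param entry_margin penetration (um) required beyond the entrance for a
#'   crossing to count as an entry; default 10 (about one cell length),
#'   rejecting entrance-grazing cells.
#' @return Data frame with one row per track: `track_id`, `entered`,
#'   `entry_frame`, `mean_speed`, `speed_fluctuation`,
#'   `furthest_distance`.
#' @export
channel_cell_summary <- function(tracks, geometry, entry_margin = 10) {
  per <- split_tracks(tracks)
  res <- lapply(per, function(tr) {
    ax <- axial_position(tr, geometry)
    cross <- which(ax[-1] >= 0 & ax[-length(ax)] < 0) + 1L
    entered <- FALSE; entry_frame <- NA_integer_
    for (k in cross) {
      if (max(ax[k:length(ax)]) >= entry_margin) {
        entered <- TRUE; entry_frame <- tr$frame[k]; break
      }
    }
    furthest <- min(max(max(ax), 0), geometry$length)
    data.frame(track_id = tr$track_id[1], entered = entered,
               entry_frame = entry_frame,
               mean_speed = mean(instantaneous_speeds(tr, "axial")),
               speed_fluctuation = speed_fluctuation(tr, "axial"),
               furthest_distance = furthest)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Count cells entering a channel
#'
#' A cell enters when its axial coordinate crosses the entrance from below
#' and subsequently reaches at least `entry_margin` inside; each track is
#' counted at most once.
#'
#' @inheritParams channel_cell_summary
#' @return Integer count, with the per-track summary as attribute
#'   `summary`.
#' @export
count_entries <- function(tracks, geometry, entry_margin = 10) {
  s <- channel_cell_summary(tracks, geometry, entry_margin)
  structure(sum(s$entered), summary = s)
}

#' Furthest-distance density profile
#'
#' Histogram of the furthest axial distance reached by every entered cell
#' (the cell-density readout of the channel assay), in half-open bins
#' `[k b, (k+1) b)` over `[0, length]`.
#'
#' @param summaries output of [channel_cell_summary()].
#' @param geometry a [channel_geometry()].
#' @param bin_width bin width (um).
#' @return Data frame `bin_start`, `bin_end`, `count`; bin counts sum to
#'   the number of entered cells.
#' @export
density_profile <- function(summaries, geometry, bin_width = 50) {
  d <- summaries$furthest_distance[summaries$entered]
  breaks <- seq(0, geometry$length + bin_width, by = bin_width)
  idx <- findInterval(d, breaks, rightmost.closed = FALSE)  # half-open bins
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             count = counts)
}

#' Fraction of entered cells stalling before a cutoff
#'
#' Fraction of entered cells whose furthest distance is below `cutoff`
#' (default 200 um, the near-entrance accumulation readout).
#'
#' @inheritParams density_profile
#' @param cutoff axial distance (um).
#' @return Fraction in \[0, 1\]; NA when no cell entered.
#' @export
fraction_within <- function(summaries, cutoff = 200) {
  d <- summaries$furthest_distance[summaries$entered]
  if (!length(d)) return(NA_real_)
  mean(d < cutoff)
}

#' Time-resolved mean speed
#'
#' Mean instantaneous speed in consecutive time windows tiling the
#' experiment; each step contributes to the window containing its
#' midpoint. Used to ask whether a cohort slows down over the assay.
#'
#' @param tracks track table.
#' @param window window width (min).
#' @param component see [instantaneous_speeds()].
#' @return Data frame `window_start`, `window_end`, `mean_speed` (NA for
#'   windows with no steps), `n_steps`.
#' @export
time_resolved_speed <- function(tracks, window, component = c("xy", "axial")) {
  component <- match.arg(component)
  per <- split_tracks(tracks)
  mids <- unlist(lapply(per, function(tr)
    (tr$t_min[-1] + tr$t_min[-nrow(tr)]) / 2))
  spd <- unlist(lapply(per, instantaneous_speeds, component = component))
  t_end <- max(vapply(per, function(tr) max(tr$t_min), numeric(1)))
  starts <- seq(0, t_end, by = window)
  starts <- starts[starts < t_end]          # windows tile [0, t_end)
  idx <- findInterval(mids, c(starts, t_end + window))
  out <- data.frame(window_start = starts, window_end = starts + window)
  out$mean_speed <- vapply(seq_along(starts), function(i) {
    v <- spd[idx == i]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  out$n_steps <- vapply(seq_along(starts), function(i) sum(idx == i),
                        numeric(1))
  out
}
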