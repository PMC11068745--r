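#' Turning angles along a track
#'
#' The turning angle at an interior time point is the angle between the
#' incoming and outgoing displacement vectors over three consecutive
#' positions, in degrees in \[0, 180\]: 0 for straight continuation, 180
#' for a full reversal. Undefined (NA) when either displacement is zero.
#'
#' @param track single-track data frame.
#' @return Numeric vector of length `n - 2` (empty for fewer than 3
#'   positions).
#' @export
turning_angles <- function(track) {
  n <- nrow(track)
  if (n < 3) return(numeric(0))
  dx <- diff(track$x_um); dy <- diff(track$y_um)
  nrm <- sqrt(dx^2 + dy^2)
  i <- seq_len(n - 2)
  dot <- dx[i] * dx[i + 1] + dy[i] * dy[i + 1]
  denom <- nrm[i] * nrm[i + 1]
  a <- rep(NA_real_, n - 2)
  ok <- denom > 0
  a[ok] <- acos(pmin(pmax(dot[ok] / denom[ok], -1), 1)) * 180 / pi
  a
}

#' Per-step metrics for a set of tracks
#'
#' One row per step (consecutive position pair): displacement, speed and,
#' for interior steps, the turning angle at the step's starting point
#' (angle between the previous and the current displacement).
#'
#' @param tracks track table.
#' @return Data frame `track_id`, `step` (1-based), `displacement_um`,
#'   `speed`, `alpha_deg` (NA for each track's first step and wherever a
#'   zero displacement makes the angle undefined).
#' @export
step_metrics <- function(tracks) {
  per <- split_tracks(tracks)
  out <- lapply(per, function(tr) {
    n <- nrow(tr)
    if (n < 2) return(NULL)
    disp <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
    dt <- diff(tr$t_min)
    alpha <- c(NA_real_, turning_angles(tr))
    data.frame(track_id = tr$track_id[1], step = seq_len(n - 1),
               displacement_um = disp, speed = disp / dt,
               alpha_deg = alpha)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify steps as persistent / confined / non-motile
#'
#' A step is motile when its displacement exceeds `motile_min_disp`.
#' Motile steps with a defined turning angle are persistent when
#' `alpha < alpha_threshold` and confined when `alpha >= alpha_threshold`
#' (the boundary angle is assigned to confined). Non-motile steps are
#' labelled `non-motile` regardless of angle; motile steps without a
#' defined angle (track ends, zero neighbouring displacement) get NA.
#'
#' @param steps output of [step_metrics()].
#' @param alpha_threshold persistent/confined boundary (degrees),
#'   default 30.
#' @param motile_min_disp displacement (um) above which a step counts as
#'   motile; default 0.65 um, one pixel at the default calibration.
#' @return `steps` with logical `motile` and character `label` columns.
#' @export
classify_steps <- function(steps, alpha_threshold = 30,
                           motile_min_disp = 0.65) {
  if (!is.finite(alpha_threshold) || alpha_threshold < 0)
    stop("alpha_threshold must be a non-negative angle in degrees")
  steps$motile <- steps$displacement_um > motile_min_disp
  steps$label <- ifelse(!steps$motile, "non-motile",
                 ifelse(is.na(steps$alpha_deg), NA_character_,
                 ifelse(steps$alpha_deg < alpha_threshold,
                        "persistent", "confined")))
  steps
}

#' Percent of motile time spent confined
#'
#' Among motile interior steps (motile, with a defined turning angle),
#' the percentage labelled confined — the directional-instability readout
#' of the pillar-chamber assay.
#'
#' @param steps classified step table ([classify_steps()]), for one track
#'   or a whole cohort.
#' @return Percent in \[0, 100\]; NA when there is no motile interior
#'   step.
#' @export
percent_time_confined <- function(steps) {
  den <- steps$motile & !is.na(steps$alpha_deg)
  if (!any(den)) return(NA_real_)
  100 * sum(steps$label[den] == "confined") / sum(den)
}

#' Per-track percent time confined
#'
#' @inheritParams percent_time_confined
#' @return Data frame `track_id`, `percent_confined`.
#' @export
percent_time_confined_by_track <- function(steps) {
  ids <- unique(steps$track_id)
  data.frame(track_id = ids,
             percent_confined = vapply(ids, function(id)
               percent_time_confined(steps[steps$track_id == id, ]),
               numeric(1)))
}

#' Trajectory (path) length
#'
#' Total path length: sum of step displacements, not the net displacement.
#'
#' @param track single-track data frame.
#' @return Length in um (0 for a single point).
#' @export
track_length <- function(track) {
  if (nrow(track) < 2) return(0)
  sum(sqrt(diff(track$x_um)^2 + diff(track$y_um)^2))
}

#' Path length of every track
#'
#' @param tracks track table.
#' @return Data frame `track_id`, `length_um`.
#' @export
track_lengths <- function(tracks) {
  per <- split_tracks(tracks)
  data.frame(track_id = as.numeric(names(per)),
             length_um = vapply(per, track_length, numeric(1)),
             row.names = NULL)
}

#' Select the n longest trajectories
#'
#' Returns the `n` tracks with the largest path length (ties broken by
#' smaller track id), the usual selection for trajectory overlay figures.
#'
#' @param tracks track table.
#' @param n number of tracks, default 16.
#' @return Track table restricted to the selected tracks.
#' @export
top_n_tracks <- function(tracks, n = 16) {
  stopifnot(n >= 1)
  len <- track_lengths(tracks)
  ord <- len[order(-len$length_um, len$track_id), ]
  keep <- utils::head(ord$track_id, n)
  out <- tracks[tracks$track_id %in% keep, , drop = FALSE]
  as_tracks(as.data.frame(out))
}
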