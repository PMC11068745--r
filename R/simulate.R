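#' Simulation configuration
#'
#' Parameters shared by the trajectory simulators. Defaults follow the
#' live-imaging protocol for the microfabricated chips: one frame every
#' 3 min for 16 h. Speeds are in um/min; `angular_noise_sd` is the standard
#' deviation (radians) of the Gaussian heading increment applied at every
#' step of the two-dimensional persistent random walk, a surrogate for
#' rotational diffusion. `angular_noise_sd = Inf` draws a fresh uniform
#' heading each step (the memoryless limit).
#'
#' @param mean_speed mean instantaneous speed (um/min), >= 0.
#' @param speed_sd per-step speed standard deviation (um/min), >= 0.
#' @param angular_noise_sd heading-increment SD (radians/step); may be `Inf`.
#' @param frame_interval time between frames (min), > 0.
#' @param duration total duration (min), >= `frame_interval`.
#' @param n_cells number of cells, >= 1.
#' @param seed integer RNG seed; identical seed + config reproduces the
#'   simulation bit-for-bit.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(mean_speed = 4, speed_sd = 1,
                              angular_noise_sd = 0.5,
                              frame_interval = 3, duration = 960,
                              n_cells = 50, seed = 1L) {
  stopifnot(mean_speed >= 0, speed_sd >= 0, frame_interval > 0,
            duration >= frame_interval, n_cells >= 1,
            angular_noise_sd >= 0)
  structure(
    list(mean_speed = mean_speed, speed_sd = speed_sd,
         angular_noise_sd = angular_noise_sd,
         frame_interval = frame_interval, duration = duration,
         n_cells = as.integer(n_cells), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# per-step speed draw; truncated at zero so displacement stays forward
.draw_speed <- function(n, mean_speed, speed_sd) {
  if (speed_sd == 0) rep(mean_speed, n)
  else pmax(0, stats::rnorm(n, mean_speed, speed_sd))
}

# Advance from p by displacement d with specular reflection off pillar
# disks and arena walls. Returns list(pos, dir): final position and the
# (unit) direction after any reflections, so the walk's heading memory is
# carried through a bounce.
.move_reflect <- function(p, d, geometry, max_bounce = 20L) {
  r <- geometry$pillar_diameter / 2
  W <- geometry$arena_size[1]; H <- geometry$arena_size[2]
  centers <- geometry$centers
  for (b in seq_len(max_bounce)) {
    len <- sqrt(sum(d^2))
    if (len < 1e-12) break
    # earliest intersection with any pillar circle along p -> p + d
    t_hit <- Inf; n_hit <- NULL
    if (nrow(centers) > 0) {
      # quadratic |p + t d - c|^2 = r^2 per pillar, vectorised
      px <- p[1] - centers[, 1]; py <- p[2] - centers[, 2]
      a <- sum(d^2)
      bq <- 2 * (px * d[1] + py * d[2])
      cq <- px^2 + py^2 - r^2
      disc <- bq^2 - 4 * a * cq
      ok <- disc >= 0
      if (any(ok)) {
        sq <- sqrt(disc[ok])
        t1 <- (-bq[ok] - sq) / (2 * a)
        t1[t1 < 1e-9 | t1 > 1] <- Inf
        if (any(is.finite(t1))) {
          i <- which.min(t1)
          idx <- which(ok)[i]
          t_hit <- t1[i]
          hit <- p + t_hit * d
          n_hit <- (hit - c(centers[idx, 1], centers[idx, 2])) / r
        }
      }
    }
    # arena walls (normal pointing inward)
    for (w in list(c(1, 0, 0), c(-1, 0, W), c(0, 1, 0), c(0, -1, H))) {
      nw <- w[1:2]; off <- w[3]
      denom <- sum(d * nw)
      if (denom < 0) {       # moving toward this wall
        # distance along d to the wall plane
        tw <- if (nw[1] != 0) (off - p[1]) / d[1] else (off - p[2]) / d[2]
        if (tw > 1e-9 && tw <= 1 && tw < t_hit) {
          t_hit <- tw; n_hit <- nw
        }
      }
    }
    if (!is.finite(t_hit)) {
      p <- p + d
      return(list(pos = p, dir = d / len))
    }
    hit <- p + t_hit * d
    rem <- (1 - t_hit) * d
    d <- rem - 2 * sum(rem * n_hit) * n_hit
    p <- hit + 1e-9 * n_hit   # nudge off the surface
  }
  list(pos = p, dir = if (sqrt(sum(d^2)) > 0) d / sqrt(sum(d^2)) else c(1, 0))
}

#' Simulate persistent random walks in a pillar chamber
#'
#' Each cell performs a heading-increment persistent random walk: per step
#' the heading receives Gaussian noise of SD `angular_noise_sd` and the
#' step length is `speed * frame_interval` with speed drawn independently
#' per step. Collisions with pillar disks and arena walls are resolved by
#' specular reflection, so the zero-noise limit remains deterministic
#' straight-line motion.
#'
#' @param config a [simulation_config()].
#' @param geometry a [pillar_geometry()].
#' @param start_region optional `c(xmin, xmax, ymin, ymax)` (um)
#'   restricting the uniform draw of starting positions (e.g. to keep
#'   cells away from arena walls); default: the whole arena.
#' @return Track table (see [as_tracks()]) with one track per cell and
#'   `duration / frame_interval + 1` positions each.
#' @export
simulate_prw_2d <- function(config, geometry, start_region = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(geometry, "pillar_geometry"))
  set.seed(config$seed)
  dt <- config$frame_interval
  n_steps <- floor(config$duration / dt)
  n <- config$n_cells
  W <- geometry$arena_size[1]; H <- geometry$arena_size[2]
  sr <- if (is.null(start_region)) c(0, W, 0, H) else start_region
  stopifnot(length(sr) == 4, sr[1] >= 0, sr[2] <= W, sr[3] >= 0, sr[4] <= H)

  # rejection-sample pillar-free starting positions
  starts <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    for (try in 1:1000) {
      p <- c(stats::runif(1, sr[1], sr[2]), stats::runif(1, sr[3], sr[4]))
      if (!.inside_pillar(p, geometry)) { starts[i, ] <- p; break }
    }
    if (is.na(starts[i, 1]))
      stop("arena is fully blocked by pillars: no free starting position found")
  }

  out <- vector("list", n)
  uniform <- is.infinite(config$angular_noise_sd)
  for (i in seq_len(n)) {
    pos <- matrix(NA_real_, n_steps + 1, 2)
    pos[1, ] <- starts[i, ]
    theta <- stats::runif(1, -pi, pi)
    speeds <- .draw_speed(n_steps, config$mean_speed, config$speed_sd)
    dtheta <- if (uniform) NULL
      else stats::rnorm(n_steps, 0, config$angular_noise_sd)
    p <- starts[i, ]
    for (k in seq_len(n_steps)) {
      theta <- if (uniform) stats::runif(1, -pi, pi) else theta + dtheta[k]
      d <- speeds[k] * dt * c(cos(theta), sin(theta))
      mv <- .move_reflect(p, d, geometry)
      p <- mv$pos
      # heading memory follows the post-reflection direction
      if (speeds[k] > 0) theta <- atan2(mv$dir[2], mv$dir[1])
      pos[k + 1, ] <- p
    }
    out[[i]] <- data.frame(track_id = i, frame = 0:n_steps,
                           t_min = (0:n_steps) * dt,
                           x_um = pos[, 1], y_um = pos[, 2])
  }
  as_tracks(do.call(rbind, out))
}

#' Simulate one-dimensional migration in microchannels
#'
#' Cells wait in the loading well just outside the channel entrance and
#' enter with probability `entry_prob` per frame (a Bernoulli trial, so the
#' number of entering cells is a controllable ground truth). Once inside, a
#' cell moves along the channel axis with per-step speed drawn from
#' `N(mean_speed, speed_sd)` truncated at zero, reversing direction with
#' probability `reverse_prob` per step, clamped to
#' `[-entry_margin, length]`. The lateral coordinate is fixed to the
#' channel centre line. `speed_profile`, if given, is a function of time
#' (min) returning the mean speed at that time and overrides `mean_speed`
#' (used e.g. to emulate cohorts that start fast and slow down).
#'
#' @param config a [simulation_config()].
#' @param geometry a [channel_geometry()].
#' @param entry_prob per-frame probability of entering, in (0, 1].
#' @param entry_margin how far outside the entrance cells wait (um).
#' @param reverse_prob per-step probability of reversing direction.
#' @param speed_profile optional function(t_min) -> mean speed (um/min).
#' @return Track table with attribute `ground_truth`: a data frame with
#'   per-cell `entry_frame` (NA when the cell never entered) and `entered`.
#' @export
simulate_channel_1d <- function(config, geometry, entry_prob = 0.5,
                                entry_margin = 10, reverse_prob = 0,
                                speed_profile = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(geometry, "channel_geometry"))
  set.seed(config$seed)
  dt <- config$frame_interval
  n_steps <- floor(config$duration / dt)
  n <- config$n_cells

  out <- vector("list", n)
  entry_frame <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    x <- numeric(n_steps + 1)
    x[1] <- -entry_margin
    entered <- FALSE
    dir <- 1
    for (k in seq_len(n_steps)) {
      t_now <- (k - 1) * dt
      if (!entered) {
        if (stats::runif(1) < entry_prob) {
          entered <- TRUE
          entry_frame[i] <- k
        } else {
          x[k + 1] <- x[k]
          next
        }
      }
      mu <- if (is.null(speed_profile)) config$mean_speed
            else speed_profile(t_now)
      v <- .draw_speed(1, mu, config$speed_sd)
      if (reverse_prob > 0 && stats::runif(1) < reverse_prob) dir <- -dir
      x[k + 1] <- min(max(x[k] + dir * v * dt, -entry_margin),
                      geometry$length)
    }
    out[[i]] <- data.frame(
      track_id = i, frame = 0:n_steps, t_min = (0:n_steps) * dt,
      x_um = geometry$entrance_x + x,
      y_um = rep(geometry$center_y, n_steps + 1))
  }
  tracks <- as_tracks(do.call(rbind, out))
  # ground truth: the Bernoulli decision, qualified by actual penetration
  # past the entry margin (slow cells may never make it inside)
  max_ax <- vapply(out, function(tr) max(tr$x_um) - geometry$entrance_x,
                   numeric(1))
  attr(tracks, "ground_truth") <- data.frame(
    track_id = seq_len(n), entry_frame = entry_frame,
    entered = !is.na(entry_frame) & max_ax >= entry_margin)
  tracks
}
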