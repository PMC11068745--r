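#' Microchannel geometry
#'
#' Describes one straight microchannel. Channels in the devices used for
#' confined one-dimensional migration are 4 um wide, 5 um high and roughly
#' 900 um long; the channel axis is taken along x, with the entrance at
#' `entrance_x` and the lateral (y) position of the channel centre at
#' `center_y`. All coordinates are in micrometres.
#'
#' @param channel_id integer identifier.
#' @param entrance_x axial coordinate of the channel entrance (um).
#' @param center_y lateral position of the channel centre line (um).
#' @param width channel width (um), default 4.
#' @param height channel height (um, metadata only), default 5.
#' @param length channel length (um), default 900.
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(channel_id = 0L, entrance_x = 0, center_y = 0,
                             width = 4, height = 5, length = 900) {
  if (!is.finite(length) || length <= 0)
    stop("channel length must be > 0")
  if (!is.finite(width) || width <= 0)
    stop("channel width must be > 0")
  structure(
    list(channel_id = as.integer(channel_id), entrance_x = entrance_x,
         center_y = center_y, width = width, height = height,
         length = length),
    class = "channel_geometry"
  )
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel %d: %g x %g um cross-section, %g um long, entrance x=%g um, center y=%g um>\n",
              x$channel_id, x$width, x$height, x$length, x$entrance_x,
              x$center_y))
  invisible(x)
}

#' Micropillar lattice geometry
#'
#' Square lattice of cylindrical pillars inside a rectangular arena, the
#' device used for confined two-dimensional migration. Default dimensions
#' follow the fabricated chips: 10 um diameter pillars spaced 30 um apart
#' in a 5 um high chamber.
#'
#' @param pillar_diameter pillar diameter (um), default 10.
#' @param spacing centre-to-centre lattice spacing (um), default 30.
#' @param arena_size numeric length-2, arena width and height (um).
#' @param height chamber height (um, metadata only), default 5.
#' @param n_pillars if 0, the arena contains no pillars (open arena);
#'   otherwise pillars fill the arena on the square lattice.
#' @return An object of class `pillar_geometry` with a `centers` matrix
#'   (one row per pillar, columns x and y, um).
#' @export
pillar_geometry <- function(pillar_diameter = 10, spacing = 30,
                            arena_size = c(300, 300), height = 5,
                            n_pillars = NULL) {
  if (spacing <= pillar_diameter)
    stop("pillar spacing must exceed pillar diameter: the arena is blocked")
  if (any(arena_size <= 0)) stop("arena_size must be positive")
  open_arena <- !is.null(n_pillars) && n_pillars == 0
  if (open_arena) {
    centers <- matrix(numeric(0), ncol = 2)
  } else {
    # lattice offset by spacing/2 so cells can start pillar-free at corners
    xs <- seq(spacing / 2, arena_size[1] - spacing / 2, by = spacing)
    ys <- seq(spacing / 2, arena_size[2] - spacing / 2, by = spacing)
    centers <- as.matrix(expand.grid(x = xs, y = ys))
  }
  structure(
    list(pillar_diameter = pillar_diameter, spacing = spacing,
         arena_size = arena_size, height = height, centers = centers),
    class = "pillar_geometry"
  )
}

#' @export
print.pillar_geometry <- function(x, ...) {
  cat(sprintf("<pillar lattice: %d pillars, %g um diameter, %g um spacing, arena %g x %g um>\n",
              nrow(x$centers), x$pillar_diameter, x$spacing,
              x$arena_size[1], x$arena_size[2]))
  invisible(x)
}

# TRUE for positions strictly inside any pillar disk
.inside_pillar <- function(pos, geometry) {
  if (nrow(geometry$centers) == 0) return(FALSE)
  r <- geometry$pillar_diameter / 2
  d2 <- (geometry$centers[, 1] - pos[1])^2 + (geometry$centers[, 2] - pos[2])^2
  any(d2 < r^2 * (1 - 1e-12))
}
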