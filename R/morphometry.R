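#' Multi-channel confocal z-stack container
#'
#' A z-stack is a named list of voxel arrays (one per channel, identical
#' dimensions, indexed `[x, y, z]`) plus the voxel size in um along each
#' axis.
#'
#' @param channels named list of 3-D numeric arrays.
#' @param voxel_size um per voxel, length 3 (x, y, z) or scalar.
#' @return Object of class `zstack`.
#' @export
zstack <- function(channels, voxel_size) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  stopifnot(length(channels) >= 1, !is.null(names(channels)),
            all(voxel_size > 0))
  d <- dim(channels[[1]])
  if (length(d) != 3) stop("channels must be 3-D arrays")
  for (ch in channels)
    if (!identical(dim(ch), d)) stop("all channels must share dimensions")
  structure(list(channels = channels, voxel_size = voxel_size),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<zstack: %s; %d x %d x %d voxels of %g x %g x %g um>\n",
              paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

# global Otsu threshold on the raw intensity scale (EBImage's otsu works
# on [0,1] images; reshape the volume into one frame)
.otsu_raw <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(Inf)
  v <- (as.vector(x) - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(matrix(v, ncol = 1)))
  th * (rng[2] - rng[1]) + rng[1]
}

# 3-D connected-component labelling: 2-D labels per slice (EBImage),
# merged across adjacent slices with union-find on overlapping pixels
.label3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offset <- 0L
  for (z in seq_len(d[3])) {
    sl <- EBImage::bwlabel(EBImage::Image(mask[, , z] * 1))
    sl <- as.matrix(sl)
    sl[sl > 0] <- sl[sl > 0] + offset
    lab[, , z] <- as.integer(sl)
    offset <- max(offset, max(sl))
  }
  n <- offset
  if (n == 0) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (z in seq_len(d[3] - 1)) {
    a <- lab[, , z]; b <- lab[, , z + 1]
    both <- a > 0 & b > 0
    if (!any(both)) next
    pairs <- unique(cbind(a[both], b[both]))
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  compact <- match(root, sort(unique(root)))
  nz <- lab > 0
  lab[nz] <- compact[lab[nz]]
  lab
}

#' Segment cells from the phalloidin channel
#'
#' Global Otsu (or fixed) threshold on the membrane channel, per-slice
#' hole filling (the membrane shell interior becomes solid), 3-D
#' connected components, and a minimum-volume filter. Cells touching the
#' stack border are flagged.
#'
#' @param stack a [zstack()].
#' @param channel channel name, default `"phalloidin"`.
#' @param threshold `"otsu"` or a fixed raw-intensity threshold.
#' @param min_volume_um3 discard components smaller than this (um^3).
#' @return List of cells, each `list(mask, volume_um3, touches_border)`;
#'   masks are mutually exclusive logical arrays. Empty list when the
#'   channel has no foreground.
#' @export
segment_cells <- function(stack, channel = "phalloidin",
                          threshold = "otsu", min_volume_um3 = 5) {
  stopifnot(inherits(stack, "zstack"))
  if (!channel %in% names(stack$channels))
    stop("channel '", channel, "' not present in stack")
  arr <- stack$channels[[channel]]
  th <- if (identical(threshold, "otsu")) .otsu_raw(arr) else threshold
  mask <- arr > th
  if (!any(mask)) return(list())
  filled <- array(FALSE, dim(mask))
  for (z in seq_len(dim(mask)[3]))
    filled[, , z] <- as.matrix(EBImage::fillHull(
      EBImage::Image(mask[, , z] * 1))) > 0
  lab <- .label3d(filled)
  vox_vol <- prod(stack$voxel_size)
  d <- dim(lab)
  out <- list()
  for (id in setdiff(sort(unique(as.vector(lab))), 0L)) {
    m <- lab == id
    vol <- sum(m) * vox_vol
    if (vol < min_volume_um3) next
    border <- any(m[1, , ]) || any(m[d[1], , ]) || any(m[, 1, ]) ||
      any(m[, d[2], ]) || any(m[, , 1]) || any(m[, , d[3]])
    out[[length(out) + 1]] <- list(mask = m, volume_um3 = vol,
                                   touches_border = border)
  }
  out
}

#' Projected inner-membrane surface
#'
#' Area enclosed by the cell outline on the z-axis maximum projection of
#' the filled mask, in um^2 — the z-projection size readout of the
#' phalloidin staining. (The 3-D voxel surface area is available
#' separately as [mask_surface_area_3d()].)
#'
#' @param mask logical 3-D cell mask.
#' @param voxel_size um per voxel, length 3.
#' @return Area in um^2.
#' @export
projected_inner_surface <- function(mask, voxel_size) {
  if (!any(mask)) stop("empty cell mask")
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  proj <- apply(mask, c(1, 2), any)
  sum(proj) * voxel_size[1] * voxel_size[2]
}

#' 3-D voxel surface area of a mask
#'
#' Secondary readout: total area of exposed voxel faces, a raster
#' approximation of the 3-D membrane surface.
#'
#' @inheritParams projected_inner_surface
#' @return Area in um^2.
#' @export
mask_surface_area_3d <- function(mask, voxel_size) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  d <- dim(mask)
  m <- mask
  # exposed faces along each axis = interior transitions + boundary faces
  fx <- sum(m[-1, , ] != m[-d[1], , ]) + sum(m[1, , ]) + sum(m[d[1], , ])
  fy <- sum(m[, -1, ] != m[, -d[2], ]) + sum(m[, 1, ]) + sum(m[, d[2], ])
  fz <- sum(m[, , -1] != m[, , -d[3]]) + sum(m[, , 1]) + sum(m[, , d[3]])
  fx * voxel_size[2] * voxel_size[3] +
    fy * voxel_size[1] * voxel_size[3] +
    fz * voxel_size[1] * voxel_size[2]
}

#' Count membrane spikes on the projected outline
#'
#' Spikes are thin protrusions of the projected cell outline: the
#' projection is morphologically opened with a disc of radius
#' `smoothing_radius` (removing protrusions thinner than the disc) to
#' obtain the smooth reference body; connected components of the residual
#' whose radial extent beyond the reference boundary reaches
#' `min_spike_length` are counted as spikes, their length being that
#' maximal extent.
#'
#' @param mask logical 3-D cell mask.
#' @param voxel_size um per voxel (x and y must be equal).
#' @param min_spike_length minimal protrusion length to count (um).
#' @param smoothing_radius disc radius for the reference body (um), > 0.
#' @return `list(count, lengths_um)`.
#' @export
count_spikes <- function(mask, voxel_size, min_spike_length = 1,
                         smoothing_radius = 1) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (smoothing_radius <= 0) stop("smoothing_radius must be > 0")
  px <- voxel_size[1]
  if (abs(voxel_size[1] - voxel_size[2]) > 1e-9)
    stop("count_spikes requires isotropic x/y voxels")
  proj <- apply(mask, c(1, 2), any) * 1
  r_px <- max(1L, round(smoothing_radius / px))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  ref <- as.matrix(EBImage::opening(EBImage::Image(proj), brush)) > 0
  if (!any(ref)) {
    warning("reference body empty after opening; no spikes counted")
    return(list(count = 0L, lengths_um = numeric(0)))
  }
  resid <- (proj > 0) & !ref
  if (!any(resid)) return(list(count = 0L, lengths_um = numeric(0)))
  # distance of each non-reference pixel to the reference body
  dmap <- as.matrix(EBImage::distmap(EBImage::Image((1 - ref) * 1)))
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(resid * 1)))
  lengths <- vapply(setdiff(sort(unique(as.vector(lab))), 0L),
                    function(id) max(dmap[lab == id]) * px, numeric(1))
  keep <- lengths >= min_spike_length
  list(count = sum(keep), lengths_um = unname(lengths[keep]))
}

#' Organelle volume within a cell
#'
#' Thresholds the organelle channel (Otsu within the cell bounding box by
#' default), intersects with the cell mask, and reports the total
#' organelle volume and its percentage of the cell volume.
#'
#' @param organelle 3-D numeric array, aligned with `mask`.
#' @param mask logical 3-D cell mask.
#' @param voxel_size um per voxel.
#' @param threshold `"otsu"` or a fixed raw-intensity threshold.
#' @return `list(volume_um3, percent)` with `percent` in \[0, 100\].
#' @export
organelle_volumes <- function(organelle, mask, voxel_size,
                              threshold = "otsu") {
  if (!any(mask)) stop("empty cell mask")
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  idx <- which(mask, arr.ind = TRUE)
  bb <- apply(idx, 2, range)
  box <- organelle[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3]]
  th <- if (identical(threshold, "otsu")) .otsu_raw(box) else threshold
  org_mask <- organelle > th & mask
  vox_vol <- prod(voxel_size)
  vol <- sum(org_mask) * vox_vol
  cell_vol <- sum(mask) * vox_vol
  pct <- 100 * vol / cell_vol
  stopifnot(pct >= 0, pct <= 100)
  list(volume_um3 = vol, percent = pct)
}

#' Per-cell morphometry table
#'
#' Runs segmentation and all per-cell measurements on a two-channel
#' stack.
#'
#' @param stack a [zstack()] with a phalloidin and (optionally) an
#'   organelle channel.
#' @param phalloidin_channel,organelle_channel channel names.
#' @param ... passed to [count_spikes()].
#' @return Data frame, one row per cell: `cell_id`, `inner_surface_um2`,
#'   `spike_count`, `cell_volume_um3`, `organelle_volume_um3`,
#'   `organelle_percent`, `touches_border`.
#' @export
cell_morphometry <- function(stack, phalloidin_channel = "phalloidin",
                             organelle_channel = "organelle", ...) {
  cells <- segment_cells(stack, channel = phalloidin_channel)
  if (!length(cells))
    return(data.frame(cell_id = integer(0), inner_surface_um2 = numeric(0),
                      spike_count = integer(0), cell_volume_um3 = numeric(0),
                      organelle_volume_um3 = numeric(0),
                      organelle_percent = numeric(0),
                      touches_border = logical(0)))
  has_org <- organelle_channel %in% names(stack$channels)
  rows <- lapply(seq_along(cells), function(i) {
    cl <- cells[[i]]
    sp <- count_spikes(cl$mask, stack$voxel_size, ...)
    if (has_org) {
      ov <- organelle_volumes(stack$channels[[organelle_channel]], cl$mask,
                              stack$voxel_size)
    } else ov <- list(volume_um3 = NA_real_, percent = NA_real_)
    data.frame(cell_id = i,
               inner_surface_um2 = projected_inner_surface(cl$mask,
                                                           stack$voxel_size),
               spike_count = sp$count, cell_volume_um3 = cl$volume_um3,
               organelle_volume_um3 = ov$volume_um3,
               organelle_percent = ov$percent,
               touches_border = cl$touches_border)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
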