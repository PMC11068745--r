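#' Specification of a synthetic 3-D cell
#'
#' Fixture generator for the confocal morphometry operations: an
#' ellipsoidal cell rendered as a membrane shell (phalloidin-like,
#' channel 1) with optional radial membrane spikes, plus an organelle
#' channel (channel 2) of small blobs occupying a prescribed fraction of
#' the cell volume. Every quantity the morphometry module measures is
#' stored as ground truth.
#'
#' @param radius cell radius (um); scalar sphere or length-3 ellipsoid
#'   semi-axes (x, y, z).
#' @param voxel_size um per voxel, scalar (isotropic) or length-3.
#' @param n_spikes number of radial membrane spikes (placed in the
#'   equatorial plane so they are visible in a z-projection).
#' @param spike_length spike length beyond the membrane (um).
#' @param spike_radius spike thickness (um).
#' @param organelle_fraction target fraction of cell volume occupied by
#'   organelle blobs, in \[0, 1\].
#' @param organelle_radius radius of one organelle blob (um).
#' @param shell_thickness membrane shell thickness (um).
#' @param margin clear margin between cell (incl. spikes) and the stack
#'   border (um); must be at least 2 voxels.
#' @return Object of class `cell3d_spec`.
#' @export
cell3d_spec <- function(radius = 3.47, voxel_size = 0.2, n_spikes = 0,
                        spike_length = 2, spike_radius = 0.4,
                        organelle_fraction = 0, organelle_radius = 0.5,
                        shell_thickness = 0.4, margin = 1) {
  if (length(radius) == 1) radius <- rep(radius, 3)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  stopifnot(all(radius > 0), all(voxel_size > 0), n_spikes >= 0,
            spike_length >= 0, organelle_fraction >= 0,
            organelle_fraction <= 1)
  if (margin < 2 * max(voxel_size))
    stop("margin must be at least 2 voxels")
  structure(
    list(radius = radius, voxel_size = voxel_size,
         n_spikes = as.integer(n_spikes), spike_length = spike_length,
         spike_radius = spike_radius,
         organelle_fraction = organelle_fraction,
         organelle_radius = organelle_radius,
         shell_thickness = shell_thickness, margin = margin),
    class = "cell3d_spec"
  )
}

#' Render a synthetic two-channel confocal z-stack
#'
#' Builds the voxel stack described by a [cell3d_spec()]: channel
#' `phalloidin` holds the membrane shell and spikes, channel `organelle`
#' holds blobs placed uniformly inside the cell until the target volume
#' fraction is reached. Ground truth records both analytic values
#' (ellipsoid projected area `pi a b`, volume `4/3 pi a b c`) and the
#' realised voxel-level volumes.
#'
#' @param spec a [cell3d_spec()].
#' @param seed integer RNG seed (spike phase and organelle placement).
#' @return A `zstack` (see [zstack()]) with attribute `ground_truth`.
#' @export
synth_cell_3d <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cell3d_spec"))
  set.seed(seed)
  vs <- spec$voxel_size
  # stack sized so the cell plus spikes keeps a clear border margin
  ext <- max(spec$radius) + spec$spike_length + spec$margin
  dims <- ceiling(2 * ext / vs) + 1
  ctr <- (dims - 1) / 2 * vs                      # um, stack centre

  xs <- (seq_len(dims[1]) - 1) * vs[1] - ctr[1]
  ys <- (seq_len(dims[2]) - 1) * vs[2] - ctr[2]
  zs <- (seq_len(dims[3]) - 1) * vs[3] - ctr[3]
  # normalised ellipsoid radius per voxel
  rho2 <- outer(outer((xs / spec$radius[1])^2, (ys / spec$radius[2])^2, "+"),
                (zs / spec$radius[3])^2, "+")
  inside <- rho2 <= 1
  t_rel <- spec$shell_thickness / min(spec$radius)
  shell <- inside & rho2 >= (1 - t_rel)^2

  memb <- array(0, dims)
  memb[shell] <- 1

  # radial spikes in the equatorial plane, evenly spaced with random phase
  spike_mask <- array(FALSE, dims)
  if (spec$n_spikes > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    iz <- which.min(abs(zs))
    rad_px <- ceiling(spec$spike_radius / vs[1:2])
    for (j in seq_len(spec$n_spikes)) {
      phi <- phase + 2 * pi * (j - 1) / spec$n_spikes
      u <- c(cos(phi), sin(phi))
      # membrane radius along u for the ellipsoid cross-section
      r0 <- 1 / sqrt((u[1] / spec$radius[1])^2 + (u[2] / spec$radius[2])^2)
      ss <- seq(r0 - spec$shell_thickness, r0 + spec$spike_length,
                by = min(vs) / 2)
      for (s in ss) {
        p <- s * u
        ix <- round(p[1] / vs[1] + (dims[1] - 1) / 2) + 1
        iy <- round(p[2] / vs[2] + (dims[2] - 1) / 2) + 1
        xr <- max(1, ix - rad_px[1]):min(dims[1], ix + rad_px[1])
        yr <- max(1, iy - rad_px[2]):min(dims[2], iy + rad_px[2])
        for (a in xr) for (b in yr) {
          if ((xs[a] - p[1])^2 + (ys[b] - p[2])^2 <= spec$spike_radius^2)
            spike_mask[a, b, iz] <- TRUE
        }
      }
    }
    memb[spike_mask] <- 1
  }

  # organelle blobs: spheres dropped uniformly inside the cell until the
  # target volume fraction is realised
  org <- array(0, dims)
  n_inside <- sum(inside)
  achieved <- 0
  if (spec$organelle_fraction > 0) {
    target <- spec$organelle_fraction * n_inside
    r_o <- spec$organelle_radius
    # centres kept one blob radius inside the membrane
    ok_ctr <- rho2 <= (1 - (r_o + spec$shell_thickness) / min(spec$radius))^2
    idx_ok <- which(ok_ctr)
    if (!length(idx_ok))
      stop("organelle blobs do not fit inside the cell")
    org_mask <- array(FALSE, dims)
    rad_px <- ceiling(r_o / vs)
    for (it in 1:10000) {
      if (sum(org_mask) >= target) break
      ci <- arrayInd(sample(idx_ok, 1), dims)
      p <- c(xs[ci[1]], ys[ci[2]], zs[ci[3]])
      xr <- max(1, ci[1] - rad_px[1]):min(dims[1], ci[1] + rad_px[1])
      yr <- max(1, ci[2] - rad_px[2]):min(dims[2], ci[2] + rad_px[2])
      zr <- max(1, ci[3] - rad_px[3]):min(dims[3], ci[3] + rad_px[3])
      d2 <- outer(outer((xs[xr] - p[1])^2, (ys[yr] - p[2])^2, "+"),
                  (zs[zr] - p[3])^2, "+")
      org_mask[xr, yr, zr] <- org_mask[xr, yr, zr] | (d2 <= r_o^2)
    }
    org_mask <- org_mask & inside
    org[org_mask] <- 1
    achieved <- sum(org_mask)
  }

  vox_vol <- prod(vs)
  cell_vox <- inside | spike_mask
  gt <- list(
    projected_area_um2 = pi * spec$radius[1] * spec$radius[2],
    volume_um3 = 4 / 3 * pi * prod(spec$radius),
    volume_vox_um3 = sum(cell_vox) * vox_vol,
    n_spikes = spec$n_spikes,
    spike_length_um = spec$spike_length,
    organelle_volume_um3 = achieved * vox_vol,
    organelle_fraction_pct = 100 * achieved / sum(cell_vox))

  st <- zstack(channels = list(phalloidin = memb, organelle = org),
               voxel_size = vs)
  attr(st, "ground_truth") <- gt
  st
}
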