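sphere <- synth_cell_3d(cell3d_spec(radius = 3.47, voxel_size = 0.2), seed = 1)

test_that("a voxelised sphere is segmented with analytic area and volume", {
  gt <- attr(sphere, "ground_truth")
  expect_equal(gt$projected_area_um2, pi * 3.47^2, tolerance = 1e-12)
  cells <- segment_cells(sphere)
  expect_length(cells, 1)
  area <- projected_inner_surface(cells[[1]]$mask, sphere$voxel_size)
  expect_lt(abs(area - gt$projected_area_um2) / gt$projected_area_um2, 0.05)
  expect_lt(abs(cells[[1]]$volume_um3 - gt$volume_um3) / gt$volume_um3, 0.05)
  expect_false(cells[[1]]$touches_border)
})

test_that("empty stacks and multiple cells are handled", {
  empty <- zstack(list(phalloidin = array(0, c(8, 8, 4))), 0.5)
  expect_length(segment_cells(empty), 0)
  # two non-touching cells in one stack
  a <- synth_cell_3d(cell3d_spec(radius = 2, voxel_size = 0.4), seed = 2)
  d <- dim(a$channels$phalloidin)
  two <- array(0, c(2 * d[1] + 4, d[2], d[3]))
  two[1:d[1], , ] <- a$channels$phalloidin
  two[(d[1] + 5):(2 * d[1] + 4), , ] <- a$channels$phalloidin
  st <- zstack(list(phalloidin = two), 0.4)
  expect_length(segment_cells(st), 2)
})

test_that("projected area of simple shapes is exact up to voxelisation", {
  # axis-aligned cuboid: projection a x b
  m <- array(FALSE, c(20, 20, 10)); m[3:12, 5:14, 2:8] <- TRUE
  expect_equal(projected_inner_surface(m, c(0.5, 0.5, 1)),
               10 * 10 * 0.25)
  # k isolated voxels in one z-plane
  m2 <- array(FALSE, c(10, 10, 5))
  m2[cbind(c(2, 5, 8), c(2, 5, 8), 3)] <- TRUE
  expect_equal(projected_inner_surface(m2, c(0.3, 0.3, 1)), 3 * 0.09)
  expect_error(projected_inner_surface(array(FALSE, c(4, 4, 4)), 0.5),
               "empty")
})

test_that("projected area is rotation-invariant and scales quadratically", {
  cells <- segment_cells(sphere)
  m <- cells[[1]]$mask
  a0 <- projected_inner_surface(m, sphere$voxel_size)
  rot <- aperm(m, c(2, 1, 3))[, dim(m)[1]:1, ]   # 90-degree in-plane rotation
  expect_equal(projected_inner_surface(rot, sphere$voxel_size), a0)
  # isotropic x2 upsampling: area within 2%
  up <- m[rep(seq_len(dim(m)[1]), each = 2),
          rep(seq_len(dim(m)[2]), each = 2), ]
  a2 <- projected_inner_surface(up, sphere$voxel_size / c(2, 2, 1))
  expect_lt(abs(a2 - a0) / a0, 0.02)
})

test_that("voxelised sphere volume error shrinks as voxels shrink", {
  err <- vapply(c(0.5, 0.35, 0.2), function(v) {
    st <- synth_cell_3d(cell3d_spec(radius = 3.47, voxel_size = v,
                                    shell_thickness = 2.5 * v), seed = 3)
    cl <- segment_cells(st)
    abs(cl[[1]]$volume_um3 - 4 / 3 * pi * 3.47^3) / (4 / 3 * pi * 3.47^3)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.05)
})

test_that("spike counting recovers the generated spike number", {
  cells <- segment_cells(sphere)
  smooth <- count_spikes(cells[[1]]$mask, sphere$voxel_size)
  expect_equal(smooth$count, 0L)               # smooth cell: no spikes
  for (k in c(3, 7)) {
    st <- synth_cell_3d(cell3d_spec(radius = 3.47, voxel_size = 0.2,
                                    n_spikes = k, spike_length = 2),
                        seed = k)
    cl <- segment_cells(st)
    sp <- count_spikes(cl[[1]]$mask, st$voxel_size, min_spike_length = 1,
                       smoothing_radius = 1)
    expect_equal(sp$count, k)
    expect_true(all(sp$lengths_um >= 1))
  }
  # sub-threshold spikes are not counted
  st_short <- synth_cell_3d(cell3d_spec(radius = 3.47, voxel_size = 0.2,
                                        n_spikes = 5, spike_length = 0.5),
                            seed = 9)
  cl_s <- segment_cells(st_short)
  expect_equal(count_spikes(cl_s[[1]]$mask, st_short$voxel_size,
                            min_spike_length = 1.2)$count, 0L)
  expect_error(count_spikes(cells[[1]]$mask, sphere$voxel_size,
                            smoothing_radius = 0), "smoothing_radius")
})

test_that("spike count is stable under in-plane rotation of the star", {
  st <- synth_cell_3d(cell3d_spec(radius = 3.47, voxel_size = 0.2,
                                  n_spikes = 5, spike_length = 2), seed = 11)
  cl <- segment_cells(st)
  m <- cl[[1]]$mask
  rot <- aperm(m, c(2, 1, 3))[, dim(m)[1]:1, ]
  n0 <- count_spikes(m, st$voxel_size)$count
  n1 <- count_spikes(rot, st$voxel_size)$count
  expect_lte(abs(n1 - n0), 1)
  expect_equal(n0, 5L)
})

test_that("organelle volume and percentage follow the generator ground truth", {
  cells <- segment_cells(sphere)
  m <- cells[[1]]$mask
  # organelle mask equal to the cell: 100%
  full <- (m * 1)
  ov <- organelle_volumes(full, m, sphere$voxel_size, threshold = 0.5)
  expect_equal(ov$percent, 100)
  # no signal: 0 um3, 0%
  none <- organelle_volumes(array(0, dim(m)), m, sphere$voxel_size)
  expect_equal(none$volume_um3, 0)
  expect_equal(none$percent, 0)
  expect_error(organelle_volumes(full, array(FALSE, dim(m)),
                                 sphere$voxel_size), "empty")
  # generated fraction recovered within 10% relative
  for (f in c(0.05, 0.30)) {
    st <- synth_cell_3d(cell3d_spec(radius = 3.47, voxel_size = 0.2,
                                    organelle_fraction = f), seed = 13)
    gt <- attr(st, "ground_truth")
    cl <- segment_cells(st)
    ov <- organelle_volumes(st$channels$organelle, cl[[1]]$mask,
                            st$voxel_size)
    expect_lt(abs(ov$percent - gt$organelle_fraction_pct) /
              gt$organelle_fraction_pct, 0.10)
    expect_lte(ov$volume_um3, cl[[1]]$volume_um3)
  }
})

test_that("the per-cell morphometry table assembles all readouts", {
  st <- synth_cell_3d(cell3d_spec(radius = 3, voxel_size = 0.25,
                                  n_spikes = 4, spike_length = 1.8,
                                  organelle_fraction = 0.12), seed = 15)
  tab <- cell_morphometry(st)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$spike_count, 4L)
  expect_gt(tab$inner_surface_um2, 0)
  expect_gte(tab$organelle_percent, 0)
  expect_lte(tab$organelle_percent, 100)
  expect_lte(tab$organelle_volume_um3, tab$cell_volume_um3)
})
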