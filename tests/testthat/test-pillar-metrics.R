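test_that("canonical turning angles are exact", {
  expect_equal(turning_angles(make_track(x = c(0, 1, 2), y = c(0, 0, 0))), 0)
  expect_equal(turning_angles(make_track(x = c(0, 1, 1), y = c(0, 0, 1))), 90)
  expect_equal(turning_angles(make_track(x = c(0, 1, 0), y = c(0, 0, 0))), 180)
  expect_length(turning_angles(make_track(x = c(0, 1))), 0)
  # zero displacement makes the angle undefined
  a <- turning_angles(make_track(x = c(0, 1, 1, 2), y = c(0, 0, 0, 0)))
  expect_true(is.na(a[1]) && is.na(a[2]))
})

test_that("turning angles match the law-of-cosines oracle on random triples", {
  set.seed(41)
  for (i in 1:200) {
    p <- matrix(runif(6, -50, 50), ncol = 2)
    got <- turning_angles(make_track(x = p[, 1], y = p[, 2]))
    ref <- oracle_turning_angle(p[1, ], p[2, ], p[3, ])
    expect_lt(abs(got - ref), 1e-9)
    expect_gte(got, 0); expect_lte(got, 180)
  }
})

test_that("turning angles are invariant under rotation and translation", {
  set.seed(43)
  tr <- make_track(x = cumsum(rnorm(12)), y = cumsum(rnorm(12)))
  a0 <- turning_angles(tr)
  for (ang in c(0.3, 1.2, 2.9)) {
    tr2 <- rotate_tracks(tr, ang)
    tr2$x_um <- tr2$x_um + 17; tr2$y_um <- tr2$y_um - 5
    expect_equal(turning_angles(tr2), a0, tolerance = 1e-9)
  }
})

test_that("step classification applies the 30-degree rule with confined at the boundary", {
  tr <- make_track(x = c(0, 1, 2), y = c(0, 0, 0))
  st <- step_metrics(tr)
  # synthetic angles around the threshold
  st3 <- data.frame(track_id = 1, step = 1:3, displacement_um = 2,
                    speed = 1, alpha_deg = c(29.999, 30.001, 30))
  cl <- classify_steps(st3, alpha_threshold = 30, motile_min_disp = 0.65)
  expect_equal(cl$label, c("persistent", "confined", "confined"))
  # zero displacement: non-motile regardless of angle
  st0 <- data.frame(track_id = 1, step = 1, displacement_um = 0,
                    speed = 0, alpha_deg = 10)
  expect_equal(classify_steps(st0)$label, "non-motile")
  expect_error(classify_steps(st3, alpha_threshold = -5), "alpha_threshold")
})

test_that("percent time confined counts motile interior steps only", {
  straight <- make_track(x = 0:10, y = rep(0, 11))
  expect_equal(percent_time_confined(classify_steps(step_metrics(straight))),
               0)
  # alternating 90-degree turns and straight continuations
  zig <- make_track(x = c(0, 1, 1, 2, 2, 3, 3, 4, 4, 5, 5),
                    y = c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4, 5))
  st <- classify_steps(step_metrics(zig), motile_min_disp = 0.5)
  expect_equal(percent_time_confined(st), 100)  # every angle is 90
  half <- data.frame(track_id = 1, step = 1:10, displacement_um = 2,
                     speed = 1, alpha_deg = rep(c(10, 90), 5))
  expect_equal(percent_time_confined(classify_steps(half)), 50)
  # conservation: persistent + confined = motile interior steps
  set.seed(47)
  tr <- make_track(x = cumsum(rnorm(50, 0, 3)), y = cumsum(rnorm(50, 0, 3)))
  cl <- classify_steps(step_metrics(tr))
  interior <- cl$motile & !is.na(cl$alpha_deg)
  expect_equal(sum(cl$label[interior] == "persistent") +
               sum(cl$label[interior] == "confined"), sum(interior))
  p <- percent_time_confined(cl)
  expect_gte(p, 0); expect_lte(p, 100)
  # no motile steps: missing value
  still <- classify_steps(step_metrics(make_track(rep(0, 5), rep(0, 5))))
  expect_true(is.na(percent_time_confined(still)))
})

test_that("percent confined equals a brute-force per-step recount on a simulation", {
  cfg <- simulation_config(mean_speed = 4, speed_sd = 1,
                           angular_noise_sd = 0.6, frame_interval = 3,
                           duration = 150, n_cells = 10, seed = 53)
  geo <- pillar_geometry(arena_size = c(500, 500))
  tr <- simulate_prw_2d(cfg, geo)
  cl <- classify_steps(step_metrics(tr))
  got <- percent_time_confined(cl)
  # brute force: walk each track by hand
  n_conf <- 0L; n_mot <- 0L
  for (t1 in split_tracks(tr)) {
    for (i in 2:(nrow(t1) - 1)) {
      v1 <- c(t1$x_um[i] - t1$x_um[i - 1], t1$y_um[i] - t1$y_um[i - 1])
      v2 <- c(t1$x_um[i + 1] - t1$x_um[i], t1$y_um[i + 1] - t1$y_um[i])
      d <- sqrt(sum(v2^2))   # the step whose angle sits at point i
      if (d <= 0.65 || sqrt(sum(v1^2)) == 0) next
      a <- oracle_turning_angle(c(t1$x_um[i - 1], t1$y_um[i - 1]),
                                c(t1$x_um[i], t1$y_um[i]),
                                c(t1$x_um[i + 1], t1$y_um[i + 1]))
      n_mot <- n_mot + 1L
      if (a >= 30) n_conf <- n_conf + 1L
    }
  }
  expect_equal(got, 100 * n_conf / n_mot, tolerance = 1e-9)
})

test_that("track length is total path length, not net displacement", {
  expect_equal(track_length(make_track(x = 0:10)), 10)
  sq <- make_track(x = c(0, 5, 5, 0, 0), y = c(0, 0, 5, 5, 0))
  expect_equal(track_length(sq), 20)
  expect_equal(track_length(make_track(x = 3)), 0)
  set.seed(59)
  tr <- make_track(x = cumsum(rnorm(30)), y = cumsum(rnorm(30)))
  ref <- sum(sapply(1:29, function(i)
    sqrt((tr$x_um[i + 1] - tr$x_um[i])^2 + (tr$y_um[i + 1] - tr$y_um[i])^2)))
  expect_equal(track_length(tr), ref, tolerance = 1e-12)
})

test_that("top_n_tracks agrees with a full sort and handles small cohorts", {
  tracks <- as_tracks(rbind(make_track(x = c(0, 5), id = 1),
                            make_track(x = c(0, 7), id = 2),
                            make_track(x = c(0, 9), id = 3)))
  expect_setequal(unique(top_n_tracks(tracks, 16)$track_id), 1:3)
  expect_setequal(unique(top_n_tracks(tracks, 2)$track_id), c(2, 3))
  set.seed(61)
  big <- do.call(rbind, lapply(1:100, function(i)
    make_track(x = cumsum(rnorm(10)), y = cumsum(rnorm(10)), id = i)))
  big <- as_tracks(big)
  lens <- track_lengths(big)
  ref <- lens$track_id[order(-lens$length_um, lens$track_id)][1:16]
  expect_setequal(unique(top_n_tracks(big, 16)$track_id), ref)
})

test_that("mean percent confined rises with angular noise and hits both limits", {
  geo <- pillar_geometry(arena_size = c(1e5, 1e5), n_pillars = 0)
  mean_conf <- function(sigma, n_cells = 50, seed = 67) {
    cfg <- simulation_config(mean_speed = 4, speed_sd = 0,
                             angular_noise_sd = sigma, frame_interval = 3,
                             duration = 3 * 50, n_cells = n_cells, seed = seed)
    tr <- simulate_prw_2d(cfg, geo, start_region = c(4e4, 6e4, 4e4, 6e4))
    by_tr <- percent_time_confined_by_track(classify_steps(step_metrics(tr)))
    mean(by_tr$percent_confined, na.rm = TRUE)
  }
  expect_equal(mean_conf(0), 0)
  levels <- vapply(c(0, 0.2, 0.4, 0.8, 1.6), mean_conf, numeric(1))
  expect_true(all(diff(levels) >= 0))
  # uniform-heading limit: alpha uniform on [0, 180], confined iff >= 30
  expect_lt(abs(mean_conf(Inf, n_cells = 100) - 100 * 150 / 180), 2)
})
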