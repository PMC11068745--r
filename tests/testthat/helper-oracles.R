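# Independent reference computations used to check the package's
# implementations, deliberately written along different routes.

# build a track table from coordinate vectors
make_track <- function(x, y = rep(0, length(x)), dt = 3, id = 1L) {
  as_tracks(data.frame(track_id = id, frame = seq_along(x) - 1L,
                       t_min = (seq_along(x) - 1L) * dt,
                       x_um = x, y_um = y))
}

# law-of-cosines turning angle at p2 of the triple (p1, p2, p3):
# the interior angle at p2 comes from the side lengths; the turning
# angle is its supplement. Avoids the dot-product route used in the
# implementation.
oracle_turning_angle <- function(p1, p2, p3) {
  a <- sqrt(sum((p3 - p2)^2))   # outgoing
  b <- sqrt(sum((p2 - p1)^2))   # incoming
  c2 <- sum((p3 - p1)^2)
  if (a == 0 || b == 0) return(NA_real_)
  cos_int <- (a^2 + b^2 - c2) / (2 * a * b)
  interior <- acos(pmin(pmax(cos_int, -1), 1)) * 180 / pi
  180 - interior
}

# exhaustive minimum-total-displacement matching between two point sets
# (rows of a and b), links longer than max_disp forbidden; returns the
# optimal assignment as a two-column matrix (index in a, index in b)
oracle_min_matching <- function(a, b, max_disp) {
  na <- nrow(a); nb <- nrow(b)
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  d[d > max_disp] <- NA
  best <- NULL; best_cost <- Inf; best_n <- -1L
  # enumerate all injective partial assignments of a-rows to b-rows
  recurse <- function(i, used, pairs, cost) {
    if (i > na) {
      n <- nrow(pairs)
      if (n > best_n || (n == best_n && cost < best_cost)) {
        best <<- pairs; best_cost <<- cost; best_n <<- n
      }
      return(invisible())
    }
    recurse(i + 1L, used, pairs, cost)          # leave a_i unmatched
    for (j in seq_len(nb)) {
      if (!used[j] && !is.na(d[i, j])) {
        used[j] <- TRUE
        recurse(i + 1L, used, rbind(pairs, c(i, j)), cost + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nb), matrix(integer(0), ncol = 2), 0)
  best[order(best[, 1]), , drop = FALSE]
}

# rotate a track table by angle (radians) about the origin
rotate_tracks <- function(tracks, angle) {
  x <- tracks$x_um * cos(angle) - tracks$y_um * sin(angle)
  y <- tracks$x_um * sin(angle) + tracks$y_um * cos(angle)
  tracks$x_um <- x; tracks$y_um <- y
  tracks
}

# fraction of ground-truth positions recovered within tol_um by any
# detected track position in the same frame
recovery_fraction <- function(truth, detected, tol_um) {
  hit <- 0L; tot <- 0L
  for (f in unique(truth$frame)) {
    gt <- truth[truth$frame == f, ]
    dt <- detected[detected$frame == f, ]
    tot <- tot + nrow(gt)
    if (!nrow(dt)) next
    for (i in seq_len(nrow(gt))) {
      dmin <- min(sqrt((dt$x_um - gt$x_um[i])^2 + (dt$y_um - gt$y_um[i])^2))
      if (dmin <= tol_um) hit <- hit + 1L
    }
  }
  hit / tot
}
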