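# shared fixture builders (all synthetic, generated in code)

# OD directly from a mass matrix on a unit test grid
od_from_matrix <- function(m, cell = 150, x0 = 0, y0 = 0, id = "test") {
  g <- grid_spec(x0, y0, cell, n_cols = ncol(m), n_rows = nrow(m))
  occurrence_dist(g, m, id)
}

# regular-interval trajectory from coordinates
traj_from_xy <- function(x, y, start = "2020-01-01", interval_h = 1,
                         id = "a1", loc_error_sd = 20) {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  trajectory(id, t0 + (seq_along(x) - 1) * interval_h * 3600, x, y,
             loc_error_sd)
}

# pure Brownian motion track (for sigma2_m recovery)
bm_track <- function(n, sigma2, interval_h = 1, seed = 1) {
  set.seed(seed)
  step_sd <- sqrt(sigma2 * interval_h)
  traj_from_xy(cumsum(c(0, rnorm(n - 1, 0, step_sd))),
               cumsum(c(0, rnorm(n - 1, 0, step_sd))))
}

# independent oracle: discrete Bhattacharyya coefficient by direct summation
ba_direct <- function(p, q) sum(sqrt(as.vector(p) * as.vector(q)))

# independent oracle: BBMM mixture cell masses for one segment by direct
# quadrature over alpha midpoints (R implementation, no shared code path)
bbmm_single_segment_oracle <- function(x0y0, x1y1, T_h, sigma2, delta,
                                       grid, n_alpha) {
  cx <- grid$x0 + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  cy <- grid$y0 + (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  mass <- matrix(0, grid$n_rows, grid$n_cols)
  for (j in seq_len(n_alpha)) {
    a <- (j - 0.5) / n_alpha
    mu <- x0y0 + a * (x1y1 - x0y0)
    v <- a * (1 - a) * T_h * sigma2 + ((1 - a)^2 + a^2) * delta^2
    dx <- dnorm(cx, mu[1], sqrt(v))
    dy <- dnorm(cy, mu[2], sqrt(v))
    mass <- mass + outer(dy, dx) * grid$cell_size^2
  }
  mass / sum(mass)
}

# small cohort metrics table with three well-separated strategy groups,
# generated directly on the metric scale (for classification unit tests)
toy_metric_table <- function(n_per = 5, seed = 1, noise = 0.03) {
  set.seed(seed)
  centres <- rbind(resident = c(0.75, 0.85, 0.8),
                   dual_range_migrant = c(0.05, 0.85, 0.8),
                   multi_range_migrant = c(0.05, 0.85, 0.05))
  rows <- do.call(rbind, lapply(rownames(centres), function(s) {
    m <- matrix(rep(centres[s, ], each = n_per), ncol = 3) +
      matrix(rnorm(3 * n_per, 0, noise), ncol = 3)
    m <- pmin(pmax(m, 0), 1)
    data.frame(animal_id = paste0(s, "_", seq_len(n_per)), truth = s,
               seasonal_overlap = m[, 1], summer_overlap = m[, 2],
               winter_overlap = m[, 3])
  }))
  rows
}

# exhaustive k-means oracle: minimal within-cluster SS over all labelings
kmeans_bruteforce <- function(X, k = 3) {
  n <- nrow(X)
  best <- Inf
  labels <- rep(1L, n)
  repeat {
    if (length(unique(labels)) == k) {
      ss <- sum(vapply(seq_len(k), function(j) {
        pts <- X[labels == j, , drop = FALSE]
        sum(sweep(pts, 2, colMeans(pts))^2)
      }, numeric(1)))
      if (ss < best) best <- ss
    }
    i <- 1L
    while (i <= n && labels[i] == k) {
      labels[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
    labels[i] <- labels[i] + 1L
  }
  best
}
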