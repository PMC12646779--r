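test_that("resident OU track honours the closed-form stationary spread", {
  p <- strategy_params("resident")
  # discrete OU stationary SD per coordinate
  stat_sd <- p$step_sd * sqrt(p$fix_interval /
                                (1 - (1 - p$attraction * p$fix_interval)^2))
  expect_equal(stat_sd, p$step_sd / sqrt(2 * p$attraction), tolerance = 0.05)
  tr <- simulate_trajectory(p, seed = 11)
  r <- sqrt((tr$fixes$x - p$summer_centre[1])^2 +
              (tr$fixes$y - p$summer_centre[2])^2)
  expect_gt(mean(r <= 6 * stat_sd), 0.999)
  emp_sd <- sqrt((var(tr$fixes$x) + var(tr$fixes$y)) / 2)
  expect_equal(emp_sd, stat_sd, tolerance = 0.10)
})

test_that("noiseless limit pins every fix on the centre schedule", {
  p <- strategy_params("dual_range", step_sd = 0)
  tr <- simulate_trajectory(p, seed = 3)
  mon <- as.integer(format(tr$fixes$timestamp, "%m", tz = "UTC"))
  in_summer <- mon %in% 6:8
  expect_true(all(tr$fixes$x[in_summer] == p$summer_centre[1]))
  expect_true(all(tr$fixes$y[in_summer] == p$summer_centre[2]))
  # winter sits exactly at distance winter_centre_distance
  in_winter <- mon %in% c(12, 1, 2)
  d <- sqrt(tr$fixes$x[in_winter]^2 + tr$fixes$y[in_winter]^2)
  expect_equal(unname(range(d)), rep(p$winter_centre_distance, 2),
               tolerance = 1e-10)
})

test_that("dual-range December positions track the year's winter centre", {
  p <- strategy_params("dual_range", winter_centre_distance = 30000)
  p0 <- strategy_params("dual_range", winter_centre_distance = 30000,
                        step_sd = 0)
  errs <- vapply(1:20, function(s) {
    tr <- simulate_trajectory(p, seed = s)
    # noiseless twin at the same seed shares the winter-centre draw, so its
    # December fixes sit exactly on that year's winter centre
    ref <- simulate_trajectory(p0, seed = s)
    mon <- as.integer(format(tr$fixes$timestamp, "%m", tz = "UTC"))
    dec <- mon == 12
    sqrt((mean(tr$fixes$x[dec]) - mean(ref$fixes$x[dec]))^2 +
           (mean(tr$fixes$y[dec]) - mean(ref$fixes$y[dec]))^2)
  }, numeric(1))
  expect_lt(mean(errs), 2000)
})

test_that("trajectory simulation is deterministic and rejects bad parameters", {
  p <- strategy_params("multi_range")
  a <- simulate_trajectory(p, seed = 5)
  b <- simulate_trajectory(p, seed = 5)
  expect_identical(a$fixes, b$fixes)
  expect_error(strategy_params("resident", attraction = NA), "non-finite")
  expect_error(strategy_params("resident", n_months = 12))
  expect_error(strategy_params("resident", winter_centre_distance = 5000),
               "resident")
})

test_that("multi-range winters move, dual-range winters repeat", {
  winter_centres <- function(strategy, seed) {
    tr <- simulate_trajectory(strategy_params(strategy, step_sd = 0), seed)
    mon <- as.integer(format(tr$fixes$timestamp, "%m", tz = "UTC"))
    yr <- as.integer(format(tr$fixes$timestamp, "%Y", tz = "UTC"))
    wy <- ifelse(mon == 12, yr, yr - 1)
    keep <- mon %in% c(12, 1, 2)
    cbind(tapply(tr$fixes$x[keep], wy[keep], mean),
          tapply(tr$fixes$y[keep], wy[keep], mean))
  }
  wd <- winter_centres("dual_range", 9)
  expect_lt(max(dist(wd)), 1)
  wm <- winter_centres("multi_range", 9)
  expect_gt(max(dist(wm)), 1000)
})

test_that("zero year-to-year SD yields identical annual layer means", {
  lp <- landscape_params(grid_extent = 15000, n_years = 4,
                         yty_sd = c(biomass = 0, spring_length = 0,
                                    snow_depth = 0))
  st <- simulate_landscape(lp, seed = 2)
  for (cv in names(st$layers)) {
    means <- vapply(1:4, function(j) mean(st$layers[[cv]][, , j]), numeric(1))
    expect_equal(max(means) - min(means), 0)
  }
})

test_that("spatial SD of the fields shrinks as the correlation length grows", {
  sds <- vapply(c(600, 1800, 5400), function(cl) {
    mean(vapply(1:10, function(s) {
      st <- simulate_landscape(landscape_params(grid_extent = 30000,
                                                corr_length = cl, n_years = 1),
                               seed = s)
      sd(as.vector(st$layers$biomass[, , 1]))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("SD of annual layer means recovers the generating yty_sd", {
  rec <- vapply(1:50, function(s) {
    st <- simulate_landscape(landscape_params(grid_extent = 9000, n_years = 5,
                                              yty_sd = c(biomass = 10)),
                             seed = s)
    sd(vapply(1:5, function(j) mean(st$layers$biomass[, , j]), numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(rec) - 10) / 10, 0.25)
})

test_that("year effects are exchangeable: permuting years keeps spatial SDs", {
  st <- simulate_landscape(landscape_params(grid_extent = 15000, n_years = 3),
                           seed = 4)
  perm <- c(3, 1, 2)
  st_perm <- st
  for (cv in names(st$layers)) st_perm$layers[[cv]] <- st$layers[[cv]][, , perm]
  mask <- matrix(TRUE, st$grid$n_rows, st$grid$n_cols)
  expect_equal(spatial_variation(st, mask), spatial_variation(st_perm, mask))
  expect_equal(unname(yty_variation(st, mask)),
               unname(yty_variation(st_perm, mask)))
})

test_that("landscape rejects an extent too small for the correlation length", {
  expect_error(simulate_landscape(landscape_params(grid_extent = 2000,
                                                   corr_length = 1000),
                                  seed = 1), "3 \\* corr_length")
})

test_that("population simulation returns a labelled, reproducible cohort", {
  lp <- landscape_params(grid_extent = 80000, n_years = 2)
  pop <- simulate_population(1, seed = 6, land_params = lp)
  expect_length(pop$trajectories, 3)
  expect_equal(nrow(pop$truth), 3)
  expect_setequal(pop$truth$strategy, c("resident", "dual_range", "multi_range"))
  pop2 <- simulate_population(1, seed = 6, land_params = lp)
  expect_identical(pop$truth, pop2$truth)
  expect_identical(pop$trajectories[[1]]$fixes, pop2$trajectories[[1]]$fixes)
  # spans at least 21 months
  for (tr in pop$trajectories) {
    rng <- range(tr$fixes$timestamp)
    expect_gte(as.numeric(diff(rng), units = "days"), 21 * 28)
  }
})
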