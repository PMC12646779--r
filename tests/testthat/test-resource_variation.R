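# small landscape shared by several blocks
land_fixture <- function(seed = 1, n_years = 3, extent = 24000, corr = 900) {
  simulate_landscape(landscape_params(grid_extent = extent, corr_length = corr,
                                      n_years = n_years), seed)
}

test_that("spatial SDs follow the population convention on hand cases", {
  st <- land_fixture()
  mask <- matrix(FALSE, st$grid$n_rows, st$grid$n_cols)
  mask[1, 1:2] <- TRUE
  st$layers$elevation[1, 1, ] <- 0
  st$layers$elevation[1, 2, ] <- 10
  sds <- spatial_variation(st, mask)
  expect_equal(unname(sds["elevation"]), 5)  # population SD of {0, 10}
  st$layers$elevation[1, 2, ] <- 0
  expect_equal(unname(spatial_variation(st, mask)["elevation"]), 0)
  mask1 <- mask & FALSE
  mask1[1, 1] <- TRUE
  expect_error(spatial_variation(st, mask1), "2 cells")
})

test_that("annual covariates are averaged across years before the spatial SD", {
  st <- land_fixture(n_years = 2)
  mask <- matrix(FALSE, st$grid$n_rows, st$grid$n_cols)
  mask[1, 1:2] <- TRUE
  st$layers$biomass[1, 1, ] <- c(0, 20)   # cell mean 10
  st$layers$biomass[1, 2, ] <- c(40, 0)   # cell mean 20
  expect_equal(unname(spatial_variation(st, mask)["biomass"]), 5)
})

test_that("smoother landscapes have smaller range-scale spatial SDs", {
  mask_sd <- function(corr, s) {
    st <- land_fixture(seed = s, n_years = 1, corr = corr)
    mask <- matrix(FALSE, st$grid$n_rows, st$grid$n_cols)
    mask[40:120, 40:120] <- TRUE
    spatial_variation(st, mask)[["biomass"]]
  }
  lo <- mean(vapply(1:5, function(s) mask_sd(600, s), numeric(1)))
  hi <- mean(vapply(1:5, function(s) mask_sd(4000, s), numeric(1)))
  expect_gt(lo, hi)
})

test_that("PC1 aggregates correlated SD columns with oriented sign", {
  # two perfectly correlated columns -> PC1 explains everything
  sd2 <- cbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4))
  sc <- pca_spatial_score(sd2)
  expect_equal(attr(sc, "var_explained"), 1)
  expect_equal(mean(sc), 0)
  expect_gt(attr(sc, "loadings")[which.max(abs(attr(sc, "loadings")))], 0)
  # rank-1 structure + noise: scores recover the generating factor
  set.seed(10)
  f <- runif(40)
  M <- outer(f, c(1, 2, 3, 0.5)) + matrix(rnorm(160, 0, 0.01), 40)
  sc2 <- pca_spatial_score(M)
  expect_gt(abs(cor(sc2, f)), 0.99)
  # zero-variance column dropped with warning
  M2 <- cbind(M, const = 1)
  expect_warning(pca_spatial_score(M2), "zero-variance")
})

test_that("year-to-year SDs use the sample convention and recover truth", {
  st <- land_fixture(n_years = 3)
  mask <- matrix(TRUE, st$grid$n_rows, st$grid$n_cols)
  st$layers$biomass[, , 1] <- 10
  st$layers$biomass[, , 2] <- 20
  st$layers$biomass[, , 3] <- 30
  expect_equal(unname(yty_variation(st, mask)["biomass"]), 10)
  st$layers$biomass[] <- 7
  expect_equal(unname(yty_variation(st, mask)["biomass"]), 0)
  st1 <- land_fixture(n_years = 1)
  expect_error(yty_variation(st1, mask), "2 years")
  # Monte-Carlo recovery of the generating SD
  rec <- vapply(1:50, function(s) {
    stl <- simulate_landscape(landscape_params(grid_extent = 9000, n_years = 5,
                                               yty_sd = c(spring_length = 15)),
                              seed = s)
    m <- matrix(TRUE, stl$grid$n_rows, stl$grid$n_cols)
    yty_variation(stl, m)[["spring_length"]]
  }, numeric(1))
  expect_lt(abs(mean(rec) - 15) / 15, 0.35)
})

test_that("standardized domain is an area-true circle on the winter centroid", {
  tr <- simulate_trajectory(strategy_params("resident"), seed = 2)
  st <- simulate_landscape(landscape_params(grid_extent = 90000), 1)
  mask <- standardized_domain(tr, st$grid, 3765)
  expect_equal(attr(mask, "radius_m"), 34619, tolerance = 1e-4)
  area_km2 <- sum(mask) * (st$grid$cell_size / 1000)^2
  expect_equal(area_km2, 3765, tolerance = 0.01)
  # translation equivariance
  tr2 <- tr
  tr2$fixes$x <- tr$fixes$x + 1500
  tr2$fixes$y <- tr$fixes$y - 3000
  m2 <- standardized_domain(tr2, st$grid, 3765)
  shift_c <- 1500 / st$grid$cell_size
  shift_r <- -3000 / st$grid$cell_size
  core <- mask[31:570, 31:570]
  expect_identical(m2[31:570 + shift_r, 31:570 + shift_c], core)
  # no winter fixes -> error
  keep <- !(as.integer(format(tr$fixes$timestamp, "%m", tz = "UTC")) %in% c(12, 1, 2))
  tr3 <- trajectory("nw", tr$fixes$timestamp[keep], tr$fixes$x[keep],
                    tr$fixes$y[keep])
  expect_error(standardized_domain(tr3, st$grid, 3765), "winter")
})

test_that("year-round range of a resident scales with the OU spread", {
  p <- strategy_params("resident")
  tr <- simulate_trajectory(p, seed = 13)
  st <- simulate_landscape(landscape_params(grid_extent = 30000), 1)
  mask <- year_round_range(tr, st$grid)
  stat_sd <- p$step_sd * sqrt(p$fix_interval /
                                (1 - (1 - p$attraction * p$fix_interval)^2))
  expected <- pi * (3 * stat_sd)^2
  got <- sum(mask) * st$grid$cell_size^2
  expect_gt(got, expected / 2)
  expect_lt(got, expected * 2)
  expect_identical(mask, year_round_range(tr, st$grid))  # deterministic
})

test_that("climate and anthropogenic indices standardize within the cohort", {
  st <- land_fixture(n_years = 2)
  masks <- lapply(1:6, function(i) {
    m <- matrix(FALSE, st$grid$n_rows, st$grid$n_cols)
    m[(i * 10):(i * 10 + 20), (i * 15):(i * 15 + 20)] <- TRUE
    m
  })
  names(masks) <- paste0("a", 1:6)
  idx <- climate_anthro_indices(st, masks)
  expect_equal(mean(idx$winter_severity), 0, tolerance = 1e-12)
  expect_equal(sd(idx$winter_severity), 1, tolerance = 1e-12)
  expect_true(all(idx$pct_agriculture >= 0 & idx$pct_agriculture <= 1))
  # doubling snow doubles conditions but leaves severity untouched
  st2 <- st
  st2$layers$snow_depth <- st$layers$snow_depth * 2
  idx2 <- climate_anthro_indices(st2, masks)
  expect_equal(idx2$winter_conditions, 2 * idx$winter_conditions)
  expect_equal(idx2$winter_severity, idx$winter_severity, tolerance = 1e-12)
  # all-zero snow -> zero conditions
  st2$layers$snow_depth[] <- 0
  expect_true(all(climate_anthro_indices(st2, masks)$winter_conditions == 0))
})

test_that("empirical and standardized domains share one code path", {
  pop <- simulate_population(2, seed = 17,
                             land_params = landscape_params(grid_extent = 80000,
                                                            n_years = 2))
  ve <- variation_summary(pop$trajectories, pop$landscape, "empirical")
  vs <- variation_summary(pop$trajectories, pop$landscape, "standardized",
                          domain_area_km2 = 1647)
  expect_identical(ve$animal_id, vs$animal_id)
  expect_identical(names(ve), names(vs))
  expect_true(all(ve$domain == "empirical"))
  expect_true(all(vs$domain == "standardized"))
  # same machinery, different masks: columns differ but stay finite
  num <- vapply(ve, is.numeric, TRUE)
  expect_true(all(is.finite(as.matrix(ve[, num]))))
  expect_true(all(is.finite(as.matrix(vs[, num]))))
})
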