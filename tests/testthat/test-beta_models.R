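test_that("AICc follows the corrected formula and its limit", {
  expect_equal(aicc(-10, 2, 10), 24 + 12 / 7)
  expect_equal(aicc(-10, 2, 1e9), 24, tolerance = 1e-6)
  expect_error(aicc(-10, 5, 6), "n must exceed")
})

test_that("intercept-only MLE matches a grid-search oracle", {
  set.seed(21)
  y <- rbeta(80, 2, 5)
  X <- matrix(1, 80, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_beta_regression(y, X)
  n <- length(y)
  yc <- (y * (n - 1) + 0.5) / n
  # oracle: profile the beta likelihood on a (mu, phi) grid
  grid_ll <- function(mu, phi) sum(dbeta(yc, mu * phi, (1 - mu) * phi, log = TRUE))
  mus <- seq(0.05, 0.95, by = 1e-4)
  prof <- vapply(mus, function(m) {
    opt <- optimize(function(lp) -grid_ll(m, exp(lp)), c(-2, 8))
    -opt$objective
  }, numeric(1))
  mu_star <- mus[which.max(prof)]
  expect_equal(plogis(fit$beta[["(Intercept)"]]), mu_star, tolerance = 1e-4)
  expect_equal(fit$loglik, max(prof), tolerance = 1e-6)
})

test_that("simulation recovery: slope, precision, fitted means", {
  set.seed(22)
  x <- rnorm(500)
  mu <- plogis(0.5 + 1.2 * x)
  y <- rbeta(500, mu * 20, (1 - mu) * 20)
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_beta_regression(y, X)
  expect_equal(unname(fit$beta), c(0.5, 1.2), tolerance = 0.15)
  expect_equal(fit$phi, 20, tolerance = 0.2 * 20)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
  expect_gt(fit$pseudo_r2, 0.5)
})

test_that("independent cross-check against glmmTMB beta family", {
  skip_if_not_installed("glmmTMB")
  set.seed(23)
  x <- rnorm(200)
  mu <- plogis(-0.3 + 0.8 * x)
  y <- rbeta(200, mu * 15, (1 - mu) * 15)
  n <- length(y)
  yc <- (y * (n - 1) + 0.5) / n
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_beta_regression(y, X)
  ref <- suppressWarnings(
    glmmTMB::glmmTMB(yc ~ x, family = glmmTMB::beta_family()))
  expect_equal(unname(fit$beta), unname(glmmTMB::fixef(ref)$cond),
               tolerance = 1e-3)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(stats::vcov(ref)$cond))), tolerance = 0.02)
})

test_that("duplicating rows preserves coefficients and shrinks SEs", {
  set.seed(24)
  x <- rnorm(100)
  mu <- plogis(0.2 + x)
  y <- rbeta(100, mu * 10, (1 - mu) * 10)
  # avoid exact 0/1 so the boundary compression is rerun-stable across n
  X <- cbind(`(Intercept)` = 1, x = x)
  f1 <- fit_beta_regression(y, X)
  f2 <- fit_beta_regression(rep(y, 2), rbind(X, X))
  expect_equal(unname(f2$beta), unname(f1$beta), tolerance = 0.02)
  expect_equal(unname(f2$se), unname(f1$se) / sqrt(2), tolerance = 0.1)
})

test_that("degenerate designs are rejected", {
  y <- rbeta(30, 2, 2)
  X <- cbind(1, 1:30, 2 * (1:30))
  expect_error(fit_beta_regression(y, X), "rank deficient")
  expect_error(fit_beta_regression(c(y[1:5], 1.2),
                                   matrix(1, 6, 1)), "\\[0, 1\\]")
  expect_error(fit_beta_regression(y[1:3], matrix(1, 3, 1)), "too few")
})

test_that("a pure-noise covariate usually raises AICc", {
  worse <- vapply(1:60, function(s) {
    set.seed(400 + s)
    y <- rbeta(60, 4, 6)
    X0 <- matrix(1, 60, 1)
    X1 <- cbind(X0, rnorm(60))
    fit_beta_regression(y, X1)$aicc > fit_beta_regression(y, X0)$aicc
  }, logical(1))
  expect_gt(mean(worse), 0.5)
})

cohort_for_models <- function(seed, yty_effect = -1.5, n = 48) {
  set.seed(seed)
  v <- data.frame(
    animal_id = paste0("a", 1:n),
    spatial_variation_score = rnorm(n),
    yty_spring_length_sd = runif(n, 2, 14),
    yty_biomass_sd = runif(n, 50, 250),
    winter_conditions = rnorm(n, 40, 8),
    winter_severity = rnorm(n),
    pct_agriculture = runif(n, 0, 0.4),
    dist_roads = runif(n, 500, 6000))
  z <- scale(v$yty_spring_length_sd)[, 1]
  mu <- plogis(-0.5 + yty_effect * z)
  metrics <- data.frame(
    animal_id = v$animal_id,
    seasonal_overlap = rbeta(n, mu * 25, (1 - mu) * 25),
    summer_overlap = runif(n, 0.6, 0.95),
    winter_overlap = rbeta(n, mu * 25, (1 - mu) * 25),
    annual_overlap = runif(n),
    n_monthly_pairs = 210, complete = TRUE)
  assignments <- data.frame(
    animal_id = v$animal_id,
    strategy = rep(c("resident", "dual_range_migrant", "multi_range_migrant"),
                   length.out = n))
  list(metrics = metrics, assignments = assignments, variation = v)
}

test_that("model sets fit the declared candidates on every subset", {
  co <- cohort_for_models(31)
  sets2 <- run_model_sets(co$metrics, co$assignments, co$variation, 2)
  expect_setequal(names(sets2),
                  c("all", "dual_vs_multi", "resident_vs_dual",
                    "resident_vs_multi"))
  for (s in names(sets2)) {
    expect_setequal(sets2[[s]]$table$candidate,
                    c("spatial", "yty", "intercept"))
    # spatial and year-to-year variation never co-occur in one candidate
    for (f in sets2[[s]]$fits) {
      nm <- names(f$beta)
      expect_false("spatial_variation_score" %in% nm &&
                     any(grepl("^yty_", nm)))
    }
    expect_equal(sum(sets2[[s]]$table$weight), 1, tolerance = 1e-12)
  }
  expect_identical(sets2$all$response, "seasonal_overlap")
  expect_identical(sets2$dual_vs_multi$response, "winter_overlap")
  expect_identical(sets2$resident_vs_dual$response, "seasonal_overlap")
  expect_identical(sets2$resident_vs_multi$response, "annual_overlap")
})

test_that("objective 3 fits seven candidates per subset", {
  co <- cohort_for_models(32)
  sets3 <- run_model_sets(co$metrics, co$assignments, co$variation, 3)
  expect_length(sets3, 4)
  for (s in names(sets3)) {
    expect_length(sets3[[s]]$fits, 7)
    expect_setequal(sets3[[s]]$table$candidate,
                    c("top_obj2", "intercept", "climate", "anthro",
                      "top_obj2_climate", "top_obj2_anthro",
                      "top_obj2_climate_anthro"))
  }
})

test_that("small subsets are refused with a diagnostic", {
  co <- cohort_for_models(33, n = 12)
  w <- capture_warnings(out <- run_model_sets(co$metrics, co$assignments,
                                              co$variation, 2, min_n = 10))
  expect_true(any(grepl("refused", w)))
  expect_true("all" %in% names(out))
  expect_false("dual_vs_multi" %in% names(out))
})
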