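#' Parameters for a synthetic movement strategy
#'
#' Describes the generator for one animal: a discrete-time
#' Ornstein-Uhlenbeck (OU) process attracted to a seasonal centre schedule.
#' The centre sits on the summer range 1 Jun - 31 Aug and on the winter range
#' 1 Dec - 28/29 Feb, and moves linearly between the two during the spring
#' (Mar-May) and autumn (Sep-Nov) transitions. Residents keep a single centre
#' year-round; dual-range migrants use one fixed winter centre across years;
#' multi-range migrants redraw each year's winter centre uniformly on a
#' circle of radius `winter_centre_distance` around the summer centre.
#'
#' @param strategy One of `"resident"`, `"dual_range"`, `"multi_range"`.
#' @param summer_centre Numeric length-2 planar point (metres).
#' @param winter_centre_distance Distance (m) from summer to winter centre;
#'   must be 0 for residents. Default 30000 for migrants.
#' @param attraction Mean-reversion rate (1/h). Default 0.05.
#' @param step_sd Diffusive step scale (m per sqrt-hour). Default 300.
#' @param fix_interval Hours between fixes. Default 2 (typical of 1-4 h GPS
#'   schedules).
#' @param start_date First fix date (`Date` or "YYYY-MM-DD").
#' @param n_months Record length in calendar months, 21-23.
#' @param loc_error_sd Nominal GPS location-error SD (m) recorded with each
#'   fix (positions themselves are exact simulator output).
#' @return An object of class `strategy_params`.
#' @export
strategy_params <- function(strategy = c("resident", "dual_range", "multi_range"),
                            summer_centre = c(0, 0),
                            winter_centre_distance = if (strategy == "resident") 0 else 30000,
                            attraction = 0.05,
                            step_sd = 300,
                            fix_interval = 2,
                            start_date = "2019-05-01",
                            n_months = 22,
                            loc_error_sd = 20) {
  strategy <- match.arg(strategy)
  start_date <- as.Date(start_date)
  vals <- c(summer_centre, winter_centre_distance, attraction, step_sd,
            fix_interval, n_months, loc_error_sd)
  if (!all(is.finite(vals))) stop("non-finite strategy parameter")
  stopifnot(length(summer_centre) == 2,
            attraction > 0, step_sd >= 0, fix_interval > 0,
            n_months >= 21, n_months <= 23,
            winter_centre_distance >= 0, loc_error_sd >= 0)
  if (strategy == "resident" && winter_centre_distance != 0)
    stop("residents must have winter_centre_distance = 0")
  if (attraction * fix_interval >= 1)
    stop("attraction * fix_interval must be < 1 for a stable OU step")
  structure(list(strategy = strategy,
                 summer_centre = as.numeric(summer_centre),
                 winter_centre_distance = winter_centre_distance,
                 winter_redraw = (strategy == "multi_range"),
                 attraction = attraction, step_sd = step_sd,
                 fix_interval = fix_interval, start_date = start_date,
                 n_months = as.integer(n_months),
                 loc_error_sd = loc_error_sd),
            class = "strategy_params")
}

# first day of the n-th month after `date`'s month
add_months <- function(date, n) {
  seq(as.Date(format(date, "%Y-%m-01")), by = "1 month", length.out = n + 1)[n + 1]
}

# winter-year of a date: winter t spans Dec t - Feb t+1
winter_year_of <- function(mon, yr) ifelse(mon == 12L, yr, yr - 1L)

# Seasonal centre schedule: given fix dates and per-winter-year winter
# centres, return the n x 2 matrix of attraction centres.
centre_schedule <- function(dates, summer_centre, winter_centres) {
  yr <- as.integer(format(dates, "%Y"))
  mon <- as.integer(format(dates, "%m"))
  n <- length(dates)
  mu <- matrix(rep(summer_centre, each = n), ncol = 2)
  wc_of <- function(wy) {
    key <- as.character(wy)
    out <- winter_centres[key, , drop = FALSE]
    if (anyNA(out)) stop("missing winter centre for winter-year ", key)
    out
  }
  is_winter <- mon %in% c(12L, 1L, 2L)
  if (any(is_winter)) {
    wy <- winter_year_of(mon[is_winter], yr[is_winter])
    mu[is_winter, ] <- as.matrix(wc_of(wy))
  }
  # spring: previous winter's centre -> summer centre
  is_spring <- mon %in% 3:5
  if (any(is_spring)) {
    y <- yr[is_spring]
    from <- as.matrix(wc_of(y - 1L))
    a <- as.numeric(dates[is_spring] - as.Date(paste0(y, "-03-01"))) /
      as.numeric(as.Date(paste0(y, "-06-01")) - as.Date(paste0(y, "-03-01")))
    mu[is_spring, ] <- from + a * (matrix(rep(summer_centre, each = sum(is_spring)),
                                          ncol = 2) - from)
  }
  # autumn: summer centre -> this winter's centre
  is_aut <- mon %in% 9:11
  if (any(is_aut)) {
    y <- yr[is_aut]
    to <- as.matrix(wc_of(y))
    a <- as.numeric(dates[is_aut] - as.Date(paste0(y, "-09-01"))) /
      as.numeric(as.Date(paste0(y, "-12-01")) - as.Date(paste0(y, "-09-01")))
    mu[is_aut, ] <- matrix(rep(summer_centre, each = sum(is_aut)), ncol = 2) +
      a * (to - matrix(rep(summer_centre, each = sum(is_aut)), ncol = 2))
  }
  mu
}

#' Simulate one GPS trajectory of known movement strategy
#'
#' Discrete-time OU track
#' `x[t+1] = x[t] + a * (mu(t) - x[t]) * dt + step_sd * sqrt(dt) * eps`
#' with `eps` standard bivariate normal and `mu(t)` the seasonal centre
#' schedule of [strategy_params()]. In the noiseless limit `step_sd = 0` the
#' track sits exactly on `mu(t)`. Reproducible for a fixed seed.
#'
#' @param params A [strategy_params()] object.
#' @param seed Integer RNG seed.
#' @return A `trajectory` (see [trajectory()]).
#' @examples
#' tr <- simulate_trajectory(strategy_params("resident"), seed = 1)
#' nrow(tr$fixes)
#' @export
simulate_trajectory <- function(params, seed) {
  stopifnot(inherits(params, "strategy_params"))
  set.seed(seed)
  dt <- params$fix_interval
  t0 <- as.POSIXct(paste(params$start_date, "00:00:00"), tz = "UTC")
  t_end <- as.POSIXct(paste(add_months(params$start_date, params$n_months),
                            "00:00:00"), tz = "UTC")
  times <- seq(t0, t_end - 1, by = dt * 3600)
  dates <- as.Date(times, tz = "UTC")
  yrs <- as.integer(format(dates, "%Y"))
  wyears <- seq(min(yrs) - 1L, max(yrs))
  # winter centres per winter-year
  sc <- params$summer_centre
  wc <- matrix(rep(sc, each = length(wyears)), ncol = 2,
               dimnames = list(as.character(wyears), c("x", "y")))
  if (params$winter_centre_distance > 0) {
    if (params$winter_redraw) {
      ang <- runif(length(wyears), 0, 2 * pi)
    } else {
      ang <- rep(runif(1, 0, 2 * pi), length(wyears))
    }
    wc[, 1] <- sc[1] + params$winter_centre_distance * cos(ang)
    wc[, 2] <- sc[2] + params$winter_centre_distance * sin(ang)
  }
  mu <- centre_schedule(dates, sc, wc)
  n <- length(times)
  if (params$step_sd == 0) {
    xy <- mu  # noiseless limit: track is the centre schedule itself
  } else {
    a <- params$attraction
    stat_sd <- params$step_sd * sqrt(dt / (1 - (1 - a * dt)^2))
    xy <- matrix(NA_real_, n, 2)
    for (k in 1:2) {
      x1 <- mu[1, k] + rnorm(1, 0, stat_sd)
      inp <- a * dt * mu[-n, k] + params$step_sd * sqrt(dt) * rnorm(n - 1)
      xy[, k] <- c(x1, stats::filter(inp, 1 - a * dt, method = "recursive",
                                     init = x1))
    }
  }
  trajectory(animal_id = paste0(params$strategy, "_seed", seed),
             timestamp = times, x = xy[, 1], y = xy[, 2],
             loc_error_sd = params$loc_error_sd)
}

#' Parameters for a synthetic covariate landscape
#'
#' @param grid_extent Side length (m) of the square landscape.
#' @param cell_size Cell size in metres (default 150).
#' @param corr_length Spatial autocorrelation scale (m) of the Gaussian
#'   smoothing kernel; must be at least `cell_size`.
#' @param n_years Number of annual layers for time-varying covariates.
#' @param yty_sd Named numeric vector of year-to-year SDs of annual layer
#'   means for the annual covariates (a scalar is recycled). Static
#'   covariates always have zero year effect.
#' @param yty_modulation Relative amplitude of the spatial modulation of the
#'   year effect (default 0.5). Each annual covariate's year effect is
#'   `e_y * m(x)` with `e_y ~ Normal(0, yty_sd^2)` and `m(x)` a smoothed
#'   field with grid mean ~1, so the landscape-average year-to-year SD is
#'   `yty_sd` while different areas — hence different individuals —
#'   experience more or less interannual variability. Set to 0 for a
#'   spatially uniform year effect.
#' @param covariate_names Covariates to generate; must include
#'   `spring_length`, `biomass`, `snow_depth`, `elevation`,
#'   `pct_agriculture`, `dist_roads`.
#' @return An object of class `landscape_params`.
#' @export
landscape_params <- function(grid_extent = 90000, cell_size = 150,
                             corr_length = 1000, n_years = 2,
                             yty_sd = c(spring_length = 8, biomass = 120,
                                        snow_depth = 10),
                             yty_modulation = 0.5,
                             covariate_names = c("spring_length", "biomass",
                                                 "snow_depth", "elevation",
                                                 "pct_agriculture", "dist_roads")) {
  required <- c("spring_length", "biomass", "snow_depth", "elevation",
                "pct_agriculture", "dist_roads")
  if (!all(required %in% covariate_names))
    stop("covariate_names must include: ", paste(required, collapse = ", "))
  stopifnot(cell_size > 0, corr_length >= cell_size, n_years >= 1,
            all(yty_sd >= 0), yty_modulation >= 0, grid_extent > 0)
  annual <- c("spring_length", "biomass", "snow_depth")
  if (is.null(names(yty_sd))) {
    stopifnot(length(yty_sd) == 1)
    yty_sd <- setNames(rep(yty_sd, length(annual)), annual)
  }
  missing_sd <- setdiff(annual, names(yty_sd))
  if (length(missing_sd))
    yty_sd[missing_sd] <- 0
  structure(list(grid_extent = grid_extent, cell_size = cell_size,
                 corr_length = corr_length, n_years = as.integer(n_years),
                 yty_sd = yty_sd[annual], yty_modulation = yty_modulation,
                 covariate_names = covariate_names, annual = annual),
            class = "landscape_params")
}

# Separable Gaussian smoothing with reflective edge padding; kernel sums to 1.
smooth_gaussian <- function(mat, sigma_cells) {
  if (sigma_cells <= 0) return(mat)
  h <- max(1L, ceiling(3 * sigma_cells))
  k <- dnorm(seq(-h, h), sd = sigma_cells)
  k <- k / sum(k)
  conv_cols <- function(m) {
    idx_top <- rev(seq_len(h))
    idx_bot <- nrow(m) - seq_len(h) + 1L
    mp <- rbind(m[idx_top, , drop = FALSE], m, m[idx_bot, , drop = FALSE])
    out <- stats::filter(mp, k, method = "convolution", sides = 2)
    matrix(out[(h + 1):(h + nrow(m)), ], nrow = nrow(m))
  }
  t(conv_cols(t(conv_cols(mat))))
}

# baseline level and fluctuation amplitude per covariate (landscape units:
# days, lbs/acre, cm, m, proportion, m)
.cov_base <- list(
  spring_length   = list(mean = 60,   amp = 15),
  biomass         = list(mean = 1000, amp = 300),
  snow_depth      = list(mean = 40,   amp = 20),
  elevation       = list(mean = 2000, amp = 400),
  pct_agriculture = list(mean = 0.15, amp = 10),   # amp on the logit scale
  dist_roads      = list(mean = 3000, amp = 2000)
)

#' Simulate a covariate raster stack
#'
#' Each covariate's spatial field is Gaussian-kernel-smoothed white noise at
#' scale `corr_length` (kernel weights sum to one, so larger correlation
#' lengths give smoother, lower-variance fields), shifted and scaled to
#' covariate-typical units. Annual covariates (`spring_length`, `biomass`,
#' `snow_depth`; the snow layer represents each year's mean daily winter snow
#' depth) additionally receive a per-year scalar offset drawn
#' `Normal(0, yty_sd^2)`; static covariates (`elevation`,
#' `pct_agriculture`, `dist_roads`) do not vary across years.
#' `pct_agriculture` is mapped through the logistic function to stay in
#' `[0, 1]`; `dist_roads` is truncated at zero.
#'
#' @param params A [landscape_params()] object.
#' @param seed Integer RNG seed.
#' @return A `covariate_stack`: list with elements `grid` ([grid_spec()],
#'   centred on the origin), `years` (integer labels), `layers` (named list
#'   of `n_rows x n_cols x n_years` arrays) and `static` (named logical).
#' @export
simulate_landscape <- function(params, seed) {
  stopifnot(inherits(params, "landscape_params"))
  if (params$grid_extent < 3 * params$corr_length)
    stop("grid_extent must be at least 3 * corr_length; the random field degenerates")
  set.seed(seed)
  n <- ceiling(params$grid_extent / params$cell_size)
  grid <- grid_spec(x0 = -n / 2 * params$cell_size, y0 = -n / 2 * params$cell_size,
                    cell_size = params$cell_size, n_cols = n, n_rows = n)
  sig_cells <- params$corr_length / params$cell_size
  years <- seq_len(params$n_years)
  layers <- list()
  static <- setNames(!(params$covariate_names %in% params$annual),
                     params$covariate_names)
  for (cv in params$covariate_names) {
    base <- .cov_base[[cv]]
    if (is.null(base)) base <- list(mean = 0, amp = 1)
    g <- smooth_gaussian(matrix(rnorm(n * n), n, n), sig_cells)
    field <- if (cv == "pct_agriculture") {
      plogis(qlogis(base$mean) + base$amp * g)
    } else if (cv == "dist_roads") {
      pmax(0, base$mean + base$amp * g)
    } else {
      base$mean + base$amp * g
    }
    arr <- array(field, dim = c(n, n, params$n_years))
    if (!static[[cv]]) {
      eff <- rnorm(params$n_years, 0, params$yty_sd[[cv]])
      modf <- 1
      if (params$yty_modulation > 0) {
        gm <- smooth_gaussian(matrix(rnorm(n * n), n, n), sig_cells)
        modf <- pmax(0, 1 + params$yty_modulation * gm / sd(as.vector(gm)))
      }
      for (j in years) arr[, , j] <- field + eff[j] * modf
    }
    layers[[cv]] <- arr
  }
  structure(list(grid = grid, years = years, layers = layers, static = static),
            class = "covariate_stack")
}

#' Simulate a labelled cohort on a shared landscape
#'
#' Places `n_per_strategy` animals of each of the three strategies at random
#' summer centres in the interior of the landscape (keeping every possible
#' winter range inside the grid), simulates their trajectories, and returns
#' the cohort with its ground-truth table.
#'
#' @param n_per_strategy Animals per strategy (>= 1).
#' @param seed Integer RNG seed controlling placement, per-animal trajectory
#'   seeds, and the landscape.
#' @param strategy_defaults Named list of [strategy_params()] templates for
#'   the three strategies; per-animal summer centres are filled in here.
#' @param land_params A [landscape_params()] object.
#' @return List with `trajectories` (named list of `trajectory`),
#'   `landscape` (`covariate_stack`) and `truth` (data.frame: `animal_id`,
#'   `strategy`, `summer_x`, `summer_y`, `winter_centre_distance`,
#'   `traj_seed`).
#' @export
simulate_population <- function(n_per_strategy, seed,
                                strategy_defaults = list(
                                  resident = strategy_params("resident"),
                                  dual_range = strategy_params("dual_range"),
                                  multi_range = strategy_params("multi_range")),
                                land_params = landscape_params()) {
  stopifnot(n_per_strategy >= 1)
  landscape <- simulate_landscape(land_params, seed)
  set.seed(seed + 1L)
  strategies <- names(strategy_defaults)
  n_tot <- n_per_strategy * length(strategies)
  reserve <- max(vapply(strategy_defaults,
                        function(p) p$winter_centre_distance, 0)) + 8000
  half <- land_params$grid_extent / 2 - reserve
  if (half <= 0) stop("landscape too small for the requested winter ranges")
  cx <- runif(n_tot, -half, half)
  cy <- runif(n_tot, -half, half)
  traj_seeds <- sample.int(.Machine$integer.max %/% 2, n_tot)
  trajectories <- list()
  truth <- data.frame()
  i <- 0L
  for (s in strategies) {
    for (j in seq_len(n_per_strategy)) {
      i <- i + 1L
      p <- strategy_defaults[[s]]
      p$summer_centre <- c(cx[i], cy[i])
      id <- sprintf("%s_%02d", s, j)
      tr <- simulate_trajectory(p, traj_seeds[i])
      tr$animal_id <- id
      trajectories[[id]] <- tr
      truth <- rbind(truth, data.frame(
        animal_id = id, strategy = s, summer_x = cx[i], summer_y = cy[i],
        winter_centre_distance = p$winter_centre_distance,
        traj_seed = traj_seeds[i]))
    }
  }
  list(trajectories = trajectories, landscape = landscape, truth = truth)
}
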