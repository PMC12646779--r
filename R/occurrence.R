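#' Brownian bridge movement model parameters
#'
#' @param sigma2_m Brownian motion variance in m^2/h (>= 0).
#' @param loc_error_sd Location-error SD in metres (delta).
#' @param max_lag Maximum gap (hours) between consecutive fixes for a
#'   segment to contribute a bridge (default 8).
#' @param n_alpha Midpoint integration steps per segment (default 10,
#'   minimum 5).
#' @return An object of class `bbmm_params`.
#' @export
bbmm_params <- function(sigma2_m, loc_error_sd = 20, max_lag = 8, n_alpha = 10) {
  stopifnot(is.finite(sigma2_m), sigma2_m >= 0, loc_error_sd >= 0,
            max_lag > 0, n_alpha >= 5)
  structure(list(sigma2_m = sigma2_m, loc_error_sd = loc_error_sd,
                 max_lag = max_lag, n_alpha = as.integer(n_alpha)),
            class = "bbmm_params")
}

#' Estimate the Brownian motion variance by leave-one-out likelihood
#'
#' Every second fix is left out and predicted from the Brownian bridge
#' between its two neighbours: at fraction `alpha` of the enclosing interval
#' `T` the bridge is normal about the linear interpolation of the
#' neighbours with variance
#' `alpha * (1 - alpha) * T * sigma2_m + ((1 - alpha)^2 + alpha^2) * delta^2`
#' per coordinate, `delta` the location-error SD. The summed log-likelihood
#' of the left-out fixes is maximized over `sigma2_m` on a log scale
#' (bracket `interval`, relative tolerance 1e-4).
#'
#' @param traj A [trajectory()] with at least 3 fixes.
#' @param loc_error_sd Location-error SD (m); defaults to the trajectory's
#'   own recorded value.
#' @param max_lag Triplets whose half-intervals exceed this gap (hours) are
#'   excluded.
#' @param interval Log-scale search bracket for `sigma2_m` (m^2/h).
#' @return Estimated `sigma2_m` (m^2/h).
#' @export
fit_bbmm_variance <- function(traj, loc_error_sd = NULL, max_lag = 8,
                              interval = c(1e-2, 1e8)) {
  stopifnot(inherits(traj, "trajectory"))
  f <- traj$fixes
  n <- nrow(f)
  if (n < 3) stop("need at least 3 fixes to estimate sigma2_m")
  if (is.null(loc_error_sd)) loc_error_sd <- stats::median(f$loc_error_sd)
  th <- as.numeric(f$timestamp) / 3600  # hours
  mid <- seq(2, n - 1, by = 2)
  gap1 <- th[mid] - th[mid - 1]
  gap2 <- th[mid + 1] - th[mid]
  ok <- gap1 <= max_lag & gap2 <= max_lag & (gap1 + gap2) > 0
  if (!any(ok)) stop("no usable bridges: all segments exceed max_lag")
  mid <- mid[ok]
  tot <- (gap1 + gap2)[ok]
  alpha <- gap1[ok] / tot
  mux <- f$x[mid - 1] + alpha * (f$x[mid + 1] - f$x[mid - 1])
  muy <- f$y[mid - 1] + alpha * (f$y[mid + 1] - f$y[mid - 1])
  errv <- ((1 - alpha)^2 + alpha^2) * loc_error_sd^2
  negll <- function(log_s2) {
    v <- alpha * (1 - alpha) * tot * exp(log_s2) + errv
    v <- pmax(v, 1e-12)
    -sum(dnorm(f$x[mid], mux, sqrt(v), log = TRUE) +
         dnorm(f$y[mid], muy, sqrt(v), log = TRUE))
  }
  opt <- optimize(negll, log(interval), tol = 1e-4)
  # if the optimum sits on the lower bracket the true value is ~0
  s2 <- exp(opt$minimum)
  if (s2 <= interval[1] * 1.01) s2 <- 0
  s2
}

# bridge components (mean, sd, weight) for one window; shared by estimate_bbmm
bbmm_components <- function(f, params) {
  th <- as.numeric(f$timestamp) / 3600
  n <- nrow(f)
  dt <- diff(th)
  seg <- which(dt > 0 & dt <= params$max_lag)
  if (!length(seg)) stop("no segment within max_lag of a neighbour")
  na <- params$n_alpha
  alpha <- (seq_len(na) - 0.5) / na
  k <- length(seg)
  a <- rep(alpha, times = k)
  i0 <- rep(seg, each = na)
  T_ <- rep(dt[seg], each = na)
  w <- T_ / na
  mux <- f$x[i0] + a * (f$x[i0 + 1] - f$x[i0])
  muy <- f$y[i0] + a * (f$y[i0 + 1] - f$y[i0])
  v <- a * (1 - a) * T_ * params$sigma2_m +
    ((1 - a)^2 + a^2) * params$loc_error_sd^2
  list(mux = mux, muy = muy, sd = sqrt(v), w = w)
}

#' Estimate a Brownian bridge occurrence distribution
#'
#' The OD is a duration-weighted mixture, over segments between consecutive
#' fixes no more than `max_lag` hours apart, of isotropic bivariate normals
#' along the bridge: at fraction `alpha` of a segment of duration `T` the
#' mean interpolates the endpoints linearly and the per-coordinate variance
#' is `alpha(1-alpha) T sigma2_m + ((1-alpha)^2 + alpha^2) delta^2`.
#' The bridge integral is discretized with `n_alpha` midpoint steps, cell
#' masses use the cell-centre approximation, and the result is normalized to
#' sum to one.
#'
#' @param traj A [trajectory()] (or window sub-trajectory) with >= 2 fixes.
#' @param grid A [grid_spec()] covering all fixes.
#' @param params A [bbmm_params()].
#' @param window_id Label stored on the result.
#' @return An [occurrence_dist()].
#' @export
estimate_bbmm <- function(traj, grid, params, window_id = "") {
  stopifnot(inherits(traj, "trajectory"), inherits(grid, "grid_spec"),
            inherits(params, "bbmm_params"))
  f <- traj$fixes
  if (nrow(f) < 2) stop("need at least 2 fixes")
  if (!grid_covers(grid, f$x, f$y)) stop("grid does not cover all fixes")
  cmp <- bbmm_components(f, params)
  mass <- gaussian_mass_grid(grid$n_rows, grid$n_cols, grid$x0, grid$y0,
                             grid$cell_size, cmp$mux, cmp$muy, cmp$sd, cmp$w)
  occurrence_dist(grid, mass, window_id)
}

#' Estimate a kernel utilization distribution
#'
#' Isotropic bivariate Gaussian kernel density over the relocations with the
#' reference bandwidth `h = sigma_hat * n^(-1/6)`,
#' `sigma_hat = sqrt((var(x) + var(y)) / 2)`, unless `bandwidth` is given.
#' Cell masses use the cell-centre approximation and are normalized to sum
#' to one.
#'
#' @param traj A [trajectory()] or a two-column matrix/data.frame of points.
#' @param grid A [grid_spec()] covering the points.
#' @param bandwidth Kernel SD in metres; `NULL` for the reference rule.
#' @param min_fixes Minimum number of points (default 30).
#' @param window_id Label stored on the result.
#' @return An [occurrence_dist()].
#' @export
estimate_kud <- function(traj, grid, bandwidth = NULL, min_fixes = 30,
                         window_id = "") {
  pts <- if (inherits(traj, "trajectory")) traj$fixes else as.data.frame(traj)
  if (is.null(pts$x)) names(pts)[1:2] <- c("x", "y")
  n <- nrow(pts)
  if (n < min_fixes) stop("need at least ", min_fixes, " points")
  if (!grid_covers(grid, pts$x, pts$y)) stop("grid does not cover all points")
  if (is.null(bandwidth)) {
    s <- sqrt((var(pts$x) + var(pts$y)) / 2)
    if (s == 0) stop("zero-variance point set: supply a bandwidth")
    bandwidth <- s * n^(-1 / 6)
  }
  stopifnot(bandwidth > 0)
  mass <- gaussian_mass_grid(grid$n_rows, grid$n_cols, grid$x0, grid$y0,
                             grid$cell_size, pts$x, pts$y,
                             rep(bandwidth, n), rep(1, n))
  occurrence_dist(grid, mass, window_id)
}

#' Volume isopleth of an occurrence distribution
#'
#' The smallest set of cells, taken in order of descending mass (ties broken
#' by cell index for determinism), whose cumulative mass reaches `level`.
#'
#' @param od An [occurrence_dist()].
#' @param level Isopleth level in (0, 1]; `level = 1` returns every cell
#'   with positive mass.
#' @return Logical matrix mask with the OD's grid attached as attribute
#'   `grid`.
#' @export
volume_isopleth <- function(od, level = 0.95) {
  stopifnot(inherits(od, "occurrence_dist"), level > 0, level <= 1)
  m <- as.vector(od$mass)
  ord <- order(m, seq_along(m), decreasing = c(TRUE, FALSE), method = "radix")
  cum <- cumsum(m[ord])
  k <- which(cum >= level * sum(m) - 1e-12)[1]
  mask <- logical(length(m))
  mask[ord[seq_len(k)]] <- m[ord[seq_len(k)]] > 0
  mask <- matrix(mask, nrow = od$grid$n_rows)
  attr(mask, "grid") <- od$grid
  mask
}

# estimator rule: BBMM when the window's fixes are frequent (median interval
# <= bbmm_max_interval hours), else KUD
window_od <- function(traj, grid, sigma2_m, loc_error_sd = 20,
                      bbmm_max_interval = 4, max_lag = 8, n_alpha = 10,
                      min_fixes = 30, window_id = "") {
  th <- as.numeric(traj$fixes$timestamp) / 3600
  med_int <- stats::median(diff(th))
  if (is.finite(med_int) && med_int <= bbmm_max_interval) {
    estimate_bbmm(traj, grid,
                  bbmm_params(sigma2_m, loc_error_sd, max_lag, n_alpha),
                  window_id)
  } else {
    estimate_kud(traj, grid, min_fixes = min_fixes, window_id = window_id)
  }
}
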