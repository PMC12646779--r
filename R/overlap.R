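# Embed an OD's mass onto a target grid on the same lattice. Exact when the
# two grids share the cell_size lattice; otherwise each source cell's mass is
# assigned to the target cell containing its centre (mass-conserving
# aggregation).
rebin_mass <- function(od, target) {
  g <- od$grid
  if (g$cell_size != target$cell_size)
    stop("incompatible cell sizes: ", g$cell_size, " vs ", target$cell_size)
  out <- matrix(0, target$n_rows, target$n_cols)
  idx <- which(od$mass > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out)
  xc <- g$x0 + (idx[, 2] - 0.5) * g$cell_size
  yc <- g$y0 + (idx[, 1] - 0.5) * g$cell_size
  tc <- floor((xc - target$x0) / target$cell_size) + 1L
  tr <- floor((yc - target$y0) / target$cell_size) + 1L
  keep <- tc >= 1 & tc <= target$n_cols & tr >= 1 & tr <= target$n_rows
  if (!all(keep))
    stop("target grid does not cover the source occurrence distribution")
  vals <- od$mass[idx]
  for (i in seq_along(vals)) out[tr[i], tc[i]] <- out[tr[i], tc[i]] + vals[i]
  out
}

# smallest grid on p's lattice covering both ODs
union_grid <- function(gp, gq) {
  cs <- gp$cell_size
  x0 <- min(gp$x0, gq$x0)
  y0 <- min(gp$y0, gq$y0)
  x0 <- gp$x0 - ceiling((gp$x0 - x0) / cs) * cs
  y0 <- gp$y0 - ceiling((gp$y0 - y0) / cs) * cs
  x1 <- max(gp$x0 + gp$n_cols * cs, gq$x0 + gq$n_cols * cs)
  y1 <- max(gp$y0 + gp$n_rows * cs, gq$y0 + gq$n_rows * cs)
  grid_spec(x0, y0, cs, ceiling((x1 - x0) / cs), ceiling((y1 - y0) / cs))
}

same_grid <- function(a, b) {
  a$cell_size == b$cell_size && a$x0 == b$x0 && a$y0 == b$y0 &&
    a$n_cols == b$n_cols && a$n_rows == b$n_rows
}

# restrict a mass vector to its `level` isopleth and renormalize
truncate_renorm <- function(mass, level) {
  if (level >= 1) return(mass / sum(mass))
  m <- as.vector(mass)
  ord <- order(m, seq_along(m), decreasing = c(TRUE, FALSE), method = "radix")
  cum <- cumsum(m[ord])
  k <- which(cum >= level * sum(m) - 1e-12)[1]
  keep <- ord[seq_len(k)]
  out <- numeric(length(m))
  out[keep] <- m[keep]
  out / sum(out)
}

#' Isopleth-restricted Bhattacharyya affinity between two ODs
#'
#' Each OD is restricted to its own `level` volume isopleth, renormalized to
#' sum to one, and the discrete Bhattacharyya coefficient
#' `sum(sqrt(p_i * q_i))` is computed over the cells of the union grid.
#' With `truncate = FALSE` (or `level = 1`) this is the plain Bhattacharyya
#' coefficient over the full supports. The two grids must share a cell size;
#' grids off the common lattice are re-binned by mass-conserving
#' aggregation.
#'
#' @param od_p,od_q [occurrence_dist()] objects.
#' @param level Isopleth level in (0, 1] (default 0.95).
#' @param truncate Restrict each OD to its isopleth before comparison
#'   (default `TRUE`); set `FALSE` for a full-support sensitivity check.
#' @return Affinity in \[0, 1\]; symmetric in its arguments.
#' @export
bhattacharyya_affinity <- function(od_p, od_q, level = 0.95, truncate = TRUE) {
  stopifnot(inherits(od_p, "occurrence_dist"), inherits(od_q, "occurrence_dist"),
            level > 0, level <= 1)
  if (same_grid(od_p$grid, od_q$grid)) {
    p <- od_p$mass
    q <- od_q$mass
  } else {
    ug <- union_grid(od_p$grid, od_q$grid)
    p <- rebin_mass(od_p, ug)
    q <- rebin_mass(od_q, ug)
  }
  if (truncate) {
    p <- truncate_renorm(p, level)
    q <- truncate_renorm(q, level)
  } else {
    p <- p / sum(p)
    q <- q / sum(q)
  }
  sum(sqrt(p * q))
}

#' The four movement metrics for one animal
#'
#' Given the animal's seasonal and monthly occurrence distributions:
#' \describe{
#'   \item{seasonal_overlap (metric 1)}{mean of the first-year and
#'     second-year summer-vs-winter affinities, pairing each summer with the
#'     winter that follows it chronologically. High values indicate
#'     residency.}
#'   \item{summer_overlap (metric 2)}{affinity between the two summer
#'     ranges across years.}
#'   \item{winter_overlap (metric 3)}{affinity between the two winter
#'     ranges across years. Low values with low metric 1 indicate
#'     multi-range migration.}
#'   \item{annual_overlap (metric 4)}{mean affinity over all pairs of
#'     monthly ODs whose sequential month indices differ by at least 2,
#'     excluding adjacent months to limit temporal autocorrelation (a July
#'     OD is never compared with June or August of the same sequence
#'     position).}
#' }
#'
#' @param ods A list with elements `summer` (list of >= 2 ODs in
#'   chronological order), `winter` (idem) and `monthly` (list over
#'   sequential month index; `NULL` entries allowed for absent months).
#' @param level Isopleth level for the affinities (default 0.95).
#' @param truncate Passed to [bhattacharyya_affinity()].
#' @return An object of class `movement_metrics`: list with
#'   `seasonal_overlap`, `summer_overlap`, `winter_overlap`,
#'   `annual_overlap`, `n_monthly_pairs`, `monthly_pairs` (2-column matrix
#'   of the month indices actually compared).
#' @export
movement_metrics <- function(ods, level = 0.95, truncate = TRUE) {
  for (s in c("summer", "winter")) {
    if (length(ods[[s]]) < 2)
      stop("incomplete animal: need two ", s, " occurrence distributions")
  }
  ba <- function(a, b) bhattacharyya_affinity(a, b, level, truncate)
  s1 <- ods$summer[[1]]; s2 <- ods$summer[[2]]
  w1 <- ods$winter[[1]]; w2 <- ods$winter[[2]]
  seasonal <- mean(c(ba(s1, w1), ba(s2, w2)))
  summer <- ba(s1, s2)
  winter <- ba(w1, w2)
  monthly <- ods$monthly
  have <- which(!vapply(monthly, is.null, logical(1)))
  pairs <- if (length(have) >= 2) {
    cmb <- t(combn(have, 2))
    cmb[cmb[, 2] - cmb[, 1] >= 2, , drop = FALSE]
  } else {
    matrix(integer(0), ncol = 2)
  }
  annual <- if (nrow(pairs) >= 1) {
    mean(vapply(seq_len(nrow(pairs)), function(i)
      ba(monthly[[pairs[i, 1]]], monthly[[pairs[i, 2]]]), numeric(1)))
  } else {
    NA_real_
  }
  structure(list(seasonal_overlap = seasonal, summer_overlap = summer,
                 winter_overlap = winter, annual_overlap = annual,
                 n_monthly_pairs = nrow(pairs), monthly_pairs = pairs),
            class = "movement_metrics")
}

#' Movement metrics for one animal, from its raw trajectory
#'
#' Convenience wrapper: splits the trajectory into seasonal and monthly
#' windows, estimates one Brownian motion variance from the full record,
#' builds one shared grid covering the whole point cloud (margin three
#' bridge/bandwidth SDs), estimates each window's OD (BBMM for fix
#' intervals up to 4 h, KUD otherwise) and distills the four metrics.
#'
#' @param traj A [trajectory()].
#' @param cell_size Grid resolution in metres (default 150).
#' @param level Isopleth level (default 0.95).
#' @param min_fixes Minimum fixes per usable window (default 30).
#' @param bbmm_max_interval BBMM/KUD switch-over fix interval in hours.
#' @param max_lag,n_alpha See [bbmm_params()].
#' @param truncate Passed to [bhattacharyya_affinity()].
#' @return A `movement_metrics` object (with the animal id attached as
#'   attribute `animal_id`), or `NULL` with a warning when the animal is
#'   incomplete (fewer than two usable summers or winters).
#' @export
animal_metrics <- function(traj, cell_size = 150, level = 0.95, min_fixes = 30,
                           bbmm_max_interval = 4, max_lag = 8, n_alpha = 10,
                           truncate = TRUE) {
  sp <- split_windows(traj, min_fixes = min_fixes)
  if (!sp$complete) {
    warning("animal ", traj$animal_id, " incomplete; skipped")
    return(NULL)
  }
  s2 <- fit_bbmm_variance(traj, max_lag = max_lag)
  delta <- stats::median(traj$fixes$loc_error_sd)
  med_int <- stats::median(diff(as.numeric(traj$fixes$timestamp) / 3600))
  margin <- 3 * max(sqrt(pmax(s2, 1) * med_int), delta, 200)
  grid <- make_grid(traj$fixes$x, traj$fixes$y, cell_size, margin)
  mk <- function(sub, id) {
    if (is.null(sub)) return(NULL)
    window_od(sub, grid, s2, delta, bbmm_max_interval, max_lag, n_alpha,
              min_fixes, id)
  }
  ods <- list(
    summer = lapply(seq_along(sp$summer), function(i)
      mk(sp$summer[[i]], paste0("summer_", names(sp$summer)[i]))),
    winter = lapply(seq_along(sp$winter), function(i)
      mk(sp$winter[[i]], paste0("winter_", names(sp$winter)[i]))),
    monthly = lapply(seq_along(sp$monthly), function(i)
      mk(sp$monthly[[i]], paste0("month_", sp$month_labels[i]))))
  mm <- movement_metrics(ods, level, truncate)
  attr(mm, "animal_id") <- traj$animal_id
  mm
}

#' Metrics table for a cohort
#'
#' @param trajectories Named list of [trajectory()] objects.
#' @param ... Passed to [animal_metrics()].
#' @return data.frame with `animal_id`, the four metrics, `n_monthly_pairs`
#'   and a `complete` flag; incomplete animals keep a row of `NA` metrics.
#' @export
cohort_metrics <- function(trajectories, ...) {
  rows <- lapply(trajectories, function(tr) {
    mm <- withCallingHandlers(animal_metrics(tr, ...),
                              warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(mm)) {
      data.frame(animal_id = tr$animal_id, seasonal_overlap = NA_real_,
                 summer_overlap = NA_real_, winter_overlap = NA_real_,
                 annual_overlap = NA_real_, n_monthly_pairs = NA_integer_,
                 complete = FALSE)
    } else {
      data.frame(animal_id = tr$animal_id,
                 seasonal_overlap = mm$seasonal_overlap,
                 summer_overlap = mm$summer_overlap,
                 winter_overlap = mm$winter_overlap,
                 annual_overlap = mm$annual_overlap,
                 n_monthly_pairs = mm$n_monthly_pairs, complete = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
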