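# mean layer across years for one covariate (matrix); static covariates are
# stored with identical slices so the mean is a no-op for them
covariate_mean_layer <- function(stack, cv) {
  arr <- stack$layers[[cv]]
  ny <- dim(arr)[3]
  if (ny == 1) return(arr[, , 1])
  Reduce(`+`, lapply(seq_len(ny), function(j) arr[, , j])) / ny
}

# cache of across-year mean layers, computed once per stack
stack_mean_layers <- function(stack) {
  setNames(lapply(names(stack$layers),
                  function(cv) covariate_mean_layer(stack, cv)),
           names(stack$layers))
}

#' Year-round range mask of an animal
#'
#' 95% kernel utilization distribution over the full 21-23-month record,
#' evaluated on the covariate grid, returned as a volume-isopleth cell mask.
#'
#' @param traj A [trajectory()].
#' @param grid The covariate grid ([grid_spec()]).
#' @param level Isopleth level (default 0.95).
#' @param bandwidth Optional kernel SD in metres (reference rule otherwise).
#' @return Logical cell mask (attribute `grid` attached).
#' @export
year_round_range <- function(traj, grid, level = 0.95, bandwidth = NULL) {
  od <- estimate_kud(traj, grid, bandwidth = bandwidth,
                     window_id = paste0(traj$animal_id, "_year_round"))
  volume_isopleth(od, level)
}

#' Spatial variation in resources over a range
#'
#' For every covariate: mean each grid cell across years (annual
#' covariates), then the SD of those cell values across the masked cells.
#' The masked cells are treated as a census of the range, so the population
#' SD convention (denominator `n`) is used.
#'
#' @param stack A `covariate_stack`.
#' @param mask Logical cell mask on the stack's grid with >= 2 cells.
#' @param mean_layers Optional precomputed across-year mean layers (internal
#'   cache for cohort summaries).
#' @return Named numeric vector of per-covariate SDs.
#' @export
spatial_variation <- function(stack, mask, mean_layers = NULL) {
  stopifnot(inherits(stack, "covariate_stack"), is.logical(mask))
  if (sum(mask) < 2)
    stop("mask must cover at least 2 cells for a spatial SD")
  if (is.null(mean_layers)) mean_layers <- stack_mean_layers(stack)
  vapply(names(stack$layers), function(cv) {
    v <- mean_layers[[cv]][mask]
    sqrt(mean((v - mean(v))^2))
  }, numeric(1))
}

#' Aggregate per-covariate spatial SDs into one spatial-variation score
#'
#' Columns are centred and scaled to unit variance and the first principal
#' component scores are returned, sign-oriented so the covariate with the
#' largest-magnitude PC1 loading loads positively. Zero-variance columns
#' are dropped with a warning.
#'
#' @param sd_matrix Numeric matrix (animals x covariates) of spatial SDs.
#' @return Numeric vector of PC1 scores (zero mean), with attributes
#'   `loadings` and `var_explained`.
#' @export
pca_spatial_score <- function(sd_matrix) {
  X <- as.matrix(sd_matrix)
  stopifnot(nrow(X) >= 2, ncol(X) >= 2, all(is.finite(X)))
  keep <- apply(X, 2, sd) > 0
  if (!all(keep)) {
    warning("dropping zero-variance covariate column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) < 2) stop("fewer than 2 covariates with variance")
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  load1 <- pc$rotation[, 1]
  if (load1[which.max(abs(load1))] < 0) {
    load1 <- -load1
    pc$x[, 1] <- -pc$x[, 1]
  }
  scores <- pc$x[, 1]
  attr(scores, "loadings") <- load1
  attr(scores, "var_explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  scores
}

#' Year-to-year variation in resources over a range
#'
#' For each covariate: the spatial mean over the masked cells in each year,
#' then the SD of those annual means across years (sample convention,
#' denominator `n - 1`: years are a sample of the process). Low values mean
#' a temporally predictable resource environment.
#'
#' @param stack A `covariate_stack` with >= 2 years for the requested
#'   covariates.
#' @param mask Logical cell mask on the stack's grid.
#' @param covariates Covariates to summarize (default the two phenology
#'   variables entering the candidate models).
#' @return Named numeric vector of SDs of annual means.
#' @export
yty_variation <- function(stack, mask,
                          covariates = c("spring_length", "biomass")) {
  stopifnot(inherits(stack, "covariate_stack"), is.logical(mask), any(mask))
  vapply(covariates, function(cv) {
    arr <- stack$layers[[cv]]
    if (is.null(arr)) stop("covariate not in stack: ", cv)
    ny <- dim(arr)[3]
    if (ny < 2) stop("need at least 2 years for ", cv)
    ann <- vapply(seq_len(ny), function(j) mean(arr[, , j][mask]), numeric(1))
    sd(ann)
  }, numeric(1))
}

#' Standardized circular availability domain
#'
#' A circle of the requested area centred on the centroid of the animal's
#' winter (1 Dec - 28/29 Feb) relocations, rasterized onto the covariate
#' grid by cell-centre inclusion. Decouples the available resource
#' environment from where the animal actually ranged.
#'
#' @param traj A [trajectory()] containing winter fixes.
#' @param grid The covariate grid ([grid_spec()]).
#' @param domain_area_km2 Domain area in square kilometres (species-level
#'   standard, e.g. 3765 for pronghorn, 1647 for elk).
#' @return Logical cell mask (attributes `grid`, `centre`, `radius_m`).
#' @export
standardized_domain <- function(traj, grid, domain_area_km2) {
  stopifnot(inherits(traj, "trajectory"), domain_area_km2 > 0)
  mon <- as.integer(format(traj$fixes$timestamp, "%m", tz = "UTC"))
  win <- mon %in% c(12L, 1L, 2L)
  if (!any(win)) stop("no winter fixes: cannot centre the standardized domain")
  cx <- mean(traj$fixes$x[win])
  cy <- mean(traj$fixes$y[win])
  radius <- sqrt(domain_area_km2 * 1e6 / pi)
  cc <- grid_centres(grid)
  dx2 <- (cc$x - cx)^2
  dy2 <- (cc$y - cy)^2
  mask <- outer(dy2, dx2, "+") <= radius^2
  attr(mask, "grid") <- grid
  attr(mask, "centre") <- c(cx, cy)
  attr(mask, "radius_m") <- radius
  mask
}

#' Winter-climate and anthropogenic indices for a cohort
#'
#' Per animal: `winter_conditions` is the mean snow depth over the masked
#' cells and across the available years (the snow layers represent
#' winter-period mean daily snow depth); `pct_agriculture` and `dist_roads`
#' are masked-cell means of the static layers. `winter_severity` is the
#' within-cohort z-score of `winter_conditions`, so it is relative to the
#' other animals summarized together (compute species by species).
#'
#' @param stack A `covariate_stack` containing `snow_depth`,
#'   `pct_agriculture` and `dist_roads`.
#' @param masks Named list (by animal) of logical cell masks.
#' @param mean_layers Optional precomputed across-year mean layers.
#' @return data.frame `animal_id`, `winter_conditions`, `winter_severity`,
#'   `pct_agriculture`, `dist_roads`.
#' @export
climate_anthro_indices <- function(stack, masks, mean_layers = NULL) {
  stopifnot(inherits(stack, "covariate_stack"), length(masks) >= 1)
  if (is.null(stack$layers$snow_depth))
    stop("snow_depth layers missing from stack")
  if (is.null(mean_layers)) mean_layers <- stack_mean_layers(stack)
  rows <- lapply(names(masks), function(id) {
    m <- masks[[id]]
    data.frame(animal_id = id,
               winter_conditions = mean(mean_layers$snow_depth[m]),
               pct_agriculture = mean(mean_layers$pct_agriculture[m]),
               dist_roads = mean(mean_layers$dist_roads[m]))
  })
  out <- do.call(rbind, rows)
  sdev <- sd(out$winter_conditions)
  out$winter_severity <- if (length(masks) > 1 && sdev > 0)
    (out$winter_conditions - mean(out$winter_conditions)) / sdev
  else 0
  out[, c("animal_id", "winter_conditions", "winter_severity",
          "pct_agriculture", "dist_roads")]
}

#' Per-animal resource-variation table
#'
#' Runs the shared mask-based code path for either availability domain:
#' per-covariate spatial SDs, the PC1 spatial-variation score, year-to-year
#' SDs of the phenology covariates, and the climate/anthropogenic indices.
#'
#' @param trajectories Named list of [trajectory()] objects.
#' @param stack A `covariate_stack`.
#' @param domain `"empirical"` (95% KUD year-round range) or
#'   `"standardized"` (circular buffer on the winter centroid).
#' @param domain_area_km2 Circle area for the standardized domain.
#' @param level Isopleth level for the empirical range.
#' @return data.frame keyed by `animal_id` and `domain` with
#'   `spatial_variation_score`, per-covariate `sd_*` columns,
#'   `yty_spring_length_sd`, `yty_biomass_sd`, `winter_conditions`,
#'   `winter_severity`, `pct_agriculture`, `dist_roads`.
#' @export
variation_summary <- function(trajectories, stack,
                              domain = c("empirical", "standardized"),
                              domain_area_km2 = 3765, level = 0.95) {
  domain <- match.arg(domain)
  masks <- lapply(trajectories, function(tr) {
    if (domain == "empirical") year_round_range(tr, stack$grid, level)
    else standardized_domain(tr, stack$grid, domain_area_km2)
  })
  names(masks) <- vapply(trajectories, `[[`, "", "animal_id")
  ml <- stack_mean_layers(stack)
  sds <- t(vapply(masks, function(m) spatial_variation(stack, m, ml),
                  numeric(length(stack$layers))))
  score <- pca_spatial_score(sds)
  yty <- t(vapply(masks, function(m) yty_variation(stack, m), numeric(2)))
  clim <- climate_anthro_indices(stack, masks, ml)
  out <- data.frame(animal_id = names(masks), domain = domain,
                    spatial_variation_score = as.numeric(score))
  colnames(sds) <- paste0("sd_", colnames(sds))
  out <- cbind(out, sds,
               yty_spring_length_sd = yty[, "spring_length"],
               yty_biomass_sd = yty[, "biomass"])
  out <- merge(out, clim, by = "animal_id", sort = FALSE)
  rownames(out) <- NULL
  out
}
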