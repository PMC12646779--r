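#' Regular analysis grid
#'
#' A `grid_spec` describes the regular square-celled grid on which occurrence
#' distributions and covariate layers live. Cell `(r, c)` has centre
#' `x = x0 + (c - 0.5) * cell_size`, `y = y0 + (r - 0.5) * cell_size`.
#'
#' @param x0,y0 Coordinates (metres) of the grid's lower-left corner.
#' @param cell_size Cell edge length in metres (default 150).
#' @param n_cols,n_rows Grid dimensions.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(x0, y0, cell_size = 150, n_cols, n_rows) {
  stopifnot(is.finite(x0), is.finite(y0), cell_size > 0,
            n_cols >= 1, n_rows >= 1)
  structure(list(x0 = x0, y0 = y0, cell_size = cell_size,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
            class = "grid_spec")
}

#' Build a grid covering a point cloud
#'
#' The origin is snapped to a multiple of `cell_size` so that grids built for
#' different animals at the same resolution share one lattice and can be
#' overlaid exactly.
#'
#' @param x,y Point coordinates in metres.
#' @param cell_size Cell edge length in metres.
#' @param margin Margin in metres added on every side; should be at least
#'   three bandwidths / bridge standard deviations of the intended estimator.
#' @return A `grid_spec`.
#' @export
make_grid <- function(x, y, cell_size = 150, margin = 1000) {
  stopifnot(length(x) == length(y), length(x) >= 1,
            all(is.finite(x)), all(is.finite(y)), margin >= 0)
  x0 <- floor((min(x) - margin) / cell_size) * cell_size
  y0 <- floor((min(y) - margin) / cell_size) * cell_size
  n_cols <- ceiling((max(x) + margin - x0) / cell_size)
  n_rows <- ceiling((max(y) + margin - y0) / cell_size)
  grid_spec(x0, y0, cell_size, n_cols, n_rows)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$x0, x$y0))
  invisible(x)
}

# cell centre coordinates
grid_centres <- function(grid) {
  list(x = grid$x0 + (seq_len(grid$n_cols) - 0.5) * grid$cell_size,
       y = grid$y0 + (seq_len(grid$n_rows) - 0.5) * grid$cell_size)
}

# TRUE if all points fall inside the grid extent
grid_covers <- function(grid, x, y) {
  all(x >= grid$x0 & x <= grid$x0 + grid$n_cols * grid$cell_size &
      y >= grid$y0 & y <= grid$y0 + grid$n_rows * grid$cell_size)
}

# row/col (1-based) of the cell containing each point
grid_cell_of <- function(grid, x, y) {
  list(row = pmin(grid$n_rows, pmax(1L, floor((y - grid$y0) / grid$cell_size) + 1L)),
       col = pmin(grid$n_cols, pmax(1L, floor((x - grid$x0) / grid$cell_size) + 1L)))
}

#' Occurrence distribution on a grid
#'
#' Probability masses (summing to one) per grid cell for one animal and one
#' temporal window.
#'
#' @param grid A `grid_spec`.
#' @param mass Numeric matrix (`n_rows` x `n_cols`) of nonnegative cell
#'   masses; normalized to sum to one.
#' @param window_id Label for the temporal window.
#' @return An object of class `occurrence_dist`.
#' @export
occurrence_dist <- function(grid, mass, window_id = "") {
  stopifnot(inherits(grid, "grid_spec"),
            is.matrix(mass),
            nrow(mass) == grid$n_rows, ncol(mass) == grid$n_cols,
            all(is.finite(mass)), all(mass >= 0))
  total <- sum(mass)
  if (total <= 0) stop("occurrence distribution has zero total mass")
  structure(list(grid = grid, mass = mass / total, window_id = window_id),
            class = "occurrence_dist")
}

#' @export
print.occurrence_dist <- function(x, ...) {
  cat(sprintf("occurrence_dist '%s' on %d x %d grid (cell %g m), mass sum %.6f\n",
              x$window_id, x$grid$n_rows, x$grid$n_cols, x$grid$cell_size,
              sum(x$mass)))
  invisible(x)
}
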