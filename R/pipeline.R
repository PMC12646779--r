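#' Write a covariate stack as plain-text rasters
#'
#' One whitespace-delimited matrix per covariate-year, named
#' `<covariate>_<year>.txt`, plus a JSON `manifest.json` recording the grid,
#' years and static flags.
#'
#' @param stack A `covariate_stack`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (cv in names(stack$layers)) {
    yrs <- if (stack$static[[cv]]) stack$years[1] else stack$years
    for (j in yrs) {
      fn <- sprintf("%s_%d.txt", cv, j)
      write.table(format(stack$layers[[cv]][, , j], digits = 10),
                  file.path(dir, fn), row.names = FALSE, col.names = FALSE,
                  quote = FALSE)
      files <- c(files, fn)
    }
  }
  g <- stack$grid
  jsonlite::write_json(
    list(grid = list(x0 = g$x0, y0 = g$y0, cell_size = g$cell_size,
                     n_cols = g$n_cols, n_rows = g$n_rows),
         years = stack$years, static = as.list(stack$static), files = files),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a covariate stack written by [write_landscape()]
#'
#' @param dir Directory containing the text rasters and `manifest.json`.
#' @return A `covariate_stack`.
#' @export
read_landscape <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  g <- man$grid
  grid <- grid_spec(g$x0, g$y0, g$cell_size, g$n_cols, g$n_rows)
  years <- as.integer(man$years)
  static <- unlist(man$static)
  covs <- names(static)
  layers <- list()
  for (cv in covs) {
    arr <- array(NA_real_, c(grid$n_rows, grid$n_cols, length(years)))
    yrs <- if (static[[cv]]) years[1] else years
    for (j in yrs) {
      m <- as.matrix(read.table(file.path(dir, sprintf("%s_%d.txt", cv, j))))
      dimnames(m) <- NULL
      arr[, , if (static[[cv]]) seq_along(years) else j] <- m
    }
    layers[[cv]] <- arr
  }
  structure(list(grid = grid, years = years, layers = layers, static = static),
            class = "covariate_stack")
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end demonstration pipeline into one
#' validated list.
#'
#' @param out_dir Run directory for the output tables.
#' @param seed Global RNG seed.
#' @param n_per_strategy Synthetic animals per strategy.
#' @param n_months Record length (21-23 months).
#' @param fix_interval Hours between fixes.
#' @param cell_size Grid resolution (m).
#' @param level Isopleth level in (0, 1].
#' @param min_fixes Minimum fixes per usable window.
#' @param kmeans_n_init,kmeans_seed k-means restarts and seed.
#' @param domain_area_km2 Standardized availability-domain area.
#' @param objectives Which model-set objectives to run (subset of `c(2, 3)`).
#' @param min_subset_n Smallest model-set subset accepted.
#' @param land_params A [landscape_params()] object.
#' @param write_rasters Also persist the landscape as text rasters.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, n_per_strategy = 20,
                            n_months = 22, fix_interval = 2, cell_size = 150,
                            level = 0.95, min_fixes = 30, kmeans_n_init = 50,
                            kmeans_seed = 1, domain_area_km2 = 3765,
                            objectives = c(2, 3), min_subset_n = 10,
                            land_params = landscape_params(),
                            write_rasters = FALSE) {
  if (!(level > 0 && level <= 1)) stop("isopleth level must lie in (0, 1]")
  stopifnot(n_per_strategy >= 1, n_months >= 21, n_months <= 23,
            fix_interval > 0, cell_size > 0, min_fixes >= 2,
            domain_area_km2 > 0, all(objectives %in% c(2, 3)))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_per_strategy = as.integer(n_per_strategy),
                 n_months = as.integer(n_months),
                 fix_interval = fix_interval, cell_size = cell_size,
                 level = level, min_fixes = min_fixes,
                 kmeans_n_init = kmeans_n_init, kmeans_seed = kmeans_seed,
                 domain_area_km2 = domain_area_km2, objectives = objectives,
                 min_subset_n = min_subset_n, land_params = land_params,
                 write_rasters = write_rasters),
            class = "pipeline_config")
}

write_df <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the end-to-end demonstration pipeline
#'
#' Stages: simulate a labelled cohort on a synthetic landscape; compute the
#' four movement metrics per animal; classify strategies by k-means;
#' summarize resource variation over the empirical and standardized
#' availability domains; fit the candidate beta-regression model sets.
#' Writes `trajectories.csv`, `truth.csv`, `metrics.csv`,
#' `assignments.csv`, `variation_empirical.csv`,
#' `variation_standardized.csv`, `model_selection_obj<k>.csv` (+
#' coefficient tables) and `manifest.json` into the run directory. All
#' outputs are pure functions of (config, seed); a rerun with the same
#' config is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return The run directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[partmig] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  defaults <- list(
    resident = strategy_params("resident", fix_interval = config$fix_interval,
                               n_months = config$n_months),
    dual_range = strategy_params("dual_range",
                                 fix_interval = config$fix_interval,
                                 n_months = config$n_months),
    multi_range = strategy_params("multi_range",
                                  fix_interval = config$fix_interval,
                                  n_months = config$n_months))
  pop <- stage("simulate", {
    p <- simulate_population(config$n_per_strategy, config$seed,
                             strategy_defaults = defaults,
                             land_params = config$land_params)
    write_trajectories(p$trajectories, file.path(config$out_dir, "trajectories.csv"))
    write_df(p$truth, file.path(config$out_dir, "truth.csv"))
    if (config$write_rasters)
      write_landscape(p$landscape, file.path(config$out_dir, "landscape"))
    p
  })
  metrics <- stage("metrics", {
    m <- cohort_metrics(pop$trajectories, cell_size = config$cell_size,
                        level = config$level, min_fixes = config$min_fixes)
    write_df(m, file.path(config$out_dir, "metrics.csv"))
    m
  })
  assignments <- stage("classify", {
    a <- kmeans_strategies(metrics, n_init = config$kmeans_n_init,
                           seed = config$kmeans_seed)
    write_df(a, file.path(config$out_dir, "assignments.csv"))
    a
  })
  variation <- stage("variation", {
    ve <- variation_summary(pop$trajectories, pop$landscape, "empirical",
                            level = config$level)
    vs <- variation_summary(pop$trajectories, pop$landscape, "standardized",
                            domain_area_km2 = config$domain_area_km2)
    write_df(ve, file.path(config$out_dir, "variation_empirical.csv"))
    write_df(vs, file.path(config$out_dir, "variation_standardized.csv"))
    ve
  })
  stage("models", {
    for (obj in config$objectives) {
      sets <- run_model_sets(metrics, assignments, variation, objective = obj,
                             min_n = config$min_subset_n)
      write_model_sets(sets, file.path(config$out_dir,
                                       sprintf("model_selection_obj%d.csv", obj)))
    }
  })
  cfg <- unclass(config)
  cfg$land_params <- unclass(cfg$land_params)
  jsonlite::write_json(
    list(package = "partmig",
         version = as.character(utils::packageVersion("partmig")),
         seed = config$seed, config = cfg),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}
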