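#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters (coefficients plus precision).
#' @param n Number of observations; must exceed `k + 1`.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  stopifnot(is.finite(loglik), k >= 1)
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Beta regression by maximum likelihood
#'
#' Mean model `mu_i = logistic(x_i' beta)` with constant precision `phi`;
#' `y_i ~ Beta(mu_i phi, (1 - mu_i) phi)`. Because overlap metrics can be
#' exactly 0 or 1, where the beta likelihood is undefined, the response is
#' first compressed by `y' = (y (n - 1) + 0.5) / n`. Standard errors come
#' from the inverse observed information (in the `(beta, log phi)`
#' parameterization) and 95% intervals are Wald. The pseudo-R2 is the
#' squared Pearson correlation between `logit(y')` and the fitted linear
#' predictor.
#'
#' @param y Proportions in \[0, 1\].
#' @param X Design matrix including the intercept column; full column rank.
#' @param max_restarts Random restarts after a failed optimization
#'   (default 5).
#' @return An object of class `beta_regression_fit`: list with `beta`,
#'   `se`, `ci` (2-column matrix), `phi`, `loglik`, `aicc`, `pseudo_r2`,
#'   `n`, `k_params`, `fitted`, `converged`.
#' @export
fit_beta_regression <- function(y, X, max_restarts = 5) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, all(is.finite(y)), all(is.finite(X)))
  if (any(y < 0 | y > 1)) stop("response values must lie in [0, 1]")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  p <- ncol(X)
  k_params <- p + 1L
  if (n <= k_params + 1) stop("too few observations for ", p, " coefficients")
  yc <- (y * (n - 1) + 0.5) / n
  negll <- function(par) {
    eta <- drop(X %*% par[1:p])
    mu <- plogis(eta)
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    phi <- exp(par[p + 1])
    -sum(dbeta(yc, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  # starting values: OLS on the logit scale; moment estimate of phi
  z <- qlogis(yc)
  b0 <- tryCatch(coef(lm.fit(X, z)), error = function(e) rep(0, p))
  b0[!is.finite(b0)] <- 0
  mu0 <- plogis(drop(X %*% b0))
  s2 <- var(yc - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(s2, 1e-8) - 1, 1)
  start <- c(b0, log(phi0))
  fit <- NULL
  for (r in 0:max_restarts) {
    st <- if (r == 0) start else start + rnorm(length(start), 0, 0.5 * r)
    cand <- tryCatch(
      optim(st, negll, method = "BFGS", hessian = FALSE,
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(cand) && cand$convergence == 0 &&
        (is.null(fit) || cand$value < fit$value)) {
      fit <- cand
      if (r == 0) break
    }
  }
  if (is.null(fit))
    stop("beta regression failed to converge after ", max_restarts,
         " restarts")
  H <- stats::optimHess(fit$par, negll)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k_params, k_params))
  se <- sqrt(pmax(diag(vc)[1:p], 0))
  beta <- fit$par[1:p]
  names(beta) <- colnames(X)
  names(se) <- colnames(X)
  eta <- drop(X %*% beta)
  ll <- -fit$value
  ci <- cbind(lower = beta - qnorm(0.975) * se,
              upper = beta + qnorm(0.975) * se)
  structure(list(beta = beta, se = se, ci = ci,
                 phi = unname(exp(fit$par[p + 1])),
                 loglik = ll, aicc = aicc(ll, k_params, n),
                 pseudo_r2 = if (var(eta) > 0) cor(qlogis(yc), eta)^2 else 0,
                 n = n, k_params = k_params, fitted = plogis(eta),
                 converged = TRUE),
            class = "beta_regression_fit")
}

#' @export
print.beta_regression_fit <- function(x, ...) {
  cat(sprintf("beta regression: n = %d, phi = %.2f, logLik = %.2f, AICc = %.2f, ps-R2 = %.3f\n",
              x$n, x$phi, x$loglik, x$aicc, x$pseudo_r2))
  tab <- cbind(estimate = x$beta, se = x$se, x$ci)
  print(round(tab, 4))
  invisible(x)
}

# candidate model definitions (predictor columns per candidate); spatial and
# year-to-year variation never co-occur in one candidate
.obj2_candidates <- list(
  spatial = "spatial_variation_score",
  yty = c("yty_spring_length_sd", "yty_biomass_sd"),
  intercept = character(0)
)

.climate_vars <- c("winter_conditions", "winter_severity")
.anthro_vars <- c("pct_agriculture", "dist_roads")

# the four data subsets and their response metric
.subset_defs <- list(
  all = list(filter = c("resident", "dual_range_migrant", "multi_range_migrant"),
             response = "seasonal_overlap"),
  dual_vs_multi = list(filter = c("dual_range_migrant", "multi_range_migrant"),
                       response = "winter_overlap"),
  resident_vs_dual = list(filter = c("resident", "dual_range_migrant"),
                          response = "seasonal_overlap"),
  resident_vs_multi = list(filter = c("resident", "multi_range_migrant"),
                           response = "annual_overlap")
)

fit_candidate <- function(df, response, vars) {
  y <- df[[response]]
  X <- matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  if (length(vars)) {  # predictors centred and scaled within the subset
    Z <- scale(as.matrix(df[, vars, drop = FALSE]))
    if (!all(is.finite(Z)))
      stop("constant or non-finite predictor in subset: ",
           paste(vars[!apply(is.finite(Z), 2, all)], collapse = ", "))
    X <- cbind(X, Z)
  }
  fit_beta_regression(y, X)
}

selection_table <- function(fits, n) {
  aic <- vapply(fits, `[[`, 0, "aicc")
  d <- aic - min(aic)
  w <- exp(-d / 2) / sum(exp(-d / 2))
  tab <- data.frame(candidate = names(fits),
                    k = vapply(fits, `[[`, 0L, "k_params"),
                    aicc = aic, delta_aicc = d, weight = w,
                    pseudo_r2 = vapply(fits, `[[`, 0, "pseudo_r2"),
                    n = n, row.names = NULL)
  tab[order(tab$aicc), ]
}

#' Candidate beta-regression model sets over the four data subsets
#'
#' Joins the metrics, strategy assignments and variation tables, builds the
#' four analysis subsets (`all` animals with seasonal overlap as response;
#' `dual_vs_multi` with winter overlap; `resident_vs_dual` with seasonal
#' overlap; `resident_vs_multi` with annual overlap), scales and centres
#' all predictors within each subset, fits every candidate by maximum
#' likelihood and ranks them by AICc.
#'
#' Objective 2 candidates: spatial variation; year-to-year variation
#' (spring length + biomass); intercept only. Spatial and year-to-year
#' variation are never combined in one candidate (they are strongly
#' correlated by construction of the landscape). Objective 3 fits seven
#' candidates: the subset's objective-2 top model, intercept-only, climate
#' (winter conditions + relative winter severity), anthropogenic (percent
#' agriculture + distance to roads), and the top objective-2 model combined
#' with climate, with anthropogenic, and with both.
#'
#' @param metrics Output of [cohort_metrics()].
#' @param assignments Output of [kmeans_strategies()].
#' @param variation Output of [variation_summary()] (one domain).
#' @param objective 2 (resource variation) or 3 (alternative hypotheses).
#' @param min_n Smallest subset size accepted (default 10); smaller subsets
#'   are refused with a warning and reported as `NULL`.
#' @return Named list per subset: list with `table` (AICc ranking),
#'   `fits` (the `beta_regression_fit`s), `response`, `top` (top
#'   candidate's name).
#' @export
run_model_sets <- function(metrics, assignments, variation, objective = 2,
                           min_n = 10) {
  stopifnot(objective %in% c(2, 3))
  df <- merge(merge(metrics, assignments[, c("animal_id", "strategy")],
                    by = "animal_id"),
              variation, by = "animal_id")
  out <- list()
  for (sname in names(.subset_defs)) {
    def <- .subset_defs[[sname]]
    sub <- df[df$strategy %in% def$filter & df$complete, , drop = FALSE]
    sub <- sub[is.finite(sub[[def$response]]), , drop = FALSE]
    if (nrow(sub) < min_n) {
      warning("subset '", sname, "' refused: only ", nrow(sub),
              " animals (< ", min_n, ")")
      out[[sname]] <- NULL
      next
    }
    cands <- .obj2_candidates
    if (objective == 3) {
      obj2_fits <- lapply(.obj2_candidates, function(v)
        fit_candidate(sub, def$response, v))
      obj2_tab <- selection_table(obj2_fits, nrow(sub))
      top_vars <- .obj2_candidates[[obj2_tab$candidate[1]]]
      cands <- list(
        top_obj2 = top_vars,
        intercept = character(0),
        climate = .climate_vars,
        anthro = .anthro_vars,
        top_obj2_climate = c(top_vars, .climate_vars),
        top_obj2_anthro = c(top_vars, .anthro_vars),
        top_obj2_climate_anthro = c(top_vars, .climate_vars, .anthro_vars))
    }
    fits <- lapply(cands, function(v) fit_candidate(sub, def$response, v))
    tab <- selection_table(fits, nrow(sub))
    out[[sname]] <- list(table = tab, fits = fits, response = def$response,
                         top = tab$candidate[1])
  }
  if (!length(out)) stop("no subset had at least ", min_n, " animals")
  out
}

#' Write model-selection results as delimited text
#'
#' @param sets Output of [run_model_sets()].
#' @param path CSV path for the selection table; a companion
#'   `*_coefficients.csv` holds estimates and 95% intervals.
#' @return `path`, invisibly.
#' @export
write_model_sets <- function(sets, path) {
  tabs <- lapply(names(sets), function(s)
    cbind(subset = s, response = sets[[s]]$response, sets[[s]]$table))
  write.csv(do.call(rbind, tabs), path, row.names = FALSE, quote = FALSE)
  coefs <- do.call(rbind, lapply(names(sets), function(s) {
    do.call(rbind, lapply(names(sets[[s]]$fits), function(cn) {
      f <- sets[[s]]$fits[[cn]]
      data.frame(subset = s, candidate = cn, term = names(f$beta),
                 estimate = unname(f$beta), se = unname(f$se),
                 lower95 = unname(f$ci[, "lower"]),
                 upper95 = unname(f$ci[, "upper"]))
    }))
  }))
  write.csv(coefs, sub("\\.csv$", "_coefficients.csv", path),
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
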