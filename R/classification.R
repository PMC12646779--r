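# k-means++ seeding: first centre uniform over points, each further centre
# sampled with probability proportional to squared distance to the nearest
# chosen centre
kmeanspp_centres <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((X - matrix(X[idx[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      idx[j + 1] <- sample.int(n, 1)
    } else {
      idx[j + 1] <- sample.int(n, 1, prob = d2)
    }
    nd <- rowSums((X - matrix(X[idx[j + 1], ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  X[idx, , drop = FALSE]
}

#' Cluster animals into movement strategies by k-means
#'
#' Lloyd's algorithm on the (unstandardized — all three share the \[0, 1\]
#' scale) seasonal, summer and winter overlap metrics, with k-means++
#' initialization and `n_init` restarts keeping the lowest within-cluster
#' sum of squares. Clusters are then named by [label_clusters()].
#' Deterministic for a fixed seed.
#'
#' @param metrics data.frame with columns `animal_id`, `seasonal_overlap`,
#'   `summer_overlap`, `winter_overlap` (incomplete rows are dropped).
#' @param k Number of clusters (default 3: resident, dual-range migrant,
#'   multi-range migrant).
#' @param n_init Number of restarts (default 50).
#' @param seed Integer RNG seed.
#' @return data.frame `animal_id`, `cluster_index`, `strategy`, the three
#'   metrics; attributes `centroids` (k x 3 matrix), `labels` (cluster ->
#'   strategy), `tot_withinss`.
#' @export
kmeans_strategies <- function(metrics, k = 3, n_init = 50, seed = 1) {
  cols <- c("seasonal_overlap", "summer_overlap", "winter_overlap")
  stopifnot(all(c("animal_id", cols) %in% names(metrics)))
  metrics <- metrics[complete.cases(metrics[, cols]), , drop = FALSE]
  X <- as.matrix(metrics[, cols])
  if (any(X < 0 | X > 1)) stop("metrics must lie in [0, 1]")
  if (nrow(X) < k) stop("need at least ", k, " complete animals")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    cen <- kmeanspp_centres(X, k)
    fit <- tryCatch(
      suppressWarnings(kmeans(X, centers = cen, algorithm = "Lloyd",
                              iter.max = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed in every restart")
  labels <- if (k == 3) label_clusters(best$centers) else
    setNames(paste0("cluster_", seq_len(k)), seq_len(k))
  out <- data.frame(animal_id = metrics$animal_id,
                    cluster_index = best$cluster,
                    strategy = unname(labels[as.character(best$cluster)]),
                    metrics[, cols], row.names = NULL)
  attr(out, "centroids") <- best$centers
  attr(out, "labels") <- labels
  attr(out, "tot_withinss") <- best$tot.withinss
  out
}

#' Name the three k-means clusters as movement strategies
#'
#' Operationalizes the verbal cluster descriptions: residents have high
#' year-round (seasonal) overlap, so the cluster with the highest
#' seasonal-overlap centroid is `resident`; of the remaining two, dual-range
#' migrants reuse the same winter range across years, so the higher
#' winter-overlap centroid is `dual_range_migrant` and the other is
#' `multi_range_migrant`.
#'
#' @param centroids 3 x 3 matrix with columns `seasonal_overlap`,
#'   `summer_overlap`, `winter_overlap` (order respected if unnamed).
#' @return Named character vector mapping cluster index ("1".."3") to
#'   strategy.
#' @export
label_clusters <- function(centroids) {
  stopifnot(nrow(centroids) == 3, ncol(centroids) >= 3)
  m1 <- centroids[, 1]
  m3 <- centroids[, 3]
  top2 <- sort(m1, decreasing = TRUE)[1:2]
  if (top2[1] == top2[2])
    stop("seasonal-overlap centroid tie: label clusters manually")
  res <- which.max(m1)
  rest <- setdiff(1:3, res)
  dual <- rest[which.max(m3[rest])]
  multi <- setdiff(rest, dual)
  out <- character(3)
  out[res] <- "resident"
  out[dual] <- "dual_range_migrant"
  out[multi] <- "multi_range_migrant"
  setNames(out, as.character(1:3))
}
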