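#' Epsilon-graph spatial clustering
#'
#' Partitions agents into clusters by chaining: two agents are linked when
#' their distance is strictly less than `epsilon`, and clusters are the
#' connected components of that graph. This is the density-based (DBSCAN
#' style) cluster definition with the core-point minimum reduced to
#' chaining (DBSCAN with `min_samples = 1` is equivalent); isolated agents
#' form singleton clusters. Ties at exactly `epsilon` are disconnected.
#'
#' @param positions Data frame with columns `x` and `y` (one row per
#'   agent), or a two-column matrix.
#' @param epsilon Linking distance (> 0).
#' @return Integer vector of cluster labels, `1 .. Nc`, contiguous.
#' @examples
#' pts <- data.frame(x = c(0, 0.5, 5, 5.4), y = 0)
#' epsilon_clusters(pts, epsilon = 1)
#' @export
epsilon_clusters <- function(positions, epsilon) {
  stopifnot(epsilon > 0)
  xy <- as.matrix(positions[, c("x", "y")])
  n <- nrow(xy)
  if (n == 1) return(1L)
  adj <- as.matrix(stats::dist(xy)) < epsilon
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

#' Fraction of the group in the largest cluster
#'
#' @param labels Cluster labels from [epsilon_clusters()].
#' @param N Group size; defaults to `length(labels)`.
#' @return Largest cluster size divided by `N`.
#' @export
largest_cluster_fraction <- function(labels, N = length(labels)) {
  max(tabulate(labels)) / N
}

#' Cohesion parameter C and mean cluster count of a trajectory
#'
#' At every post-burn-in snapshot the agents are partitioned into
#' epsilon-clusters; the cohesion parameter C is the time average of the
#' largest-cluster fraction, and `Nc_mean` the time average of the cluster
#' count. C = 1 means the group was a single cluster at every sampled time
#' (never fragmented). Replicate averaging is left to the sweep layer.
#'
#' @param traj A `flock_trajectory` from [simulate_flock()], or a states
#'   data frame with columns `time`, `id`, `x`, `y`.
#' @param epsilon Linking distance; defaults to the trajectory's
#'   `params$epsilon` (must be given for plain data frames).
#' @param burn_fraction Fraction of the horizon discarded as burn-in
#'   (default 0.2; must be < 1).
#' @return A `flock_cohesion` object: list with `C`, `Nc_mean`, `epsilon`,
#'   and `per_time` (tibble `time`, `largest_fraction`, `n_clusters`).
#' @examples
#' traj <- simulate_flock(flock_params(N = 10, K = 5), t_end = 10, seed = 2)
#' glance(cohesion_parameter(traj))
#' @export
cohesion_parameter <- function(traj, epsilon = NULL, burn_fraction = 0.2) {
  if (burn_fraction >= 1) stop("`burn_fraction` must be < 1")
  if (inherits(traj, "flock_trajectory")) {
    if (is.null(epsilon)) epsilon <- traj$params$epsilon
    states <- traj$states
    t_end <- traj$t_end
  } else {
    if (is.null(epsilon)) stop("`epsilon` is required for plain state tables")
    states <- traj
    t_end <- max(states$time)
  }
  t0 <- burn_fraction * t_end
  kept <- dplyr::filter(states, .data$time >= t0 - 1e-9)
  if (nrow(kept) == 0) stop("no post-burn-in samples")
  per_time <- kept |>
    tidyr::nest(.by = "time") |>
    dplyr::mutate(stats = purrr::map(.data$data, function(d) {
      lab <- epsilon_clusters(d, epsilon)
      tibble::tibble(
        largest_fraction = largest_cluster_fraction(lab),
        n_clusters = max(lab)
      )
    })) |>
    dplyr::select("time", "stats") |>
    tidyr::unnest("stats")
  structure(
    list(
      C = mean(per_time$largest_fraction),
      Nc_mean = mean(per_time$n_clusters),
      epsilon = epsilon,
      per_time = per_time
    ),
    class = "flock_cohesion"
  )
}

#' Pooled cluster-size distribution of a trajectory
#'
#' Sizes of every epsilon-cluster at every post-burn-in snapshot; used to
#' characterise break-up (e.g. fragmentation into clusters of size 2-3
#' under nearest-neighbour-only interaction).
#'
#' @inheritParams cohesion_parameter
#' @return Tibble with columns `time`, `cluster`, `size`.
#' @export
cluster_size_distribution <- function(traj, epsilon = NULL,
                                      burn_fraction = 0.2) {
  if (inherits(traj, "flock_trajectory")) {
    if (is.null(epsilon)) epsilon <- traj$params$epsilon
    states <- traj$states
    t_end <- traj$t_end
  } else {
    states <- traj
    t_end <- max(states$time)
  }
  t0 <- burn_fraction * t_end
  states |>
    dplyr::filter(.data$time >= t0 - 1e-9) |>
    dplyr::group_by(.data$time) |>
    dplyr::reframe({
      lab <- epsilon_clusters(dplyr::pick("x", "y"), epsilon)
      sz <- tabulate(lab)
      tibble::tibble(cluster = seq_along(sz), size = sz)
    })
}

#' @export
print.flock_cohesion <- function(x, ...) {
  cat(sprintf(
    "<flock_cohesion> C = %.3f, Nc_mean = %.2f (epsilon = %g, %d snapshots)\n",
    x$C, x$Nc_mean, x$epsilon, nrow(x$per_time)
  ))
  invisible(x)
}

#' @export
tidy.flock_cohesion <- function(x, ...) x$per_time

#' @export
glance.flock_cohesion <- function(x, ...) {
  tibble::tibble(
    C = x$C, Nc_mean = x$Nc_mean, epsilon = x$epsilon,
    n_samples = nrow(x$per_time)
  )
}

#' Alternate cohesion measures of a static configuration
#'
#' The three classical cohesivity summaries: mean nearest-neighbour
#' distance, area of the convex hull of the positions, and mean distance
#' to the group barycenter. The epsilon-cluster cohesion parameter is a
#' more stringent alternative to these.
#'
#' @param positions Data frame with columns `x`, `y`, or two-column matrix.
#' @return Tibble with columns `mean_nnd`, `hull_area`,
#'   `mean_barycenter_dist`. Hull area is 0 for fewer than 3 distinct
#'   points.
#' @export
alternate_metrics <- function(positions) {
  xy <- as.matrix(positions[, c("x", "y")])
  n <- nrow(xy)
  if (n < 2) {
    return(tibble::tibble(mean_nnd = NA_real_, hull_area = 0,
                          mean_barycenter_dist = 0))
  }
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  mean_nnd <- mean(apply(d, 1, min))
  hull_area <- 0
  if (n >= 3) {
    h <- grDevices::chull(xy)
    if (length(h) >= 3) {
      hx <- xy[h, 1]; hy <- xy[h, 2]
      hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    }
  }
  bc <- colMeans(xy)
  mean_bary <- mean(sqrt((xy[, 1] - bc[1])^2 + (xy[, 2] - bc[2])^2))
  tibble::tibble(mean_nnd = mean_nnd, hull_area = hull_area,
                 mean_barycenter_dist = mean_bary)
}
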