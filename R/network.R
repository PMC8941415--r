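#' Natural time window of the attraction network
#'
#' The window length over which attraction interactions are accumulated
#' into one directed graph: `t_w = epsilon / s0`, the time an organism
#' moving at its desired speed needs to break free from its cluster.
#'
#' @param epsilon Cluster-distance scale (length).
#' @param s0 Desired speed (> 0).
#' @return The window length `t_w`.
#' @examples
#' time_window(1, 1)
#' time_window(0.3, 1.5)
#' @export
time_window <- function(epsilon, s0) {
  if (s0 <= 0) stop("`s0` must be positive")
  epsilon / s0
}

#' Windowed attraction adjacency matrix
#'
#' Builds the binary directed adjacency of the attraction interaction
#' network over the window `[t_start, t_start + t_w)`: `A[i, j] = 1` iff
#' some attraction event with focal `i` and partner `j` falls in the
#' window. Alignment and spontaneous-turn events are ignored, edge
#' multiplicity is collapsed to 1, and the diagonal is zero. The graph is
#' directed: `i -> j` does not imply `j -> i`, because each organism
#' randomly and asynchronously chooses whom to move towards.
#'
#' @param events Event data frame (`time`, `focal`, `etype`, `partners`
#'   list-column), as in a `flock_trajectory`.
#' @param t_start Window start time.
#' @param t_w Window length.
#' @param N Group size (ids must lie in `1..N`).
#' @return An `N x N` binary matrix.
#' @export
build_adjacency <- function(events, t_start, t_w, N) {
  A <- matrix(0L, N, N)
  keep <- events$etype == "attract" &
    events$time >= t_start & events$time < t_start + t_w
  foc <- events$focal[keep]
  par <- events$partners[keep]
  for (m in seq_along(foc)) {
    js <- par[[m]]
    if (length(js) == 0) next
    if (any(c(foc[m], js) < 1) || any(c(foc[m], js) > N)) {
      stop("event ids outside 1..N")
    }
    A[foc[m], js] <- 1L
  }
  diag(A) <- 0L
  A
}

#' Directed reachability (transitive closure)
#'
#' `reach[i, j] = 1` iff a directed path of length >= 1 exists from `i`
#' to `j` in the adjacency `A`; the diagonal is set to 1 by convention
#' (every node reaches itself), so singleton sub-groups are well defined.
#'
#' @param A Square binary adjacency matrix with zero diagonal.
#' @return Binary reachability matrix of the same dimension.
#' @export
reachability <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("`A` must be square")
  g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "directed")
  reach <- (igraph::distances(g, mode = "out") < Inf) * 1L
  diag(reach) <- 1L
  reach
}

#' Mutually reachable sub-groups
#'
#' Partitions the nodes into classes of the equivalence
#' `i ~ j <=> reach[i, j] = 1 and reach[j, i] = 1` — the strongly
#' connected components of the interaction graph. Nodes reachable only
#' one way stay in different sub-groups; isolated nodes are singletons.
#'
#' @param reach Reachability matrix from [reachability()].
#' @return Integer membership vector (classes `1 .. n_subgroups`).
#' @examples
#' A <- matrix(0L, 5, 5)
#' A[cbind(c(1, 3, 2, 4, 5, 2), c(3, 2, 1, 5, 4, 4))] <- 1L
#' strongly_connected_subgroups(reachability(A)) # {1,2,3} and {4,5}
#' @export
strongly_connected_subgroups <- function(reach) {
  mutual <- (reach != 0) & (t(reach) != 0)
  diag(mutual) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(mutual, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

#' Network parameter Np from an event log
#'
#' Tiles the post-burn-in span into disjoint consecutive windows of length
#' `t_w = epsilon / s0`; in each window builds the attraction adjacency,
#' its reachability, and the mutually reachable sub-group partition, and
#' records the largest sub-group size normalized by `N`. `Np` is the mean
#' of that fraction over windows (replicate averaging is left to the
#' sweep layer). `Np` close to 1 means attraction interactions knit the
#' whole group together within every window.
#'
#' @param events Event data frame, or a `flock_trajectory`.
#' @param params A [flock_params()] object (ignored when `events` is a
#'   trajectory, whose own parameters are used).
#' @param t_total Total simulated time (ignored for trajectories).
#' @param burn_fraction Fraction of `t_total` discarded before windowing.
#' @return A `flock_network` object: list with `Np`, `t_w`, and
#'   `per_window` (tibble `t_start`, `largest_fraction`, `n_subgroups`).
#' @export
network_parameter <- function(events, params = NULL, t_total = NULL,
                              burn_fraction = 0.2) {
  if (inherits(events, "flock_trajectory")) {
    params <- events$params
    t_total <- events$t_end
    events <- events$events
  }
  stopifnot(!is.null(params), !is.null(t_total))
  t_w <- time_window(params$epsilon, params$s0)
  t0 <- burn_fraction * t_total
  n_win <- floor((t_total - t0) / t_w + 1e-9)
  if (n_win < 1) stop("no complete window after burn-in")
  starts <- t0 + (seq_len(n_win) - 1) * t_w
  per_window <- purrr::map_dfr(starts, function(ts) {
    A <- build_adjacency(events, ts, t_w, params$N)
    part <- strongly_connected_subgroups(reachability(A))
    tibble::tibble(
      t_start = ts,
      largest_fraction = max(tabulate(part)) / params$N,
      n_subgroups = max(part)
    )
  })
  structure(
    list(Np = mean(per_window$largest_fraction), t_w = t_w,
         per_window = per_window),
    class = "flock_network"
  )
}

#' @export
print.flock_network <- function(x, ...) {
  cat(sprintf("<flock_network> Np = %.3f over %d windows of t_w = %g\n",
              x$Np, nrow(x$per_window), x$t_w))
  invisible(x)
}

#' @export
tidy.flock_network <- function(x, ...) x$per_window

#' @export
glance.flock_network <- function(x, ...) {
  tibble::tibble(Np = x$Np, t_w = x$t_w, n_windows = nrow(x$per_window))
}
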