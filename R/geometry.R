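#' Wrap an angle into (-pi, pi]
#'
#' Reduces angles modulo 2*pi to the half-open interval (-pi, pi]. The
#' boundary maps to +pi (so `wrap_angle(3 * pi)` is `pi`, not `-pi`).
#'
#' @param theta Numeric vector of angles in radians; must be finite.
#' @return Numeric vector of the same length, each element in (-pi, pi].
#' @examples
#' wrap_angle(c(0, 3 * pi, -7 * pi / 2))
#' @export
wrap_angle <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta))) {
    stop("`theta` must be finite numeric")
  }
  wrap_fast(theta)
}

# unchecked kernel shared by the hot simulation paths
wrap_fast <- function(theta) {
  r <- theta %% (2 * pi)
  r - 2 * pi * (r > pi)
}

#' Circular mean of a set of headings
#'
#' Angle of the vector sum of the unit vectors `(cos(theta), sin(theta))`.
#' When the resultant length is below `1e-12` (e.g. an antipodal pair) the
#' mean direction is undefined and `NA` is returned; callers decide the
#' fallback (the simulator keeps the current heading).
#'
#' @param headings Non-empty numeric vector of angles (radians).
#' @return A single angle in (-pi, pi], or `NA_real_` when undefined.
#' @examples
#' circular_mean(c(0, pi / 3, -pi / 3))
#' circular_mean(c(pi / 2, -pi / 2)) # NA: zero resultant
#' @export
circular_mean <- function(headings) {
  if (length(headings) == 0) stop("`headings` must be non-empty")
  S <- sum(sin(headings))
  C <- sum(cos(headings))
  if (sqrt(S^2 + C^2) < 1e-12) return(NA_real_)
  wrap_fast(atan2(S, C))
}

# Vector-level kernels used by both the tibble-facing API and the event loop.
# x, y, heading are parallel vectors over all agents; `focal` is an index.

visible_idx <- function(x, y, heading, focal, fov) {
  others <- setdiff(seq_along(x), focal)
  if (length(others) == 0 || fov <= 0) return(integer(0))
  if (fov >= 2 * pi - 1e-12) return(others)
  dx <- x[others] - x[focal]
  dy <- y[others] - y[focal]
  d2 <- dx^2 + dy^2
  bearing <- wrap_fast(atan2(dy, dx) - heading[focal])
  # coincident agents are always visible regardless of bearing
  others[abs(bearing) <= fov / 2 + 1e-12 | d2 == 0]
}

rank_idx <- function(x, y, focal, visible, K) {
  if (length(visible) == 0) return(integer(0))
  d2 <- (x[visible] - x[focal])^2 + (y[visible] - y[focal])^2
  ord <- order(d2, visible) # distance ties broken by ascending id
  visible[ord][seq_len(min(K, length(visible)))]
}

#' Visible neighbours of a focal agent
#'
#' Returns the ids of agents whose bearing from the focal agent lies within
#' its visual field of total angle `fov` centred on its heading. Agents at
#' zero distance from the focal agent are always visible.
#'
#' @param states Data frame with columns `id`, `x`, `y`, `heading` (one row
#'   per agent).
#' @param focal Id of the focal agent (must appear in `states$id`).
#' @param fov Total visual field angle (radians).
#' @return Integer vector of visible ids (unordered).
#' @export
visible_neighbours <- function(states, fov = 2 * pi * (300 / 360), focal) {
  i <- match(focal, states$id)
  if (is.na(i)) stop("`focal` not found in `states$id`")
  idx <- visible_idx(states$x, states$y, states$heading, i, fov)
  states$id[idx]
}

#' Rank visible neighbours topologically
#'
#' Orders a set of visible agents by ascending Euclidean distance from the
#' focal agent and keeps the nearest `K`; distance ties are broken by
#' ascending id so the ranking is deterministic.
#'
#' @inheritParams visible_neighbours
#' @param visible Integer vector of candidate ids (e.g. from
#'   [visible_neighbours()]).
#' @param K Neighbourhood size; at most `K` ids are returned.
#' @return Ordered integer vector of length `min(K, length(visible))`.
#' @export
rank_topological <- function(states, focal, visible, K) {
  stopifnot(K >= 1)
  i <- match(focal, states$id)
  if (is.na(i)) stop("`focal` not found in `states$id`")
  vi <- match(visible, states$id)
  if (anyNA(vi)) stop("`visible` contains ids not in `states$id`")
  states$id[rank_idx(states$x, states$y, i, vi, K)]
}

#' Randomly choose interaction partners from a ranked neighbour list
#'
#' Uniform sample without replacement of `min(k, length(ranked))` ids.
#' This is the stochastic element of neighbour choice: with `k = 1` the
#' focal agent interacts with one uniformly random member of its `K`
#' nearest visible neighbours.
#'
#' @param ranked Ordered id vector (output of [rank_topological()]).
#' @param k Number of partners to draw (`k >= 1`).
#' @return Integer vector of chosen ids (empty when `ranked` is empty).
#' @export
choose_partners <- function(ranked, k) {
  stopifnot(k >= 1)
  n <- length(ranked)
  if (n == 0) return(integer(0))
  m <- min(k, n)
  if (m == n) return(ranked)
  ranked[sample.int(n, m)]
}
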