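#' Model parameters for the agent-based flocking model
#'
#' Constructs and validates the full parameter set of the spatially explicit
#' model. Each of the `N` organisms perceives its `K` nearest neighbours
#' (by topological rank, restricted to its visual field) and, at each
#' behavioural event, interacts with `k` of them chosen uniformly at random.
#' `k = 1` gives the stochastic pairwise interaction; `k = K` gives the
#' Vicsek-like local averaging interaction.
#'
#' Rates are per unit time per agent: alignment events occur at rate `r_p`,
#' attraction events at `r_c`, and spontaneous turns at `r_s`. Setting
#' `minimal = TRUE` selects the minimal point-particle variant: full visual
#' field, collision avoidance off, and speed pinned at `s0`.
#'
#' @param N Group size (integer >= 1).
#' @param K Perceived-neighbourhood size, `1 <= K <= N - 1` (for `N = 1`,
#'   `K` is ignored).
#' @param k Interacting subset size, `1 <= k <= K`.
#' @param r_p,r_c,r_s Alignment, attraction, and spontaneous-turn rates
#'   (1/time); all non-negative. `r_a` is accepted as a synonym for `r_c`.
#' @param s0 Desired speed (length/time).
#' @param sigma_a2 Variance of the circular-normal turn-angle distribution
#'   (rad^2).
#' @param sigma_s2 Variance of the truncated-normal speed distribution
#'   ((length/time)^2).
#' @param fov Total visual field angle in radians. Default 300 degrees,
#'   i.e. a 60 degree blind cone behind the agent.
#' @param d_c Collision-avoidance trigger distance (length).
#' @param avoid_turn_rate Angular speed of avoidance turning (rad/time).
#' @param avoid_slow_factor Multiplicative speed reduction while avoiding,
#'   in (0, 1].
#' @param s_min,s_max Speed clamp bounds, `s_min <= s0 <= s_max`.
#' @param epsilon Cluster-distance scale (length); also the reference
#'   distance of the attraction speed law.
#' @param minimal Logical; use the minimal point-particle variant.
#' @param r_a Synonym for `r_c`; supply at most one of the two.
#'
#' @return An object of class `flock_params` (a validated named list).
#' @examples
#' p <- flock_params(N = 30, K = 10)
#' p$epsilon
#' @export
flock_params <- function(N, K = 1, k = 1,
                         r_p = 1, r_c = 1, r_s = 3,
                         s0 = 1, sigma_a2 = 1, sigma_s2 = 0.01,
                         fov = 2 * pi * (300 / 360), d_c = 0.2,
                         avoid_turn_rate = pi, avoid_slow_factor = 0.5,
                         s_min = 0.1, s_max = 2, epsilon = 2,
                         minimal = FALSE, r_a = NULL) {
  if (!is.null(r_a)) {
    if (!missing(r_c) && !isTRUE(all.equal(r_a, r_c))) {
      stop("supply either `r_c` or its synonym `r_a`, not conflicting values")
    }
    r_c <- r_a
  }
  N <- as.integer(N); K <- as.integer(K); k <- as.integer(k)
  stopifnot(length(N) == 1, N >= 1, length(K) == 1, length(k) == 1)
  if (N > 1 && (K < 1 || K > N - 1)) {
    stop("`K` must satisfy 1 <= K <= N - 1 (got K = ", K, ", N = ", N, ")")
  }
  if (k < 1 || k > K) stop("`k` must satisfy 1 <= k <= K")
  for (nm in c("r_p", "r_c", "r_s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop("`", nm, "` must be a single non-negative finite number")
    }
  }
  stopifnot(
    s0 >= 0, sigma_a2 >= 0, sigma_s2 >= 0,
    fov > 0, fov <= 2 * pi + 1e-12,
    d_c >= 0, avoid_turn_rate >= 0,
    avoid_slow_factor > 0, avoid_slow_factor <= 1,
    s_min >= 0, s_min <= s0, s0 <= s_max,
    epsilon > 0
  )
  if (isTRUE(minimal)) {
    # point-particle variant: omnidirectional perception, no avoidance,
    # speed held at s0
    fov <- 2 * pi
    s_min <- s0
    s_max <- s0
    sigma_s2 <- 0
  }
  structure(
    list(
      N = N, K = K, k = k, r_p = r_p, r_c = r_c, r_s = r_s,
      s0 = s0, sigma_a2 = sigma_a2, sigma_s2 = sigma_s2,
      fov = fov, d_c = d_c, avoid_turn_rate = avoid_turn_rate,
      avoid_slow_factor = avoid_slow_factor,
      s_min = s_min, s_max = s_max, epsilon = epsilon,
      minimal = isTRUE(minimal)
    ),
    class = "flock_params"
  )
}

#' @export
print.flock_params <- function(x, ...) {
  mode <- if (x$k == 1) "stochastic pairwise (k = 1)" else
    if (x$k == x$K) "local averaging (k = K)" else
      sprintf("explicit k = %d", x$k)
  cat(sprintf(
    "<flock_params> N = %d, K = %d, %s%s\n", x$N, x$K, mode,
    if (x$minimal) ", minimal variant" else ""
  ))
  cat(sprintf(
    "  rates r_p = %g, r_c = %g, r_s = %g; s0 = %g in [%g, %g]; epsilon = %g\n",
    x$r_p, x$r_c, x$r_s, x$s0, x$s_min, x$s_max, x$epsilon
  ))
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
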