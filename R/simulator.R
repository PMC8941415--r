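#' Draw the next behavioural event
#'
#' Global Gillespie construction of the asynchronous update schedule: the
#' waiting time to the next event is exponential with total propensity
#' `Lambda = N * (r_p + r_c + r_s)`, the focal agent is uniform over the
#' group, and the event type is drawn with probabilities proportional to
#' the per-agent rates. Equivalent to independent exponential clocks per
#' agent and behaviour; every event involves exactly one focal agent at a
#' unique time.
#'
#' @param params A [flock_params()] object.
#' @return A list with elements `dt` (waiting time), `focal` (agent id) and
#'   `etype` (one of `"align"`, `"attract"`, `"turn"`).
#' @examples
#' set.seed(1)
#' sample_next_event(flock_params(N = 10, K = 3))
#' @export
sample_next_event <- function(params) {
  rates <- c(align = params$r_p, attract = params$r_c, turn = params$r_s)
  total <- sum(rates)
  if (total <= 0) stop("all behavioural rates are zero: no dynamics")
  list(
    dt = stats::rexp(1, rate = params$N * total),
    focal = sample.int(params$N, 1),
    etype = names(rates)[sample.int(3, 1, prob = rates / total)]
  )
}

# --- behavioural kernels on the vector state (x, y, s, th) ----------------

kernel_align <- function(st, focal, partners, p) {
  if (length(partners) == 0) return(st)
  if (length(partners) == 1) {
    st$th[focal] <- st$th[partners]
    if (!p$minimal) st$s[focal] <- st$s[partners]
  } else {
    mu <- circular_mean(st$th[partners])
    if (!is.na(mu)) st$th[focal] <- mu
    if (!p$minimal) {
      st$s[focal] <- clamp(mean(st$s[partners]), p$s_min, p$s_max)
    }
  }
  st
}

kernel_attract <- function(st, focal, partners, p) {
  if (length(partners) == 0) return(st)
  cx <- mean(st$x[partners])
  cy <- mean(st$y[partners])
  dx <- cx - st$x[focal]
  dy <- cy - st$y[focal]
  d <- sqrt(dx^2 + dy^2)
  if (d > 1e-9) {
    st$th[focal] <- atan2(dy, dx)
    st$s[focal] <- if (p$minimal) p$s0 else clamp(p$s0 * d / p$epsilon, p$s_min, p$s_max)
  } else {
    # focal already at the partners' centroid: keep heading, cruise at s0
    st$s[focal] <- p$s0
  }
  st
}

kernel_turn <- function(st, focal, p) {
  if (p$sigma_a2 > 0) {
    st$th[focal] <- wrap_fast(st$th[focal] + stats::rnorm(1, 0, sqrt(p$sigma_a2)))
  }
  if (p$minimal || p$sigma_s2 == 0) {
    st$s[focal] <- p$s0
  } else {
    repeat {
      s_new <- stats::rnorm(1, p$s0, sqrt(p$sigma_s2))
      if (s_new >= p$s_min && s_new <= p$s_max) break
    }
    st$s[focal] <- s_new
  }
  st
}

# one avoidance micro-step; also reports the smallest inter-agent distance
# so the caller can skip distance checks while no pair can possibly be
# within d_c (closing speed is bounded by 2 * s_max)
avoid_step <- function(st, p, dt) {
  n <- length(st$x)
  if (n < 2 || p$d_c <= 0) return(list(st = st, min_d = Inf))
  dxm <- matrix(st$x, n, n, byrow = TRUE) - st$x
  dym <- matrix(st$y, n, n, byrow = TRUE) - st$y
  d2 <- dxm * dxm + dym * dym
  d2[seq.int(1L, n * n, by = n + 1L)] <- Inf
  nearest <- max.col(-d2, ties.method = "first")
  d2near <- d2[seq_len(n) + (nearest - 1L) * n]
  min_d <- sqrt(min(d2near))
  hit <- which(d2near < p$d_c^2)
  if (length(hit) == 0) return(list(st = st, min_d = min_d))
  max_turn <- p$avoid_turn_rate * dt
  j <- nearest[hit]
  away <- atan2(st$y[hit] - st$y[j], st$x[hit] - st$x[j])
  delta <- wrap_fast(away - st$th[hit])
  turn <- sign(delta) * pmin(max_turn, abs(delta))
  # coincident offender: deterministic counter-clockwise escape turn
  turn[d2near[hit] == 0] <- max_turn
  st$th[hit] <- wrap_fast(st$th[hit] + turn)
  st$s[hit] <- pmax(p$s_min, st$s[hit] * p$avoid_slow_factor)
  list(st = st, min_d = min_d)
}

kernel_avoid <- function(st, p, dt) avoid_step(st, p, dt)$st

kernel_advance <- function(st, dt) {
  st$x <- st$x + st$s * cos(st$th) * dt
  st$y <- st$y + st$s * sin(st$th) * dt
  st
}

# --- tibble-facing single-step operations ---------------------------------

as_state <- function(states) {
  list(x = states$x, y = states$y, s = states$speed, th = states$heading)
}

from_state <- function(st, states) {
  states$x <- st$x
  states$y <- st$y
  states$speed <- st$s
  states$heading <- st$th
  states
}

#' Apply one behavioural rule to a focal agent
#'
#' `apply_alignment()` makes the focal agent copy its partners: with one
#' partner the heading and speed are copied exactly; with several, the
#' heading becomes the circular mean of the partners' headings (kept
#' unchanged when the mean is undefined) and the speed the arithmetic mean
#' of their speeds, clamped to `[s_min, s_max]`. `apply_attraction()` turns
#' the focal agent towards the centroid of its partners and sets its speed
#' to `s0 * d / epsilon` (clamped), where `d` is the distance to the
#' centroid; an agent already at the centroid keeps its heading and cruises
#' at `s0`. With no partners both rules are no-ops.
#'
#' @param states Agent data frame (`id`, `x`, `y`, `speed`, `heading`).
#' @param focal Focal agent id.
#' @param partners Integer vector of partner ids (possibly empty).
#' @param params A [flock_params()] object.
#' @return The updated `states` data frame.
#' @export
apply_alignment <- function(states, focal, partners, params) {
  i <- match(focal, states$id)
  pj <- match(partners, states$id)
  from_state(kernel_align(as_state(states), i, pj, params), states)
}

#' @rdname apply_alignment
#' @export
apply_attraction <- function(states, focal, partners, params) {
  i <- match(focal, states$id)
  pj <- match(partners, states$id)
  from_state(kernel_attract(as_state(states), i, pj, params), states)
}

#' Spontaneous turn of a single agent
#'
#' Draws a new heading from a wrapped normal centred on the current heading
#' with variance `sigma_a2`, and a new speed from a normal with mean `s0`
#' and variance `sigma_s2`, redrawn until it falls in `[s_min, s_max]`.
#' In the minimal variant the speed stays at `s0`.
#'
#' @inheritParams apply_alignment
#' @return The updated `states` data frame.
#' @export
apply_spontaneous_turn <- function(states, focal, params) {
  i <- match(focal, states$id)
  from_state(kernel_turn(as_state(states), i, params), states)
}

#' Collision avoidance over one micro-step
#'
#' Every agent with at least one other agent closer than `d_c` rotates its
#' heading towards the direction pointing directly away from its nearest
#' offender, by at most `avoid_turn_rate * dt`, and has its speed multiplied
#' by `avoid_slow_factor` (floored at `s_min`). Coincident agents turn
#' counter-clockwise. Applied continuously during motion, not as a scheduled
#' event; never invoked in the minimal variant.
#'
#' @inheritParams apply_alignment
#' @param dt Micro-step duration (> 0).
#' @return The updated `states` data frame.
#' @export
apply_collision_avoidance <- function(states, params, dt) {
  stopifnot(dt > 0)
  from_state(kernel_avoid(as_state(states), params, dt), states)
}

#' Ballistic position update
#'
#' Moves every agent along its heading at its current speed for time `dt`
#' (`x <- x + s * e * dt`); speeds and headings are untouched.
#'
#' @inheritParams apply_alignment
#' @param dt Duration (>= 0).
#' @return The updated `states` data frame.
#' @export
advance_positions <- function(states, dt) {
  if (dt < 0) stop("`dt` must be non-negative")
  from_state(kernel_advance(as_state(states), dt), states)
}

#' Run one realization of the agent-based model
#'
#' Event loop: waiting times, focal agents and event types are drawn by the
#' Gillespie scheduler; between events the world advances ballistically in
#' micro-steps of `micro_dt` with collision avoidance applied at each
#' micro-step; at each event time the focal agent's visible neighbours are
#' ranked by distance, `k` partners are drawn uniformly from the nearest
#' `K`, and the behavioural rule is applied. Snapshots of all agent states
#' are recorded on the regular `sample_dt` grid, and every event is logged
#' with its time, focal agent, type and partner set (empty when no visible
#' neighbour existed). Fully reproducible from `seed`.
#'
#' Unless `init` is given, agents start uniformly in a disc of radius
#' `epsilon * sqrt(N)` (so initial density is independent of `N`), with
#' uniform headings and speed `s0`.
#'
#' @param params A [flock_params()] object.
#' @param t_end Simulation horizon (> 0).
#' @param sample_dt Snapshot spacing (default 0.5).
#' @param seed Integer seed for the realization's RNG stream.
#' @param init Optional initial states data frame (`id`, `x`, `y`, `speed`,
#'   `heading`).
#' @param micro_dt Micro-step for motion and avoidance; default
#'   `min(0.01, epsilon / (10 * s_max))`.
#' @return A `flock_trajectory`: list with `states` (tibble `time`, `id`,
#'   `x`, `y`, `speed`, `heading`), `events` (tibble `time`, `focal`,
#'   `etype`, `partners` list-column), `params`, `t_end`, `sample_dt`,
#'   `seed`.
#' @examples
#' traj <- simulate_flock(flock_params(N = 5, K = 2), t_end = 5, seed = 1)
#' dplyr::count(traj$events, etype)
#' @export
simulate_flock <- function(params, t_end, sample_dt = 0.5, seed = 1L,
                           init = NULL, micro_dt = NULL) {
  stopifnot(inherits(params, "flock_params"), t_end > 0, sample_dt > 0)
  p <- params
  if (is.null(micro_dt)) micro_dt <- min(0.01, p$epsilon / (10 * p$s_max))
  set.seed(as.integer(seed))

  if (is.null(init)) {
    r <- p$epsilon * sqrt(p$N) * sqrt(stats::runif(p$N))
    ang <- stats::runif(p$N, -pi, pi)
    st <- list(
      x = r * cos(ang), y = r * sin(ang),
      s = rep(p$s0, p$N), th = stats::runif(p$N, -pi, pi)
    )
  } else {
    stopifnot(nrow(init) == p$N)
    init <- init[order(init$id), ]
    st <- list(x = init$x, y = init$y, s = init$speed, th = init$heading)
  }

  sample_times <- seq(0, t_end, by = sample_dt)
  n_samp <- length(sample_times)
  snap_x <- matrix(NA_real_, n_samp, p$N)
  snap_y <- matrix(NA_real_, n_samp, p$N)
  snap_s <- matrix(NA_real_, n_samp, p$N)
  snap_th <- matrix(NA_real_, n_samp, p$N)
  record <- function(i) {
    snap_x[i, ] <<- st$x; snap_y[i, ] <<- st$y
    snap_s[i, ] <<- st$s; snap_th[i, ] <<- st$th
  }
  record(1)
  next_samp <- 2L

  ev_cap <- 1024L
  ev_t <- numeric(ev_cap); ev_f <- integer(ev_cap)
  ev_e <- character(ev_cap); ev_p <- vector("list", ev_cap)
  n_ev <- 0L

  t_now <- 0
  rates_on <- (p$r_p + p$r_c + p$r_s) > 0

  safe_steps <- 0L
  advance_to <- function(t_target) {
    while (t_now < t_target - 1e-12) {
      step <- min(micro_dt, t_target - t_now)
      if (next_samp <= n_samp) {
        step <- min(step, sample_times[next_samp] - t_now)
      }
      st <<- kernel_advance(st, step)
      if (!p$minimal) {
        if (safe_steps > 0L) {
          safe_steps <<- safe_steps - 1L
        } else {
          res <- avoid_step(st, p, step)
          st <<- res$st
          gap <- res$min_d - p$d_c
          if (gap > 0) {
            safe_steps <<- as.integer(
              min(gap %/% (2 * p$s_max * micro_dt), 1e9)
            )
          }
        }
      }
      t_now <<- t_now + step
      while (next_samp <= n_samp && t_now >= sample_times[next_samp] - 1e-9) {
        record(next_samp)
        next_samp <<- next_samp + 1L
      }
    }
  }

  while (rates_on) {
    ev <- sample_next_event(p)
    t_ev <- t_now + ev$dt
    if (t_ev > t_end) break
    advance_to(t_ev)
    t_now <- t_ev
    partners <- integer(0)
    if (ev$etype == "turn") {
      st <- kernel_turn(st, ev$focal, p)
    } else {
      vis <- visible_idx(st$x, st$y, st$th, ev$focal, p$fov)
      ranked <- rank_idx(st$x, st$y, ev$focal, vis, p$K)
      partners <- choose_partners(ranked, p$k)
      st <- if (ev$etype == "align") {
        kernel_align(st, ev$focal, partners, p)
      } else {
        kernel_attract(st, ev$focal, partners, p)
      }
    }
    n_ev <- n_ev + 1L
    if (n_ev > ev_cap) {
      ev_cap <- ev_cap * 2L
      length(ev_t) <- ev_cap; length(ev_f) <- ev_cap
      length(ev_e) <- ev_cap; length(ev_p) <- ev_cap
    }
    ev_t[n_ev] <- t_ev; ev_f[n_ev] <- ev$focal
    ev_e[n_ev] <- ev$etype; ev_p[[n_ev]] <- partners
  }
  advance_to(t_end)
  while (next_samp <= n_samp) { # guard against floating-point shortfall
    record(next_samp)
    next_samp <- next_samp + 1L
  }

  states <- tibble::tibble(
    time = rep(sample_times, each = p$N),
    id = rep(seq_len(p$N), times = n_samp),
    x = as.vector(t(snap_x)),
    y = as.vector(t(snap_y)),
    speed = as.vector(t(snap_s)),
    heading = as.vector(t(snap_th))
  )
  events <- tibble::tibble(
    time = ev_t[seq_len(n_ev)],
    focal = ev_f[seq_len(n_ev)],
    etype = ev_e[seq_len(n_ev)],
    partners = ev_p[seq_len(n_ev)]
  )
  structure(
    list(states = states, events = events, params = p,
         t_end = t_end, sample_dt = sample_dt, seed = as.integer(seed)),
    class = "flock_trajectory"
  )
}

#' @export
print.flock_trajectory <- function(x, ...) {
  cat(sprintf(
    "<flock_trajectory> N = %d, t_end = %g, %d snapshots, %d events (seed %d)\n",
    x$params$N, x$t_end, length(unique(x$states$time)), nrow(x$events), x$seed
  ))
  invisible(x)
}

#' @export
tidy.flock_trajectory <- function(x, ...) x$states

#' @export
glance.flock_trajectory <- function(x, ...) {
  tibble::tibble(
    N = x$params$N, K = x$params$K, k = x$params$k,
    t_end = x$t_end, n_snapshots = length(unique(x$states$time)),
    n_events = nrow(x$events), seed = x$seed
  )
}
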