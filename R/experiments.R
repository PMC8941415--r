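config_defaults <- function() {
  list(
    N_list = 30L, K_list = NULL, k_mode = "pairwise", k = NA_integer_,
    t_end = 200, sample_dt = 0.5, replicates = 10L, base_seed = 1L,
    burn_fraction = 0.2, output_dir = ".",
    r_p = 1, r_c = 1, r_s = 3, s0 = 1, sigma_a2 = 1, sigma_s2 = 0.01,
    fov = 2 * pi * (300 / 360), d_c = 0.2, avoid_turn_rate = pi,
    avoid_slow_factor = 0.5, s_min = 0.1, s_max = 2, epsilon = 2,
    minimal = FALSE
  )
}

#' Build or load a sweep configuration
#'
#' `flock_config()` assembles and validates an experiment configuration
#' from named values; `load_config()` reads one from a flat YAML file.
#' Unknown keys are an error (typo safety), missing keys take the model's
#' default parameter set. `k_mode` is one of `"pairwise"` (`k = 1`),
#' `"averaging"` (`k = K`) or `"explicit"` (supply `k`).
#'
#' @param ... Named configuration values (see [flock_params()] plus
#'   `N_list`, `K_list`, `k_mode`, `k`, `t_end`, `sample_dt`,
#'   `replicates`, `base_seed`, `burn_fraction`, `output_dir`).
#' @return An `experiment_config` (validated named list).
#' @examples
#' cfg <- flock_config(N_list = 10, K_list = c(1, 3), replicates = 2,
#'                     t_end = 10)
#' @export
flock_config <- function(...) {
  user <- list(...)
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, user)
  if (is.null(cfg$K_list)) stop("`K_list` is required")
  cfg$N_list <- as.integer(cfg$N_list)
  cfg$K_list <- as.integer(cfg$K_list)
  cfg$replicates <- as.integer(cfg$replicates)
  cfg$base_seed <- as.integer(cfg$base_seed)
  if (cfg$replicates < 1) stop("`replicates` must be >= 1")
  if (!cfg$k_mode %in% c("pairwise", "averaging", "explicit")) {
    stop("`k_mode` must be one of pairwise, averaging, explicit")
  }
  if (is.null(cfg$k)) cfg$k <- NA_integer_
  cfg$k <- as.integer(cfg$k)
  if (cfg$k_mode == "explicit" && is.na(cfg$k)) {
    stop("`k` is required when k_mode = 'explicit'")
  }
  for (N in cfg$N_list) {
    if (any(cfg$K_list > N - 1)) {
      stop("every K must satisfy K <= N - 1 (violated for N = ", N, ")")
    }
  }
  # instantiating the params validates the model-level invariants
  flock_params(
    N = max(cfg$N_list), K = 1, k = 1, r_p = cfg$r_p, r_c = cfg$r_c,
    r_s = cfg$r_s, s0 = cfg$s0, sigma_a2 = cfg$sigma_a2,
    sigma_s2 = cfg$sigma_s2, fov = cfg$fov, d_c = cfg$d_c,
    avoid_turn_rate = cfg$avoid_turn_rate,
    avoid_slow_factor = cfg$avoid_slow_factor, s_min = cfg$s_min,
    s_max = cfg$s_max, epsilon = cfg$epsilon, minimal = cfg$minimal
  )
  structure(cfg, class = "experiment_config")
}

#' @rdname flock_config
#' @param path Path to a YAML file with flat keys.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must contain a YAML mapping")
  do.call(flock_config, vals)
}

#' Write a configuration to YAML
#'
#' @param config An `experiment_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

params_for <- function(cfg, N, K) {
  k <- switch(cfg$k_mode, pairwise = 1L, averaging = K, explicit = cfg$k)
  flock_params(
    N = N, K = K, k = min(k, K), r_p = cfg$r_p, r_c = cfg$r_c,
    r_s = cfg$r_s, s0 = cfg$s0, sigma_a2 = cfg$sigma_a2,
    sigma_s2 = cfg$sigma_s2, fov = cfg$fov, d_c = cfg$d_c,
    avoid_turn_rate = cfg$avoid_turn_rate,
    avoid_slow_factor = cfg$avoid_slow_factor, s_min = cfg$s_min,
    s_max = cfg$s_max, epsilon = cfg$epsilon, minimal = cfg$minimal
  )
}

#' Run a replicate sweep over group and neighbourhood sizes
#'
#' For every combination of `N` in `N_list`, `K` in `K_list` and
#' replicate, runs one realization of the model (seeded
#' `base_seed + replicate - 1` so the whole sweep is a pure function of
#' the configuration), then computes the cohesion parameter C, the mean
#' cluster count Nc, and the network parameter Np. Replicate averaging is
#' done by [summarise_sweep()].
#'
#' @param config An `experiment_config` from [flock_config()] or
#'   [load_config()].
#' @param .progress Print a line per completed cell.
#' @return A `flock_sweep` tibble with one row per
#'   `(N, K, k_mode, replicate)` and columns `C`, `Nc_mean`, `Np`, `seed`.
#' @export
run_sweep <- function(config, .progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  grid <- tidyr::expand_grid(
    N = config$N_list, K = config$K_list,
    replicate = seq_len(config$replicates)
  )
  rows <- purrr::pmap(grid, function(N, K, replicate) {
    p <- params_for(config, N, K)
    seed <- config$base_seed + replicate - 1L
    traj <- simulate_flock(p, t_end = config$t_end,
                           sample_dt = config$sample_dt, seed = seed)
    coh <- cohesion_parameter(traj, burn_fraction = config$burn_fraction)
    net <- network_parameter(traj, burn_fraction = config$burn_fraction)
    if (.progress) {
      message(sprintf("N=%d K=%d rep=%d: C=%.3f Np=%.3f",
                      N, K, replicate, coh$C, net$Np))
    }
    tibble::tibble(
      N = N, K = K, k_mode = config$k_mode, replicate = replicate,
      seed = seed, C = coh$C, Nc_mean = coh$Nc_mean, Np = net$Np
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("flock_sweep", class(out))
  attr(out, "config") <- config
  out
}

#' Replicate-averaged sweep summary
#'
#' Means and standard errors of C, Nc and Np over replicates for each
#' `(N, K, k_mode)` cell.
#'
#' @param sweep A `flock_sweep` from [run_sweep()].
#' @return Tibble with columns `N`, `K`, `k_mode`, `n_rep`, `C`, `C_se`,
#'   `Nc_mean`, `Nc_se`, `Np`, `Np_se`.
#' @export
summarise_sweep <- function(sweep) {
  se <- function(v) stats::sd(v) / sqrt(length(v))
  sweep |>
    dplyr::group_by(.data$N, .data$K, .data$k_mode) |>
    dplyr::summarise(
      n_rep = dplyr::n(),
      C_se = se(.data$C), C = mean(.data$C),
      Nc_se = se(.data$Nc_mean), Nc_mean = mean(.data$Nc_mean),
      Np_se = se(.data$Np), Np = mean(.data$Np),
      .groups = "drop"
    ) |>
    dplyr::select("N", "K", "k_mode", "n_rep", "C", "C_se",
                  "Nc_mean", "Nc_se", "Np", "Np_se")
}

#' Estimate the cohesion saturation threshold K*/N
#'
#' Operationalizes "cohesion saturates": the smallest `K/N` at which the
#' replicate-averaged cohesion curve reaches `factor` (default 0.95) of
#' its value at `K = N - 1`, with linear interpolation between sampled
#' `K`. Returns `NA` when the curve never reaches the target.
#'
#' @param summary A replicate-averaged table (from [summarise_sweep()], or
#'   any data frame with columns `N`, `K`, `C`) containing a C-vs-K curve
#'   for group size `N` that includes `K = N - 1`.
#' @param N Group size whose curve to use.
#' @param factor Saturation fraction of the plateau value (default 0.95).
#' @return The threshold ratio `K*/N`, or `NA_real_` ("no saturation").
#' @export
estimate_saturation_threshold <- function(summary, N, factor = 0.95) {
  curve <- summary[summary$N == N, c("K", "C")]
  curve <- curve[order(curve$K), ]
  if (nrow(curve) < 2) stop("need a C-vs-K curve with at least 2 points")
  if (!(N - 1) %in% curve$K) stop("curve must include K = N - 1")
  target <- factor * curve$C[curve$K == N - 1]
  above <- which(curve$C >= target)
  if (length(above) == 0) return(NA_real_)
  i <- above[1]
  if (i == 1) return(curve$K[1] / N)
  K_lo <- curve$K[i - 1]; K_hi <- curve$K[i]
  C_lo <- curve$C[i - 1]; C_hi <- curve$C[i]
  K_star <- K_lo + (target - C_lo) / (C_hi - C_lo) * (K_hi - K_lo)
  K_star / N
}

#' Deterministic fixtures for analysis-stage testing
#'
#' Generates agent configurations and synthetic event logs with known
#' ground truth, so every analysis stage can be exercised without running
#' the simulator.
#'
#' Kinds:
#' * `"line"`: `n` agents on the x-axis at spacing `spacing`.
#' * `"two_blobs"`: two tight groups of `n1` and `n2` agents with centres
#'   `gap` apart.
#' * `"ring"`: `n` agents equally spaced on a circle of radius `radius`.
#' * `"event_log_cycle"`: attraction events forming a full directed cycle
#'   `1 -> 2 -> ... -> n -> 1` inside each of `n_windows` windows of
#'   length `t_w` (per-window Np = 1 by construction).
#' * `"event_log_halves"`: attraction cycles confined to the two halves
#'   of the group in every window (per-window largest sub-group = n/2).
#'
#' @param kind Fixture kind (see above).
#' @param n,n1,n2 Agent counts.
#' @param spacing,gap,radius Geometry (length units).
#' @param speed,heading State values given to every agent.
#' @param t_w,n_windows Event-log window length and count.
#' @return A states tibble (`id`, `x`, `y`, `speed`, `heading`) or an
#'   events tibble (`time`, `focal`, `etype`, `partners`).
#' @examples
#' make_fixture("line", n = 10, spacing = 0.9)
#' @export
make_fixture <- function(kind, n = 10, spacing = 0.9, n1 = 5, n2 = 5,
                         gap = 10, radius = 1, speed = 1, heading = 0,
                         t_w = 1, n_windows = 5) {
  states <- function(x, y) {
    tibble::tibble(id = seq_along(x), x = x, y = y,
                   speed = speed, heading = heading)
  }
  cycle_events <- function(ids, t0, t_w) {
    nn <- length(ids)
    tibble::tibble(
      time = t0 + t_w * (seq_len(nn) - 0.5) / nn,
      focal = ids,
      etype = "attract",
      partners = as.list(ids[c(seq_len(nn)[-1], 1)])
    )
  }
  switch(kind,
    line = states(x = (seq_len(n) - 1) * spacing, y = rep(0, n)),
    two_blobs = {
      ang1 <- 2 * pi * (seq_len(n1) - 1) / n1
      ang2 <- 2 * pi * (seq_len(n2) - 1) / n2
      states(
        x = c(0.1 * cos(ang1), gap + 0.1 * cos(ang2)),
        y = c(0.1 * sin(ang1), 0.1 * sin(ang2))
      )
    },
    ring = {
      ang <- 2 * pi * (seq_len(n) - 1) / n
      states(x = radius * cos(ang), y = radius * sin(ang))
    },
    event_log_cycle = purrr::map_dfr(
      seq_len(n_windows) - 1,
      function(w) cycle_events(seq_len(n), w * t_w, t_w)
    ),
    event_log_halves = {
      half <- n %/% 2
      purrr::map_dfr(seq_len(n_windows) - 1, function(w) {
        dplyr::bind_rows(
          cycle_events(seq_len(half), w * t_w, t_w / 2),
          cycle_events(half + seq_len(n - half), w * t_w + t_w / 2, t_w / 2)
        )
      })
    },
    stop("unknown fixture kind: ", kind)
  )
}

#' Build a static trajectory from a fixture configuration
#'
#' Repeats one agent configuration over a regular time grid with an empty
#' event log — a trajectory in which nothing moves, useful as ground
#' truth for the cohesion statistics (e.g. an always-cohesive group).
#'
#' @param states States tibble (e.g. from [make_fixture()]).
#' @param t_end Horizon; snapshots at `seq(0, t_end, by = sample_dt)`.
#' @param sample_dt Snapshot spacing.
#' @param params Optional [flock_params()]; defaults to a minimal set
#'   matching the fixture size.
#' @return A `flock_trajectory`.
#' @export
static_trajectory <- function(states, t_end, sample_dt = 1,
                              params = NULL) {
  n <- nrow(states)
  if (is.null(params)) {
    params <- flock_params(N = n, K = max(1L, min(3L, n - 1L)))
  }
  times <- seq(0, t_end, by = sample_dt)
  snap <- tidyr::expand_grid(time = times, states)
  structure(
    list(
      states = dplyr::select(snap, "time", "id", "x", "y", "speed", "heading"),
      events = tibble::tibble(time = numeric(0), focal = integer(0),
                              etype = character(0), partners = list()),
      params = params, t_end = t_end, sample_dt = sample_dt, seed = NA_integer_
    ),
    class = "flock_trajectory"
  )
}
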