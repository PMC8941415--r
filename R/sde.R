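#' Parameters of the mean-field polarization SDEs
#'
#' The polarization order parameter `m` (scalar, in `[-1, 1]`) obeys one
#' of two Langevin equations depending on the interaction type:
#'
#' * pairwise copying:  `dm/dt = -a m + g(m) eta(t)`
#' * higher-order (averaging, rate `h`):
#'   `dm/dt = -a m + h (1 - m^2) m + g(m) eta(t)`
#'
#' with multiplicative noise amplitude
#' `g(m) = sqrt((c_eff (1 - m^2) + a) / N)` where `c_eff = c` for the
#' pairwise model and `c + h` for the higher-order one. In the pairwise
#' model order is noise-induced (the drift is purely relaxing); the
#' higher-order drift has stable fixed points at
#' `m = +/- sqrt(1 - a/h)` when `h > a` and can hold the system ordered
#' deterministically. Fluctuations vanish as `N -> Inf`.
#'
#' @param a Spontaneous (random-turn) rate (1/time).
#' @param c Pairwise copy rate (1/time).
#' @param h Higher-order interaction rate (1/time); 0 in the pairwise
#'   model.
#' @param N Group size (>= 2); scales the noise as `1/sqrt(N)`.
#' @param dt Euler-Maruyama step (default 1e-3).
#' @param m0 Initial order parameter in `[-1, 1]`.
#' @return An `sde_params` object.
#' @export
sde_params <- function(a, c = 0, h = 0, N, dt = 1e-3, m0 = 0) {
  stopifnot(a >= 0, c >= 0, h >= 0, N >= 2, dt > 0, abs(m0) <= 1)
  structure(list(a = a, c = c, h = h, N = as.integer(N), dt = dt, m0 = m0),
            class = "sde_params")
}

#' Drift of the polarization SDE
#'
#' @param m Order parameter value(s), `|m| <= 1`.
#' @param params An [sde_params()] object.
#' @param model `"pairwise"` or `"higher"`.
#' @return Deterministic drift `dm/dt` at `m`.
#' @export
sde_drift <- function(m, params, model = c("pairwise", "higher")) {
  model <- match.arg(model)
  if (any(abs(m) > 1 + 1e-12)) stop("`m` must lie in [-1, 1]")
  switch(model,
    pairwise = -params$a * m,
    higher = -params$a * m + params$h * (1 - m^2) * m
  )
}

#' Noise amplitude of the polarization SDE
#'
#' `sqrt((c_eff (1 - m^2) + a) / N)` with `c_eff = c` (pairwise) or
#' `c + h` (higher). The `radicand` argument switches to the alternative
#' reading `(1 - |m|)^2` of the multiplicative factor so the two
#' interpretations can be compared.
#'
#' @inheritParams sde_drift
#' @param radicand `"one_minus_m2"` (default) or `"one_minus_abs_m_sq"`.
#' @return Noise amplitude (>= 0), strictly positive when `a > 0`.
#' @export
sde_diffusion <- function(m, params, model = c("pairwise", "higher"),
                          radicand = c("one_minus_m2", "one_minus_abs_m_sq")) {
  model <- match.arg(model)
  radicand <- match.arg(radicand)
  if (any(abs(m) > 1 + 1e-12)) stop("`m` must lie in [-1, 1]")
  c_eff <- if (model == "pairwise") params$c else params$c + params$h
  fac <- if (radicand == "one_minus_m2") 1 - m^2 else (1 - abs(m))^2
  rad <- (c_eff * fac + params$a) / params$N
  if (any(rad < 0)) stop("negative radicand")
  sqrt(rad)
}

#' Euler-Maruyama integration of the polarization SDE
#'
#' `m <- m + drift * dt + diffusion * sqrt(dt) * z` with standard normal
#' `z`, clamped to `[-1, 1]` after every step. Reproducible from `seed`.
#' A warning is issued when `dt` is large relative to the fastest rate
#' (stability heuristic `dt >= 1 / (2 (a + c + h))`).
#'
#' @param params An [sde_params()] object.
#' @param t_end Integration horizon (> 0).
#' @param model `"pairwise"` or `"higher"`.
#' @param seed Integer RNG seed.
#' @param noise Set `FALSE` to integrate the deterministic drift only.
#' @param record_every Record every this-many steps (thinning; default 1).
#' @param radicand Passed to [sde_diffusion()].
#' @return An `sde_trace`: list with `times`, `m` (clamped), `params`,
#'   `model`, `seed`.
#' @examples
#' tr <- simulate_sde(sde_params(a = 1, c = 1, N = 50), t_end = 10, seed = 1)
#' glance(tr)
#' @export
simulate_sde <- function(params, t_end, model = c("pairwise", "higher"),
                         seed = 1L, noise = TRUE, record_every = 1L,
                         radicand = "one_minus_m2") {
  model <- match.arg(model)
  stopifnot(inherits(params, "sde_params"), t_end > 0, record_every >= 1)
  rate_sum <- params$a + params$c + params$h
  if (rate_sum > 0 && params$dt >= 1 / (2 * rate_sum)) {
    warning("`dt` is large relative to the rates; integration may be unstable")
  }
  set.seed(as.integer(seed))
  n_steps <- ceiling(t_end / params$dt)
  c_eff <- if (model == "pairwise") params$c else params$c + params$h
  use_m2 <- identical(radicand, "one_minus_m2")
  a <- params$a; h <- params$h; N <- params$N; dt <- params$dt
  sq_dt <- sqrt(dt)
  higher <- model == "higher"
  z <- if (noise) stats::rnorm(n_steps) else numeric(n_steps)

  rec_idx <- seq(record_every, n_steps, by = record_every)
  out <- numeric(length(rec_idx) + 1)
  out[1] <- params$m0
  m <- params$m0
  r <- 1L
  next_rec <- rec_idx[1]
  for (i in seq_len(n_steps)) {
    drift <- if (higher) -a * m + h * (1 - m^2) * m else -a * m
    fac <- if (use_m2) 1 - m^2 else (1 - abs(m))^2
    g <- sqrt((c_eff * fac + a) / N)
    m <- m + drift * dt + g * sq_dt * z[i]
    if (m > 1) m <- 1 else if (m < -1) m <- -1
    if (i == next_rec) {
      r <- r + 1L
      out[r] <- m
      next_rec <- if (r <= length(rec_idx)) rec_idx[r] else Inf
    }
  }
  structure(
    list(times = c(0, rec_idx * dt), m = out, params = params,
         model = model, seed = as.integer(seed)),
    class = "sde_trace"
  )
}

#' Stationary moments of an SDE trace
#'
#' Sample mean, variance, and mean absolute value of the post-burn-in
#' portion of an order-parameter trace. For the pairwise model at small
#' `|m|` the stationary variance approaches the Ornstein-Uhlenbeck value
#' `(c + a) / (2 a N)`.
#'
#' @param trace An `sde_trace` from [simulate_sde()].
#' @param burn_fraction Fraction of the trace discarded (default 0.2).
#' @return Tibble with columns `mean_m`, `var_m`, `mean_abs_m`, `n`.
#' @export
stationary_moments <- function(trace, burn_fraction = 0.2) {
  keep <- trace$times >= burn_fraction * max(trace$times) - 1e-12
  m <- trace$m[keep]
  if (length(m) < 100) stop("need at least 100 post-burn-in samples")
  tibble::tibble(
    mean_m = mean(m),
    var_m = stats::var(m),
    mean_abs_m = mean(abs(m)),
    n = length(m)
  )
}

#' @export
print.sde_trace <- function(x, ...) {
  cat(sprintf("<sde_trace> %s model, %d samples to t = %g (seed %d)\n",
              x$model, length(x$m), max(x$times), x$seed))
  invisible(x)
}

#' @export
tidy.sde_trace <- function(x, ...) tibble::tibble(time = x$times, m = x$m)

#' @export
glance.sde_trace <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(model = x$model, a = x$params$a, c = x$params$c,
                   h = x$params$h, N = x$params$N),
    stationary_moments(x)
  )
}
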