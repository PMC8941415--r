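p_small <- flock_params(N = 10, K = 3, k = 1)

test_that("sample_next_event reproduces the Gillespie statistics", {
  # degenerate mixture: only turns possible
  p_turn <- flock_params(N = 5, K = 2, r_p = 0, r_c = 0, r_s = 1)
  set.seed(1)
  expect_true(all(replicate(50, sample_next_event(p_turn)$etype) == "turn"))
  expect_error(
    sample_next_event(flock_params(N = 5, K = 2, r_p = 0, r_c = 0, r_s = 0)),
    "zero"
  )
  # exponential waiting with total propensity N * (r_p + r_c + r_s)
  p3 <- flock_params(N = 10, K = 3, r_p = 1, r_c = 1, r_s = 1)
  set.seed(2)
  ev <- replicate(10000, sample_next_event(p3), simplify = FALSE)
  dts <- vapply(ev, `[[`, numeric(1), "dt")
  lambda <- 10 * 3
  expect_lt(abs(mean(dts) - 1 / lambda), 3 * (1 / lambda) / sqrt(10000))
  # event-type mixture proportional to the rates
  p_mix <- flock_params(N = 10, K = 3, r_p = 2, r_c = 1, r_s = 1)
  set.seed(3)
  types <- replicate(10000, sample_next_event(p_mix)$etype)
  freq <- table(types) / 10000
  for (nm in c("align", "attract", "turn")) {
    pr <- c(align = 0.5, attract = 0.25, turn = 0.25)[[nm]]
    expect_lt(abs(freq[[nm]] - pr), 3 * sqrt(pr * (1 - pr) / 10000))
  }
})

test_that("alignment copies one partner exactly and averages several", {
  st <- tibble::tibble(
    id = 1:4, x = c(0, 1, 2, 3), y = 0,
    speed = c(1, 2, 1, 3), heading = c(0, 1.3, 0, pi / 2)
  )
  out <- apply_alignment(st, focal = 1, partners = 2L, p_small)
  expect_equal(out$heading[1], 1.3)
  expect_equal(out$speed[1], 2)
  # circular mean of {0, pi/2} and arithmetic mean of {1, 3}
  st2 <- dplyr::mutate(st, heading = c(0.4, 0, pi / 2, 0))
  out2 <- apply_alignment(st2, focal = 1, partners = c(2L, 3L), p_small)
  expect_equal(out2$heading[1], pi / 4)
  expect_equal(out2$speed[1], 1.5)
  # no visible neighbour: no-op
  expect_identical(apply_alignment(st, 1, integer(0), p_small), st)
  # undefined circular mean keeps the current heading
  st3 <- dplyr::mutate(st, heading = c(0.4, pi / 2, -pi / 2, 0))
  out3 <- apply_alignment(st3, focal = 1, partners = c(2L, 3L), p_small)
  expect_equal(out3$heading[1], 0.4)
})

test_that("attraction heads to the partner centroid with distance-scaled speed", {
  p <- flock_params(N = 4, K = 3, s0 = 1, s_min = 0.1, s_max = 2, epsilon = 1)
  st <- tibble::tibble(
    id = 1:4, x = c(0, 2, 0, 0), y = c(0, 0, 5, -5),
    speed = 1, heading = 2
  )
  out <- apply_attraction(st, focal = 1, partners = 2L, p)
  expect_equal(out$heading[1], 0) # straight towards +x
  # worked example: centroid (2, 1), d = 1 from focal (2, 0)
  st2 <- tibble::tibble(
    id = 1:3, x = c(2, 1, 3), y = c(0, 1, 1), speed = 1, heading = 0
  )
  out2 <- apply_attraction(st2, focal = 1, partners = c(2L, 3L), p)
  expect_equal(out2$heading[1], pi / 2)
  expect_equal(out2$speed[1], 1) # clamp(1 * 1 / 1, 0.1, 2)
  # focal at the centroid: heading kept, cruise speed s0
  st3 <- tibble::tibble(
    id = 1:3, x = c(0, -1, 1), y = c(0, 0, 0), speed = 0.3, heading = 0.9
  )
  out3 <- apply_attraction(st3, focal = 1, partners = c(2L, 3L), p)
  expect_equal(out3$heading[1], 0.9)
  expect_equal(out3$speed[1], 1)
  expect_identical(apply_attraction(st, 1, integer(0), p), st)
})

test_that("spontaneous turns follow the wrapped/truncated normal laws", {
  p0 <- flock_params(N = 2, K = 1, sigma_a2 = 0, sigma_s2 = 0)
  st <- tibble::tibble(id = 1:2, x = c(0, 1), y = 0, speed = 0.7,
                       heading = 0.5)
  out <- apply_spontaneous_turn(st, 1, p0)
  expect_equal(out$heading[1], 0.5)
  expect_equal(out$speed[1], p0$s0)
  # sample statistics of the wrapped-normal heading draw
  pa <- flock_params(N = 2, K = 1, sigma_a2 = 0.04, sigma_s2 = 0.01,
                     s_min = 0)
  set.seed(5)
  draws <- replicate(10000, {
    o <- apply_spontaneous_turn(st, 1, pa)
    c(o$heading[1], o$speed[1])
  })
  resultant <- c(mean(cos(draws[1, ] - 0.5)), mean(sin(draws[1, ] - 0.5)))
  expect_lt(abs(atan2(resultant[2], resultant[1])), 3 * 0.2 / sqrt(10000))
  circ_var <- 1 - sqrt(sum(c(mean(cos(draws[1, ])), mean(sin(draws[1, ])))^2))
  expect_lt(abs(circ_var - (1 - exp(-0.04 / 2))), 0.005)
  expect_lt(abs(mean(draws[2, ]) - 1), 3 * 0.1 / sqrt(10000))
})

test_that("collision avoidance turns away and slows down within range", {
  p <- flock_params(N = 2, K = 1, d_c = 0.2, avoid_turn_rate = pi,
                    avoid_slow_factor = 0.5, s_min = 0.1)
  far <- tibble::tibble(id = 1:2, x = c(0, 2), y = 0, speed = 1,
                        heading = c(0, pi))
  expect_identical(apply_collision_avoidance(far, p, dt = 0.01), far)
  near <- tibble::tibble(id = 1:2, x = c(0, 0.1), y = 0, speed = 1,
                         heading = c(0, pi))
  out <- apply_collision_avoidance(near, p, dt = 0.01)
  # each rotates towards facing directly away by avoid_turn_rate * dt
  expect_equal(abs(wrap_angle(out$heading - near$heading)),
               rep(pi * 0.01, 2))
  expect_equal(out$speed, c(0.5, 0.5))
  # coincident agents: deterministic counter-clockwise turn, no crash
  co <- tibble::tibble(id = 1:2, x = 0, y = 0, speed = 1, heading = c(0, 1))
  outc <- apply_collision_avoidance(co, p, dt = 0.01)
  expect_equal(wrap_angle(outc$heading - co$heading), rep(pi * 0.01, 2))
})

test_that("ballistic advance is linear in time", {
  st <- tibble::tibble(id = 1:2, x = c(0, 1), y = 0, speed = c(2, 1),
                       heading = c(0, pi / 2))
  expect_identical(advance_positions(st, 0), st)
  out <- advance_positions(st, 0.5)
  expect_equal(out$x[1], 1)
  expect_equal(out$y[2], 0.5)
  half <- advance_positions(advance_positions(st, 0.25), 0.25)
  expect_equal(half, out)
  expect_error(advance_positions(st, -1), "non-negative")
})

test_that("a lone agent has no partners; only turns change its state", {
  traj <- simulate_flock(flock_params(N = 1, K = 1), t_end = 20, seed = 4)
  # align/attract events fail (no visible neighbour) and are logged with
  # empty partner sets; they leave the state untouched
  expect_true(all(lengths(traj$events$partners) == 0))
  expect_gt(sum(traj$events$etype == "turn"), 0)
  # between consecutive turn events the heading is piecewise constant,
  # i.e. the motion is a speed-varying random walk driven by turns alone
  headings <- unique(traj$states$heading)
  n_turns <- sum(traj$events$etype == "turn")
  expect_lte(length(headings), n_turns + 1)
})

test_that("trajectories are bit-identical under the same seed", {
  a <- simulate_flock(p_small, t_end = 10, seed = 123)
  b <- simulate_flock(p_small, t_end = 10, seed = 123)
  expect_identical(a, b)
  c <- simulate_flock(p_small, t_end = 10, seed = 124)
  expect_false(identical(a$states, c$states))
})

test_that("aligned pair with no noise is a fixed point of the dynamics", {
  p <- flock_params(N = 2, K = 1, k = 1, r_c = 0, r_p = 2, r_s = 0,
                    sigma_a2 = 0, sigma_s2 = 0, d_c = 0)
  init <- tibble::tibble(id = 1:2, x = c(0, 0.5), y = 0, speed = 1,
                         heading = 0.8)
  traj <- simulate_flock(p, t_end = 10, seed = 6, init = init)
  expect_true(all(traj$states$heading == 0.8))
  expect_true(all(traj$states$speed == 1))
})

test_that("event times increase strictly and gaps are exponential", {
  traj <- simulate_flock(flock_params(N = 10, K = 3), t_end = 60, seed = 8)
  expect_true(all(diff(traj$events$time) > 0))
  gaps <- diff(c(0, traj$events$time))
  lambda <- 10 * (traj$params$r_p + traj$params$r_c + traj$params$r_s)
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp", rate = lambda))
  expect_gt(ks$p.value, 0.01)
})

test_that("speeds stay inside [s_min, s_max] at all sampled times", {
  traj <- simulate_flock(flock_params(N = 15, K = 5, k = 2), t_end = 30,
                         seed = 9)
  expect_true(all(traj$states$speed >= traj$params$s_min - 1e-12))
  expect_true(all(traj$states$speed <= traj$params$s_max + 1e-12))
  expect_true(all(traj$states$heading > -pi & traj$states$heading <= pi))
})

test_that("minimal variant keeps speed pinned at s0 with avoidance off", {
  pm <- flock_params(N = 8, K = 3, minimal = TRUE)
  expect_equal(pm$fov, 2 * pi)
  traj <- simulate_flock(pm, t_end = 30, seed = 10)
  expect_true(all(traj$states$speed == pm$s0))
})

test_that("behavioural kernels are equivariant under agent relabelling", {
  set.seed(12)
  st <- random_states(8)
  perm <- sample(8)
  rel <- st[perm, ]
  p <- flock_params(N = 8, K = 3, k = 2)
  out <- apply_alignment(st, focal = 2, partners = c(5L, 7L), p)
  out_rel <- apply_alignment(rel, focal = 2, partners = c(5L, 7L), p)
  expect_equal(dplyr::arrange(out_rel, id), dplyr::arrange(out, id))
  out2 <- apply_attraction(st, focal = 3, partners = c(1L, 8L), p)
  out2_rel <- apply_attraction(rel, focal = 3, partners = c(1L, 8L), p)
  expect_equal(dplyr::arrange(out2_rel, id), dplyr::arrange(out2, id))
})
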