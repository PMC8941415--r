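test_that("the window length is the cluster scale over the desired speed", {
  expect_equal(time_window(1, 1), 1)
  expect_equal(time_window(2, 4), 0.5)
  expect_equal(time_window(0.3, 1.5), 0.2)
  expect_error(time_window(1, 0), "positive")
})

test_that("adjacency keeps only attraction events inside the window", {
  expect_equal(build_adjacency(tibble::tibble(
    time = numeric(0), focal = integer(0), etype = character(0),
    partners = list()
  ), 0, 1, 4), matrix(0L, 4, 4))
  ev <- tibble::tibble(
    time = c(0.1, 0.2, 0.5, 1.2),
    focal = c(1L, 2L, 3L, 1L),
    etype = c("attract", "align", "attract", "attract"),
    partners = list(2L, 3L, integer(0), 4L)
  )
  A <- build_adjacency(ev, 0, 1, 4)
  expect_equal(A[1, 2], 1L) # the directed edge is one way only
  expect_equal(A[2, 1], 0L)
  expect_equal(sum(A), 1L) # align ignored, empty partners ignored,
  expect_equal(A[1, 4], 0L) # t = 1.2 outside [0, 1)
  expect_error(build_adjacency(dplyr::mutate(ev, focal = focal + 10),
                               0, 2, 4), "ids")
})

test_that("adjacency builder agrees with a linear event scan", {
  set.seed(41)
  for (rep in 1:10) {
    ev <- random_event_log(200, N = 12, t_max = 10)
    t0 <- runif(1, 0, 8)
    expect_identical(build_adjacency(ev, t0, 1.5, 12),
                     adjacency_scan(ev, t0, 1.5, 12))
  }
})

test_that("reachability is the transitive closure with self-reachability", {
  expect_equal(reachability(matrix(0L, 3, 3)), diag(1L, 3))
  chain <- matrix(0L, 3, 3)
  chain[1, 2] <- chain[2, 3] <- 1L
  r <- reachability(chain)
  expect_equal(r[1, 3], 1L)
  expect_equal(r[3, 1], 0L)
  expect_error(reachability(matrix(0L, 2, 3)), "square")
})

test_that("reachability and sub-groups agree with Warshall and pairwise oracles", {
  set.seed(42)
  for (rep in 1:30) {
    A <- random_digraph(12)
    r <- reachability(A)
    expect_equal(r, closure_boolpow(A))
    # closure of closure = closure (idempotence); diag already set
    r2 <- r
    diag(r2) <- 0L
    expect_equal(reachability(r2), r)
    expect_true(same_partition(strongly_connected_subgroups(r),
                               mutual_classes(r)))
  }
})

test_that("one-way links do not merge mutually reachable sub-groups", {
  # edges 1->3, 3->2, 2->1 form one cycle; 4->5, 5->4 another; 2->4 one-way
  A <- matrix(0L, 5, 5)
  A[cbind(c(1, 3, 2, 4, 5, 2), c(3, 2, 1, 5, 4, 4))] <- 1L
  part <- strongly_connected_subgroups(reachability(A))
  expect_true(same_partition(part, c(1L, 1L, 1L, 2L, 2L)))
  # complete digraph: one class
  full <- matrix(1L, 4, 4)
  diag(full) <- 0L
  expect_equal(max(strongly_connected_subgroups(reachability(full))), 1)
})

test_that("sub-groups refine weak components", {
  set.seed(43)
  for (rep in 1:10) {
    A <- random_digraph(10, p = 0.12)
    part <- strongly_connected_subgroups(reachability(A))
    weak <- igraph::components(
      igraph::graph_from_adjacency_matrix(A, mode = "directed"),
      mode = "weak"
    )$membership
    for (cl in unique(part)) {
      expect_equal(length(unique(weak[part == cl])), 1)
    }
    expect_lte(max(tabulate(part)), max(tabulate(weak)))
  }
})

test_that("Np is the windowed mean largest sub-group fraction", {
  ev <- make_fixture("event_log_cycle", n = 8, t_w = 1, n_windows = 6)
  p <- flock_params(N = 8, K = 3, epsilon = 1) # t_w = 1
  net <- network_parameter(ev, p, t_total = 6, burn_fraction = 0)
  expect_equal(net$Np, 1)
  expect_equal(nrow(net$per_window), 6)
  ev2 <- make_fixture("event_log_halves", n = 10, t_w = 1, n_windows = 6)
  p2 <- flock_params(N = 10, K = 3, epsilon = 1)
  net2 <- network_parameter(ev2, p2, t_total = 6, burn_fraction = 0)
  expect_equal(net2$Np, 0.5)
  expect_true(all(net2$per_window$n_subgroups == 2))
  expect_error(network_parameter(ev, p, t_total = 0.5, burn_fraction = 0),
               "window")
})

test_that("windowed analysis equals window-by-window oracle composition", {
  traj <- simulate_flock(flock_params(N = 10, K = 4), t_end = 20, seed = 44)
  net <- network_parameter(traj, burn_fraction = 0.2)
  t_w <- traj$params$epsilon / traj$params$s0
  starts <- 4 + t_w * (0:(nrow(net$per_window) - 1))
  fr <- vapply(starts, function(t0) {
    A <- adjacency_scan(traj$events, t0, t_w, 10)
    part <- mutual_classes(closure_boolpow(A))
    max(tabulate(part)) / 10
  }, numeric(1))
  expect_equal(net$per_window$largest_fraction, fr)
  expect_equal(net$Np, mean(fr))
})

test_that("relabelling agents permutes adjacency and partition consistently", {
  set.seed(45)
  ev <- random_event_log(150, N = 9, t_max = 5)
  perm <- sample(9)
  ev_rel <- dplyr::mutate(ev,
    focal = perm[focal],
    partners = lapply(partners, function(p) perm[p])
  )
  A <- build_adjacency(ev, 1, 2, 9)
  A_rel <- build_adjacency(ev_rel, 1, 2, 9)
  expect_equal(A_rel[perm, perm], A)
  part <- strongly_connected_subgroups(reachability(A))
  part_rel <- strongly_connected_subgroups(reachability(A_rel))
  expect_true(same_partition(part, part_rel[perm]))
})
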