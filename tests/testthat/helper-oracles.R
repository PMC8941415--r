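# Independent brute-force oracles used to cross-check the implementation.

# connected components of the "< eps" graph by explicit union-find
uf_clusters <- function(xy, eps) {
  n <- nrow(xy)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
      if (d < eps) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# partitions agree up to relabelling
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# transitive closure by iterated boolean matrix powers (Warshall-style)
closure_boolpow <- function(A) {
  n <- nrow(A)
  reach <- A != 0
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  out <- reach * 1L
  diag(out) <- 1L
  out
}

# mutual-reachability classes by explicit pairwise check
mutual_classes <- function(reach) {
  n <- nrow(reach)
  lab <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (lab[i] > 0) next
    nxt <- nxt + 1L
    lab[i] <- nxt
    for (j in seq_len(n)) {
      if (j != i && reach[i, j] == 1 && reach[j, i] == 1) lab[j] <- nxt
    }
  }
  lab
}

# per-agent bearing filter written independently of the package kernel
brute_visible <- function(states, focal, fov) {
  f <- states[states$id == focal, ]
  out <- integer(0)
  for (j in states$id[states$id != focal]) {
    o <- states[states$id == j, ]
    dx <- o$x - f$x; dy <- o$y - f$y
    if (dx == 0 && dy == 0) { out <- c(out, j); next }
    b <- atan2(dy, dx) - f$heading
    b <- atan2(sin(b), cos(b)) # wrap via sin/cos, no shared code
    if (abs(b) <= fov / 2 + 1e-12) out <- c(out, j)
  }
  out
}

# exhaustive distance sort with id tie-break
brute_rank <- function(states, focal, visible, K) {
  f <- states[states$id == focal, ]
  d <- sapply(visible, function(j) {
    o <- states[states$id == j, ]
    sqrt((o$x - f$x)^2 + (o$y - f$y)^2)
  })
  ord <- order(d, visible)
  visible[ord][seq_len(min(K, length(visible)))]
}

# linear scan over the event log
adjacency_scan <- function(events, t_start, t_w, N) {
  A <- matrix(0L, N, N)
  for (m in seq_len(nrow(events))) {
    if (events$etype[m] != "attract") next
    tt <- events$time[m]
    if (tt < t_start || tt >= t_start + t_w) next
    for (j in events$partners[[m]]) A[events$focal[m], j] <- 1L
  }
  diag(A) <- 0L
  A
}

random_states <- function(n, scale = 5) {
  tibble::tibble(
    id = seq_len(n),
    x = stats::runif(n, -scale, scale),
    y = stats::runif(n, -scale, scale),
    speed = stats::runif(n, 0.1, 2),
    heading = stats::runif(n, -pi, pi)
  )
}

random_digraph <- function(n, p = 0.15) {
  A <- matrix(as.integer(stats::runif(n * n) < p), n, n)
  diag(A) <- 0L
  A
}

random_event_log <- function(n_events, N, t_max, k_max = 3) {
  tibble::tibble(
    time = sort(stats::runif(n_events, 0, t_max)),
    focal = sample.int(N, n_events, replace = TRUE),
    etype = sample(c("align", "attract", "turn"), n_events, replace = TRUE),
    partners = lapply(seq_len(n_events), function(i) {
      nk <- sample.int(k_max, 1) - 1L
      sample(setdiff(seq_len(N), i %% N + 1L), min(nk, N - 1L))
    })
  )
}
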