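# Heavy simulation products shared by several acceptance checks, computed
# once per test run. Conditions: N = 30, default parameters, t_end = 200,
# 10 replicates seeded base_seed + r - 1 with base_seed = 1.

.sim_cache <- new.env(parent = emptyenv())

pairwise_sweep <- function() {
  if (is.null(.sim_cache$pairwise)) {
    cfg <- flock_config(
      N_list = 30, K_list = c(1, 2, 5, 8, 10, 15, 29),
      k_mode = "pairwise", replicates = 10, t_end = 200, base_seed = 1
    )
    .sim_cache$pairwise <- run_sweep(cfg)
  }
  .sim_cache$pairwise
}

averaging_sweep_k5 <- function() {
  if (is.null(.sim_cache$averaging)) {
    cfg <- flock_config(
      N_list = 30, K_list = 5, k_mode = "averaging",
      replicates = 10, t_end = 200, base_seed = 1
    )
    .sim_cache$averaging <- run_sweep(cfg)
  }
  .sim_cache$averaging
}

k1_cluster_sizes <- function() {
  if (is.null(.sim_cache$k1_sizes)) {
    p <- flock_params(N = 30, K = 1, k = 1)
    .sim_cache$k1_sizes <- unlist(lapply(1:10, function(r) {
      traj <- simulate_flock(p, t_end = 200, seed = r)
      cluster_size_distribution(traj, burn_fraction = 0.2)$size
    }))
  }
  .sim_cache$k1_sizes
}
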