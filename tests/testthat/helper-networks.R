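# Shared fixtures, built in code.

# Random small DAG with random positive CPTs (for oracle-equivalence tests).
random_network <- function(n_nodes, max_states = 5) {
  nodes <- paste0("X", seq_len(n_nodes))
  states <- lapply(nodes, function(nd) paste0("s", seq_len(sample(2:max_states, 1))))
  names(states) <- nodes
  parents <- setNames(vector("list", n_nodes), nodes)
  for (i in seq_along(nodes)) {
    prev <- nodes[seq_len(i - 1)]
    k <- if (length(prev)) sample(0:min(2, length(prev)), 1) else 0
    parents[[nodes[i]]] <- if (k > 0) sample(prev, k) else character(0)
  }
  net <- new_network(states, parents)
  randomize_cpts(net)
}

randomize_cpts <- function(net) {
  for (nd in net$nodes) {
    cpt <- net$cpts[[nd]]
    pr <- matrix(stats::rgamma(nrow(cpt$prob) * ncol(cpt$prob), 1) + 1e-4,
                 nrow(cpt$prob))
    net <- tnmbn:::set_cpt_prob(net, nd, pr / rowSums(pr))
  }
  net
}

random_evidence <- function(net, max_k = 2) {
  k <- sample(0:min(max_k, length(net$nodes) - 1), 1)
  if (k == 0) return(list())
  nds <- sample(net$nodes, k)
  ev <- lapply(nds, function(nd) sample(net$states[[nd]], 1))
  names(ev) <- nds
  ev
}

# A reduced-state-space variant of the ten-node network (small enough for
# full-joint enumeration).
reduced_tnm_config <- function() {
  cfg <- default_state_config()
  cfg$T_7 <- c("T1a", "T4")
  cfg$T_567 <- c("T1", "T4")
  cfg$N_7 <- cfg$N_567 <- c("N0", "N2")
  cfg$M_7 <- c("M0", "M1b")
  cfg$M_567 <- c("M0", "M1")
  cfg
}

# Memoized small fitted network on faithful synthetic data, shared by the
# reclassification / survival tests so EM runs once per session.
.fit_cache <- new.env(parent = emptyenv())

small_fitted_net <- function() {
  if (is.null(.fit_cache$net)) {
    cfg <- simulation_config(n_records = 20000, seed = 4711)
    sim <- simulate_registry(cfg)
    net <- build_structure()
    net <- init_hidden_cpts(net, sim$records[sim$records$edition == "7", ])
    fit <- em_fit(net, sim$records, config = em_config(max_iterations = 60))
    .fit_cache$net <- fit$network
    .fit_cache$sim <- sim
    .fit_cache$diagnostics <- fit$diagnostics
  }
  .fit_cache$net
}

small_fitted_sim <- function() {
  small_fitted_net()
  .fit_cache$sim
}

small_fitted_diagnostics <- function() {
  small_fitted_net()
  .fit_cache$diagnostics
}

# Network with the transition priors applied and stage CPTs clamped but no
# data-driven fitting (deterministic toy for query-recipe tests).
prior_only_net <- function(params = default_prior_params()) {
  net <- build_structure()
  net <- tnmbn:::apply_transition_priors(net, make_transition_priors(params = params))
  tnmbn:::clamp_stage_cpts(net)
}
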