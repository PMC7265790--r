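# Network construction, exact inference, the enumeration oracle, and
# serialization.

test_that("the staging network has ten nodes with the documented parent sets", {
  net <- build_structure()
  expect_length(net$nodes, 10L)
  expect_setequal(net$nodes, c("edition", "T_7", "N_7", "M_7", "TNM_7",
                               "T_567", "N_567", "M_567", "TNM_567", "death"))
  expect_setequal(node_parents(net, "T_567"), c("edition", "T_7"))
  expect_setequal(node_parents(net, "N_567"), c("edition", "N_7"))
  expect_setequal(node_parents(net, "M_567"), c("edition", "M_7"))
  expect_setequal(node_parents(net, "TNM_7"), c("T_7", "N_7", "M_7"))
  expect_setequal(node_parents(net, "TNM_567"),
                  c("edition", "T_567", "N_567", "M_567"))
  expect_identical(node_parents(net, "death"), "TNM_7")
  for (root in c("edition", "T_7", "N_7", "M_7")) {
    expect_length(node_parents(net, root), 0L)
  }
  # 14 directed edges in total
  expect_identical(sum(lengths(net$parents)), 14L)
})

test_that("construction validates the state configuration", {
  cfg <- default_state_config()
  cfg$death <- NULL
  expect_error(build_structure(cfg), "missing node")
  cfg <- default_state_config()
  cfg$T_7 <- character(0)
  expect_error(build_structure(cfg), "non-empty")
  cfg <- default_state_config()
  cfg$N_7 <- c("N0", "N0")
  expect_error(build_structure(cfg), "duplicates")
  expect_error(new_network(list(A = "a", B = "b"), list(A = "B", B = "A")), "cycle")
})

test_that("CPT rows must be normalized and rows stay normalized after fitting", {
  expect_error(new_cpt("x", c("a", "b"), prob = matrix(c(0.5, 0.2), 1)), "sum to 1")
  expect_error(new_cpt("x", c("a", "b"), prob = matrix(c(1.5, -0.5), 1)), "negative")
  net <- small_fitted_net()
  for (nd in net$nodes) {
    expect_true(all(abs(rowSums(net$cpts[[nd]]$prob) - 1) < 1e-9), label = nd)
  }
})

test_that("degenerate and uniform posteriors behave as expected", {
  net <- build_structure()
  # uniform CPTs, no evidence: uniform posterior on any root
  p <- infer_posterior(net, list(), "T_7")
  expect_equal(p$probabilities, rep(1 / 6, 6))
  # posterior with no evidence equals the root's prior CPT row
  net2 <- randomize_cpts(net)
  for (root in c("edition", "T_7", "N_7", "M_7")) {
    expect_equal(infer_posterior(net2, list(), root)$probabilities,
                 as.numeric(net2$cpts[[root]]$prob[1, ]), tolerance = 1e-12)
  }
  # deterministic CPTs with full root evidence give a degenerate posterior
  net3 <- prior_only_net()
  net3 <- init_hidden_cpts(net3, data.frame(edition = character(0), t = character(0),
                                            n = character(0), m = character(0),
                                            stage = character(0),
                                            survival = character(0)))
  post <- infer_posterior(net3, list(edition = "7", T_7 = "T3", N_7 = "N2",
                                     M_7 = "M0"), "TNM_567")
  expect_equal(max(post$probabilities), 1, tolerance = 1e-12)
  expect_identical(post$states[which.max(post$probabilities)], "IIIA")
})

test_that("exact inference matches the enumeration oracle on random networks", {
  set.seed(2024)
  for (rep in 1:60) {
    net <- random_network(sample(2:6, 1))
    ev <- random_evidence(net)
    query <- sample(setdiff(net$nodes, names(ev)), 1)
    a <- infer_posterior(net, ev, query)
    b <- brute_force_posterior(net, ev, query)
    expect_lt(max(abs(a$probabilities - b$probabilities)), 1e-9)
  }
})

test_that("inference is invariant to evidence order", {
  set.seed(5)
  net <- randomize_cpts(build_structure())
  ev <- list(edition = "6", T_567 = "T2", N_567 = "N2", M_567 = "M0")
  for (rep in 1:5) {
    perm <- sample(length(ev))
    expect_equal(infer_posterior(net, ev[perm], "TNM_7")$probabilities,
                 infer_posterior(net, ev, "TNM_7")$probabilities,
                 tolerance = 1e-12)
  }
})

test_that("impossible evidence raises an error naming the assignment", {
  net <- prior_only_net()
  # a 6th-edition record can never show the 7th-edition token T1a
  expect_error(infer_posterior(net, list(edition = "6", T_567 = "T1a"), "TNM_7"),
               "impossible evidence.*T_567=T1a")
  expect_error(infer_posterior(net, list(edition = "9"), "TNM_7"), "not legal")
  expect_error(infer_posterior(net, list(bogus = "x"), "TNM_7"), "unknown node")
})

test_that("the enumeration oracle reproduces closed-form results", {
  # single node: posterior equals the prior
  net <- new_network(list(A = c("a1", "a2")), list(A = character(0)))
  net <- tnmbn:::set_cpt_prob(net, "A", matrix(c(0.3, 0.7), 1))
  expect_equal(brute_force_posterior(net, list(), "A")$probabilities, c(0.3, 0.7))
  # two-node chain with evidence on the child: Bayes' rule by hand
  net2 <- new_network(list(A = c("a1", "a2"), B = c("b1", "b2")),
                      list(A = character(0), B = "A"))
  net2 <- tnmbn:::set_cpt_prob(net2, "A", matrix(c(0.6, 0.4), 1))
  net2 <- tnmbn:::set_cpt_prob(net2, "B", matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))
  post <- brute_force_posterior(net2, list(B = "b1"), "A")
  # P(A=a1|B=b1) = .6*.9 / (.6*.9 + .4*.2)
  expect_equal(post$probabilities[1], 0.54 / 0.62, tolerance = 1e-12)
  # cap on the joint size
  net3 <- random_network(4)
  expect_error(brute_force_posterior(net3, list(), net3$nodes[1], cap = 2),
               "exceeds cap")
})

test_that("oracle agrees with variable elimination on the full staging network", {
  set.seed(77)
  net <- randomize_cpts(build_structure())
  ev <- list(edition = "7", T_7 = "T2b", N_7 = "N2", M_7 = "M0")
  for (query in c("TNM_567", "death", "T_567")) {
    a <- infer_posterior(net, ev, query)
    b <- brute_force_posterior(net, ev, query)
    expect_lt(max(abs(a$probabilities - b$probabilities)), 1e-9)
  }
})

test_that("log-likelihood of partial observations matches the oracle marginal", {
  set.seed(31)
  net <- random_network(5, max_states = 3)
  records <- lapply(1:20, function(i) random_evidence(net, max_k = 3))
  ll <- joint_log_likelihood(net, records)
  oracle <- sum(vapply(records, function(ev) {
    log(marginal_probability(net, ev, method = "enumeration"))
  }, numeric(1)))
  expect_equal(as.numeric(ll), oracle, tolerance = 1e-9)
  # nothing observed: marginal of nothing is 1, contributes log 1 = 0
  expect_equal(as.numeric(joint_log_likelihood(net, list(list()))), 0)
  # a fully observed record under consistent deterministic CPTs contributes 0
  det <- new_network(list(A = c("a1", "a2")), list(A = character(0)))
  det <- tnmbn:::set_cpt_prob(det, "A", matrix(c(1, 0), 1))
  expect_equal(as.numeric(joint_log_likelihood(det, list(list(A = "a1")))), 0)
  # impossible observations are flagged
  ll2 <- joint_log_likelihood(det, list(list(A = "a2"), list(A = "a1")))
  expect_identical(attr(ll2, "impossible"), 1L)
  expect_identical(as.numeric(ll2), -Inf)
})

test_that("network JSON serialization round-trips exactly", {
  set.seed(9)
  net <- randomize_cpts(build_structure())
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_identical(back$nodes, net$nodes)
  expect_identical(back$states, net$states)
  for (nd in net$nodes) {
    expect_identical(back$cpts[[nd]]$prob, net$cpts[[nd]]$prob, label = nd)
  }
  # schema version is enforced
  doc <- jsonlite::read_json(path)
  doc$schema_version <- 99L
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path2, auto_unbox = TRUE, digits = NA)
  expect_error(read_network_json(path2), "schema version")
})
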