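#' @importFrom stats setNames
NULL

TNM_NODES <- c("edition", "T_7", "N_7", "M_7", "TNM_7",
               "T_567", "N_567", "M_567", "TNM_567", "death")

TNM_PARENTS <- list(
  edition = character(0),
  T_7     = character(0),
  N_7     = character(0),
  M_7     = character(0),
  TNM_7   = c("T_7", "N_7", "M_7"),
  T_567   = c("edition", "T_7"),
  N_567   = c("edition", "N_7"),
  M_567   = c("edition", "M_7"),
  TNM_567 = c("edition", "T_567", "N_567", "M_567"),
  death   = c("TNM_7")
)

#' Default node state spaces for the staging network
#'
#' Returns the default state configuration for the ten-node network: the
#' edition node (`"5"`, `"6"`, `"7"`), hidden 7th-edition descriptor nodes,
#' observed cross-edition descriptor nodes whose state spaces are the union
#' of all edition vocabularies, the two stage-group nodes, and the
#' five-category survival node. Unknown/unassessable descriptor tokens
#' (TX, T0, NX, MX) are excluded from the network state spaces by default;
#' pass a modified configuration to [build_structure()] to include them.
#'
#' @param survival_boundaries Month cut-points for the survival categories,
#'   see [survival_categories()].
#' @return Named list mapping each node name to its ordered state labels.
#' @export
default_state_config <- function(survival_boundaries = default_survival_boundaries()) {
  list(
    edition = c("5", "6", "7"),
    T_7     = c("T1a", "T1b", "T2a", "T2b", "T3", "T4"),
    N_7     = c("N0", "N1", "N2", "N3"),
    M_7     = c("M0", "M1a", "M1b"),
    TNM_7   = stage_levels(),
    T_567   = c("T1", "T2", "T3", "T4", "T1a", "T1b", "T2a", "T2b"),
    N_567   = c("N0", "N1", "N2", "N3"),
    M_567   = c("M0", "M1", "M1a", "M1b"),
    TNM_567 = stage_levels(),
    death   = survival_categories(survival_boundaries)
  )
}

#' Conditional probability table
#'
#' Constructs a CPT for `node` given its `parents`. Rows index parent-state
#' combinations in mixed-radix order, little-endian in the parent list (the
#' first parent varies fastest); columns index child states. Every row must
#' be a probability vector.
#'
#' @param node Node name.
#' @param states Ordered child state labels.
#' @param parents Ordered parent node names (may be empty).
#' @param parent_states Named list of parent state labels, in `parents` order.
#' @param prob Numeric matrix, `prod(lengths(parent_states))` rows by
#'   `length(states)` columns. Defaults to uniform.
#' @param never_observed Logical vector flagging rows that were never
#'   supported by data (kept uniform so inference never divides by zero).
#' @return An object of class `bn_cpt`.
#' @export
new_cpt <- function(node, states, parents = character(0),
                    parent_states = list(), prob = NULL,
                    never_observed = NULL) {
  stopifnot(is.character(node), length(node) == 1L,
            is.character(states), length(states) >= 1L, !anyDuplicated(states))
  parent_states <- parent_states[parents]
  n_rows <- if (length(parents)) prod(vapply(parent_states, length, integer(1))) else 1L
  k <- length(states)
  if (is.null(prob)) prob <- matrix(1 / k, nrow = n_rows, ncol = k)
  prob <- as.matrix(prob)
  if (nrow(prob) != n_rows || ncol(prob) != k) {
    stop(sprintf("CPT for '%s': probability matrix must be %d x %d", node, n_rows, k),
         call. = FALSE)
  }
  if (any(prob < -1e-12)) stop(sprintf("CPT for '%s': negative probability", node), call. = FALSE)
  bad <- abs(rowSums(prob) - 1) > 1e-9
  if (any(bad)) {
    stop(sprintf("CPT for '%s': %d row(s) do not sum to 1 (first: row %d, sum %.12f)",
                 node, sum(bad), which(bad)[1], rowSums(prob)[which(bad)[1]]),
         call. = FALSE)
  }
  colnames(prob) <- states
  if (is.null(never_observed)) never_observed <- rep(FALSE, n_rows)
  structure(list(node = node, states = states, parents = parents,
                 parent_states = parent_states, prob = prob,
                 never_observed = never_observed),
            class = "bn_cpt")
}

# Row index for given parent state indices (matrix n x n_parents),
# mixed-radix little-endian in parent order.
cpt_row_index <- function(cpt, parent_idx) {
  if (!length(cpt$parents)) return(rep(1L, max(1L, nrow(parent_idx))))
  dims <- vapply(cpt$parent_states, length, integer(1))
  strides <- cumprod(c(1L, dims[-length(dims)]))
  as.integer(1L + (parent_idx - 1L) %*% strides)
}

# Expand parent state combinations in row order.
cpt_parent_grid <- function(cpt) {
  if (!length(cpt$parents)) return(data.frame(row.names = 1L))
  g <- expand.grid(cpt$parent_states, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(g) <- cpt$parents
  g
}

# CPT as a factor over (child, parents...).
cpt_as_factor <- function(cpt) {
  states <- c(setNames(list(cpt$states), cpt$node), cpt$parent_states)
  new_factor(states, as.numeric(t(cpt$prob)))
}

#' @export
print.bn_cpt <- function(x, ...) {
  cat(sprintf("CPT for node '%s' (%d states) given {%s} (%d rows)\n",
              x$node, length(x$states), paste(x$parents, collapse = ", "),
              nrow(x$prob)))
  invisible(x)
}

topo_sort <- function(parents) {
  nodes <- names(parents)
  order <- character(0)
  placed <- setNames(rep(FALSE, length(nodes)), nodes)
  while (length(order) < length(nodes)) {
    ready <- nodes[!placed[nodes] &
                     vapply(nodes, function(nd) all(placed[parents[[nd]]]), logical(1))]
    ready <- setdiff(ready, order)
    if (!length(ready)) stop("parent sets contain a cycle", call. = FALSE)
    order <- c(order, ready)
    placed[ready] <- TRUE
  }
  order
}

#' Construct a discrete Bayesian network
#'
#' Generic constructor used by [build_structure()] and by tests that build
#' small randomized networks. Nodes are stored in topological order; all
#' CPTs start uniform.
#'
#' @param states Named list: node name -> ordered character state labels.
#' @param parents Named list: node name -> character vector of parent names
#'   (must induce an acyclic graph).
#' @return An object of class `tnm_network`.
#' @export
new_network <- function(states, parents) {
  nodes <- names(states)
  if (is.null(nodes) || anyDuplicated(nodes)) stop("states must be uniquely named", call. = FALSE)
  parents <- parents[nodes]
  names(parents) <- nodes
  for (nd in nodes) {
    if (is.null(parents[[nd]])) parents[[nd]] <- character(0)
    bad <- setdiff(parents[[nd]], nodes)
    if (length(bad)) stop("unknown parent(s) of ", nd, ": ", paste(bad, collapse = ", "),
                          call. = FALSE)
    st <- states[[nd]]
    if (!is.character(st) || !length(st) || anyDuplicated(st)) {
      stop(sprintf("states for node '%s' must be a non-empty character vector without duplicates", nd),
           call. = FALSE)
    }
  }
  nodes <- topo_sort(parents)
  cpts <- lapply(nodes, function(nd) new_cpt(nd, states[[nd]], parents[[nd]], states[parents[[nd]]]))
  names(cpts) <- nodes
  structure(list(nodes = nodes, states = states[nodes], parents = parents[nodes],
                 cpts = cpts),
            class = "tnm_network")
}

#' Build the ten-node staging network
#'
#' Constructs the fixed directed acyclic graph used for cross-edition TNM
#' reclassification and survival prediction: root nodes `edition`, `T_7`,
#' `N_7`, `M_7` (the hidden, newest-edition descriptors); `TNM_7` with
#' parents `T_7`, `N_7`, `M_7`; observed counterparts `T_567`, `N_567`,
#' `M_567`, each with parents `edition` and its hidden counterpart;
#' `TNM_567` with parents `edition` and the three observed descriptors;
#' and `death` with single parent `TNM_7` (survival is driven by the
#' newest-edition stage, which approximates the true disease state best).
#' All CPTs start uniform.
#'
#' @param config Named list of state spaces for all ten nodes, as returned
#'   by [default_state_config()].
#' @return An object of class `tnm_network`.
#' @export
build_structure <- function(config = default_state_config()) {
  missing <- setdiff(TNM_NODES, names(config))
  if (length(missing)) {
    stop("state configuration is missing node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nd in TNM_NODES) {
    st <- config[[nd]]
    if (!is.character(st) || !length(st) || anyDuplicated(st)) {
      stop(sprintf("states for node '%s' must be a non-empty character vector without duplicates", nd),
           call. = FALSE)
    }
  }
  extra <- setdiff(names(config), TNM_NODES)
  if (length(extra)) {
    stop("state configuration has unknown node(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  new_network(config[TNM_NODES], TNM_PARENTS)
}

#' @export
print.tnm_network <- function(x, ...) {
  cat(sprintf("<tnm_network> %d nodes\n", length(x$nodes)))
  for (nd in x$nodes) {
    cat(sprintf("  %-8s [%d states] <- {%s}\n", nd, length(x$states[[nd]]),
                paste(x$parents[[nd]], collapse = ", ")))
  }
  invisible(x)
}

#' Node state spaces of a network
#' @param net A `tnm_network`.
#' @param node Optional node name; if omitted, the full named list.
#' @return Character vector of states, or the named list of all of them.
#' @export
node_states <- function(net, node = NULL) {
  if (is.null(node)) return(net$states)
  st <- net$states[[node]]
  if (is.null(st)) stop("unknown node: ", node, call. = FALSE)
  st
}

#' Parent sets of a network
#' @inheritParams node_states
#' @return Character vector of parent names, or the named list of all of them.
#' @export
node_parents <- function(net, node = NULL) {
  if (is.null(node)) return(net$parents)
  pa <- net$parents[[node]]
  if (is.null(pa) && !node %in% net$nodes) stop("unknown node: ", node, call. = FALSE)
  pa
}

check_evidence <- function(net, evidence) {
  evidence <- as.list(evidence)
  if (!length(evidence)) return(evidence)
  if (is.null(names(evidence)) || any(!nzchar(names(evidence)))) {
    stop("evidence must be a named list/vector of node = state", call. = FALSE)
  }
  for (nd in names(evidence)) {
    if (!nd %in% net$nodes) stop("evidence on unknown node: ", nd, call. = FALSE)
    st <- as.character(evidence[[nd]])
    if (length(st) != 1L || !st %in% net$states[[nd]]) {
      stop(sprintf("evidence state '%s' is not legal for node '%s'",
                   paste(st, collapse = "/"), nd), call. = FALSE)
    }
  }
  lapply(evidence, as.character)
}

reduced_factors <- function(net, evidence) {
  lapply(net$cpts, function(cpt) {
    f <- cpt_as_factor(cpt)
    for (nd in intersect(names(evidence), factor_vars(f))) {
      f <- factor_reduce(f, nd, evidence[[nd]])
    }
    f
  })
}

#' Exact posterior of a node given evidence
#'
#' Computes the exact posterior distribution of `query` given `evidence` by
#' variable elimination. Deterministic for a given (network, evidence,
#' query) triple and invariant to the order in which evidence is listed.
#'
#' @param net A `tnm_network`.
#' @param evidence Named list/vector `node = state`; may be empty, and may
#'   include hidden nodes.
#' @param query Node name to query.
#' @return A `bn_posterior`: list with `node`, `states`, `probabilities`
#'   (summing to 1).
#' @export
infer_posterior <- function(net, evidence = list(), query) {
  evidence <- check_evidence(net, evidence)
  if (!query %in% net$nodes) stop("unknown query node: ", query, call. = FALSE)
  if (query %in% names(evidence)) {
    p <- as.numeric(net$states[[query]] == evidence[[query]])
    return(structure(list(node = query, states = net$states[[query]], probabilities = p),
                     class = "bn_posterior"))
  }
  res <- ve_eliminate(reduced_factors(net, evidence), keep = query)
  if (!is.array(res) || sum(res) <= 0) {
    stop("impossible evidence: ",
         paste(sprintf("%s=%s", names(evidence), unlist(evidence)), collapse = ", "),
         call. = FALSE)
  }
  p <- as.numeric(res)[match(net$states[[query]], dimnames(res)[[1]])]
  structure(list(node = query, states = net$states[[query]],
                 probabilities = p / sum(p)),
            class = "bn_posterior")
}

#' @export
print.bn_posterior <- function(x, digits = 4, ...) {
  cat(sprintf("Posterior for '%s':\n", x$node))
  print(round(setNames(x$probabilities, x$states), digits))
  invisible(x)
}

#' Exact joint posterior over a set of nodes
#'
#' Like [infer_posterior()] but returns the normalized joint over several
#' query nodes as an array with one named dimension per node.
#'
#' @inheritParams infer_posterior
#' @param vars Character vector of query node names (none observed).
#' @return Numeric array over `vars`, summing to 1.
#' @export
infer_joint <- function(net, evidence = list(), vars) {
  evidence <- check_evidence(net, evidence)
  if (any(vars %in% names(evidence))) {
    stop("joint query on observed node(s): ",
         paste(intersect(vars, names(evidence)), collapse = ", "), call. = FALSE)
  }
  res <- ve_eliminate(reduced_factors(net, evidence), keep = vars)
  if (!is.array(res) || sum(res) <= 0) {
    stop("impossible evidence: ",
         paste(sprintf("%s=%s", names(evidence), unlist(evidence)), collapse = ", "),
         call. = FALSE)
  }
  res <- aperm(res, match(vars, factor_vars(res)))
  res / sum(res)
}

#' Marginal probability of the evidence
#'
#' Probability of an observed partial assignment under the model, with all
#' other nodes marginalized out. `method = "enumeration"` recomputes it by
#' brute-force summation of the fully expanded joint and serves as an
#' independent oracle.
#'
#' @inheritParams infer_posterior
#' @param method `"ve"` (variable elimination) or `"enumeration"`.
#' @param cap Maximum number of joint assignments enumerated.
#' @return Scalar probability.
#' @export
marginal_probability <- function(net, evidence = list(), method = c("ve", "enumeration"),
                                 cap = 1e8) {
  method <- match.arg(method)
  evidence <- check_evidence(net, evidence)
  if (method == "ve") {
    z <- ve_eliminate(reduced_factors(net, evidence), keep = character(0))
    return(as.numeric(z))
  }
  enum_joint(net, evidence, cap = cap)$z
}

# Brute-force enumeration of the joint over all non-evidence nodes.
# Returns the grid of free-variable state indices, the joint probability of
# each full assignment, and the total z. Independent of the factor algebra.
enum_joint <- function(net, evidence, cap = 1e8) {
  free <- setdiff(net$nodes, names(evidence))
  dims <- vapply(net$states[free], length, integer(1))
  n <- prod(as.numeric(dims))
  if (n > cap) {
    stop(sprintf("joint state space (%.3g assignments) exceeds cap %.3g", n, cap),
         call. = FALSE)
  }
  grid <- expand.grid(lapply(dims, seq_len), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- free
  nr <- nrow(grid)
  state_idx <- function(nd) {
    if (nd %in% free) grid[[nd]]
    else rep(match(evidence[[nd]], net$states[[nd]]), nr)
  }
  p <- rep(1, nr)
  for (nd in net$nodes) {
    cpt <- net$cpts[[nd]]
    if (length(cpt$parents)) {
      pidx <- do.call(cbind, lapply(cpt$parents, state_idx))
      row <- cpt_row_index(cpt, pidx)
    } else {
      row <- rep(1L, nr)
    }
    p <- p * cpt$prob[cbind(row, state_idx(nd))]
  }
  list(free = free, grid = grid, p = p, z = sum(p))
}

#' Posterior by full-joint enumeration (testing oracle)
#'
#' Computes the same posterior as [infer_posterior()] by enumerating every
#' assignment of the non-evidence nodes and summing the joint
#' `prod(P(X | parents))` over all non-query variables. Exponential in the
#' number of nodes; intended as an independent correctness oracle.
#'
#' @inheritParams infer_posterior
#' @param cap Maximum number of enumerated assignments (error beyond it).
#' @return A `bn_posterior`.
#' @export
brute_force_posterior <- function(net, evidence = list(), query, cap = 1e8) {
  evidence <- check_evidence(net, evidence)
  if (!query %in% net$nodes) stop("unknown query node: ", query, call. = FALSE)
  if (query %in% names(evidence)) {
    p <- as.numeric(net$states[[query]] == evidence[[query]])
    return(structure(list(node = query, states = net$states[[query]], probabilities = p),
                     class = "bn_posterior"))
  }
  ej <- enum_joint(net, evidence, cap = cap)
  if (ej$z <= 0) {
    stop("impossible evidence: ",
         paste(sprintf("%s=%s", names(evidence), unlist(evidence)), collapse = ", "),
         call. = FALSE)
  }
  k <- length(net$states[[query]])
  tot <- vapply(seq_len(k), function(i) sum(ej$p[ej$grid[[query]] == i]), numeric(1))
  structure(list(node = query, states = net$states[[query]],
                 probabilities = tot / ej$z),
            class = "bn_posterior")
}

#' Log-likelihood of partially observed records
#'
#' Sums, over records, the log marginal probability of each record's
#' observed assignment (hidden and missing nodes marginalized out). Records
#' whose observations have probability zero contribute `-Inf` and are
#' flagged in the `impossible` attribute.
#'
#' @param net A `tnm_network`.
#' @param records List of named evidence lists (possibly empty lists).
#' @return Scalar log-likelihood with attribute `impossible` (record
#'   indices with zero-probability observations).
#' @export
joint_log_likelihood <- function(net, records) {
  ll <- vapply(records, function(ev) {
    z <- marginal_probability(net, ev)
    if (z <= 0) -Inf else log(z)
  }, numeric(1))
  out <- sum(ll)
  attr(out, "impossible") <- which(!is.finite(ll))
  out
}

#' Serialize a network to JSON
#'
#' Writes nodes, state spaces, parent sets and flattened CPTs (row-major:
#' each parent-state combination's probability vector is contiguous; rows in
#' mixed-radix little-endian parent order) with a schema version field.
#' Numbers are written at full precision so a read/write round trip
#' reproduces the network exactly.
#'
#' @param net A `tnm_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  doc <- list(
    schema_version = 1L,
    nodes = lapply(net$nodes, function(nd) {
      list(name = nd, states = net$states[[nd]], parents = net$parents[[nd]])
    }),
    cpts = lapply(net$nodes, function(nd) {
      cpt <- net$cpts[[nd]]
      list(node = nd, prob = as.numeric(t(cpt$prob)),
           never_observed = cpt$never_observed)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a network from JSON
#'
#' @param path File written by [write_network_json()].
#' @return A `tnm_network`.
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(doc$schema_version) || doc$schema_version != 1L) {
    stop("unsupported network schema version", call. = FALSE)
  }
  states <- list()
  parents <- list()
  for (nd in doc$nodes) {
    states[[nd$name]] <- as.character(nd$states)
    parents[[nd$name]] <- as.character(unlist(nd$parents))
  }
  net <- new_network(states, parents)
  for (entry in doc$cpts) {
    cpt <- net$cpts[[entry$node]]
    prob <- matrix(as.numeric(entry$prob), nrow = nrow(cpt$prob),
                   ncol = ncol(cpt$prob), byrow = TRUE)
    net$cpts[[entry$node]] <- new_cpt(entry$node, cpt$states, cpt$parents,
                                      cpt$parent_states, prob,
                                      as.logical(entry$never_observed))
  }
  net
}

# Replace one CPT's probability matrix, revalidating.
set_cpt_prob <- function(net, node, prob, never_observed = NULL) {
  cpt <- net$cpts[[node]]
  net$cpts[[node]] <- new_cpt(node, cpt$states, cpt$parents, cpt$parent_states,
                              prob, never_observed)
  net
}
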