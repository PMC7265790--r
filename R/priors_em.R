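# Cross-edition transition priors and expectation-maximization fitting.

HIDDEN_NODES <- c("T_7", "N_7", "M_7", "TNM_7")
OBSERVED_NODES <- c("edition", "T_567", "N_567", "M_567", "TNM_567", "death")

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Default cross-edition prior parameters
#'
#' Reads the versioned prior specification shipped with the package: the
#' descriptor-level changes between the 6th and 7th editions expressed as
#' conditional probabilities of the observed descriptor given the hidden
#' 7th-edition descriptor, for editions 5/6 (editions 5 and 6 share one
#' table because no descriptor definitions changed between them).
#' @return List with components `T` and `M` (named probability maps).
#' @export
default_prior_params <- function() {
  cached_json("transition_priors.json")[c("T", "M")]
}

prior_row <- function(child_states, mapping) {
  p <- rep(0, length(child_states))
  names(p) <- child_states
  for (tok in names(mapping)) {
    if (!tok %in% child_states) {
      stop("prior refers to unknown state: ", tok, call. = FALSE)
    }
    p[tok] <- as.numeric(mapping[[tok]])
  }
  if (abs(sum(p) - 1) > 1e-9) stop("prior row does not sum to 1", call. = FALSE)
  p
}

#' Manually specified cross-edition transition priors
#'
#' Builds the CPTs `P(T_567 | edition, T_7)`, `P(N_567 | edition, N_7)` and
#' `P(M_567 | edition, M_7)` that encode the descriptor changes between
#' editions. Rows for edition 7 are the identity (the observed descriptor
#' equals the hidden one). Editions 5 and 6 share one table: the hidden T3
#' row is split 50-50 between T2 and T3, hidden T1a/T1b collapse to T1,
#' T2a/T2b to T2, M1a/M1b map to M1 with probability 1, and the
#' multifocal-T4 ambiguity appears as a small T4-row spread and M0-row leak
#' (see the shipped `transition_priors.json`). The N table is the identity
#' for all editions.
#'
#' @param config Node state configuration, see [default_state_config()].
#' @param params Prior parameter maps, see [default_prior_params()].
#' @return Named list of `bn_cpt` objects for `T_567`, `N_567`, `M_567`.
#' @export
make_transition_priors <- function(config = default_state_config(),
                                   params = default_prior_params()) {
  build <- function(child, hidden, table56) {
    child_states <- config[[child]]
    parent_states <- list(edition = config[["edition"]])
    parent_states[[hidden]] <- config[[hidden]]
    template <- new_cpt(child, child_states, c("edition", hidden), parent_states)
    grid <- cpt_parent_grid(template)
    prob <- matrix(0, nrow = nrow(grid), ncol = length(child_states))
    for (i in seq_len(nrow(grid))) {
      h <- grid[[hidden]][i]
      prob[i, ] <- if (grid$edition[i] == "7") {
        as.numeric(child_states == h)
      } else {
        prior_row(child_states, table56[[h]])
      }
    }
    new_cpt(child, child_states, c("edition", hidden), parent_states, prob)
  }
  params_t <- params$T
  params_m <- params$M
  identity_map <- function(states) setNames(lapply(states, function(s) setNames(list(1), s)), states)
  priors <- list(
    T_567 = build("T_567", "T_7", params_t),
    N_567 = build("N_567", "N_7", identity_map(config$N_7)),
    M_567 = build("M_567", "M_7", params_m)
  )
  priors
}

# Set the transition-prior CPTs on a network.
apply_transition_priors <- function(net, priors) {
  for (nd in names(priors)) {
    cpt <- priors[[nd]]
    ref <- net$cpts[[nd]]
    if (!identical(cpt$states, ref$states) || !identical(cpt$parents, ref$parents)) {
      stop("transition prior for ", nd, " does not match the network state spaces",
           call. = FALSE)
    }
    net$cpts[[nd]] <- cpt
  }
  net
}

# Clamp TNM_7 and TNM_567 to the deterministic stage-grouping function.
clamp_stage_cpts <- function(net) {
  clamp <- function(node, stage_fun) {
    cpt <- net$cpts[[node]]
    grid <- cpt_parent_grid(cpt)
    prob <- matrix(0, nrow = nrow(grid), ncol = length(cpt$states))
    never <- rep(FALSE, nrow(grid))
    for (i in seq_len(nrow(grid))) {
      st <- stage_fun(grid[i, , drop = FALSE])
      j <- match(st, cpt$states)
      if (is.na(j)) {
        prob[i, ] <- 1 / length(cpt$states)
        never[i] <- TRUE
      } else {
        prob[i, j] <- 1
      }
    }
    set_cpt_prob(net, node, prob, never)
  }
  net <- clamp("TNM_7", function(g) {
    stage_group(g$T_7, g$N_7, g$M_7, "7")
  })
  net <- clamp("TNM_567", function(g) {
    ed <- g$edition
    voc <- tnm_vocabulary(ed)
    if (!g$T_567 %in% voc$t || !g$N_567 %in% voc$n || !g$M_567 %in% voc$m) {
      return(NA_character_)   # token illegal for this edition: unreachable row
    }
    stage_group(g$T_567, g$N_567, g$M_567, ed)
  })
  net
}

smoothed_freq <- function(values, states, pseudo_count) {
  counts <- table(factor(values, levels = states))
  as.numeric(counts + pseudo_count) / (sum(counts) + length(states) * pseudo_count)
}

#' Initialize hidden-node CPTs from 7th-edition records
#'
#' For 7th-edition records the observed descriptors equal the hidden ones,
#' so the hidden root CPTs (`T_7`, `N_7`, `M_7`) are set to smoothed
#' relative frequencies of the observed descriptors, the stage-group CPTs
#' are clamped to the deterministic grouping function (or estimated from
#' frequencies when `clamp_deterministic = FALSE`), and the survival CPT
#' `P(death | TNM_7)` is initialized from observed survival frequencies per
#' stage.
#'
#' @param net A `tnm_network` (typically fresh from [build_structure()]).
#' @param records_7 Data frame of 7th-edition records with columns
#'   `edition`, `t`, `n`, `m`, `stage`, `survival`.
#' @param pseudo_count Dirichlet smoothing weight added per state.
#' @param clamp_deterministic Clamp the stage CPTs to the grouping tables.
#' @return The updated network.
#' @export
init_hidden_cpts <- function(net, records_7, pseudo_count = 1,
                             clamp_deterministic = TRUE) {
  if (nrow(records_7) > 0 && any(as.character(records_7$edition) != "7")) {
    stop("init_hidden_cpts requires 7th-edition records only", call. = FALSE)
  }
  roots <- list(T_7 = records_7$t, N_7 = records_7$n, M_7 = records_7$m)
  for (nd in names(roots)) {
    vals <- as.character(roots[[nd]])
    bad <- setdiff(unique(vals), net$states[[nd]])
    if (length(bad)) {
      stop(sprintf("record value(s) outside the %s state space: %s", nd,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    net <- set_cpt_prob(net, nd, matrix(smoothed_freq(vals, net$states[[nd]], pseudo_count),
                                        nrow = 1))
  }
  # survival per 7th-edition stage
  death_states <- net$states[["death"]]
  stage_states <- net$states[["TNM_7"]]
  prob <- matrix(0, nrow = length(stage_states), ncol = length(death_states))
  never <- rep(FALSE, length(stage_states))
  for (i in seq_along(stage_states)) {
    sub <- records_7$survival[records_7$stage == stage_states[i] & !is.na(records_7$survival)]
    if (!length(sub) && pseudo_count == 0) {
      prob[i, ] <- 1 / length(death_states)
      never[i] <- TRUE
    } else {
      never[i] <- !length(sub)
      prob[i, ] <- smoothed_freq(sub, death_states, max(pseudo_count, if (!length(sub)) 1 else 0))
    }
  }
  net <- set_cpt_prob(net, "death", prob, never)
  if (clamp_deterministic) {
    net <- clamp_stage_cpts(net)
  } else if (nrow(records_7) > 0) {
    # frequency estimate of TNM_7 given descriptors (identity data)
    cpt <- net$cpts[["TNM_7"]]
    grid <- cpt_parent_grid(cpt)
    prob <- matrix(0, nrow = nrow(grid), ncol = length(cpt$states))
    never <- rep(FALSE, nrow(grid))
    key_rec <- paste(records_7$t, records_7$n, records_7$m)
    for (i in seq_len(nrow(grid))) {
      sub <- records_7$stage[key_rec == paste(grid$T_7[i], grid$N_7[i], grid$M_7[i])]
      never[i] <- !length(sub)
      prob[i, ] <- smoothed_freq(sub, cpt$states, max(pseudo_count, if (!length(sub)) 1 else 0))
    }
    net <- set_cpt_prob(net, "TNM_7", prob, never)
  }
  net
}

#' Resample training records to a fixed size per edition
#'
#' Draws, with replacement, `n_per_edition` records for each TNM edition so
#' the unequal edition mix of a registry does not dominate learning.
#'
#' @param records Data frame with an `edition` column.
#' @param n_per_edition Records drawn per edition (default 45000).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param editions Editions to resample (default all three).
#' @return Data frame with exactly `n_per_edition` rows per edition.
#' @export
resample_training <- function(records, n_per_edition = 45000, seed,
                              editions = c("5", "6", "7")) {
  ed <- as.character(records$edition)
  empty <- editions[!editions %in% ed]
  if (length(empty)) {
    stop("no records to resample for edition(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    out <- lapply(editions, function(e) {
      idx <- which(ed == e)
      records[sample(idx, n_per_edition, replace = TRUE), , drop = FALSE]
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' EM configuration
#'
#' @param max_iterations Maximum EM iterations.
#' @param tolerance Stop when the total log-likelihood improves by less
#'   than this.
#' @param pseudo_count Dirichlet smoothing weight added per CPT cell in the
#'   M-step.
#' @param clamp_deterministic Keep the stage-group CPTs fixed at the
#'   grouping tables (stage grouping is definitional).
#' @param prior_strength Weight with which the transition priors enter the
#'   M-step as Dirichlet pseudo-counts (0 = priors are initialization only).
#' @param tie_editions_56 Pool the edition-5 and edition-6 rows of the
#'   conversion CPTs in the M-step. No descriptor definitions changed
#'   between those editions, so their conversions from the hidden
#'   7th-edition state are one mapping; tying the rows estimates it from
#'   the combined subsamples.
#' @param seed Optional integer seed (EM itself is deterministic; kept for
#'   interface uniformity).
#' @return List of class `em_config`.
#' @export
em_config <- function(max_iterations = 200, tolerance = 1e-4, pseudo_count = 1,
                      clamp_deterministic = TRUE, prior_strength = 0,
                      tie_editions_56 = TRUE, seed = NULL) {
  stopifnot(max_iterations >= 1, tolerance > 0, pseudo_count >= 0, prior_strength >= 0)
  structure(list(max_iterations = as.integer(max_iterations), tolerance = tolerance,
                 pseudo_count = pseudo_count, clamp_deterministic = clamp_deterministic,
                 prior_strength = prior_strength,
                 tie_editions_56 = isTRUE(tie_editions_56), seed = seed),
            class = "em_config")
}

records_to_evidence <- function(records, net) {
  ev_cols <- c(edition = "edition", T_567 = "t", N_567 = "n", M_567 = "m",
               TNM_567 = "stage", death = "survival")
  lapply(seq_len(nrow(records)), function(i) {
    ev <- list()
    for (nd in names(ev_cols)) {
      v <- as.character(records[[ev_cols[[nd]]]][i])
      if (!is.na(v)) ev[[nd]] <- v
    }
    ev
  })
}

#' Fit the network CPTs by expectation-maximization
#'
#' Records observe `edition`, `T_567`, `N_567`, `M_567`, `TNM_567` and
#' (possibly missing) `death`; the 7th-edition nodes are hidden and
#' marginalized exactly in the E-step. The transition priors are the
#' iteration-0 values of the cross-edition CPTs. The E-step groups records
#' by their observed-assignment tuple (registry rows repeat heavily), a
#' pure optimization that leaves the expected sufficient statistics exact.
#' The per-iteration log-likelihood trace is non-decreasing (EM guarantee).
#'
#' @param net A `tnm_network`, typically after [init_hidden_cpts()].
#' @param records Data frame with columns `edition`, `t`, `n`, `m`,
#'   `stage`, `survival` (NA = missing). Records whose observed values fall
#'   outside the network state spaces (e.g. stage `UNKNOWN`) are dropped
#'   with a message.
#' @param priors Transition priors from [make_transition_priors()].
#' @param config An [em_config()].
#' @param engine `"auto"` uses a specialized E-step that exploits the fixed
#'   topology and clamped stage CPTs when possible, `"generic"` forces the
#'   factor-algebra path. Both compute identical expected sufficient
#'   statistics (an exactness contract checked in the test suite).
#' @return List with elements `network` (fitted), `diagnostics` (data frame
#'   with `iteration`, `log_likelihood`, `max_cpt_delta`), and `converged`.
#' @export
em_fit <- function(net, records, priors = make_transition_priors(),
                   config = em_config(), engine = c("auto", "generic")) {
  engine <- match.arg(engine)
  hidden_seen <- intersect(names(records), HIDDEN_NODES)
  if (length(hidden_seen)) {
    stop("training records must not observe hidden node(s): ",
         paste(hidden_seen, collapse = ", "), call. = FALSE)
  }
  net <- apply_transition_priors(net, priors)
  clamped <- if (config$clamp_deterministic) {
    net <- clamp_stage_cpts(net)
    c("TNM_7", "TNM_567")
  } else {
    character(0)
  }

  # drop records outside the state spaces
  ok <- as.character(records$edition) %in% net$states$edition &
    as.character(records$t) %in% net$states$T_567 &
    as.character(records$n) %in% net$states$N_567 &
    as.character(records$m) %in% net$states$M_567 &
    as.character(records$stage) %in% net$states$TNM_567 &
    (is.na(records$survival) | as.character(records$survival) %in% net$states$death)
  if (any(!ok)) {
    message(sum(!ok), " record(s) outside the network state spaces dropped before EM")
    records <- records[ok, , drop = FALSE]
  }
  if (!nrow(records)) stop("no usable training records", call. = FALSE)

  # group by distinct observed tuple
  key <- paste(records$edition, records$t, records$n, records$m, records$stage,
               ifelse(is.na(records$survival), "<NA>", records$survival), sep = "\r")
  tab <- table(key)
  first <- records[match(names(tab), key), , drop = FALSE]
  weights <- as.numeric(tab)
  tuples <- records_to_evidence(first, net)

  # Dirichlet pseudo-counts from the priors, if requested
  prior_counts <- if (config$prior_strength > 0) {
    lapply(priors, function(cpt) config$prior_strength * cpt$prob)
  } else {
    NULL
  }

  # Support masks: cells that are exactly zero at iteration 0 encode
  # structural constraints (edition vocabularies, identity rows) and stay
  # zero; Dirichlet smoothing is applied within the support only, so EM
  # keeps the zeros it would preserve without smoothing.
  support <- lapply(net$cpts, function(cpt) cpt$prob > 0)

  free_nodes <- lapply(tuples, function(ev) setdiff(net$nodes, names(ev)))
  ll_trace <- numeric(0)
  delta_trace <- numeric(0)
  converged <- FALSE

  use_fast <- engine == "auto" && config$clamp_deterministic &&
    identical(net$parents, TNM_PARENTS[net$nodes]) &&
    all(apply(net$cpts$TNM_7$prob, 1, max) == 1)
  fast <- if (use_fast) fast_estep_setup(net, first) else NULL

  for (iter in seq_len(config$max_iterations)) {
    counts <- lapply(net$nodes, function(nd) {
      cpt <- net$cpts[[nd]]
      dims <- c(length(cpt$states), vapply(cpt$parent_states, length, integer(1)))
      array(0, dim = dims)
    })
    names(counts) <- net$nodes
    ll <- 0

    if (use_fast) {
      es <- fast_estep(net, fast, weights, counts)
      counts <- es$counts
      ll <- es$ll
    } else {
      base <- lapply(net$cpts, cpt_as_factor)
      for (ti in seq_along(tuples)) {
        ev <- tuples[[ti]]
        w <- weights[ti]
        free <- free_nodes[[ti]]
        fs <- lapply(base, function(f) {
          for (nd in intersect(names(ev), factor_vars(f))) f <- factor_reduce(f, nd, ev[[nd]])
          f
        })
        jp <- ve_eliminate(fs, keep = free)
        z <- if (is.array(jp)) sum(jp) else as.numeric(jp)
        if (!is.finite(z) || z <= 0) {
          stop("record tuple ", ti, " has zero probability under the current model",
               call. = FALSE)
        }
        ll <- ll + w * log(z)
        if (is.array(jp)) jp <- jp / z
        for (nd in setdiff(net$nodes, clamped)) {
          fam <- c(nd, net$parents[[nd]])
          free_f <- intersect(free, fam)
          sub <- if (length(free_f)) {
            marg <- factor_marginalize(jp, setdiff(factor_vars(jp), free_f))
            if (is.array(marg)) aperm(marg, match(intersect(fam, free_f), factor_vars(marg)))
            else marg
          } else {
            1
          }
          idx <- lapply(fam, function(v) {
            if (v %in% names(ev)) match(ev[[v]], net$states[[v]]) else TRUE
          })
          cur <- do.call(`[`, c(list(counts[[nd]]), idx))
          counts[[nd]] <- do.call(`[<-`, c(list(counts[[nd]]), idx,
                                           list(cur + w * as.numeric(sub))))
        }
      }
    }

    # M-step
    old_probs <- lapply(net$cpts, function(cpt) cpt$prob)
    for (nd in setdiff(net$nodes, clamped)) {
      k <- length(net$cpts[[nd]]$states)
      raw <- t(matrix(as.numeric(counts[[nd]]), nrow = k))
      if (!is.null(prior_counts[[nd]])) raw <- raw + prior_counts[[nd]]
      if (config$tie_editions_56 && nd %in% c("T_567", "N_567", "M_567")) {
        # one shared conversion per hidden state for editions 5 and 6: pool
        # the expected counts before smoothing so the tied M-step maximizes
        # a single penalized objective
        g <- cpt_parent_grid(net$cpts[[nd]])
        if (all(c("5", "6") %in% g$edition)) {
          hidden <- net$parents[[nd]][2]
          for (h in unique(g[[hidden]])) {
            r5 <- which(g$edition == "5" & g[[hidden]] == h)
            r6 <- which(g$edition == "6" & g[[hidden]] == h)
            pooled <- raw[r5, ] + raw[r6, ]
            raw[r5, ] <- pooled
            raw[r6, ] <- pooled
          }
        }
      }
      sup <- support[[nd]]
      raw <- (raw + config$pseudo_count) * sup
      never <- rowSums(raw) <= 0
      prob <- raw
      prob[never, ] <- 1 / k
      tot <- rowSums(prob)
      prob <- prob / tot
      net <- set_cpt_prob(net, nd, prob, never)
    }
    delta <- max(vapply(net$nodes, function(nd) {
      max(abs(net$cpts[[nd]]$prob - old_probs[[nd]]))
    }, numeric(1)))

    ll_trace <- c(ll_trace, ll)
    delta_trace <- c(delta_trace, delta)
    if (iter >= 2 && (ll - ll_trace[iter - 1]) < config$tolerance) {
      converged <- TRUE
      break
    }
  }

  list(network = net,
       diagnostics = data.frame(iteration = seq_along(ll_trace),
                                log_likelihood = ll_trace,
                                max_cpt_delta = delta_trace),
       converged = converged)
}

# Precomputed index structures for the specialized E-step. Valid when the
# stage CPTs are clamped deterministic on the fixed ten-node topology: the
# hidden joint then factorizes as
#   P(T_7, N_7, M_7 | ev) propto a_T(T_7) a_N(N_7) a_M(M_7) d(stage7(T,N,M))
# with a_X(h) = P(h) P(x_obs | edition, h) and d the (possibly marginal)
# survival term.
fast_estep_setup <- function(net, first) {
  st <- net$states
  e <- match(as.character(first$edition), st$edition)
  t_col <- match(as.character(first$t), st$T_567)
  n_col <- match(as.character(first$n), st$N_567)
  m_col <- match(as.character(first$m), st$M_567)
  s_col <- match(as.character(first$stage), st$TNM_567)
  d_col <- match(as.character(first$survival), st$death)
  d_col[is.na(d_col)] <- 0L
  ne <- length(st$edition)
  # transition CPT row indices (edition varies fastest)
  rowsT <- outer(ne * (seq_along(st$T_7) - 1L), e, `+`)
  rowsN <- outer(ne * (seq_along(st$N_7) - 1L), e, `+`)
  rowsM <- outer(ne * (seq_along(st$M_7) - 1L), e, `+`)
  # TNM_567 CPT row index for the observed (edition, T, N, M)
  d567 <- c(ne, length(st$T_567), length(st$N_567))
  row567 <- e + d567[1] * (t_col - 1L) + d567[1] * d567[2] * (n_col - 1L) +
    d567[1] * d567[2] * d567[3] * (m_col - 1L)
  # deterministic 7th-edition stage per hidden combo (T fastest)
  grid <- expand.grid(T_7 = st$T_7, N_7 = st$N_7, M_7 = st$M_7,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  s7 <- match(stage_group(grid$T_7, grid$N_7, grid$M_7, "7"), st$TNM_7)
  S <- matrix(0, nrow = length(st$TNM_7), ncol = nrow(grid))
  S[cbind(s7, seq_len(nrow(grid)))] <- 1
  list(e = e, t_col = t_col, n_col = n_col, m_col = m_col, s_col = s_col,
       d_col = d_col, rowsT = rowsT, rowsN = rowsN, rowsM = rowsM,
       row567 = row567, s7 = s7, S = S,
       kT = length(st$T_7), kN = length(st$N_7), kM = length(st$M_7))
}

fast_estep <- function(net, fast, weights, counts) {
  pT <- net$cpts$T_7$prob[1, ]
  pN <- net$cpts$N_7$prob[1, ]
  pM <- net$cpts$M_7$prob[1, ]
  pE <- net$cpts$edition$prob[1, ]
  Tp <- net$cpts$T_567$prob
  Np <- net$cpts$N_567$prob
  Mp <- net$cpts$M_567$prob
  Dp <- net$cpts$death$prob
  Sp <- net$cpts$TNM_567$prob
  ones <- rep(1, nrow(Dp))
  ll <- 0
  for (i in seq_along(weights)) {
    w <- weights[i]
    aT <- pT * Tp[fast$rowsT[, i], fast$t_col[i]]
    aN <- pN * Np[fast$rowsN[, i], fast$n_col[i]]
    aM <- pM * Mp[fast$rowsM[, i], fast$m_col[i]]
    g567 <- Sp[fast$row567[i], fast$s_col[i]]
    d <- fast$d_col[i]
    dvec <- if (d > 0L) Dp[, d] else ones
    jf <- as.numeric(outer(outer(aT, aN), aM)) * dvec[fast$s7]
    z0 <- sum(jf)
    if (!is.finite(z0) || z0 <= 0 || g567 <= 0) {
      stop("record tuple ", i, " has zero probability under the current model",
           call. = FALSE)
    }
    ll <- ll + w * log(z0 * g567 * pE[fast$e[i]])
    jf <- jf / z0
    margT <- rowSums(matrix(jf, fast$kT))
    margN <- rowSums(matrix(colSums(matrix(jf, fast$kT)), fast$kN))
    margM <- colSums(matrix(jf, fast$kT * fast$kN))
    margS <- as.numeric(fast$S %*% jf)
    e <- fast$e[i]
    counts$T_7 <- counts$T_7 + w * margT
    counts$N_7 <- counts$N_7 + w * margN
    counts$M_7 <- counts$M_7 + w * margM
    counts$edition[e] <- counts$edition[e] + w
    counts$T_567[fast$t_col[i], e, ] <- counts$T_567[fast$t_col[i], e, ] + w * margT
    counts$N_567[fast$n_col[i], e, ] <- counts$N_567[fast$n_col[i], e, ] + w * margN
    counts$M_567[fast$m_col[i], e, ] <- counts$M_567[fast$m_col[i], e, ] + w * margM
    if (d > 0L) {
      counts$death[d, ] <- counts$death[d, ] + w * margS
    } else {
      counts$death <- counts$death + w * t(Dp * margS)
    }
  }
  list(counts = counts, ll = ll)
}
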