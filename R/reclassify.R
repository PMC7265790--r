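# High-level queries: probabilistic cross-edition stage reclassification
# and multiclass survival prediction.

#' Point prediction from a posterior
#'
#' Selects the state with the highest posterior probability. Ties (within
#' `tol`) are broken deterministically by configured state order: the first
#' state attaining the maximum wins, and `tie_flag` is set.
#'
#' @param posterior A `bn_posterior` (or a bare named probability vector).
#' @param tol Absolute tolerance within which two probabilities count as
#'   tied.
#' @return List with `state` and `tie_flag`.
#' @export
argmax_predict <- function(posterior, tol = 1e-12) {
  if (inherits(posterior, "bn_posterior")) {
    p <- posterior$probabilities
    states <- posterior$states
  } else {
    p <- as.numeric(posterior)
    states <- names(posterior)
    if (is.null(states)) stop("posterior must be named or a bn_posterior", call. = FALSE)
  }
  mx <- max(p)
  hits <- which(p >= mx - tol)
  list(state = states[hits[1]], tie_flag = length(hits) > 1L)
}

source_evidence <- function(net, t, n, m, source_edition) {
  source_edition <- check_edition(source_edition)
  if (source_edition == "7") {
    ev <- list(T_7 = t, N_7 = n, M_7 = m)
    bad <- c(!t %in% net$states$T_7, !n %in% net$states$N_7, !m %in% net$states$M_7)
    if (any(bad)) {
      stop(sprintf("(%s, %s, %s) contains token(s) outside the hidden 7th-edition state space%s",
                   t, n, m,
                   if (t %in% c("T1", "T2")) " (bare T1/T2 must be refined to a/b substages)" else ""),
           call. = FALSE)
    }
    ev
  } else {
    voc <- tnm_vocabulary(source_edition)
    if (!t %in% voc$t || !n %in% voc$n || !m %in% voc$m) {
      stop(sprintf("(%s, %s, %s) is not a valid edition-%s descriptor triple",
                   t, n, m, source_edition), call. = FALSE)
    }
    if (!t %in% net$states$T_567 || !n %in% net$states$N_567 || !m %in% net$states$M_567) {
      stop(sprintf("(%s, %s, %s) contains token(s) outside the network state space", t, n, m),
           call. = FALSE)
    }
    list(edition = source_edition, T_567 = t, N_567 = n, M_567 = m)
  }
}

#' Probabilistic cross-edition stage reclassification
#'
#' Expresses a tumor staged under one TNM edition in the stage groups of
#' another edition, as a full posterior distribution (a weighted
#' reclassification) plus a point prediction.
#'
#' For a 7th-edition source the default recipe sets evidence directly on
#' the hidden nodes `T_7`/`N_7`/`M_7` together with `edition =
#' target_edition`, and queries `TNM_567`. For a 5th/6th-edition source,
#' evidence goes on `edition = source` and the observed descriptor nodes,
#' and `TNM_7` is queried (the target must then be edition 7; reclassifying
#' between editions 5 and 6 is the identity because their grouping tables
#' are identical). The alternative `recipe = "observed"` enters 7th-edition
#' descriptors through the observed nodes with `edition = 7`, infers the
#' hidden-descriptor posterior, and mixes target-edition queries over it;
#' with identity edition-7 conversion rows the two recipes coincide.
#'
#' @param net A fitted `tnm_network`.
#' @param t,n,m Descriptor tokens of the source edition.
#' @param source_edition,target_edition Editions (`"5"`, `"6"`, `"7"`).
#' @param recipe Evidence recipe for 7th-edition sources, see Details.
#' @return A `tnm_reclassification`: list with `target_edition`,
#'   `posterior` (a `bn_posterior` over stage groups), `point_prediction`,
#'   `tie_flag`.
#' @export
reclassify_stage <- function(net, t, n, m, source_edition, target_edition,
                             recipe = c("hidden", "observed")) {
  recipe <- match.arg(recipe)
  source_edition <- check_edition(source_edition)
  target_edition <- check_edition(target_edition)
  if (source_edition != "7" && target_edition != "7") {
    # editions 5 and 6 share one grouping table: deterministic identity
    st <- stage_group(t, n, m, source_edition)
    states <- net$states$TNM_567
    if (!st %in% states) {
      stop(sprintf("stage group '%s' is outside the network state space", st), call. = FALSE)
    }
    post <- structure(list(node = "TNM_567", states = states,
                           probabilities = as.numeric(states == st)),
                      class = "bn_posterior")
  } else if (source_edition == "7") {
    ev <- source_evidence(net, t, n, m, "7")
    if (target_edition == "7") {
      query <- "TNM_7"
      post <- infer_posterior(net, ev, query)
    } else if (recipe == "hidden") {
      ev$edition <- target_edition
      post <- infer_posterior(net, ev, "TNM_567")
    } else {
      # observed recipe: posterior over hidden descriptors given the
      # 7th-edition observation, then mix target-edition stage queries
      obs_ev <- list(edition = "7", T_567 = t, N_567 = n, M_567 = m)
      w <- infer_joint(net, obs_ev, c("T_7", "N_7", "M_7"))
      states <- net$states$TNM_567
      acc <- numeric(length(states))
      nz <- which(w > 0, arr.ind = TRUE)
      for (r in seq_len(nrow(nz))) {
        hev <- list(edition = target_edition,
                    T_7 = dimnames(w)[[1]][nz[r, 1]],
                    N_7 = dimnames(w)[[2]][nz[r, 2]],
                    M_7 = dimnames(w)[[3]][nz[r, 3]])
        acc <- acc + w[nz[r, , drop = FALSE]] *
          infer_posterior(net, hev, "TNM_567")$probabilities
      }
      post <- structure(list(node = "TNM_567", states = states,
                             probabilities = acc / sum(acc)),
                        class = "bn_posterior")
    }
  } else {
    if (target_edition != "7") stop("unreachable", call. = FALSE)
    ev <- source_evidence(net, t, n, m, source_edition)
    post <- infer_posterior(net, ev, "TNM_7")
  }
  am <- argmax_predict(post)
  structure(list(target_edition = target_edition, posterior = post,
                 point_prediction = am$state, tie_flag = am$tie_flag),
            class = "tnm_reclassification")
}

#' @export
print.tnm_reclassification <- function(x, digits = 4, ...) {
  cat(sprintf("Reclassification to edition %s: %s%s\n", x$target_edition,
              x$point_prediction, if (x$tie_flag) " (tie)" else ""))
  print(round(stats::setNames(x$posterior$probabilities, x$posterior$states), digits))
  invisible(x)
}

#' Multiclass survival prediction
#'
#' Full five-category posterior over survival since diagnosis, given a
#' descriptor triple from any edition. Evidence follows the
#' [reclassify_stage()] conventions (hidden nodes for 7th-edition sources,
#' observed nodes plus the edition for 5th/6th-edition sources); the
#' `death` node is queried.
#'
#' @inheritParams reclassify_stage
#' @param edition Source edition of the descriptors.
#' @return A `bn_posterior` over the survival categories.
#' @export
predict_survival <- function(net, t, n, m, edition) {
  ev <- source_evidence(net, t, n, m, edition)
  infer_posterior(net, ev, "death")
}

#' Batch reclassification of a record table
#'
#' Applies [reclassify_stage()] to every row and returns one probability
#' column per target-edition stage group plus the point prediction and tie
#' flag.
#'
#' @param net A fitted `tnm_network`.
#' @param records Data frame with columns `t`, `n`, `m`, `edition`.
#' @param target_edition Target TNM edition.
#' @param recipe Evidence recipe, see [reclassify_stage()].
#' @return Data frame with columns `p_<stage>`, `point_prediction`,
#'   `tie_flag`.
#' @export
reclassify_batch <- function(net, records, target_edition,
                             recipe = c("hidden", "observed")) {
  recipe <- match.arg(recipe)
  stages <- if (check_edition(target_edition) == "7") net$states$TNM_7 else net$states$TNM_567
  key <- paste(records$edition, records$t, records$n, records$m)
  uniq <- !duplicated(key)
  cache <- new.env(parent = emptyenv())
  for (i in which(uniq)) {
    res <- reclassify_stage(net, as.character(records$t[i]), as.character(records$n[i]),
                            as.character(records$m[i]), as.character(records$edition[i]),
                            target_edition, recipe)
    assign(key[i], res, envir = cache)
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    res <- get(key[i], envir = cache)
    p <- stats::setNames(res$posterior$probabilities, res$posterior$states)[stages]
    c(as.list(p), list(point_prediction = res$point_prediction, tie_flag = res$tie_flag))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  names(out) <- c(paste0("p_", stages), "point_prediction", "tie_flag")
  rownames(out) <- NULL
  out
}
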