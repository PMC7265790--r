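# Confusion matrices, macro/micro multiclass metrics, the worst-case
# ambiguity adjustment, ROC-AUC, and probability calibration.

#' Multiclass confusion matrix
#'
#' @param truth,predicted Equal-length label vectors.
#' @param labels Ordered class labels (all values of `truth` and
#'   `predicted` must occur in it).
#' @return Integer matrix of class `confusion_matrix`; rows are truth,
#'   columns are predictions.
#' @export
confusion_matrix <- function(truth, predicted, labels = sort(unique(c(truth, predicted)))) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have the same length", call. = FALSE)
  }
  unknown <- setdiff(unique(c(truth, predicted)), labels)
  if (length(unknown)) {
    stop("label(s) not in the class list: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cm <- table(factor(truth, levels = labels), factor(predicted, levels = labels))
  out <- matrix(as.integer(cm), nrow = length(labels),
                dimnames = list(truth = labels, predicted = labels))
  class(out) <- c("confusion_matrix", "matrix")
  out
}

#' Macro- and micro-averaged multiclass metrics
#'
#' Per class (one-vs-rest): sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP). Macro averages are unweighted means over classes; classes
#' with no truth instances have undefined sensitivity and are excluded
#' from the macro mean (with a warning, and listed in `excluded_classes`).
#' Micro averages pool the one-vs-rest TP/FP/TN/FN counts before computing
#' the metric; micro-averaged sensitivity then equals overall accuracy
#' (trace/total), which is also reported, together with the mean of the
#' per-class one-vs-rest accuracies (`mean_class_accuracy`), since both
#' averaging conventions are in circulation.
#'
#' @param cm A `confusion_matrix`.
#' @return List of class `metric_set`: `per_class` (data frame),
#'   `macro_sensitivity`, `micro_sensitivity`, `macro_specificity`,
#'   `micro_specificity`, `accuracy`, `mean_class_accuracy`,
#'   `excluded_classes`.
#' @export
aggregate_metrics <- function(cm) {
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  labels <- rownames(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  class_acc <- (tp + tn) / n
  excluded <- labels[is.na(sens)]
  if (length(excluded)) {
    warning("class(es) without truth instances excluded from macro averages: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  structure(list(
    per_class = data.frame(class = labels, tp = as.integer(tp), fp = as.integer(fp),
                           tn = as.integer(tn), fn = as.integer(fn),
                           sensitivity = sens, specificity = spec,
                           accuracy = class_acc, stringsAsFactors = FALSE,
                           row.names = NULL),
    macro_sensitivity = mean(sens, na.rm = TRUE),
    micro_sensitivity = sum(tp) / sum(tp + fn),
    macro_specificity = mean(spec, na.rm = TRUE),
    micro_specificity = sum(tn) / sum(tn + fp),
    accuracy = sum(tp) / n,
    mean_class_accuracy = mean(class_acc),
    excluded_classes = excluded
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 4, ...) {
  cat("Multiclass metrics:\n")
  cat(sprintf("  accuracy            %.*f\n", digits, x$accuracy))
  cat(sprintf("  macro sensitivity   %.*f   micro sensitivity   %.*f\n",
              digits, x$macro_sensitivity, digits, x$micro_sensitivity))
  cat(sprintf("  macro specificity   %.*f   micro specificity   %.*f\n",
              digits, x$macro_specificity, digits, x$micro_specificity))
  invisible(x)
}

#' Worst-case adjustment for ambiguous ground truth
#'
#' Records whose rule-based ground truth is a two-candidate stage range
#' cannot be scored normally. The worst-case construction adds each such
#' record to the confusion matrix with the truth candidate that makes the
#' prediction wrong: if the prediction matches one candidate, the other
#' candidate is chosen; if it matches neither, the first candidate in the
#' label order of `cm` is used. The off-diagonal (error) total can only
#' grow; with no ambiguous records the matrix is returned unchanged.
#'
#' @param cm A `confusion_matrix`.
#' @param ambiguous Data frame with columns `candidate1`, `candidate2`
#'   (the two truth candidates) and `predicted`; zero rows allowed.
#' @return The adjusted `confusion_matrix`.
#' @export
worst_case_adjustment <- function(cm, ambiguous) {
  if (is.null(ambiguous) || nrow(ambiguous) == 0) return(cm)
  need <- c("candidate1", "candidate2", "predicted")
  if (!all(need %in% names(ambiguous))) {
    stop("ambiguous must have columns candidate1, candidate2, predicted", call. = FALSE)
  }
  labels <- rownames(cm)
  for (i in seq_len(nrow(ambiguous))) {
    cand <- as.character(c(ambiguous$candidate1[i], ambiguous$candidate2[i]))
    pred <- as.character(ambiguous$predicted[i])
    if (length(unique(cand)) != 2L) {
      stop("ambiguous record ", i, " must have exactly 2 distinct truth candidates",
           call. = FALSE)
    }
    if (!all(c(cand, pred) %in% labels)) {
      stop("ambiguous record ", i, " uses label(s) outside the confusion matrix",
           call. = FALSE)
    }
    # order candidates by the matrix label order, then pick the first that
    # differs from the prediction
    cand <- cand[order(match(cand, labels))]
    truth <- if (pred == cand[1]) cand[2] else cand[1]
    cm[truth, pred] <- cm[truth, pred] + 1L
  }
  cm
}

#' ROC area under the curve by the rank statistic
#'
#' Computes AUC as the Mann-Whitney U statistic with midranks for ties:
#' the probability that a randomly chosen positive scores above a randomly
#' chosen negative (ties counting one half). Invariant under strictly
#' monotone transformations of the scores.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (logical, or coercible 0/1).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc_binary <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop("scores and labels must be equal-length and free of missing values",
         call. = FALSE)
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)   # midranks for ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration points per input subpopulation
#'
#' Each unique combination of observed inputs (edition, T_567, N_567,
#' M_567, TNM_567) defines a subpopulation. For each, the predicted
#' probability of the given survival category is compared with its observed
#' frequency; the subpopulation size drives the bubble size in a
#' calibration bubble plot. Records with missing survival are not
#' evaluable and are dropped.
#'
#' @param net A fitted `tnm_network`.
#' @param records Data frame with columns `edition`, `t`, `n`, `m`,
#'   `stage`, `survival`.
#' @param category Survival category label whose probability is assessed
#'   (default: the top, >= 24 months, category).
#' @return Data frame with columns `edition`, `t`, `n`, `m`, `stage`,
#'   `predicted`, `observed`, `size`.
#' @export
calibration_points <- function(net, records, category = NULL) {
  if (is.null(category)) category <- net$states$death[length(net$states$death)]
  if (!category %in% net$states$death) {
    stop("unknown survival category: ", category, call. = FALSE)
  }
  records <- records[!is.na(records$survival), , drop = FALSE]
  if (!nrow(records)) stop("no evaluable records (all survival missing)", call. = FALSE)
  key <- paste(records$edition, records$t, records$n, records$m, records$stage, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(idx, function(ii) {
    i <- ii[1]
    ev <- list(edition = as.character(records$edition[i]),
               T_567 = as.character(records$t[i]),
               N_567 = as.character(records$n[i]),
               M_567 = as.character(records$m[i]),
               TNM_567 = as.character(records$stage[i]))
    post <- infer_posterior(net, ev, "death")
    data.frame(edition = ev$edition, t = ev$T_567, n = ev$N_567, m = ev$M_567,
               stage = ev$TNM_567,
               predicted = post$probabilities[match(category, post$states)],
               observed = mean(records$survival[ii] == category),
               size = length(ii),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quantile-binned calibration curve
#'
#' Sorts prediction/outcome pairs by predicted probability (stable sort:
#' ties stay in input order), partitions them into contiguous bins of
#' `samples_per_bin` pairs (the last bin may be smaller), and returns
#' per-bin means. With 21,000 pairs and 1,000 samples per bin this yields
#' the 21-bin curve layout.
#'
#' @param predicted Predicted probabilities.
#' @param observed Binary outcomes (logical or 0/1).
#' @param samples_per_bin Pairs per bin (>= 1).
#' @return Data frame with columns `mean_predicted`, `mean_observed`, `n`.
#' @export
calibration_curve <- function(predicted, observed, samples_per_bin = 1000) {
  observed <- as.numeric(observed)
  if (!length(predicted)) stop("empty input", call. = FALSE)
  if (length(predicted) != length(observed)) stop("length mismatch", call. = FALSE)
  if (samples_per_bin < 1) stop("samples_per_bin must be >= 1", call. = FALSE)
  ord <- order(predicted)   # radix sort: stable for ties
  p <- predicted[ord]
  y <- observed[ord]
  n <- length(p)
  bin <- ceiling(seq_len(n) / samples_per_bin)
  data.frame(
    mean_predicted = as.numeric(tapply(p, bin, mean)),
    mean_observed = as.numeric(tapply(y, bin, mean)),
    n = as.integer(tapply(y, bin, length)),
    row.names = NULL
  )
}
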