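#' Build a predicted-by-observed confusion matrix
#'
#' Rows are predicted compartments plus an explicit `"None"` row, columns
#' are observed compartments. Every observed annotation of every evaluated
#' protein contributes total mass exactly 1 to its column: to the diagonal
#' when the label was predicted; to the `"None"` row when nothing was
#' predicted; otherwise to the top-scoring predicted row (default) or
#' spread as `1/|P|` over all predicted rows (`attribution = "fractional"`).
#' Column sums therefore equal the per-class observed annotation counts,
#' and a protein annotated in several compartments is counted once per
#' annotation.
#'
#' @param observed An `snl_annotations` with labels for every evaluated id.
#' @param predictions List of `snl_prediction`.
#' @param attribution `"top-score"` or `"fractional"` handling of missed
#'   observed labels under multi-label predictions. Predictions without
#'   stored scores (e.g. homology transfers) use the first predicted label
#'   in vocabulary order as "top".
#' @param labels Label vocabulary (defaults to the 13 compartments).
#' @return Numeric `(length(labels) + 1) x length(labels)` matrix of class
#'   counts, with a final `"None"` row.
#' @export
build_confusion <- function(observed, predictions,
                            attribution = c("top-score", "fractional"),
                            labels = subnuclear_compartments()) {
  attribution <- match.arg(attribution)
  conf <- matrix(0, length(labels) + 1L, length(labels),
                 dimnames = list(c(labels, "None"), labels))
  for (p in predictions) {
    obs <- observed$labels[[p$protein]]
    if (is.null(obs)) {
      stop("prediction for protein without observed annotation: ", p$protein)
    }
    pred <- p$labels
    for (c_obs in obs) {
      if (c_obs %in% pred) {
        conf[c_obs, c_obs] <- conf[c_obs, c_obs] + 1
      } else if (length(pred) == 0L) {
        conf["None", c_obs] <- conf["None", c_obs] + 1
      } else if (attribution == "fractional") {
        conf[pred, c_obs] <- conf[pred, c_obs] + 1 / length(pred)
      } else {
        top <- if (!is.null(p$scores)) {
          pred[which.max(p$scores[pred])]
        } else {
          pred[order(match(pred, labels))][1L]
        }
        conf[top, c_obs] <- conf[top, c_obs] + 1
      }
    }
  }
  conf
}

#' Overall accuracy Q(n) from a confusion matrix
#'
#' 100 times the total diagonal (correctly predicted annotations) over the
#' total number of observed annotations. With multi-label proteins counted
#' once per annotation, the denominator is the annotation count, not the
#' protein count.
#'
#' @param confusion Matrix from [build_confusion()] (or any matrix whose
#'   first `ncol` rows align with its columns).
#' @return Accuracy in percent.
#' @export
q_n <- function(confusion) {
  total <- sum(confusion)
  if (!is.matrix(confusion) || ncol(confusion) == 0L || total <= 0) {
    stop("confusion matrix is empty")
  }
  d <- sum(diag(confusion[colnames(confusion), , drop = FALSE]))
  100 * d / total
}

#' Per-class TP/FP/FN/TN counts from a confusion matrix
#'
#' @param confusion Matrix from [build_confusion()].
#' @return Data frame with one row per class: `label`, `TP`, `FP`, `FN`,
#'   `TN`.
#' @export
confusion_class_counts <- function(confusion) {
  classes <- colnames(confusion)
  total <- sum(confusion)
  tp <- diag(confusion[classes, , drop = FALSE])
  fn <- colSums(confusion) - tp
  fp <- rowSums(confusion)[classes] - tp
  data.frame(label = classes, TP = unname(tp), FP = unname(fp),
             FN = unname(fn), TN = unname(total - tp - fp - fn),
             row.names = NULL)
}

#' True positive rate in percent
#'
#' `TPR = 100 * TP / (TP + FN)`; `NA` with a warning when the class has no
#' observed positives.
#'
#' @param counts List or one-row data frame with `TP` and `FN`.
#' @return TPR in percent, or `NA`.
#' @export
tpr <- function(counts) {
  denom <- counts$TP + counts$FN
  if (denom == 0) {
    warning("TPR undefined: no observed positives")
    return(NA_real_)
  }
  100 * counts$TP / denom
}

#' False positive rate in percent
#'
#' `FPR = 100 - 100 * TN / (TN + FP)`; `NA` with a warning when the class
#' has no observed negatives.
#'
#' @param counts List or one-row data frame with `TN` and `FP`.
#' @return FPR in percent, or `NA`.
#' @export
fpr <- function(counts) {
  denom <- counts$TN + counts$FP
  if (denom == 0) {
    warning("FPR undefined: no observed negatives")
    return(NA_real_)
  }
  100 - 100 * counts$TN / denom
}

#' Area under the ROC curve
#'
#' Sweeps a decision threshold over the scores, traces the (FPR, TPR)
#' curve and integrates it by the trapezoid rule; tied scores move the
#' operating point diagonally, which averages over their orderings and
#' makes the result identical to the rank-sum (Mann-Whitney) statistic.
#'
#' @param scores Numeric vector of decision values (larger = more
#'   positive).
#' @param truth Logical vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.logical(truth)
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc needs both positive and negative examples")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  # cumulative counts at each distinct threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(t)
  fp <- cumsum(!t)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr_pts <- c(0, tp[last] / n_pos)
  fpr_pts <- c(0, fp[last] / n_neg)
  sum(diff(fpr_pts) * (head(tpr_pts, -1) + tpr_pts[-1]) / 2)
}

#' Cumulative accuracy and coverage over reliability thresholds
#'
#' For each reliability threshold, restricts the evaluation to predictions
#' with `RI >= threshold` and reports the retained fraction of proteins
#' (coverage) and the overall accuracy on the retained subset.
#'
#' @param predictions List of `snl_prediction`.
#' @param observed An `snl_annotations`.
#' @param bin_width Threshold step on the 0-100 reliability scale.
#' @param attribution Passed to [build_confusion()].
#' @return Data frame with columns `ri_threshold`, `coverage` (percent of
#'   proteins retained) and `accuracy` (percent; `NA` when nothing is
#'   retained).
#' @export
ri_curve <- function(predictions, observed, bin_width = 20,
                     attribution = "top-score") {
  ris <- vapply(predictions, function(p) as.numeric(p$ri), numeric(1))
  thresholds <- seq(0, 100, by = bin_width)
  rows <- lapply(thresholds, function(th) {
    keep <- ris >= th
    acc <- if (any(keep)) {
      q_n(build_confusion(observed, predictions[keep],
                          attribution = attribution))
    } else {
      NA_real_
    }
    data.frame(ri_threshold = th,
               coverage = 100 * mean(keep),
               accuracy = acc)
  })
  do.call(rbind, rows)
}

#' Stratified k-fold partition
#'
#' Splits ids into `k` disjoint folds so that each class's members are
#' spread as evenly as possible (per-class fold counts differ by at most
#' one). Multi-label ids are stratified by their rarest label, which keeps
#' minority classes represented in every fold where their size allows.
#'
#' @param ids Character vector of ids.
#' @param labels Named list id -> character vector of labels (or a
#'   character vector of single labels).
#' @param k Number of folds.
#' @param seed Integer seed controlling the shuffle.
#' @return List of `k` character vectors partitioning `ids`.
#' @export
stratified_kfold <- function(ids, labels, k = 5L, seed = 1L) {
  if (k > length(ids)) stop("k = ", k, " exceeds number of ids")
  if (!is.list(labels)) labels <- as.list(labels)
  class_of <- vapply(ids, function(id) {
    l <- labels[[id]]
    if (is.null(l) || length(l) == 0L) return(".none")
    if (length(l) == 1L) return(l[1])
    sizes <- vapply(l, function(lab) {
      sum(vapply(labels[ids], function(x) lab %in% x, logical(1)))
    }, numeric(1))
    l[which.min(sizes)]
  }, character(1))
  folds <- vector("list", k)
  withr::with_seed(seed, {
    offset <- 0L
    for (cls in sample(unique(class_of))) {
      members <- sample(ids[class_of == cls])
      slots <- (offset + seq_along(members) - 1L) %% k + 1L
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], members[slots == f])
      }
      offset <- (offset + length(members)) %% k
    }
  })
  folds
}

#' Stratified cross-validation of the de novo battery
#'
#' Trains on `k - 1` folds and predicts the held-out fold, rotating over
#' all folds so every protein is predicted exactly once by a model that
#' never saw it. When a hit table is supplied the full combination
#' protocol is evaluated (homology transfer from the training folds'
#' annotations, self-hits excluded, de novo otherwise); without hits the
#' evaluation is purely de novo.
#'
#' @param profiles Named list of `snl_profile` keyed by protein id.
#' @param annotations An `snl_annotations` covering all ids.
#' @param task `"subnuclear"` (13 one-vs-rest classifiers) or
#'   `"traveler"` (single binary classifier).
#' @param config An [svm_config()].
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @param hits Optional alignment hit table enabling homology transfer.
#' @param evalue_threshold E-value cutoff for homology transfer.
#' @return List with `predictions` (named list of `snl_prediction` across
#'   all held-out folds), `folds`, and `q` (overall accuracy percent:
#'   Q13-style for `"subnuclear"` via [build_confusion()]/[q_n()], fraction
#'   of correct traveler calls for `"traveler"`).
#' @export
cross_validate <- function(profiles, annotations,
                           task = c("subnuclear", "traveler"),
                           config = NULL, k = 5L, seed = 1L, hits = NULL,
                           evalue_threshold = 1e-20) {
  task <- match.arg(task)
  if (is.null(config)) {
    config <- if (task == "subnuclear") svm_config()
              else svm_config(class_weighting = "none")
  }
  ids <- names(profiles)
  strat <- if (task == "subnuclear") annotations$labels else
    lapply(annotations$traveler[ids], function(f) {
      if (f) "traveler" else "nuclear-only"
    })
  folds <- stratified_kfold(ids, strat, k = k, seed = seed)
  fvs <- feature_maps(profiles, config$kernel_params)
  all_preds <- list()
  for (f in seq_len(k)) {
    test_ids <- folds[[f]]
    train_ids <- setdiff(ids, test_ids)
    train_db <- annotation_db(
      labels = annotations$labels[names(annotations$labels) %in% train_ids],
      traveler = annotations$traveler[names(annotations$traveler) %in%
                                        train_ids])
    battery <- if (task == "subnuclear") {
      suppressWarnings(train_battery(fvs[train_ids], train_db, config))
    } else {
      train_traveler(fvs[train_ids], train_db, config)
    }
    ctx <- ri_context(battery, fvs[train_ids], train_db)
    fold_hits <- if (is.null(hits)) {
      data.frame(query = character(), subject = character(),
                 pide = numeric(), evalue = numeric())
    } else {
      hits[hits$subject %in% train_ids, , drop = FALSE]
    }
    hb_res <- setNames(lapply(test_ids, function(id) {
      hb_infer(id, fold_hits, train_db, evalue_threshold,
               exclude_self = TRUE,
               target = if (task == "subnuclear") "labels" else "traveler")
    }), test_ids)
    ml_ids <- test_ids[vapply(hb_res, is.null, logical(1))]
    dm <- if (length(ml_ids)) decision_matrix(battery, fvs[ml_ids]) else NULL
    preds <- setNames(lapply(test_ids, function(id) {
      hb <- hb_res[[id]]
      if (!is.null(hb)) {
        labs <- if (task == "subnuclear") hb$labels else {
          if (hb$labels) "traveler" else character(0)
        }
        return(structure(list(protein = id, labels = labs,
                              ri = ri_hb(hb$pide), source = "HB",
                              scores = NULL,
                              traveler = if (task == "traveler") hb$labels
                                         else NULL),
                         class = "snl_prediction"))
      }
      s <- setNames(dm[id, ], colnames(dm))
      labs <- predict_labels(s)
      if (length(labs) == 0L) {
        return(structure(list(protein = id, labels = character(0), ri = 0L,
                              source = "NONE", scores = s,
                              traveler = if (task == "traveler") FALSE
                                         else NULL),
                         class = "snl_prediction"))
      }
      top <- labs[which.max(s[labs])]
      structure(list(protein = id, labels = labs,
                     ri = ri_svm(s[[top]], ctx, top), source = "ML",
                     scores = s,
                     traveler = if (task == "traveler")
                       s[["traveler"]] > 0 else NULL),
                class = "snl_prediction")
    }), test_ids)
    all_preds <- c(all_preds, preds)
  }
  all_preds <- all_preds[ids]
  q <- if (task == "subnuclear") {
    q_n(build_confusion(annotations, all_preds))
  } else {
    calls <- vapply(all_preds, function(p) isTRUE(p$traveler), logical(1))
    100 * mean(calls == annotations$traveler[ids])
  }
  list(predictions = all_preds, folds = folds, q = q)
}
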