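#' Per-label normalizers for the SVM reliability index
#'
#' The reliability index of a de novo prediction rescales the raw SVM score
#' into `[0, 100]` by the maximum raw score observed on a reference set
#' (normally the training fold): `RI = raw * 100 / max(raw)`. The maximum
#' is taken per label over the positive scores of that label's annotated
#' positives, matching the per-class structure of the battery; labels whose
#' positives never score above 0 fall back to the maximum positive score
#' over all reference proteins.
#'
#' @param battery An `snl_battery`.
#' @param profiles Reference profiles (list of `snl_profile` or `snl_fv`),
#'   normally the training set.
#' @param annotations An `snl_annotations` covering the reference ids.
#' @return Object of class `snl_ri_context`: named numeric `max_raw`.
#' @export
ri_context <- function(battery, profiles, annotations) {
  dm <- decision_matrix(battery, profiles)
  max_raw <- setNames(rep(NA_real_, ncol(dm)), colnames(dm))
  for (label in colnames(dm)) {
    pos_ids <- if (label == "traveler") {
      names(annotations$traveler)[annotations$traveler]
    } else {
      names(annotations$labels)[vapply(annotations$labels, function(l) {
        label %in% l
      }, logical(1))]
    }
    s <- dm[rownames(dm) %in% pos_ids, label]
    s <- s[is.finite(s) & s > 0]
    if (length(s)) {
      max_raw[label] <- max(s)
    } else {
      all_s <- dm[, label]
      all_s <- all_s[is.finite(all_s) & all_s > 0]
      if (length(all_s)) max_raw[label] <- max(all_s)
    }
  }
  structure(list(max_raw = max_raw), class = "snl_ri_context")
}

#' Reliability index of a de novo (SVM) prediction
#'
#' `RI = round(raw * 100 / max_raw[label])`, clamped to `[0, 100]`;
#' non-positive raw scores map to 0. Rounding is to the nearest integer,
#' half away from zero.
#'
#' @param raw Raw SVM decision value.
#' @param context An [ri_context()] object.
#' @param label The predicted label whose normalizer to use.
#' @return Integer reliability index in `[0, 100]`.
#' @export
ri_svm <- function(raw, context, label) {
  if (!label %in% names(context$max_raw)) {
    stop("no reliability normalizer for label '", label, "'")
  }
  mx <- context$max_raw[[label]]
  if (is.na(mx)) {
    warning("no positive reference score for label '", label,
            "'; reliability reported as 0")
    return(0L)
  }
  if (!is.finite(raw) || raw <= 0) return(0L)
  as.integer(pmin(100, floor(raw * 100 / mx + 0.5)))
}

#' Predict the localization of one protein
#'
#' The combination protocol: transfer the annotation of the best
#' significant homolog when one exists; otherwise fall back to the SVM
#' battery. A de novo prediction with no positive decision value yields the
#' explicit outcome "None" (empty label set, source `"NONE"`).
#'
#' @param query Protein id.
#' @param profile The query's `snl_profile` (or precomputed `snl_fv`).
#' @param hits Alignment hit table (may be empty).
#' @param battery Trained `snl_battery`.
#' @param db `snl_annotations` used as the homology donor database.
#' @param ri_ctx An [ri_context()] for the battery.
#' @param evalue_threshold E-value cutoff for homology transfer.
#' @param exclude_self Drop self-hits before transfer.
#' @return Object of class `snl_prediction`: list with `protein`, `labels`
#'   (character vector, possibly empty), `ri` (integer in `[0, 100]`),
#'   `source` (`"HB"`, `"ML"` or `"NONE"`) and, for de novo predictions,
#'   the raw `scores`.
#' @export
predict_protein <- function(query, profile, hits, battery, db, ri_ctx,
                            evalue_threshold = 1e-20, exclude_self = TRUE) {
  hb <- hb_infer(query, hits, db, evalue_threshold, exclude_self,
                 target = "labels")
  if (!is.null(hb)) {
    return(structure(list(protein = query, labels = hb$labels,
                          ri = ri_hb(hb$pide), source = "HB",
                          scores = NULL, subject = hb$subject),
                     class = "snl_prediction"))
  }
  scores <- decision_values(battery, profile)
  labels <- predict_labels(scores)
  if (length(labels) == 0L) {
    return(structure(list(protein = query, labels = character(0),
                          ri = 0L, source = "NONE", scores = scores),
                     class = "snl_prediction"))
  }
  top <- labels[which.max(scores[labels])]
  structure(list(protein = query, labels = labels,
                 ri = ri_svm(scores[[top]], ri_ctx, top), source = "ML",
                 scores = scores),
            class = "snl_prediction")
}

#' @export
print.snl_prediction <- function(x, ...) {
  lab <- if (length(x$labels)) paste(x$labels, collapse = "; ") else "None"
  cat("<snl_prediction> ", x$protein, " -> ", lab, " (RI ", x$ri, ", ",
      x$source, ")\n", sep = "")
  invisible(x)
}

#' Predict a batch of proteins
#'
#' @param profiles Named list of `snl_profile` (or `snl_fv`) keyed by
#'   protein id.
#' @param hits Alignment hit table shared by all queries.
#' @param battery,db,ri_ctx,evalue_threshold,exclude_self As in
#'   [predict_protein()].
#' @return Named list of `snl_prediction`.
#' @export
predict_set <- function(profiles, hits, battery, db, ri_ctx,
                        evalue_threshold = 1e-20, exclude_self = TRUE) {
  ids <- names(profiles)
  if (is.null(ids)) {
    ids <- vapply(profiles, function(p) p$id, character(1))
  }
  preds <- lapply(seq_along(profiles), function(i) {
    predict_protein(ids[i], profiles[[i]], hits, battery, db, ri_ctx,
                    evalue_threshold, exclude_self)
  })
  setNames(preds, ids)
}

#' Flatten predictions into a table
#'
#' @param predictions List of `snl_prediction`.
#' @return Data frame with columns `protein`, `labels` (semicolon-joined,
#'   `"None"` when empty), `ri` and `source`.
#' @export
predictions_table <- function(predictions) {
  data.frame(
    protein = vapply(predictions, function(p) p$protein, character(1)),
    labels = vapply(predictions, function(p) {
      if (length(p$labels)) paste(p$labels, collapse = ";") else "None"
    }, character(1)),
    ri = vapply(predictions, function(p) as.integer(p$ri), integer(1)),
    source = vapply(predictions, function(p) p$source, character(1)),
    row.names = NULL)
}
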