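#' Compartment composition spectrum of a prediction set
#'
#' The spectrum is the distribution of predicted label assignments over the
#' 13 compartments: each predicted label of each protein counts once, and
#' counts are normalized to fractions summing to 1. Proteins with an empty
#' prediction ("None") are excluded.
#'
#' @param predictions List of `snl_prediction`, or a named list of label
#'   character vectors.
#' @param labels Label vocabulary.
#' @return Object of class `snl_spectrum`: list with `fractions` (named
#'   13-vector summing to 1) and `n` (number of label assignments).
#' @export
location_spectrum <- function(predictions,
                              labels = subnuclear_compartments()) {
  sets <- lapply(predictions, function(p) {
    if (inherits(p, "snl_prediction")) p$labels else p
  })
  sets <- sets[lengths(sets) > 0L]
  if (length(sets) == 0L) stop("all predictions are empty; no spectrum")
  counts <- table(factor(unlist(sets), levels = labels))
  n <- sum(counts)
  structure(list(fractions = setNames(as.numeric(counts) / n, labels),
                 n = n),
            class = "snl_spectrum")
}

#' @export
print.snl_spectrum <- function(x, ...) {
  cat("<snl_spectrum> over", x$n, "label assignments\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Correct a predicted compartment distribution for classifier bias
#'
#' A classifier with unequal per-class error rates distorts the predicted
#' composition of an unlabeled set. Writing `M[i, j]` for the probability
#' that a protein observed in class `i` is predicted in outcome `j`
#' (estimated by column-normalizing a development-set confusion matrix,
#' with the "None" row as a 14th outcome), the observed outcome
#' distribution is `q = t(M) p` for a true class distribution `p`. This
#' function inverts that relation by non-negative least squares with the
#' simplex constraint `sum(p) = 1`; an ill-conditioned `M` triggers a
#' warning and a ridge-regularized solve.
#'
#' @param predicted_counts Named numeric vector of predicted-outcome counts
#'   over the confusion's rows (the `"None"` entry may be omitted and
#'   defaults to 0).
#' @param confusion Development-set confusion matrix from
#'   [build_confusion()].
#' @return An `snl_spectrum` for the bias-corrected class distribution.
#' @export
bias_correct <- function(predicted_counts, confusion) {
  outcomes <- rownames(confusion)
  classes <- colnames(confusion)
  obs_totals <- colSums(confusion)
  if (any(obs_totals <= 0)) {
    stop("confusion must be estimated on a set with all classes present")
  }
  q <- setNames(numeric(length(outcomes)), outcomes)
  unknown <- setdiff(names(predicted_counts), outcomes)
  if (length(unknown)) {
    stop("predicted counts for unknown outcomes: ",
         paste(unknown, collapse = ", "))
  }
  q[names(predicted_counts)] <- predicted_counts
  if (sum(q) <= 0) stop("predicted counts are all zero")
  q <- q / sum(q)
  # M: classes x outcomes, rows sum to 1; A = t(M): outcomes x classes
  M <- t(sweep(confusion, 2, obs_totals, "/"))
  A <- t(M)
  kappa_A <- kappa(A, exact = TRUE)
  if (!is.finite(kappa_A) || kappa_A > 1e8) {
    warning("confusion model is ill-conditioned (kappa = ",
            format(kappa_A, digits = 3), "); ridge-regularized solve")
    A <- rbind(A, sqrt(1e-6) * diag(length(classes)))
    q <- c(q, numeric(length(classes)))
  }
  lambda <- 1e3  # weight of the simplex constraint row
  A_aug <- rbind(A, lambda)
  b_aug <- c(q, lambda)
  p <- pracma::lsqnonneg(A_aug, b_aug)$x
  if (sum(p) <= 0) stop("bias correction degenerated to the zero vector")
  structure(list(fractions = setNames(p / sum(p), classes),
                 n = sum(predicted_counts)),
            class = "snl_spectrum")
}

#' Euclidean distance between two composition spectra
#'
#' Distance between the percent-scale spectra of two prediction sets, with
#' an optional bootstrap standard error obtained by resampling proteins
#' (with replacement) independently within each set.
#'
#' @param preds_a,preds_b Prediction sets as accepted by
#'   [location_spectrum()], or `snl_spectrum` objects (then no bootstrap).
#' @param bootstrap Number of bootstrap resamples (0 disables the SE).
#' @param seed Seed for the resampling.
#' @param labels Label vocabulary.
#' @return List with `distance` (percent scale) and `se` (`NA` when not
#'   bootstrapped).
#' @export
spectrum_distance <- function(preds_a, preds_b, bootstrap = 1000L,
                              seed = 1L,
                              labels = subnuclear_compartments()) {
  pct <- function(x) 100 * x$fractions
  direct <- inherits(preds_a, "snl_spectrum")
  sa <- if (direct) preds_a else location_spectrum(preds_a, labels)
  sb <- if (inherits(preds_b, "snl_spectrum")) preds_b else
    location_spectrum(preds_b, labels)
  d <- sqrt(sum((pct(sa) - pct(sb))^2))
  se <- NA_real_
  if (bootstrap > 0 && !direct && !inherits(preds_b, "snl_spectrum")) {
    boot <- withr::with_seed(seed, {
      vapply(seq_len(bootstrap), function(i) {
        ra <- preds_a[sample(length(preds_a), replace = TRUE)]
        rb <- preds_b[sample(length(preds_b), replace = TRUE)]
        sqrt(sum((pct(location_spectrum(ra, labels)) -
                    pct(location_spectrum(rb, labels)))^2))
      }, numeric(1))
    })
    se <- sd(boot)
  }
  list(distance = d, se = se)
}

#' Agreement between two multi-label predictions
#'
#' The fraction of the larger prediction's labels that also appear in the
#' smaller one: with `n = max(|a|, |b|)`, agreement is
#' `|intersect(a, b)| / n`. It is 1 exactly when the two sets are
#' identical, 0 when they are disjoint, and penalizes over-prediction: a
#' seven-label prediction sharing one label with a two-label prediction
#' scores 1/7.
#'
#' @param a,b Non-empty character vectors of predicted labels.
#' @return Agreement score in `[0, 1]`.
#' @export
agreement <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("agreement is undefined for empty prediction sets")
  }
  length(intersect(a, b)) / max(length(a), length(b))
}
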