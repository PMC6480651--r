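#' Configuration for the one-vs-rest SVM battery
#'
#' @param C Soft-margin penalty of the error term (positive).
#' @param tol Stopping tolerance of the dual solver (positive).
#' @param kernel_params An [kernel_params()] object (default parameters
#'   when `NULL`).
#' @param class_weighting `"inverse-frequency"` weights each class by
#'   `n / (2 * n_class)` so the positive:negative weight ratio equals the
#'   inverse of the class-frequency ratio; `"none"` leaves both at 1.
#' @return An object of class `snl_svm_config`.
#' @export
svm_config <- function(C = 1, tol = 1e-3, kernel_params = NULL,
                       class_weighting = c("inverse-frequency", "none")) {
  class_weighting <- match.arg(class_weighting)
  if (is.null(kernel_params)) {
    kernel_params <- subnucleaR::kernel_params()
  }
  if (!is.numeric(C) || C <= 0) stop("C must be > 0")
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  structure(list(C = C, tol = tol, kernel_params = kernel_params,
                 class_weighting = class_weighting),
            class = "snl_svm_config")
}

# Fit one binary soft-margin SVM on a precomputed kernel matrix by solving
# the weighted C-SVC dual
#   max_a  sum(a) - 0.5 a' (yy' * K) a,  0 <= a_i <= C * w(class_i),
#   sum(a * y) = 0
# with kernlab's interior-point QP. An interior-point solve converges to
# the dual optimum independent of sample order, so retraining on permuted
# data reproduces the decision function. Returns NULL when a class is
# empty. The stored classifier carries the support vectors' ids, feature
# vectors, dual coefficients and bias, so its decision function
# f(x) = sum_i coef_i K(sv_i, x) + bias is reproducible from the stored
# fields alone.
.fit_binary <- function(K, fvs, positive, positive_label, config) {
  n <- length(positive)
  n_pos <- sum(positive)
  if (n_pos == 0L || n_pos == n) return(NULL)
  y <- ifelse(positive, 1, -1)
  weights <- c(neg = 1, pos = 1)
  if (config$class_weighting == "inverse-frequency") {
    weights <- c(neg = n / (2 * (n - n_pos)), pos = n / (2 * n_pos))
  }
  ub <- config$C * ifelse(positive, weights[["pos"]], weights[["neg"]])
  H <- (y %o% y) * K + diag(1e-8, n)
  sigf <- max(5, min(12, ceiling(-log10(config$tol)) + 2))
  sol <- kernlab::ipop(c = rep(-1, n), H = H, A = matrix(y, 1), b = 0,
                       l = rep(0, n), u = ub, r = 0, sigf = sigf,
                       maxiter = 100)
  alpha <- as.numeric(kernlab::primal(sol))
  alpha <- pmin(pmax(alpha, 0), ub)
  f0 <- as.numeric(K %*% (alpha * y))
  eps <- 1e-6 * max(ub)
  free <- alpha > eps & alpha < ub - eps
  bias <- if (any(free)) {
    mean(y[free] - f0[free])
  } else {
    # no free vectors: take the midpoint of the feasible bias interval
    # (zero-alpha positives and bound negatives bound b from below;
    #  bound positives and zero-alpha negatives bound it from above)
    lo <- suppressWarnings(max((y - f0)[(y > 0 & alpha <= eps) |
                                          (y < 0 & alpha >= ub - eps)]))
    hi <- suppressWarnings(min((y - f0)[(y > 0 & alpha >= ub - eps) |
                                          (y < 0 & alpha <= eps)]))
    if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2 else 0
  }
  sv <- which(alpha > eps)
  coefs <- (alpha * y)[sv]
  dec <- f0 + bias
  structure(list(positive_label = positive_label,
                 support_ids = colnames(K)[sv],
                 support_fvs = fvs[sv],
                 dual_coefficients = coefs,
                 bias = bias,
                 training_decisions = setNames(dec, colnames(K)),
                 config = config),
            class = "snl_svm")
}

#' @export
print.snl_svm <- function(x, ...) {
  cat("<snl_svm> positive class '", x$positive_label, "', ",
      length(x$support_ids), " support vectors\n", sep = "")
  invisible(x)
}

#' Train the 13 one-vs-rest sub-nuclear classifiers
#'
#' One binary SVM per compartment, trained on the precomputed profile
#' kernel to separate the proteins annotated in that compartment from the
#' proteins in any of the other twelve. A protein with several labels is a
#' positive example for each of its compartments. With inverse-frequency
#' class weighting (the default) each class's errors are weighted by the
#' inverse of its frequency, which counteracts the strong class imbalance
#' typical of sub-nuclear annotation sets.
#'
#' @param profiles List of `snl_profile`, all ids annotated in `annotations`.
#' @param annotations An `snl_annotations` database.
#' @param config An [svm_config()].
#' @return Object of class `snl_battery`: list of `snl_svm` classifiers
#'   (one per compartment with at least one positive; empty classes are
#'   skipped with a warning and always score `-Inf`).
#' @export
train_battery <- function(profiles, annotations, config = svm_config()) {
  ids <- names(profiles)
  if (is.null(ids)) ids <- vapply(profiles, function(p) p$id, character(1))
  missing <- setdiff(ids, names(annotations$labels))
  if (length(missing)) {
    stop("profiles without annotation: ", paste(missing, collapse = ", "))
  }
  fvs <- feature_maps(profiles, config$kernel_params)
  K <- kernel_matrix(fvs, config$kernel_params)
  classifiers <- list()
  for (label in subnuclear_compartments()) {
    positive <- vapply(ids, function(id) {
      label %in% annotations$labels[[id]]
    }, logical(1))
    if (sum(positive) == 0L) {
      warning("no positives for class '", label, "'; classifier skipped")
      next
    }
    if (sum(positive) < 2L) {
      warning("class '", label, "' has fewer than 2 positives")
    }
    cls <- .fit_binary(K, fvs, positive, label, config)
    if (!is.null(cls)) classifiers[[label]] <- cls
  }
  structure(list(classifiers = classifiers,
                 labels = subnuclear_compartments(),
                 kernel_params = config$kernel_params),
            class = "snl_battery")
}

#' Train the binary traveler classifier
#'
#' Separates proteins functional exclusively in the nucleus from "traveler"
#' proteins also functional in other cellular compartments. The traveler
#' task is typically close to balanced, so class weighting defaults to
#' `"none"`.
#'
#' @param profiles List of `snl_profile` whose ids carry traveler flags.
#' @param annotations An `snl_annotations` with `traveler` flags for every
#'   profile id.
#' @param config An [svm_config()]; default has no class weighting.
#' @return An `snl_battery` with the single classifier `"traveler"`.
#' @export
train_traveler <- function(profiles, annotations,
                           config = svm_config(class_weighting = "none")) {
  ids <- names(profiles)
  if (is.null(ids)) ids <- vapply(profiles, function(p) p$id, character(1))
  missing <- setdiff(ids, names(annotations$traveler))
  if (length(missing)) {
    stop("profiles without traveler flag: ", paste(missing, collapse = ", "))
  }
  positive <- unname(annotations$traveler[ids])
  if (all(positive) || !any(positive)) {
    stop("traveler training set is degenerate: all flags are ",
         all(positive))
  }
  fvs <- feature_maps(profiles, config$kernel_params)
  K <- kernel_matrix(fvs, config$kernel_params)
  cls <- .fit_binary(K, fvs, positive, "traveler", config)
  structure(list(classifiers = list(traveler = cls),
                 labels = "traveler",
                 kernel_params = config$kernel_params),
            class = "snl_battery")
}

#' @export
print.snl_battery <- function(x, ...) {
  cat("<snl_battery> ", length(x$classifiers), " classifier(s): ",
      paste(names(x$classifiers), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Raw SVM decision values for a profile
#'
#' Evaluates every classifier's decision function
#' `f(x) = sum_i coef_i K(sv_i, x) + bias` against its stored support
#' vectors. Classes skipped at training time score `-Inf`.
#'
#' @param battery An `snl_battery`.
#' @param profile An `snl_profile`, or a precomputed `snl_fv`.
#' @return Named numeric vector, one raw decision value per battery label.
#' @export
decision_values <- function(battery, profile) {
  fv <- if (inherits(profile, "snl_fv")) profile
        else feature_map(profile, battery$kernel_params)
  scores <- setNames(rep(-Inf, length(battery$labels)), battery$labels)
  for (label in names(battery$classifiers)) {
    cls <- battery$classifiers[[label]]
    kv <- vapply(cls$support_fvs, profile_kernel, numeric(1), v = fv,
                 normalize = battery$kernel_params$normalize)
    scores[label] <- sum(cls$dual_coefficients * kv) + cls$bias
  }
  scores
}

#' Decision values for a batch of profiles
#'
#' @param battery An `snl_battery`.
#' @param profiles List of `snl_profile` or `snl_fv`.
#' @return Matrix, one row per profile, one column per battery label.
#' @export
decision_matrix <- function(battery, profiles) {
  fvs <- if (length(profiles) && inherits(profiles[[1]], "snl_fv")) profiles
         else feature_maps(profiles, battery$kernel_params)
  out <- matrix(-Inf, length(fvs), length(battery$labels),
                dimnames = list(names(fvs), battery$labels))
  for (label in names(battery$classifiers)) {
    cls <- battery$classifiers[[label]]
    Kc <- kernel_cross(fvs, cls$support_fvs,
                       normalize = battery$kernel_params$normalize)
    out[, label] <- as.numeric(Kc %*% cls$dual_coefficients) + cls$bias
  }
  out
}

#' Turn raw decision values into a predicted label set
#'
#' Every label whose raw score is strictly positive is predicted; an empty
#' set is the explicit outcome "None" (no compartment predicted).
#'
#' @param scores Named numeric vector of raw decision values.
#' @return Character vector of predicted labels (possibly empty).
#' @export
predict_labels <- function(scores) {
  names(scores)[!is.na(scores) & scores > 0]
}

#' Serialize a trained battery to a versioned JSON archive
#'
#' Stores support ids, support feature vectors, dual coefficients, bias and
#' configuration at full double precision, so [read_battery()] restores a
#' battery whose decision values match the original exactly.
#'
#' @param battery An `snl_battery`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_battery <- function(battery, path) {
  ser <- list(
    format = "subnucleaR-battery",
    version = 1L,
    labels = battery$labels,
    kernel_params = unclass(battery$kernel_params),
    classifiers = lapply(battery$classifiers, function(cls) {
      list(positive_label = cls$positive_label,
           support_ids = cls$support_ids,
           support_fvs = lapply(cls$support_fvs, function(f) {
             list(k = f$k, idx = f$idx, counts = f$counts)
           }),
           dual_coefficients = cls$dual_coefficients,
           bias = cls$bias,
           config = list(C = cls$config$C, tol = cls$config$tol,
                         class_weighting = cls$config$class_weighting))
    })
  )
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a battery written by [write_battery()]
#'
#' @param path Path to the JSON archive.
#' @return An `snl_battery`.
#' @export
read_battery <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(ser$format, "subnucleaR-battery")) {
    stop("not a battery archive: ", path)
  }
  kp <- kernel_params(ser$kernel_params$k, ser$kernel_params$sigma,
                      ser$kernel_params$normalize)
  classifiers <- lapply(ser$classifiers, function(cl) {
    cfg <- svm_config(C = cl$config$C, tol = cl$config$tol,
                      kernel_params = kp,
                      class_weighting = cl$config$class_weighting)
    structure(list(
      positive_label = cl$positive_label,
      support_ids = cl$support_ids,
      support_fvs = lapply(cl$support_fvs, function(f) {
        structure(list(k = as.integer(f$k),
                       idx = as.numeric(unlist(f$idx)),
                       counts = as.numeric(unlist(f$counts))),
                  class = "snl_fv")
      }),
      dual_coefficients = as.numeric(cl$dual_coefficients),
      bias = cl$bias,
      config = cfg), class = "snl_svm")
  })
  structure(list(classifiers = classifiers, labels = ser$labels,
                 kernel_params = kp),
            class = "snl_battery")
}
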