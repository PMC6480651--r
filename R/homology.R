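#' Transfer annotation from the best alignment hit
#'
#' Among the query's hits, keep those whose subject carries an annotation
#' of the requested kind, whose E-value passes the threshold, and (when
#' `exclude_self`) whose subject differs from the query. The complete label
#' set (or traveler flag) of the hit with the highest percent sequence
#' identity is transferred; ties on identity are broken by smaller E-value,
#' then by lexicographic subject id. Absence of a usable hit is a valid
#' outcome (`NULL`), in which case the caller falls back to de novo
#' prediction.
#'
#' @param query Query protein id.
#' @param hits Data frame of hits as from [read_blast_tab()].
#' @param db An `snl_annotations`.
#' @param evalue_threshold Keep hits with `evalue <= evalue_threshold`.
#'   Conventional defaults are `1e-20` for sub-nuclear compartments and
#'   `1e-5` for the traveler task.
#' @param exclude_self Drop hits whose subject equals the query (needed for
#'   honest performance estimation on annotated sets).
#' @param target `"labels"` to transfer the compartment label set,
#'   `"traveler"` to transfer the traveler flag.
#' @return `NULL`, or a list of class `snl_hb` with elements `labels`
#'   (character vector, or logical flag for the traveler target), `pide`
#'   and `subject`.
#' @export
hb_infer <- function(query, hits, db, evalue_threshold = 1e-20,
                     exclude_self = TRUE, target = c("labels", "traveler")) {
  target <- match.arg(target)
  if (evalue_threshold <= 0) stop("evalue_threshold must be > 0")
  h <- hits[hits$query == query, , drop = FALSE]
  annotated <- if (target == "labels") names(db$labels) else
    names(db$traveler)
  keep <- h$subject %in% annotated & h$evalue <= evalue_threshold
  if (exclude_self) keep <- keep & h$subject != query
  h <- h[keep, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  h <- h[order(-h$pide, h$evalue, h$subject), , drop = FALSE]
  best <- h[1L, ]
  labels <- if (target == "labels") db$labels[[best$subject]] else
    unname(db$traveler[best$subject])
  structure(list(labels = labels, pide = best$pide, subject = best$subject),
            class = "snl_hb")
}

#' Reliability index of a homology-based prediction
#'
#' `RI = int(10 * (PIDE - 20) / 8)`, truncated toward zero and clamped to
#' `[0, 100]`: 20% identity or less maps to 0, 100% identity to 100.
#' Identities below 20% (possible for accepted distant hits) clamp to 0.
#'
#' @param pide Percent sequence identity in `[0, 100]`.
#' @return Integer reliability index in `[0, 100]`.
#' @export
ri_hb <- function(pide) {
  if (any(is.na(pide)) || any(pide < 0) || any(pide > 100)) {
    stop("pide must be in [0, 100]")
  }
  ri <- floor(10 * (pide - 20) / 8)
  as.integer(pmin(100, pmax(0, ri)))
}
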