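#' Parameters of the profile string kernel
#'
#' The kernel maps a profile to a sparse `20^k`-dimensional count vector:
#' coordinate `m` counts the positions at which k-mer `m` is "conserved",
#' i.e. the sum of the profile's per-residue costs over the k-mer window
#' falls strictly below the threshold `sigma`. Smaller `sigma` keeps only
#' strongly conserved k-mers; larger `sigma` admits more of the `20^k`
#' strings per window.
#'
#' @param k k-mer length (positive integer; 2-6 is the practical range).
#' @param sigma Conservation threshold (positive real).
#' @param normalize Cosine-normalize kernel values so self-similarity is 1.
#' @return An object of class `snl_kernel_params`.
#' @export
kernel_params <- function(k = 4L, sigma = 6.0, normalize = TRUE) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  structure(list(k = k, sigma = sigma, normalize = isTRUE(normalize)),
            class = "snl_kernel_params")
}

#' k-mers conserved at one profile position
#'
#' Enumerates exactly the k-mers whose summed per-residue cost over the
#' window starting at `pos` is `< sigma`. The search expands one residue at
#' a time and prunes any prefix whose partial sum already reaches `sigma`;
#' because costs are non-negative this is equivalent to exhaustive
#' enumeration over all `20^k` strings.
#'
#' @param profile An `snl_profile`.
#' @param pos Window start, `1 <= pos <= L - k + 1`.
#' @param params An `snl_kernel_params`.
#' @return Numeric vector of 0-based k-mer indices (see [kmer_index()]),
#'   sorted increasingly.
#' @export
conserved_kmers_at <- function(profile, pos, params) {
  k <- params$k
  L <- nrow(profile$scores)
  if (pos < 1L || pos > L - k + 1L) {
    stop("pos must be in [1, ", L - k + 1L, "], got ", pos)
  }
  idx <- 0
  cost <- 0
  for (j in seq_len(k)) {
    cj <- profile$scores[pos + j - 1L, ]
    n <- length(idx)
    idx <- rep(idx, each = 20L) * 20 + rep.int(0:19, n)
    cost <- rep(cost, each = 20L) + rep.int(unname(cj), n)
    keep <- cost < params$sigma
    idx <- idx[keep]
    cost <- cost[keep]
    if (length(idx) == 0L) break
  }
  sort(idx)
}

#' Map a profile to its sparse k-mer count vector
#'
#' Coordinate `m` of the feature vector is the number of window positions
#' at which k-mer `m` is conserved (cost sum `< sigma`).
#'
#' @param profile An `snl_profile`.
#' @param params An `snl_kernel_params`.
#' @return An object of class `snl_fv`: list with `k`, sorted 0-based
#'   `idx` and matching positive integer `counts`. Profiles shorter than
#'   `k` yield an empty vector with a warning.
#' @export
feature_map <- function(profile, params) {
  k <- params$k
  L <- nrow(profile$scores)
  if (L < k) {
    warning("profile ", profile$id, " is shorter than k = ", k,
            "; empty feature vector")
    return(structure(list(k = k, idx = numeric(), counts = numeric()),
                     class = "snl_fv"))
  }
  hits <- lapply(seq_len(L - k + 1L), function(pos) {
    conserved_kmers_at(profile, pos, params)
  })
  all_idx <- sort(unlist(hits, use.names = FALSE))
  if (length(all_idx) == 0L) {
    return(structure(list(k = k, idx = numeric(), counts = numeric()),
                     class = "snl_fv"))
  }
  r <- rle(all_idx)
  structure(list(k = k, idx = r$values, counts = as.numeric(r$lengths)),
            class = "snl_fv")
}

#' @export
print.snl_fv <- function(x, ...) {
  cat("<snl_fv> k=", x$k, ", ", length(x$idx), " distinct k-mers, total ",
      sum(x$counts), "\n", sep = "")
  invisible(x)
}

#' Feature vectors for a list of profiles
#'
#' Already-computed feature vectors pass through unchanged, so callers can
#' cache the expensive map once and reuse it across folds and batteries.
#'
#' @param profiles List of `snl_profile` objects (or `snl_fv`, returned
#'   as-is).
#' @param params An `snl_kernel_params`.
#' @return Named list of `snl_fv`, keyed by profile id.
#' @export
feature_maps <- function(profiles, params) {
  if (length(profiles) && inherits(profiles[[1]], "snl_fv")) {
    return(profiles)
  }
  fvs <- lapply(profiles, feature_map, params = params)
  names(fvs) <- vapply(profiles, function(p) p$id, character(1))
  fvs
}

# Stack feature vectors into a sparse count matrix over the union of
# observed k-mer indices (column order = sorted union).
.fv_sparse <- function(fvs, universe = NULL) {
  if (is.null(universe)) {
    universe <- sort(unique(unlist(lapply(fvs, function(f) f$idx),
                                   use.names = FALSE)))
  }
  i <- rep(seq_along(fvs), vapply(fvs, function(f) length(f$idx), integer(1)))
  j <- match(unlist(lapply(fvs, function(f) f$idx), use.names = FALSE),
             universe)
  x <- unlist(lapply(fvs, function(f) f$counts), use.names = FALSE)
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(fvs), length(universe)),
                       dimnames = list(names(fvs), NULL))
}

# Sparse dot product of two feature vectors.
.fv_dot <- function(u, v) {
  if (length(u$idx) == 0L || length(v$idx) == 0L) return(0)
  m <- match(u$idx, v$idx)
  hit <- !is.na(m)
  if (!any(hit)) return(0)
  sum(u$counts[hit] * v$counts[m[hit]])
}

#' Profile kernel between two feature vectors
#'
#' The raw kernel is the dot product of the sparse count vectors. With
#' `normalize = TRUE` it is cosine-normalized,
#' `K(u,v)/sqrt(K(u,u) K(v,v))`, with the convention that the value is 0
#' when either self-kernel is 0 (empty feature vector).
#'
#' @param u,v `snl_fv` objects with equal `k`.
#' @param normalize Logical.
#' @return Kernel value (scalar).
#' @export
profile_kernel <- function(u, v, normalize = TRUE) {
  if (u$k != v$k) stop("feature vectors have different k: ", u$k, " vs ", v$k)
  d <- .fv_dot(u, v)
  if (!normalize) return(d)
  su <- sum(u$counts^2)
  sv <- sum(v$counts^2)
  if (su == 0 || sv == 0) return(0)
  d / sqrt(su * sv)
}

#' Kernel matrix over a list of profiles
#'
#' Feature vectors are computed once per profile and reused for all pairs.
#'
#' @param profiles List of `snl_profile`, or a precomputed list of `snl_fv`
#'   (as from [feature_maps()]).
#' @param params An `snl_kernel_params` (ignored when feature vectors are
#'   supplied, except for `normalize`).
#' @return Symmetric numeric matrix with profile ids as dimnames; under
#'   normalization the diagonal is 1 (or 0 for empty vectors).
#' @export
kernel_matrix <- function(profiles, params = kernel_params()) {
  if (length(profiles) == 0L) stop("kernel_matrix needs a non-empty list")
  fvs <- if (inherits(profiles[[1]], "snl_fv")) profiles
         else feature_maps(profiles, params)
  X <- .fv_sparse(fvs)
  K <- as.matrix(Matrix::tcrossprod(X))
  dimnames(K) <- list(names(fvs), names(fvs))
  if (params$normalize) {
    norms <- sqrt(diag(K))
    denom <- outer(norms, norms)
    K <- ifelse(denom > 0, K / denom, 0)
    dimnames(K) <- list(names(fvs), names(fvs))
  }
  K
}

#' Rectangular kernel matrix between two feature-vector lists
#'
#' @param fvs_row,fvs_col Lists of `snl_fv`.
#' @param normalize Logical.
#' @return `length(fvs_row) x length(fvs_col)` matrix.
#' @export
kernel_cross <- function(fvs_row, fvs_col, normalize = TRUE) {
  universe <- sort(unique(unlist(c(lapply(fvs_row, function(f) f$idx),
                                   lapply(fvs_col, function(f) f$idx)),
                                 use.names = FALSE)))
  Xr <- .fv_sparse(fvs_row, universe)
  Xc <- .fv_sparse(fvs_col, universe)
  K <- as.matrix(Matrix::tcrossprod(Xr, Xc))
  dimnames(K) <- list(names(fvs_row), names(fvs_col))
  if (normalize) {
    nr <- sqrt(vapply(fvs_row, function(f) sum(f$counts^2), numeric(1)))
    nc <- sqrt(vapply(fvs_col, function(f) sum(f$counts^2), numeric(1)))
    denom <- outer(nr, nc)
    K <- ifelse(denom > 0, K / denom, 0)
    dimnames(K) <- list(names(fvs_row), names(fvs_col))
  }
  K
}

#' Dump a feature vector as a two-column TSV
#'
#' Writes `kmer <TAB> count` rows, k-mers decoded to residue strings.
#'
#' @param fv An `snl_fv`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_vector <- function(fv, path) {
  df <- data.frame(kmer = kmer_string(fv$idx, fv$k), count = fv$counts)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
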