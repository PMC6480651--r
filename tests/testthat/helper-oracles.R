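# Independent oracles and shared fixtures for the test suite.

# A small, fast generator configuration used across tests.
small_config <- function(...) {
  generator_config(n_classes = 3L, n_per_class = 8L, profile_length = 60L,
                   n_motifs_per_class = 2L, sites_per_motif = 2L,
                   seed = 101L, ...)
}

# Random profile with uniform costs in [0, max_cost].
random_profile <- function(id, L, max_cost = 3) {
  new_profile(id, matrix(runif(L * 20, 0, max_cost), L, 20),
              source = "synthetic")
}

# Exhaustive enumeration oracle for conserved k-mers: tries all 20^k
# strings at a window, no pruning.
brute_conserved <- function(profile, pos, k, sigma) {
  grids <- rev(rep(list(0:19), k))
  all_digits <- as.matrix(do.call(expand.grid, grids))[, k:1, drop = FALSE]
  cost <- rowSums(vapply(seq_len(k), function(j) {
    profile$scores[pos + j - 1L, all_digits[, j] + 1L]
  }, numeric(20^k)))
  idx <- as.numeric(all_digits %*% 20^((k - 1):0))
  sort(idx[cost < sigma])
}

# Dense-vector dot-product oracle for the kernel (k = 2 only).
dense_dot <- function(u, v) {
  du <- numeric(400)
  dv <- numeric(400)
  du[u$idx + 1] <- u$counts
  dv[v$idx + 1] <- v$counts
  sum(du * dv)
}

# Pair-counting (Mann-Whitney) oracle for the AUC.
pair_count_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Direct-summation oracle for the upper-tail hypergeometric probability
# P(X >= x) when drawing n from N with K successes.
hyper_tail <- function(x, K, N, n) {
  upper <- min(K, n)
  if (x > upper) return(0)
  sum(vapply(x:upper, function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, numeric(1)))
}

# Brute-force PPI cell counting: enumerates every unordered protein pair
# (for num_pos) and every edge (for num_obs), attributing each to the
# unique unordered label pairs {i in labels(u), j in labels(v)}.
brute_ppi_counts <- function(edges, comp, labels) {
  nl <- length(labels)
  pos <- matrix(0, nl, nl, dimnames = list(labels, labels))
  obs <- matrix(0, nl, nl, dimnames = list(labels, labels))
  ids <- names(comp)
  add_cells <- function(m, lu, lv) {
    cells <- unique(t(apply(expand.grid(lu, lv, stringsAsFactors = FALSE),
                            1, function(r) sort(unname(r)))))
    for (r in seq_len(nrow(cells))) {
      i <- cells[r, 1]
      j <- cells[r, 2]
      m[i, j] <- m[i, j] + 1
      if (i != j) m[j, i] <- m[j, i] + 1
    }
    m
  }
  for (a in seq_along(ids)) {
    for (b in seq_len(a - 1L)) {
      pos <- add_cells(pos, comp[[ids[a]]], comp[[ids[b]]])
    }
  }
  for (e in seq_len(nrow(edges))) {
    lu <- comp[[edges$a[e]]]
    lv <- comp[[edges$b[e]]]
    if (is.null(lu) || is.null(lv)) next
    obs <- add_cells(obs, lu, lv)
  }
  list(num_pos = pos, num_obs = obs)
}

# The development-set confusion matrix of the 13-compartment predictor,
# transcribed for worked-example tests: rows = predicted (plus "None"),
# columns = observed, classes ordered largest to smallest.
dev_confusion <- function() {
  labels <- subnuclear_compartments()
  m <- rbind(
    c(506, 32, 11,  7,  0,  6,  3,  1,  1,  4,  6,  1,  1),
    c( 49, 461, 29, 11,  4, 12,  3,  6,  2,  3,  2,  1,  2),
    c( 14, 19, 153,  2,  2,  4,  1,  1,  0,  2,  1,  0,  0),
    c( 12, 13,  9, 38,  2,  3,  2,  1,  1,  0,  1,  0,  0),
    c(  5,  6,  3,  2, 41,  3,  7,  0,  2,  0,  1,  0,  0),
    c(  7,  9,  5,  4,  2, 25,  1,  0,  0,  1,  0,  0,  0),
    c(  4,  4,  1,  0,  3,  1, 34,  0,  6,  0,  1,  0,  0),
    c(  3,  5,  2,  0,  1,  1,  0, 10,  0,  1,  0,  0,  0),
    c(  4,  4,  1,  2,  3,  0,  6,  0, 15,  0,  1,  0,  0),
    c( 39, 38, 30, 11,  7,  8,  5, 10,  3, 13,  2,  1,  2),
    c(  4,  5,  0,  1,  1,  0,  1,  1,  2,  2,  5,  0,  0),
    c( 32, 27, 19,  8, 10,  9,  7,  5,  1,  1,  1,  8,  1),
    c(  0,  3,  0,  0,  0,  0,  0,  1,  0,  0,  0,  0,  4),
    c( 18, 27, 29,  9,  4,  2,  2,  6,  1,  2,  4,  3,  3))
  dimnames(m) <- list(c(labels, "None"), labels)
  m
}
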