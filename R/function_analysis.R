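#' Benjamini-Hochberg adjusted p-values
#'
#' Thin validated wrapper over the standard step-up adjustment: adjusted
#' values are monotone after sorting, never smaller than the raw p-values
#' at the same ranks, and capped at 1.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must be in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Hypergeometric GO-term enrichment of a protein set
#'
#' For each term annotated in the background, tests whether the target set
#' contains more term-annotated proteins than expected when drawing
#' `|target|` proteins from the background without replacement: the
#' upper-tail hypergeometric probability of the observed overlap or more.
#' P-values are adjusted across all tested terms by Benjamini-Hochberg,
#' and a term is flagged significant when its adjusted value falls below
#' `alpha`.
#'
#' @param target Character vector of protein ids (subset of `background`).
#' @param background Character vector of protein ids.
#' @param go_map Named list protein id -> character vector of GO terms.
#' @param alpha Significance threshold applied to the adjusted p-value.
#' @return Data frame sorted by p-value: `term`, `overlap`, `target_size`,
#'   `background_count`, `background_size`, `p_value`, `q_value`,
#'   `significant`.
#' @export
hypergeom_enrichment <- function(target, background, go_map, alpha = 0.01) {
  target <- unique(target)
  background <- unique(background)
  if (!all(target %in% background)) {
    stop("target must be a subset of the background")
  }
  covered <- intersect(names(go_map), background)
  outside <- setdiff(unlist(go_map[setdiff(names(go_map), background)]),
                     unlist(go_map[covered]))
  if (length(outside)) {
    warning(length(outside), " term(s) annotate no background protein; ",
            "skipped")
  }
  term_members <- split(
    rep(covered, lengths(go_map[covered])),
    unlist(go_map[covered], use.names = FALSE))
  N <- length(background)
  n <- length(target)
  rows <- lapply(names(term_members), function(term) {
    members <- unique(term_members[[term]])
    K <- length(members)
    x <- length(intersect(members, target))
    data.frame(term = term, overlap = x, target_size = n,
               background_count = K, background_size = N,
               p_value = phyper(x - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(), overlap = integer(),
                      target_size = integer(), background_count = integer(),
                      background_size = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical()))
  }
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < alpha
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  out
}

#' Build a protein-protein interaction graph
#'
#' Edges are deduplicated and self-loops removed. Nodes carry an optional
#' group tag (e.g. `nuclear-only` / `traveler` / `non-nuclear`) and an
#' optional compartment label set.
#'
#' @param edges Data frame with id columns `a` and `b` (as from
#'   [read_edges()]).
#' @param groups Optional named character vector: protein id -> group tag.
#' @param compartments Optional named list: protein id -> label set.
#' @return Object of class `snl_ppi`: list with the `igraph` `graph`,
#'   `groups` and `compartments`.
#' @export
ppi_graph <- function(edges, groups = NULL, compartments = NULL) {
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  extra <- unique(c(names(groups), names(compartments)))
  extra <- setdiff(extra, igraph::V(g)$name)
  if (length(extra)) g <- igraph::add_vertices(g, length(extra), name = extra)
  structure(list(graph = g, groups = groups, compartments = compartments),
            class = "snl_ppi")
}

#' @export
print.snl_ppi <- function(x, ...) {
  cat("<snl_ppi> ", igraph::vcount(x$graph), " proteins, ",
      igraph::ecount(x$graph), " interactions\n", sep = "")
  invisible(x)
}

# Number of possible unordered protein pairs contributing to cell (i, j):
# n_i * n_j ordered pairs, minus the n_ij self-pairings of proteins
# carrying both labels, minus the C(n_ij, 2) unordered pairs counted in
# both orientations. For i == j it is C(n_i, 2).
.num_pos_cell <- function(i, j, members) {
  if (i == j) {
    n <- length(members[[i]])
    return(n * (n - 1) / 2)
  }
  n_i <- length(members[[i]])
  n_j <- length(members[[j]])
  n_ij <- length(intersect(members[[i]], members[[j]]))
  n_i * n_j - n_ij - n_ij * (n_ij - 1) / 2
}

# Unique unordered label pairs {i, j} that an edge (u, v) contributes to:
# one occurrence per pair i in labels(u), j in labels(v), deduplicated.
.edge_cells <- function(lu, lv) {
  cells <- unique(rbind(
    expand.grid(i = lu, j = lv, stringsAsFactors = FALSE)))
  key <- apply(cells, 1, function(r) paste(sort(r), collapse = "\r"))
  cells[!duplicated(key), , drop = FALSE]
}

#' Compartment-pair interaction odds ratios
#'
#' For each unordered compartment pair `(i, j)`, the ratio of observed
#' interactions between proteins labeled `i` and `j` to the count expected
#' if interactions were distributed over protein pairs at random:
#' `num_exp(i,j) = num_pos(i,j) / sum(num_pos) * num_obs_total`, with
#' `num_pos` the number of possible protein pairs for the cell and
#' `num_obs_total` the total observed cell mass. A protein carrying both
#' labels contributes to both margins; the identical pair-counting rule in
#' the numerator and denominator keeps the odds at exactly 1 when observed
#' counts equal expectation. Cells with `num_exp = 0` are `NA`.
#'
#' @param graph An `snl_ppi` whose `compartments` cover the labeled
#'   proteins.
#' @param labels Label vocabulary (defaults to the 13 compartments).
#' @return List with symmetric matrices `odds`, `num_obs`, `num_exp`,
#'   `num_pos`, and the scalar `num_obs_total`.
#' @export
ppi_odds <- function(graph, labels = subnuclear_compartments()) {
  comp <- graph$compartments
  if (is.null(comp) || length(comp) == 0L) {
    stop("ppi_odds needs compartment labels on the graph")
  }
  members <- lapply(labels, function(l) {
    names(comp)[vapply(comp, function(x) l %in% x, logical(1))]
  })
  names(members) <- labels
  nl <- length(labels)
  num_pos <- matrix(0, nl, nl, dimnames = list(labels, labels))
  for (a in seq_len(nl)) {
    for (b in a:nl) {
      num_pos[a, b] <- num_pos[b, a] <-
        .num_pos_cell(labels[a], labels[b], members)
    }
  }
  num_obs <- matrix(0, nl, nl, dimnames = list(labels, labels))
  el <- igraph::as_edgelist(graph$graph)
  for (e in seq_len(nrow(el))) {
    lu <- intersect(comp[[el[e, 1]]], labels)
    lv <- intersect(comp[[el[e, 2]]], labels)
    if (length(lu) == 0L || length(lv) == 0L) next
    cells <- .edge_cells(lu, lv)
    for (r in seq_len(nrow(cells))) {
      i <- cells$i[r]
      j <- cells$j[r]
      num_obs[i, j] <- num_obs[i, j] + 1
      if (i != j) num_obs[j, i] <- num_obs[j, i] + 1
    }
  }
  # total observed cell mass: each cell counted once (upper triangle)
  num_obs_total <- sum(num_obs[upper.tri(num_obs, diag = TRUE)])
  if (num_obs_total == 0) {
    stop("no observed interactions among compartment-labeled proteins")
  }
  pos_total <- sum(num_pos[upper.tri(num_pos, diag = TRUE)])
  num_exp <- num_pos / pos_total * num_obs_total
  odds <- ifelse(num_exp > 0, num_obs / num_exp, NA_real_)
  list(odds = odds, num_obs = num_obs, num_exp = num_exp,
       num_pos = num_pos, num_obs_total = num_obs_total)
}

#' Degree and component statistics of an interaction graph
#'
#' @param graph An `snl_ppi` (its `groups` tags define the grouping; nodes
#'   without a tag form the group `"untagged"`).
#' @return List with `mean_degree` (named by group), `components` (data
#'   frame of component sizes), `n_components`, and `largest_fraction`
#'   (per-group fraction of members inside the largest component).
#' @export
degree_stats <- function(graph) {
  g <- graph$graph
  if (igraph::vcount(g) == 0L) stop("graph has no nodes")
  deg <- igraph::degree(g)
  tags <- rep("untagged", length(deg))
  names(tags) <- names(deg)
  if (!is.null(graph$groups)) {
    known <- intersect(names(deg), names(graph$groups))
    tags[known] <- graph$groups[known]
  }
  comp <- igraph::components(g)
  largest <- which.max(comp$csize)
  in_largest <- comp$membership == largest
  list(
    mean_degree = tapply(deg, tags, mean),
    components = data.frame(component = seq_along(comp$csize),
                            size = comp$csize),
    n_components = comp$no,
    largest_fraction = tapply(in_largest, tags, mean))
}
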