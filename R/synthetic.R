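#' Configuration of the synthetic-data generators
#'
#' The generators emulate the statistical structure the predictor assumes:
#' each compartment class is marked by a small set of class-specific k-mers
#' planted into otherwise uninformative profiles at near-zero conservation
#' cost; homology hit tables cover a controlled fraction of queries with
#' same-class annotated donors; interaction networks connect
#' within-compartment protein pairs at one rate and between-compartment
#' pairs at another; GO tables enrich one designated term per compartment.
#'
#' Background cells draw costs uniformly from `[bg_cost_min, bg_cost_max]`
#' (well above `sigma / motif_k` per residue, so background windows rarely
#' clear the conservation threshold), except that with probability
#' `noise_prob` a cell is "cheap" (cost in `[noise_cost_min,
#' noise_cost_max]`), producing a realistic scatter of spurious conserved
#' k-mers. Planted motif residues cost `motif_strength` each.
#'
#' @param n_classes Number of compartment classes (at most 13).
#' @param n_per_class Proteins per class.
#' @param profile_length Positions per profile.
#' @param motif_k Length of planted motifs.
#' @param n_motifs_per_class Distinct motifs marking each class.
#' @param sites_per_motif Planted occurrences of each motif per protein.
#' @param motif_strength Per-residue cost of planted motif cells.
#' @param bg_cost_min,bg_cost_max Uniform range of background cell costs.
#' @param noise_prob Probability that a background cell is cheap.
#' @param noise_cost_min,noise_cost_max Uniform range of cheap-cell costs.
#' @param multi_label_frac Fraction of proteins additionally carrying a
#'   second class's motifs (and label).
#' @param class_size_decay Geometric decay factor of class sizes (1 =
#'   balanced; 0.8 shrinks each successive class to 80%), emulating the
#'   strong imbalance of real sub-nuclear annotation sets.
#' @param traveler_frac Fraction of proteins flagged as travelers (marked
#'   by a dedicated traveler motif set).
#' @param homolog_coverage Fraction of queries given a significant
#'   annotated same-class hit.
#' @param pide_range Percent-identity range of generated hits.
#' @param within_ppi_rate,between_ppi_rate Edge probabilities for protein
#'   pairs sharing / not sharing a compartment.
#' @param enriched_term_odds Odds ratio of the designated enriched GO term
#'   per compartment.
#' @param n_filler_terms Number of uninformative filler GO terms.
#' @param seed Integer seed; all generators are deterministic given the
#'   config.
#' @return Object of class `snl_gen_config`.
#' @export
generator_config <- function(n_classes = 13L, n_per_class = 20L,
                             profile_length = 150L, motif_k = 4L,
                             n_motifs_per_class = 3L, sites_per_motif = 3L,
                             motif_strength = 0.1,
                             bg_cost_min = 2.5, bg_cost_max = 7,
                             noise_prob = 0.02,
                             noise_cost_min = 0.5, noise_cost_max = 2,
                             multi_label_frac = 0.1,
                             class_size_decay = 1,
                             traveler_frac = 0.5,
                             homolog_coverage = 0.5,
                             pide_range = c(40, 100),
                             within_ppi_rate = 0.2,
                             between_ppi_rate = 0.05,
                             enriched_term_odds = 10,
                             n_filler_terms = 30L,
                             seed = 1L) {
  cfg <- list(n_classes = as.integer(n_classes),
              n_per_class = as.integer(n_per_class),
              profile_length = as.integer(profile_length),
              motif_k = as.integer(motif_k),
              n_motifs_per_class = as.integer(n_motifs_per_class),
              sites_per_motif = as.integer(sites_per_motif),
              motif_strength = motif_strength,
              bg_cost_min = bg_cost_min, bg_cost_max = bg_cost_max,
              noise_prob = noise_prob,
              noise_cost_min = noise_cost_min,
              noise_cost_max = noise_cost_max,
              multi_label_frac = multi_label_frac,
              class_size_decay = class_size_decay,
              traveler_frac = traveler_frac,
              homolog_coverage = homolog_coverage,
              pide_range = pide_range,
              within_ppi_rate = within_ppi_rate,
              between_ppi_rate = between_ppi_rate,
              enriched_term_odds = enriched_term_odds,
              n_filler_terms = as.integer(n_filler_terms),
              seed = as.integer(seed))
  stopifnot(cfg$n_classes >= 1, cfg$n_classes <= 13,
            cfg$motif_k >= 1,
            cfg$multi_label_frac >= 0, cfg$multi_label_frac <= 1,
            cfg$traveler_frac >= 0, cfg$traveler_frac <= 1,
            cfg$homolog_coverage >= 0, cfg$homolog_coverage <= 1,
            cfg$within_ppi_rate >= 0, cfg$within_ppi_rate <= 1,
            cfg$between_ppi_rate >= 0, cfg$between_ppi_rate <= 1,
            !is.na(cfg$seed))
  structure(cfg, class = "snl_gen_config")
}

# distinct random k-mer indices: n draws without replacement from [0, 20^k)
.random_motifs <- function(n, k) {
  space <- 20^k
  idx <- unique(floor(runif(4 * n) * space))
  while (length(idx) < n) {
    idx <- unique(c(idx, floor(runif(4 * n) * space)))
  }
  idx[seq_len(n)]
}

# plant motif `kmer_idx` at `start`: motif residues get cost
# `motif_strength`, all other residues at those positions are pushed to
# the expensive background range so only the motif clears the threshold.
.plant <- function(scores, kmer_idx, k, start, strength, bg_min, bg_max) {
  residues <- match(strsplit(kmer_string(kmer_idx, k), "")[[1]],
                    aa_alphabet())
  for (j in seq_len(k)) {
    scores[start + j - 1L, ] <- runif(20, bg_min, bg_max)
    scores[start + j - 1L, residues[j]] <- strength
  }
  scores
}

#' Generate labeled synthetic profiles
#'
#' Each class receives a distinct set of planted motifs; each protein of
#' the class carries every class motif at `sites_per_motif` random
#' non-overlapping positions. A `multi_label_frac` fraction of proteins
#' additionally carries the motifs (and label) of a second class, and a
#' `traveler_frac` fraction carries the traveler motif set and flag.
#'
#' @param config An [generator_config()].
#' @return List with `profiles` (named list of `snl_profile`),
#'   `annotations` (`snl_annotations`) and `truth` (planted motif indices
#'   per class, planted site bookkeeping per protein).
#' @export
gen_profiles <- function(config) {
  k <- config$motif_k
  L <- config$profile_length
  if (k > L) stop("motif_k exceeds profile_length")
  labels13 <- subnuclear_compartments()[seq_len(config$n_classes)]
  sizes <- pmax(0L, round(config$n_per_class *
                            config$class_size_decay^(seq_len(config$n_classes) - 1)))
  withr::with_seed(config$seed, {
    n_motifs_total <- (config$n_classes + 1L) * config$n_motifs_per_class
    motif_pool <- .random_motifs(n_motifs_total, k)
    class_motifs <- split(motif_pool[seq_len(config$n_classes *
                                               config$n_motifs_per_class)],
                          rep(seq_len(config$n_classes),
                              each = config$n_motifs_per_class))
    names(class_motifs) <- labels13
    traveler_motifs <- motif_pool[(config$n_classes *
                                     config$n_motifs_per_class + 1L):
                                    n_motifs_total]
    profiles <- list()
    labels <- list()
    traveler <- logical()
    site_truth <- list()
    for (ci in seq_len(config$n_classes)) {
      if (sizes[ci] == 0L) next
      for (m in seq_len(sizes[ci])) {
        id <- sprintf("%s_%03d", gsub(" ", "_", labels13[ci]), m)
        lab <- labels13[ci]
        if (config$n_classes > 1 && runif(1) < config$multi_label_frac) {
          lab <- c(lab, sample(setdiff(labels13, lab), 1L))
        }
        is_trav <- runif(1) < config$traveler_frac
        scores <- matrix(runif(L * 20, config$bg_cost_min,
                               config$bg_cost_max), L, 20)
        cheap <- runif(L * 20) < config$noise_prob
        scores[cheap] <- runif(sum(cheap), config$noise_cost_min,
                               config$noise_cost_max)
        motifs <- unlist(class_motifs[lab], use.names = FALSE)
        if (is_trav) motifs <- c(motifs, traveler_motifs)
        plan <- rep(motifs, each = config$sites_per_motif)
        # non-overlapping placement: sample from the k-aligned blocks
        blocks <- 1L + k * (seq_len(L %/% k) - 1L)
        if (length(plan) > length(blocks)) {
          stop("profile_length too small to place all motif sites")
        }
        starts <- sample(blocks, length(plan))
        placed <- data.frame(motif = plan, start = starts)
        for (r in seq_len(nrow(placed))) {
          scores <- .plant(scores, placed$motif[r], k, placed$start[r],
                           config$motif_strength, config$bg_cost_min,
                           config$bg_cost_max)
        }
        profiles[[id]] <- new_profile(id, scores, source = "synthetic")
        labels[[id]] <- lab
        traveler[id] <- is_trav
        site_truth[[id]] <- placed
      }
    }
  })
  list(profiles = profiles,
       annotations = annotation_db(labels = labels, traveler = traveler),
       truth = list(class_motifs = class_motifs,
                    traveler_motifs = traveler_motifs,
                    sites = site_truth))
}

#' Generate a synthetic homology hit table
#'
#' A `homolog_coverage` fraction of annotated queries receives one
#' significant hit to a same-class annotated donor (E-value well below the
#' threshold, identity drawn from `pide_range`); the remaining queries
#' receive either nothing or an above-threshold decoy hit. Queries whose
#' class has no other member cannot receive a donor and stay uncovered.
#'
#' @param config An [generator_config()].
#' @param db An `snl_annotations` naming the queries and donors.
#' @param evalue_threshold Significance threshold the covered hits must
#'   beat.
#' @return List with `hits` (data frame as from [read_blast_tab()]) and
#'   `covered` (character vector of queries given a significant donor).
#' @export
gen_homology <- function(config, db, evalue_threshold = 1e-20) {
  ids <- names(db$labels)
  withr::with_seed(config$seed + 1L, {
    rows <- list()
    covered <- character(0)
    for (id in ids) {
      if (runif(1) < config$homolog_coverage) {
        same <- setdiff(
          ids[vapply(db$labels, function(l) {
            any(l %in% db$labels[[id]])
          }, logical(1))], id)
        if (length(same) == 0L) next
        donor <- if (length(same) == 1L) same else sample(same, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          query = id, subject = donor,
          pide = runif(1, config$pide_range[1], config$pide_range[2]),
          evalue = evalue_threshold * 10^(-runif(1, 5, 40)))
        covered <- c(covered, id)
      } else if (runif(1) < 0.5) {
        decoy <- if (length(ids) == 1L) ids else sample(setdiff(ids, id), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          query = id, subject = decoy,
          pide = runif(1, 15, 30),
          evalue = evalue_threshold * 10^runif(1, 2, 10))
      }
    }
  })
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(), subject = character(),
               pide = numeric(), evalue = numeric())
  list(hits = hits, covered = covered)
}

#' Generate a synthetic interaction edge table
#'
#' Every unordered protein pair is connected independently: with
#' `within_ppi_rate` when the two proteins share a compartment label,
#' `between_ppi_rate` otherwise. Evidence columns are populated so the
#' edges pass the binary-direct evidence filter of [read_edges()].
#'
#' @param config An [generator_config()].
#' @param compartment_map Named list: protein id -> label set.
#' @return Data frame with columns `a`, `b`, `is_direct`, `y2h`,
#'   `n_pubmed`.
#' @export
gen_ppi <- function(config, compartment_map) {
  ids <- names(compartment_map)
  if (length(ids) < 2L) stop("need at least two proteins")
  pairs <- combn(ids, 2L)
  shares <- vapply(seq_len(ncol(pairs)), function(i) {
    length(intersect(compartment_map[[pairs[1, i]]],
                     compartment_map[[pairs[2, i]]])) > 0L
  }, logical(1))
  withr::with_seed(config$seed + 2L, {
    rate <- ifelse(shares, config$within_ppi_rate, config$between_ppi_rate)
    drawn <- runif(ncol(pairs)) < rate
  })
  data.frame(a = pairs[1, drawn], b = pairs[2, drawn],
             is_direct = 1L, y2h = 1L, n_pubmed = 2L)
}

#' Generate a synthetic GO annotation table
#'
#' One designated term per compartment is enriched in that compartment's
#' proteins at the configured odds ratio (baseline annotation probability
#' 0.2 outside the target set); filler terms annotate all proteins at a
#' uniform rate.
#'
#' @param config An [generator_config()].
#' @param target_sets Named list: compartment -> protein ids.
#' @param background Character vector of all protein ids.
#' @return List with `go` (data frame `id`, `term`), `designated` (named
#'   character vector compartment -> enriched term id).
#' @export
gen_go <- function(config, target_sets, background) {
  p0 <- 0.2
  odds0 <- p0 / (1 - p0)
  p1 <- config$enriched_term_odds * odds0 /
    (1 + config$enriched_term_odds * odds0)
  designated <- setNames(sprintf("GO:9%06d", seq_along(target_sets)),
                         names(target_sets))
  withr::with_seed(config$seed + 3L, {
    rows <- list()
    for (ci in seq_along(target_sets)) {
      inside <- background %in% target_sets[[ci]]
      p <- ifelse(inside, p1, p0)
      hit <- runif(length(background)) < p
      if (any(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          id = background[hit], term = unname(designated[ci]))
      }
    }
    for (t in seq_len(config$n_filler_terms)) {
      hit <- runif(length(background)) < 0.15
      if (any(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          id = background[hit], term = sprintf("GO:0%06d", t))
      }
    }
  })
  go <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), term = character())
  list(go = go, designated = designated)
}
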