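test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  p <- runif(40)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("enrichment p-values match closed forms and the summation oracle", {
  background <- sprintf("b%03d", 1:100)
  target <- background[1:5]
  go_map <- c(
    setNames(lapply(1:5, function(i) "GO:X"), target),          # exact hit
    setNames(lapply(6:100, function(i) "GO:flat"), background[6:100]))
  go_map <- lapply(background, function(id) {
    c(if (id %in% target) "GO:X", "GO:flat")
  })
  names(go_map) <- background
  res <- hypergeom_enrichment(target, background, go_map)
  px <- res$p_value[res$term == "GO:X"]
  expect_equal(px, 1 / choose(100, 5), tolerance = 1e-12)
  expect_equal(res$p_value[res$term == "GO:flat"], 1)
  expect_true(res$significant[res$term == "GO:X"])

  set.seed(7)
  for (i in 1:10) {
    N <- 60
    n <- 15
    K <- sample(5:30, 1)
    bg <- sprintf("p%02d", 1:N)
    tg <- sample(bg, n)
    members <- sample(bg, K)
    gm <- lapply(bg, function(id) if (id %in% members) "GO:T" else "GO:other")
    names(gm) <- bg
    x <- length(intersect(tg, members))
    res_i <- hypergeom_enrichment(tg, bg, gm)
    expect_equal(res_i$p_value[res_i$term == "GO:T"],
                 hyper_tail(x, K, N, n), tolerance = 1e-12)
  }
})

test_that("targets outside the background are rejected", {
  expect_error(hypergeom_enrichment(c("a", "zz"), c("a", "b"),
                                    list(a = "GO:1", b = "GO:1")),
               "subset")
})

test_that("PPI odds match brute-force pair enumeration on a toy graph", {
  set.seed(19)
  labels <- subnuclear_compartments()[1:4]
  ids <- sprintf("n%02d", 1:20)
  comp <- lapply(seq_along(ids), function(i) {
    sample(labels, sample(1:2, 1, prob = c(0.7, 0.3)))
  })
  names(comp) <- ids
  pairs <- combn(ids, 2)
  drawn <- runif(ncol(pairs)) < 0.3
  edges <- data.frame(a = pairs[1, drawn], b = pairs[2, drawn])
  g <- ppi_graph(edges, compartments = comp)
  res <- ppi_odds(g, labels = labels)
  oracle <- brute_ppi_counts(edges, comp, labels)
  expect_equal(res$num_pos, oracle$num_pos)
  expect_equal(res$num_obs, oracle$num_obs)
  obs_total <- sum(oracle$num_obs[upper.tri(oracle$num_obs, diag = TRUE)])
  pos_total <- sum(oracle$num_pos[upper.tri(oracle$num_pos, diag = TRUE)])
  exp_manual <- oracle$num_pos / pos_total * obs_total
  expect_equal(res$odds, ifelse(exp_manual > 0,
                                oracle$num_obs / exp_manual, NA_real_))
  # the expectation conserves the observed mass exactly
  expect_equal(sum(res$num_exp[upper.tri(res$num_exp, diag = TRUE)]),
               res$num_obs_total, tolerance = 1e-12)
})

test_that("absent between-compartment edges give zero odds", {
  comp <- list(a1 = "chromatin", a2 = "chromatin", b1 = "nucleolus",
               b2 = "nucleolus")
  edges <- data.frame(a = c("a1", "b1"), b = c("a2", "b2"))
  g <- ppi_graph(edges, compartments = comp)
  res <- ppi_odds(g, labels = c("chromatin", "nucleolus"))
  expect_equal(res$odds["chromatin", "nucleolus"], 0)
  expect_gt(res$odds["chromatin", "chromatin"], 0)
})

test_that("degree and component statistics handle canonical graphs", {
  star <- data.frame(a = rep("hub", 4), b = paste0("leaf", 1:4))
  gs <- ppi_graph(star, groups = c(hub = "center",
                                   setNames(rep("leaf", 4),
                                            paste0("leaf", 1:4))))
  st <- degree_stats(gs)
  expect_equal(unname(st$mean_degree["center"]), 4)
  expect_equal(unname(st$mean_degree["leaf"]), 1)
  expect_equal(st$n_components, 1)
  expect_equal(unname(st$largest_fraction["leaf"]), 1)

  tri2 <- data.frame(a = c("x1", "x2", "x3", "y1", "y2", "y3"),
                     b = c("x2", "x3", "x1", "y2", "y3", "y1"))
  gt <- ppi_graph(tri2)
  st2 <- degree_stats(gt)
  expect_equal(st2$n_components, 2)
  expect_equal(sort(st2$components$size), c(3, 3))
  expect_equal(unname(st2$mean_degree["untagged"]), 2)
})

test_that("group-dependent edge rates show up in mean degrees", {
  set.seed(23)
  ids <- sprintf("v%03d", 1:60)
  groups <- setNames(rep(c("dense", "sparse"), each = 30), ids)
  pairs <- combn(ids, 2)
  rate <- ifelse(groups[pairs[1, ]] == "dense" &
                   groups[pairs[2, ]] == "dense", 0.4, 0.05)
  drawn <- runif(ncol(pairs)) < rate
  g <- ppi_graph(data.frame(a = pairs[1, drawn], b = pairs[2, drawn]),
                 groups = groups)
  st <- degree_stats(g)
  expect_gt(st$mean_degree["dense"], st$mean_degree["sparse"])
})

test_that("self-loops and duplicate edges are dropped from the graph", {
  edges <- data.frame(a = c("p1", "p1", "p1", "p2"),
                      b = c("p2", "p2", "p1", "p3"))
  g <- ppi_graph(edges)
  expect_equal(igraph::ecount(g$graph), 2)
  expect_equal(igraph::vcount(g$graph), 3)
})
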