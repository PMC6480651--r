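mk_pred <- function(protein, labels, ri = 50L, scores = NULL,
                    source = "ML") {
  structure(list(protein = protein, labels = labels, ri = as.integer(ri),
                 source = source, scores = scores),
            class = "snl_prediction")
}

mk_db <- function(labels) annotation_db(labels = labels)

test_that("perfect single-label predictions give a diagonal matrix", {
  db <- mk_db(list(p1 = "chromatin", p2 = "nucleolus", p3 = "kinetochore"))
  preds <- list(mk_pred("p1", "chromatin"), mk_pred("p2", "nucleolus"),
                mk_pred("p3", "kinetochore"))
  conf <- build_confusion(db, preds)
  expect_equal(sum(conf), 3)
  expect_equal(conf["chromatin", "chromatin"], 1)
  expect_equal(sum(conf) - sum(diag(conf[colnames(conf), ])), 0)
  expect_equal(q_n(conf), 100)
})

test_that("empty predictions land in the None row", {
  db <- mk_db(list(p1 = "chromatin", p2 = c("nucleolus", "PML body")))
  preds <- list(mk_pred("p1", character(0), source = "NONE"),
                mk_pred("p2", character(0), source = "NONE"))
  conf <- build_confusion(db, preds)
  expect_equal(unname(conf["None", c("chromatin", "nucleolus", "PML body")]),
               c(1, 1, 1))
  expect_equal(sum(conf), 3)
  expect_equal(q_n(conf), 0)
})

test_that("fractional attribution spreads misses but keeps column sums", {
  db <- mk_db(list(p1 = "chromatin", p2 = "nucleolus", p3 = "chromatin"))
  preds <- list(
    mk_pred("p1", "chromatin"),
    mk_pred("p2", c("chromatin", "kinetochore")),  # miss, two predicted
    mk_pred("p3", "chromatin"))
  conf <- build_confusion(db, preds, attribution = "fractional")
  expect_equal(conf["chromatin", "nucleolus"], 0.5)
  expect_equal(conf["kinetochore", "nucleolus"], 0.5)
  expect_equal(unname(colSums(conf)[c("chromatin", "nucleolus")]), c(2, 1))

  conf_top <- build_confusion(db, list(
    mk_pred("p2", c("chromatin", "kinetochore"),
            scores = c(chromatin = 0.2, kinetochore = 0.9))), "top-score")
  expect_equal(conf_top["kinetochore", "nucleolus"], 1)
})

test_that("column sums equal observed annotation counts in both modes", {
  sim <- gen_profiles(small_config(multi_label_frac = 0.4))
  db <- sim$annotations
  set.seed(8)
  preds <- lapply(names(db$labels), function(id) {
    labs <- sample(subnuclear_compartments()[1:4],
                   sample(0:2, 1))
    mk_pred(id, labs, scores = setNames(runif(4), subnuclear_compartments()[1:4]))
  })
  obs_counts <- table(factor(unlist(db$labels),
                             levels = subnuclear_compartments()))
  for (mode in c("top-score", "fractional")) {
    conf <- build_confusion(db, preds, attribution = mode)
    expect_equal(unname(colSums(conf)), as.numeric(obs_counts),
                 tolerance = 1e-12)
  }
})

test_that("predictions for unknown proteins are rejected", {
  db <- mk_db(list(p1 = "chromatin"))
  expect_error(build_confusion(db, list(mk_pred("ghost", "chromatin"))),
               "ghost")
})

test_that("accuracy is invariant under class permutation and matches random baseline", {
  labels <- subnuclear_compartments()[1:5]
  set.seed(44)
  ids <- sprintf("p%03d", 1:400)
  truth <- setNames(as.list(sample(labels, 400, replace = TRUE)), ids)
  db <- mk_db(truth)
  preds <- lapply(ids, function(id) mk_pred(id, sample(labels, 1)))
  conf <- build_confusion(db, preds, labels = labels)
  q <- q_n(conf)
  # uniform random assignment over n equal classes scores about 100/n
  expect_lt(abs(q - 100 / 5), 7.5)
  perm <- sample(5)
  conf_perm <- conf[c(perm, 6), perm]
  expect_equal(q_n(conf_perm), q)
})

test_that("per-class rates follow their defining formulas", {
  counts <- list(TP = 8, FN = 6, FP = 4, TN = 100)
  expect_equal(tpr(counts), 100 * 8 / 14)
  expect_equal(fpr(counts), 100 - 100 * 100 / 104)
  expect_warning(v <- tpr(list(TP = 0, FN = 0)), "undefined")
  expect_true(is.na(v))
  expect_warning(w <- fpr(list(TN = 0, FP = 0)), "undefined")
  expect_true(is.na(w))
  perfect <- list(TP = 10, FN = 0, FP = 0, TN = 90)
  expect_equal(tpr(perfect), 100)
  expect_equal(fpr(perfect), 0)
})

test_that("class counts derived from a confusion matrix sum correctly", {
  conf <- dev_confusion()
  counts <- confusion_class_counts(conf)
  expect_equal(counts$TP + counts$FN, unname(colSums(conf)))
  expect_equal(counts$TP + counts$FP + counts$FN + counts$TN,
               rep(sum(conf), 13))
  spindle <- counts[counts$label == "spindle apparatus", ]
  expect_equal(tpr(spindle), 100 * 8 / 14, tolerance = 1e-12)
})

test_that("AUC matches the pair-counting oracle and handles edge cases", {
  expect_equal(roc_auc(c(5, 4, 3, 1, 0.5), c(TRUE, TRUE, TRUE, FALSE, FALSE)),
               1.0)
  expect_equal(roc_auc(rep(2, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both")
  set.seed(12)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    scores <- sample(round(rnorm(n), 1))  # coarse values force ties
    truth <- runif(n) < 0.4
    if (!any(truth) || all(truth)) next
    expect_equal(roc_auc(scores, truth), pair_count_auc(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("the reliability curve starts at full coverage and overall accuracy", {
  db <- mk_db(list(p1 = "chromatin", p2 = "nucleolus", p3 = "chromatin",
                   p4 = "PML body"))
  preds <- list(mk_pred("p1", "chromatin", ri = 90),
                mk_pred("p2", "chromatin", ri = 30),
                mk_pred("p3", "chromatin", ri = 70),
                mk_pred("p4", "PML body", ri = 10))
  curve <- ri_curve(preds, db)
  expect_equal(curve$ri_threshold, seq(0, 100, 20))
  expect_equal(curve$coverage[1], 100)
  expect_equal(curve$accuracy[1], q_n(build_confusion(db, preds)))
  expect_true(all(diff(curve$coverage) <= 0))
  expect_equal(curve$coverage[curve$ri_threshold == 80], 25)
  expect_equal(curve$accuracy[curve$ri_threshold == 80], 100)
})

test_that("stratified folds balance classes and partition the ids", {
  ids <- sprintf("p%03d", 1:100)
  labels <- setNames(rep(c("chromatin", "nucleolus"), each = 50), ids)
  folds <- stratified_kfold(ids, labels, k = 5, seed = 9)
  expect_length(folds, 5)
  expect_setequal(unlist(folds), ids)
  expect_equal(anyDuplicated(unlist(folds)), 0L)
  for (f in folds) {
    expect_equal(sum(labels[f] == "chromatin"), 10)
    expect_equal(sum(labels[f] == "nucleolus"), 10)
  }
})

test_that("tiny classes spread at most one member per fold", {
  ids <- c(sprintf("a%02d", 1:20), "r1", "r2", "r3")
  labels <- setNames(c(rep("chromatin", 20), rep("perinucleolar", 3)), ids)
  folds <- stratified_kfold(ids, labels, k = 5, seed = 2)
  per_fold <- vapply(folds, function(f) {
    sum(labels[f] == "perinucleolar")
  }, numeric(1))
  expect_true(all(per_fold <= 1))
  expect_error(stratified_kfold(c("x", "y"), c(x = "a", y = "b"), k = 5),
               "exceeds")
})
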