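# Two linearly separable synthetic classes via planted motifs.
separable_sim <- function(n_classes = 2, n = 10, seed = 7) {
  gen_profiles(generator_config(n_classes = n_classes, n_per_class = n,
                                profile_length = 80, n_motifs_per_class = 2,
                                sites_per_motif = 2, multi_label_frac = 0,
                                traveler_frac = 0.5, noise_prob = 0.01,
                                seed = seed))
}

test_that("well-separated classes reach perfect training accuracy", {
  sim <- separable_sim()
  bat <- suppressWarnings(train_battery(sim$profiles, sim$annotations))
  dm <- decision_matrix(bat, sim$profiles)
  for (id in names(sim$profiles)) {
    expect_setequal(predict_labels(setNames(dm[id, ], colnames(dm))),
                    sim$annotations$labels[[id]])
  }
})

test_that("inverse-frequency weighting bounds dual coefficients at C * w", {
  sim <- separable_sim(n = 12, seed = 21)
  # imbalance 1:5 between the two classes by dropping positives
  ids <- names(sim$profiles)
  cls1 <- names(Filter(function(l) "chromatin" %in% l,
                       sim$annotations$labels))
  keep <- c(cls1[1:4], setdiff(ids, cls1))
  db <- annotation_db(labels = sim$annotations$labels[keep],
                      traveler = sim$annotations$traveler[keep])
  cfg <- svm_config(C = 2)
  bat <- suppressWarnings(train_battery(sim$profiles[keep], db, cfg))
  cls <- bat$classifiers$chromatin
  n <- length(keep)
  n_pos <- 4
  w_pos <- n / (2 * n_pos)
  w_neg <- n / (2 * (n - n_pos))
  expect_equal(w_pos / w_neg, (n - n_pos) / n_pos)  # inverse-frequency ratio
  pos_coef <- cls$dual_coefficients[cls$dual_coefficients > 0]
  neg_coef <- cls$dual_coefficients[cls$dual_coefficients < 0]
  expect_lte(max(pos_coef), cfg$C * w_pos + 1e-6)
  expect_lte(max(-neg_coef), cfg$C * w_neg + 1e-6)
})

test_that("decision values match hand recomputation from stored fields", {
  sim <- separable_sim()
  kp <- kernel_params(k = 2, sigma = 3)
  cfg <- svm_config(kernel_params = kp)
  fvs <- feature_maps(sim$profiles, kp)
  bat <- suppressWarnings(train_battery(fvs, sim$annotations, cfg))
  cls <- bat$classifiers[[1]]
  x <- fvs[[3]]
  # dense-vector kernel oracle, independent of the sparse dot path
  kv <- vapply(cls$support_fvs, function(s) {
    d <- dense_dot(s, x)
    d / sqrt(dense_dot(s, s) * dense_dot(x, x))
  }, numeric(1))
  by_hand <- sum(cls$dual_coefficients * kv) + cls$bias
  got <- decision_values(bat, sim$profiles[[3]])
  expect_equal(unname(got[cls$positive_label]), by_hand, tolerance = 1e-9)
})

test_that("decision values are invariant to classifier and sample order", {
  sim <- separable_sim()
  cfg <- svm_config(tol = 1e-8)
  fvs <- feature_maps(sim$profiles, cfg$kernel_params)
  bat <- suppressWarnings(train_battery(fvs, sim$annotations, cfg))
  dm <- decision_matrix(bat, fvs)
  set.seed(5)
  perm <- sample(length(fvs))
  bat2 <- suppressWarnings(train_battery(fvs[perm], sim$annotations, cfg))
  dm2 <- decision_matrix(bat2, fvs)
  expect_equal(dm2[rownames(dm), colnames(dm)], dm, tolerance = 1e-6)
})

test_that("increasing C never hurts training accuracy on separable data", {
  sim <- separable_sim(n = 8, seed = 31)
  accs <- vapply(c(0.1, 1, 10), function(C) {
    bat <- suppressWarnings(train_battery(sim$profiles, sim$annotations,
                                          svm_config(C = C)))
    dm <- decision_matrix(bat, sim$profiles)
    mean(vapply(rownames(dm), function(id) {
      setequal(predict_labels(setNames(dm[id, ], colnames(dm))),
               sim$annotations$labels[[id]])
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("empty classes are skipped and score -Inf", {
  sim <- separable_sim()
  expect_warning(bat <- train_battery(sim$profiles, sim$annotations),
                 "skipped")
  dv <- decision_values(bat, sim$profiles[[1]])
  expect_length(dv, 13)
  expect_true(is.infinite(dv[["perinucleolar"]]) && dv[["perinucleolar"]] < 0)
})

test_that("the traveler classifier trains and rejects degenerate flags", {
  sim <- separable_sim(n = 12, seed = 3)
  bat <- train_traveler(sim$profiles, sim$annotations)
  dm <- decision_matrix(bat, sim$profiles)
  truth <- sim$annotations$traveler[rownames(dm)]
  expect_gte(mean((dm[, "traveler"] > 0) == truth), 0.9)

  all_pos <- annotation_db(labels = sim$annotations$labels,
                           traveler = setNames(rep(TRUE, length(truth)),
                                               names(truth)))
  expect_error(train_traveler(sim$profiles, all_pos), "degenerate")
})

test_that("label thresholding implements the positive-score rule", {
  s <- c(a = -1, b = -0.2, c = -3)
  expect_length(predict_labels(s), 0)
  expect_setequal(predict_labels(c(a = 0.4, b = 0.1, c = -1)), c("a", "b"))
  expect_equal(predict_labels(c(a = 0.3, b = -0.1, c = -0.5)), "a")
})

test_that("battery serialization round-trips decision values exactly", {
  sim <- separable_sim()
  cfg <- svm_config(kernel_params = kernel_params(k = 3, sigma = 5))
  bat <- suppressWarnings(train_battery(sim$profiles, sim$annotations, cfg))
  f <- withr::local_tempfile(fileext = ".json")
  write_battery(bat, f)
  bat2 <- read_battery(f)
  expect_equal(names(bat2$classifiers), names(bat$classifiers))
  expect_identical(bat2$kernel_params$k, 3L)
  dv1 <- decision_values(bat, sim$profiles[[5]])
  dv2 <- decision_values(bat2, sim$profiles[[5]])
  expect_equal(dv1, dv2, tolerance = 1e-12)
})
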