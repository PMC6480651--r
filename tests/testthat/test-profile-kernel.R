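test_that("conserved k-mer enumeration matches forced cases", {
  p_all1 <- new_profile("u", matrix(1, 4, 20), source = "synthetic")
  expect_length(conserved_kmers_at(p_all1, 1, kernel_params(k = 2, sigma = 1.5)),
                0)

  # exactly one zero-cost residue per position, everything else expensive
  m <- matrix(10, 3, 20)
  m[1, 3] <- 0
  m[2, 5] <- 0
  p_single <- new_profile("s", m, source = "synthetic")
  got <- conserved_kmers_at(p_single, 1, kernel_params(k = 2, sigma = 0.5))
  expect_equal(got, (3 - 1) * 20 + (5 - 1))

  expect_error(conserved_kmers_at(p_all1, 4, kernel_params(k = 2, sigma = 1)),
               "pos")
})

test_that("pruned enumeration equals exhaustive enumeration", {
  set.seed(42)
  for (i in 1:30) {
    k <- sample(2:3, 1)
    p <- random_profile(paste0("r", i), 5, max_cost = 2.5)
    sigma <- runif(1, 0.5, 3)
    pos <- sample(5 - k + 1, 1)
    expect_equal(conserved_kmers_at(p, pos, kernel_params(k = k, sigma = sigma)),
                 brute_conserved(p, pos, k, sigma))
  }
})

test_that("feature map counts conserved windows additively", {
  # two identical windows, separated by an expensive position
  m <- matrix(10, 5, 20)
  m[1, 1] <- m[2, 2] <- 0   # "AR" at positions 1-2
  m[4, 1] <- m[5, 2] <- 0   # "AR" at positions 4-5
  p <- new_profile("w", m, source = "synthetic")
  fv <- feature_map(p, kernel_params(k = 2, sigma = 0.5))
  expect_equal(fv$idx, kmer_index("AR"))
  expect_equal(fv$counts, 2)
})

test_that("infinite threshold saturates every k-mer at L - k + 1 counts", {
  p <- random_profile("sat", 4, max_cost = 1)
  fv <- feature_map(p, kernel_params(k = 2, sigma = 1e9))
  expect_length(fv$idx, 400)
  expect_true(all(fv$counts == 3))
  expect_equal(sum(fv$counts), 3 * 400)
})

test_that("profiles shorter than k yield an empty vector with a warning", {
  p <- random_profile("short", 2)
  expect_warning(fv <- feature_map(p, kernel_params(k = 4, sigma = 6)),
                 "shorter")
  expect_length(fv$idx, 0)
})

test_that("planted motifs are recovered with exact counts", {
  cfg <- small_config(noise_prob = 0, motif_strength = 0)
  sim <- gen_profiles(cfg)
  kp <- kernel_params(k = cfg$motif_k, sigma = 6)
  for (id in names(sim$profiles)[1:5]) {
    fv <- feature_map(sim$profiles[[id]], kp)
    placed <- sim$truth$sites[[id]]
    expected <- table(placed$motif)
    got <- fv$counts[match(as.numeric(names(expected)), fv$idx)]
    expect_equal(got, as.numeric(expected), ignore_attr = TRUE)
  }
})

test_that("sparse kernel agrees with the dense oracle and normalizes", {
  set.seed(11)
  kp <- kernel_params(k = 2, sigma = 2)
  u <- feature_map(random_profile("u", 12, 2), kp)
  v <- feature_map(random_profile("v", 12, 2), kp)
  expect_equal(profile_kernel(u, v, normalize = FALSE), dense_dot(u, v))
  expect_equal(profile_kernel(u, u, normalize = TRUE), 1)

  disj_a <- structure(list(k = 2L, idx = c(0, 5), counts = c(1, 2)),
                      class = "snl_fv")
  disj_b <- structure(list(k = 2L, idx = c(7, 9), counts = c(3, 1)),
                      class = "snl_fv")
  expect_equal(profile_kernel(disj_a, disj_b, normalize = FALSE), 0)
  expect_equal(profile_kernel(disj_a, disj_b, normalize = TRUE), 0)
  bad <- structure(list(k = 3L, idx = 0, counts = 1), class = "snl_fv")
  expect_error(profile_kernel(disj_a, bad), "different k")
})

test_that("kernel symmetry and Cauchy-Schwarz hold on random profiles", {
  set.seed(13)
  kp <- kernel_params(k = 2, sigma = 2.5)
  fvs <- lapply(1:8, function(i) feature_map(random_profile(paste0("p", i),
                                                            10, 2), kp))
  for (i in 1:7) {
    u <- fvs[[i]]
    v <- fvs[[i + 1]]
    kuv <- profile_kernel(u, v, normalize = FALSE)
    expect_equal(kuv, profile_kernel(v, u, normalize = FALSE))
    expect_lte(abs(kuv),
               sqrt(profile_kernel(u, u, FALSE) * profile_kernel(v, v, FALSE)) +
                 1e-12)
  }
})

test_that("feature support grows monotonically with sigma", {
  set.seed(17)
  p <- random_profile("mono", 15, 3)
  prev <- numeric(0)
  for (sigma in c(1, 2, 3, 4.5)) {
    fv <- feature_map(p, kernel_params(k = 3, sigma = sigma))
    expect_true(all(prev %in% fv$idx))
    prev <- fv$idx
  }
})

test_that("kernel matrices are symmetric, unit-diagonal and PSD", {
  set.seed(19)
  profs <- lapply(1:10, function(i) random_profile(paste0("m", i), 12, 2))
  names(profs) <- paste0("m", 1:10)
  kp <- kernel_params(k = 2, sigma = 2.5)
  K <- kernel_matrix(profs, kp)
  expect_equal(K, t(K))
  expect_equal(unname(diag(K)), rep(1, 10))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)

  K1 <- kernel_matrix(profs[1], kp)
  expect_equal(unname(K1), matrix(1, 1, 1))

  perm <- c(3, 1, 2, 5, 4, 6, 10, 9, 7, 8)
  Kp <- kernel_matrix(profs[perm], kp)
  expect_equal(Kp, K[perm, perm])
})

test_that("feature vectors dump to a readable k-mer table", {
  fv <- structure(list(k = 2L, idx = c(kmer_index("AR"), kmer_index("ND")),
                       counts = c(2, 1)), class = "snl_fv")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_vector(fv, f)
  df <- read.delim(f)
  expect_equal(df$kmer, c("AR", "ND"))
  expect_equal(df$count, c(2, 1))
})
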