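test_that("indicator embedding makes squared Euclidean = base-pair distance", {
  set.seed(21)
  structs <- lapply(1:12, function(i) random_nested_structure(22))
  emb <- multifold:::pair_indicator_matrix(structs, 22)
  for (a in 1:11) {
    for (b in (a + 1):12) {
      expect_identical(sum((emb[a, ] - emb[b, ])^2),
                       as.numeric(basepair_distance(structs[[a]], structs[[b]])))
    }
  }
})

test_that("cluster_k recovers separated groups and is deterministic", {
  sA <- rna_structure(30, rbind(c(1, 12), c(2, 11), c(3, 10)))
  sB <- rna_structure(30, rbind(c(15, 28), c(16, 27), c(17, 26), c(18, 25)))
  pool <- pool_samples(list(
    fake_sample_set(c(rep(list(sA), 10), rep(list(sB), 10)), rep(0, 20), "d1")))
  expect_equal(cluster_k(pool, 1), rep(1L, 20))
  lab <- cluster_k(pool, 2, seed = 3)
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:10])), 1)   # exact group recovery
  expect_equal(length(unique(lab[11:20])), 1)
  expect_false(lab[1] == lab[11])
  expect_identical(lab, cluster_k(pool, 2, seed = 3))
  # more clusters than distinct structures: one per distinct structure
  expect_equal(length(unique(cluster_k(pool, 10, seed = 1))), 2)
  expect_error(cluster_k(pool, 0), "k must be")
})

test_that("feature probabilities follow the Boltzmann-weighted formula", {
  s1 <- rna_structure(12, rbind(c(2, 9), c(3, 8)))
  s2 <- rna_structure(12, rbind(c(2, 9), c(1, 12)))
  # singleton cluster: its features have probability 1
  pool1 <- pool_samples(list(fake_sample_set(list(s1), 0, "d")))
  fp1 <- feature_probabilities(pool1)
  expect_equal(fp1$pair[2, 9], 1)
  expect_equal(fp1$pair[3, 8], 1)
  expect_equal(sum(fp1$pair), 2)
  expect_equal(fp1$unpaired[1], 1)
  # two equal-energy structures: shared pair 1.0, private pairs 0.5
  pool2 <- pool_samples(list(fake_sample_set(list(s1, s2), c(1, 1), "d")))
  fp2 <- feature_probabilities(pool2)
  expect_equal(fp2$pair[2, 9], 1)
  expect_equal(fp2$pair[3, 8], 0.5)
  expect_equal(fp2$pair[1, 12], 0.5)
  # duplicates are dropped before weighting (non-redundant set)
  pool3 <- pool_samples(list(
    fake_sample_set(c(rep(list(s1), 5), list(s2)), rep(1, 6), "d")))
  fp3 <- feature_probabilities(pool3)
  expect_equal(fp3$pair[3, 8], 0.5)
  # hand-evaluated random case with distinct Turner energies
  set.seed(22)
  structs <- lapply(1:4, function(i) random_nested_structure(14))
  e <- runif(4, -3, 3)
  pool4 <- pool_samples(list(fake_sample_set(structs, e, "d")))
  fp4 <- feature_probabilities(pool4)
  db <- vapply(structs, as_dotbracket, character(1))
  keep <- !duplicated(db)
  w <- exp(-e[keep] / RT_37C)
  w <- w / sum(w)
  target <- sum(w[vapply(structs[keep], function(s)
    any(s$pairs[, 1] == structs[[1]]$pairs[1, 1] &
        s$pairs[, 2] == structs[[1]]$pairs[1, 2]), logical(1))])
  expect_equal(fp4$pair[structs[[1]]$pairs[1, 1], structs[[1]]$pairs[1, 2]],
               target, tolerance = 1e-12)
})

test_that("per-position feature probabilities sum to one", {
  set.seed(23)
  structs <- lapply(1:8, function(i) random_nested_structure(18))
  pool <- pool_samples(list(fake_sample_set(structs, runif(8, -2, 2), "d")))
  fp <- feature_probabilities(pool)
  persite <- rowSums(fp$pair) + colSums(fp$pair) + fp$unpaired
  expect_equal(persite, rep(1, 18), tolerance = 1e-9)
})

test_that("MEA centroid maximizes the expected-accuracy objective", {
  # singleton cluster: the centroid is the structure itself
  s1 <- rna_structure(12, rbind(c(2, 9), c(3, 8)))
  pool1 <- pool_samples(list(fake_sample_set(list(s1), 0, "d")))
  cent <- mea_centroid(feature_probabilities(pool1))
  expect_equal(cent$pairs, s1$pairs)
  # all pair probabilities zero: open chain
  fp0 <- structure(list(n = 10, pair = matrix(0, 10, 10),
                        unpaired = rep(0.5, 10)), class = "feature_probs")
  expect_equal(NROW(mea_centroid(fp0)$pairs), 0)
  # exhaustive oracle on random clusters, n <= 12
  set.seed(24)
  for (case in 1:20) {
    n <- sample(8:12, 1)
    structs <- lapply(1:5, function(i) random_nested_structure(n))
    pool <- pool_samples(list(fake_sample_set(structs, runif(5, -2, 2), "d")))
    fp <- feature_probabilities(pool)
    cent <- mea_centroid(fp)
    expect_equal(mea_objective(cent, fp), brute_mea_objective(fp),
                 tolerance = 1e-9)
  }
})

test_that("highly_similar applies the delta threshold inclusively", {
  s <- rna_structure(12, rbind(c(1, 10)))
  s_same <- rna_structure(12, rbind(c(1, 10)))
  s_one <- rna_structure(12, rbind(c(1, 10), c(2, 9)))
  s_two <- rna_structure(12, rbind(c(2, 9)))
  expect_true(highly_similar(s, s_same, 1))
  expect_true(highly_similar(s, s_one, 1))   # distance 1, delta 1
  expect_false(highly_similar(s, s_two, 1))  # distance 2
})

test_that("select_k collapses degenerate pools and splits bimodal ones", {
  sA <- rna_structure(30, rbind(c(1, 12), c(2, 11), c(3, 10)))
  sA1 <- rna_structure(30, rbind(c(1, 12), c(2, 11)))
  sB <- rna_structure(30, rbind(c(15, 28), c(16, 27), c(17, 26), c(18, 25)))
  # one dominant conformation (two variants differing by one pair): splitting
  # it yields two significant, highly similar clusters, so the criterion
  # fires at k_start and the single-cluster fallback is returned
  degen <- pool_samples(list(
    fake_sample_set(c(rep(list(sA), 30), rep(list(sA1), 30)), rep(0, 60), "d")))
  cl <- select_k(degen, seed = 5)
  expect_equal(cl$k, 1)
  expect_equal(sort(unlist(lapply(cl$clusters, `[[`, "indices"))), 1:60)
  # balanced bimodal pool at distance 7: two significant clusters at k = 2
  bimod <- pool_samples(list(
    fake_sample_set(c(rep(list(sA), 30), rep(list(sB), 30)), rep(0, 60), "d")))
  cl2 <- select_k(bimod, seed = 5)
  expect_equal(cl2$k, 2)
  expect_true(all(vapply(cl2$clusters, `[[`, numeric(1), "stability") > 1 / 3))
  # conservation: clusters partition the pool
  expect_equal(sort(unlist(lapply(cl2$clusters, `[[`, "indices"))), 1:60)
  # unreachable epsilon: criterion never fires, k_max cap with warning
  expect_warning(
    capk <- select_k(bimod, k_max = 4, epsilon = 2, seed = 5),
    "k_max")
  expect_lte(capk$k, 4)
})
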