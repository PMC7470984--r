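test_that("condition probabilities normalize over the sampled multiset", {
  s <- rna_structure(10)
  # identical copies: 1/M each
  ss <- fake_sample_set(rep(list(s), 8), rep(2.5, 8), "d")
  expect_equal(condition_probability(ss), rep(1 / 8, 8))
  # energies 0 and RT*ln 2: probabilities 2/3 and 1/3
  ss2 <- fake_sample_set(list(s, s), c(0, RT_37C * log(2)), "d")
  expect_equal(condition_probability(ss2), c(2 / 3, 1 / 3))
  # always a distribution
  set.seed(41)
  ss3 <- fake_sample_set(rep(list(s), 20), rnorm(20, 0, 5), "d")
  expect_equal(sum(condition_probability(ss3)), 1)
})

test_that("stability accumulates condition probabilities and is conserved", {
  sA <- rna_structure(20, rbind(c(1, 10)))
  sB <- rna_structure(20, rbind(c(5, 15)))
  sets <- list(
    fake_sample_set(c(rep(list(sA), 5), rep(list(sB), 5)), rep(1, 10), "d1"),
    fake_sample_set(c(rep(list(sA), 5), rep(list(sB), 5)), rep(1, 10), "d2"))
  pool <- pool_samples(sets)
  # single cluster holding everything: stability = |D|
  one <- multifold:::build_clusters(pool, rep(1L, 20))
  expect_equal(one[[1]]$stability, 2)
  # uniform-energy pool split by structure: |D|/2 per cluster
  assign <- rep(rep(1:2, each = 5), 2)
  halves <- multifold:::build_clusters(pool, assign)
  expect_equal(vapply(halves, `[[`, numeric(1), "stability"), c(1, 1))
  # conservation holds for arbitrary assignments
  set.seed(42)
  for (case in 1:10) {
    rand_assign <- sample(1:3, 20, replace = TRUE)
    cl <- multifold:::build_clusters(pool, rand_assign)
    expect_equal(sum(vapply(cl, `[[`, numeric(1), "stability")), 2,
                 tolerance = 1e-9)
  }
})

test_that("support counts conditions above tau; tau = 1/(k+1) never strands one", {
  sA <- rna_structure(20, rbind(c(1, 10)))
  sB <- rna_structure(20, rbind(c(5, 15)))
  # cluster 1 holds all of d1 and all of d2: support 2 at any tau <= 1
  pool <- pool_samples(list(
    fake_sample_set(rep(list(sA), 4), rep(0, 4), "d1"),
    fake_sample_set(rep(list(sA), 4), rep(0, 4), "d2")))
  clustering <- structure(list(
    clusters = multifold:::build_clusters(pool, rep(1L, 8)),
    k = 1, assignment = rep(1L, 8), epsilon = 2 / 3), class = "clustering")
  sc <- score_clusters(clustering)
  expect_equal(sc$support, 2L)
  # a cluster with zero mass in d2 is not supported by d2
  pool2 <- pool_samples(list(
    fake_sample_set(rep(list(sA), 4), rep(0, 4), "d1"),
    fake_sample_set(rep(list(sB), 4), rep(0, 4), "d2")))
  clustering2 <- structure(list(
    clusters = multifold:::build_clusters(pool2, rep(1:2, each = 4)),
    k = 2, assignment = rep(1:2, each = 4), epsilon = 2 / 3),
    class = "clustering")
  sc2 <- score_clusters(clustering2)
  expect_equal(sc2$support, c(1L, 1L))
  # pigeonhole: with tau = 1/(k+1) every condition supports some cluster
  set.seed(43)
  for (case in 1:20) {
    n_cond <- sample(1:4, 1)
    sets <- lapply(seq_len(n_cond), function(d)
      fake_sample_set(rep(list(sA), 12), rnorm(12, 0, 2), paste0("d", d)))
    pool <- pool_samples(sets)
    assign <- sample(1:4, 12 * n_cond, replace = TRUE)
    clusters <- multifold:::build_clusters(pool, assign)
    k <- length(clusters)
    tau <- 1 / (k + 1)
    mass <- do.call(rbind, lapply(clusters, `[[`, "cond_mass"))
    expect_true(all(apply(mass, 2, max) >= tau))
  }
})

test_that("pareto_select keeps exactly the non-dominated clusters, ranked", {
  one <- data.frame(stability = 1.2, support = 2)
  expect_equal(pareto_select(one), one)
  ab <- data.frame(stability = c(2, 1), support = c(3, 1))
  expect_equal(NROW(pareto_select(ab)), 1)   # full dominance
  inc <- data.frame(stability = c(2, 1), support = c(1, 3))
  expect_equal(pareto_select(inc)$stability, c(2, 1))  # incomparable, ranked
  expect_equal(NROW(pareto_select(inc[0, ])), 0)
  # brute-force dominance filtering on random score sets
  set.seed(44)
  for (case in 1:25) {
    k <- sample(2:50, 1)
    sc <- data.frame(stability = round(runif(k, 0, 3), 2),
                     support = sample(0:4, k, replace = TRUE))
    got <- pareto_select(sc)
    keep <- vapply(seq_len(k), function(a) {
      !any(sc$stability >= sc$stability[a] & sc$support >= sc$support[a] &
             (sc$stability > sc$stability[a] | sc$support > sc$support[a]))
    }, logical(1))
    want <- sc[keep, , drop = FALSE]
    want <- want[order(-want$stability, -want$support), ]
    expect_equal(got$stability, want$stability)
    expect_equal(got$support, want$support)
  }
})

test_that("probing-free prediction returns a single ranked centroid", {
  seq <- rna_sequence("GGCAGGCAAAAGCCUGCC")
  pred <- predict_structures(seq, condition_set(),
                             config = run_config(m = 300, seed = 2))
  expect_s3_class(pred, "multifold_prediction")
  expect_equal(nrow(pred), 1)  # mono-probing Pareto front is one cluster
  expect_equal(pred$support, 1L)
  expect_equal(pred$stability, 1, tolerance = 1e-9)
})

test_that("multi-condition prediction recovers the reference and resists outliers", {
  fix <- make_three_hairpin()
  panel <- simulate_condition_panel(fix$ref, fix$seq, 3,
                                    params = sim_params(flip_prob = 0.1),
                                    seed = 11)
  pred <- predict_structures(fix$seq, panel, config = run_config(m = 400, seed = 5))
  expect_equal(evaluate_predictions(pred, fix$ref)$mcc[1], 1)
  # 2 faithful + 1 adversarial condition: top centroid still the reference
  panel_out <- simulate_condition_panel(fix$ref, fix$seq, 2,
    params = sim_params(flip_prob = 0.05),
    outliers = list(list(structure = fix$decoy, count = 1)), seed = 13)
  pred_out <- predict_structures(fix$seq, panel_out,
                                 config = run_config(m = 400, seed = 7))
  expect_equal(evaluate_predictions(pred_out, fix$ref)$mcc[1], 1)
  # determinism of the full pipeline
  pred2 <- predict_structures(fix$seq, panel, config = run_config(m = 400, seed = 5))
  expect_identical(pred$structure, pred2$structure)
  expect_equal(pred$stability, pred2$stability)
})
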