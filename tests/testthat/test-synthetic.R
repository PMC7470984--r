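test_that("profile simulation is seed-deterministic with faithful class means", {
  fix <- make_three_hairpin()
  p1 <- simulate_profile(fix$ref, fix$seq, sim_params(), seed = 3)
  p2 <- simulate_profile(fix$ref, fix$seq, sim_params(), seed = 3)
  expect_identical(p1$values, p2$values)
  expect_identical(p1$valid, p2$valid)
  expect_false(identical(
    p1$values, simulate_profile(fix$ref, fix$seq, sim_params(), seed = 4)$values))

  # law of large numbers on a long duplex: empirical means within 3 SE
  n <- 4000
  pairs <- cbind(1:(n / 2 - 2), n - (1:(n / 2 - 2)) + 1)
  big <- multifold:::new_rna_structure(n, pairs)
  seq_big <- rna_sequence(paste(rep(c("G", "A", "C"),
                                    c(n / 2 - 2, 4, n / 2 - 2)), collapse = ""))
  prof <- simulate_profile(big, seq_big, sim_params(dropout = 0), seed = 5)
  paired_mask <- pairing_vector(big) != 0
  m_paired <- mean(prof$values[paired_mask])
  m_unpaired <- mean(prof$values[!paired_mask])
  se_paired <- 0.08 / sqrt(sum(paired_mask))
  expect_lt(abs(m_paired - 0.08), 3 * se_paired)
  se_unpaired <- sqrt(2 * 0.45^2 / sum(!paired_mask))
  expect_lt(abs(m_unpaired - 2 * 0.45), 3 * se_unpaired)
  expect_gt(m_unpaired, m_paired)

  # dropout marks the expected fraction missing
  prof_d <- simulate_profile(big, seq_big, sim_params(dropout = 0.2), seed = 6)
  expect_lt(abs(mean(!prof_d$valid) - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("noise-free profiles make single-condition recovery exact", {
  fix <- make_three_hairpin()
  clean <- sim_params(paired = list(kind = "constant", value = 0),
                      unpaired = list(kind = "constant", value = 2),
                      dropout = 0)
  prof <- simulate_profile(fix$ref, fix$seq, clean, seed = 1)
  pred <- predict_structures(fix$seq, prof, config = run_config(m = 300, seed = 2))
  expect_equal(evaluate_predictions(pred, fix$ref)$mcc[1], 1)
})

test_that("condition panels encode provenance and isolate decoys", {
  fix <- make_three_hairpin()
  panel <- simulate_condition_panel(fix$ref, fix$seq, 3, seed = 7)
  expect_named(panel, c("cond1", "cond2", "cond3"))
  panel2 <- simulate_condition_panel(fix$ref, fix$seq, 3, seed = 7)
  expect_identical(lapply(panel, `[[`, "values"),
                   lapply(panel2, `[[`, "values"))
  # 2 faithful + 1 decoy: the decoy sits farthest from the others on average
  po <- simulate_condition_panel(fix$ref, fix$seq, 2,
    outliers = list(list(structure = fix$decoy, count = 1)), seed = 8)
  cd <- distance_matrix(fix$seq, po)
  D <- cd$D
  avg <- rowMeans(D) * nrow(D) / (nrow(D) - 1)
  expect_equal(names(which.max(avg)), "decoy1")
})

test_that("mutant panels perturb pairing status at the requested rate", {
  fix <- make_three_hairpin()
  wt_only <- simulate_mutant_panel(fix$ref, fix$seq, n_mutants = 0)
  expect_named(wt_only, "WT")
  panel <- simulate_mutant_panel(fix$ref, fix$seq, n_mutants = 3,
                                 local_rewire_rate = 0.05, seed = 9)
  expect_named(panel, c("WT", "M1", "M2", "M3"))
  # rewire rate 0: mutants draw from the same class layout as WT
  p0 <- simulate_mutant_panel(fix$ref, fix$seq, n_mutants = 2,
                              local_rewire_rate = 0,
                              params = sim_params(dropout = 0), seed = 10)
  paired_mask <- pairing_vector(fix$ref) != 0
  for (d in c("M1", "M2")) {
    expect_lt(mean(p0[[d]]$values[paired_mask]),
              mean(p0[[d]]$values[!paired_mask]))
    # every paired position draws from the low-reactivity class
    expect_lt(max(p0[[d]]$values[paired_mask]), 3)
  }
})

test_that("adding mutant conditions does not hurt recovery", {
  fix <- make_three_hairpin()
  noisy <- sim_params(flip_prob = 0.15)
  wt_mcc <- numeric(0)
  mut_mcc <- numeric(0)
  for (sd in 1:4) {
    wt <- simulate_mutant_panel(fix$ref, fix$seq, 0, params = noisy,
                                seed = 30 + sd)
    pw <- predict_structures(fix$seq, wt, config = run_config(m = 300, seed = sd))
    wt_mcc <- c(wt_mcc, evaluate_predictions(pw, fix$ref)$mcc[1])
    mp <- simulate_mutant_panel(fix$ref, fix$seq, 3, local_rewire_rate = 0.03,
                                params = noisy, seed = 30 + sd)
    pm <- predict_structures(fix$seq, mp, config = run_config(m = 300, seed = sd))
    mut_mcc <- c(mut_mcc, evaluate_predictions(pm, fix$ref)$mcc[1])
  }
  expect_gte(mean(mut_mcc), mean(wt_mcc))
})

test_that("recovery quality does not improve with heavier noise", {
  fix <- make_three_hairpin()
  mean_mcc <- function(flip) {
    vals <- vapply(1:3, function(sd) {
      panel <- simulate_condition_panel(fix$ref, fix$seq, 2,
        params = sim_params(flip_prob = flip), seed = 60 + sd)
      pred <- predict_structures(fix$seq, panel,
                                 config = run_config(m = 250, seed = sd))
      evaluate_predictions(pred, fix$ref)$mcc[1]
    }, numeric(1))
    mean(vals)
  }
  expect_gte(mean_mcc(0), mean_mcc(0.45))
})

test_that("panels round-trip through standard files", {
  fix <- make_three_hairpin()
  panel <- simulate_condition_panel(fix$ref, fix$seq, 2, seed = 12)
  dir <- withr::local_tempdir()
  write_panel(panel, fix$seq, dir)
  expect_true(file.exists(file.path(dir, "sequence.fa")))
  seq_back <- read_rna_fasta(file.path(dir, "sequence.fa"))
  expect_equal(unclass(seq_back), unclass(fix$seq), ignore_attr = TRUE)
  prof_back <- read_reactivity_file(file.path(dir, "cond1.shape"), seq_back,
                                    condition = "cond1")
  expect_equal(prof_back$valid, panel$cond1$valid)
  expect_equal(prof_back$values[prof_back$valid],
               panel$cond1$values[panel$cond1$valid], tolerance = 1e-6)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_true(manifest$synthetic)
})
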