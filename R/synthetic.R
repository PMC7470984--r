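#' Simulation parameters for synthetic reactivity profiles
#'
#' Defines the statistical structure of simulated probing signals: paired
#' positions draw low reactivities, unpaired positions high ones. The
#' defaults (exponential with mean 0.08 for paired, gamma with shape 2 and
#' scale 0.45 for unpaired, 5% dropout) are package choices emulating
#' normalized probing data; they are fully configurable. `flip_prob`
#' injects class noise: with that probability a position draws from the
#' wrong class's distribution, which is the generator's noise dial.
#' Distributions may be replaced by constants
#' (`list(kind = "constant", value = ...)`) for noise-free experiments.
#'
#' @param paired,unpaired Distribution specs: `list(kind = "exponential",
#'   mean = )`, `list(kind = "gamma", shape = , scale = )`, or
#'   `list(kind = "constant", value = )`.
#' @param dropout Fraction of positions marked missing.
#' @param flip_prob Probability a position draws from the wrong class.
#' @param reagent `"SHAPE"`, `"DMS"` or `"CMCT"` (controls masking).
#' @return A `sim_params` object.
#' @export
sim_params <- function(paired = list(kind = "exponential", mean = 0.08),
                       unpaired = list(kind = "gamma", shape = 2, scale = 0.45),
                       dropout = 0.05, flip_prob = 0, reagent = "SHAPE") {
  stopifnot(dropout >= 0, dropout < 1, flip_prob >= 0, flip_prob <= 1)
  structure(list(paired = paired, unpaired = unpaired, dropout = dropout,
                 flip_prob = flip_prob, reagent = reagent),
            class = "sim_params")
}

draw_reactivities <- function(spec, n) {
  switch(spec$kind,
    exponential = stats::rexp(n, rate = 1 / spec$mean),
    gamma = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
    constant = rep(spec$value, n),
    stop("unknown distribution kind '", spec$kind, "'", call. = FALSE)
  )
}

#' Simulate a reactivity profile from a known structure
#'
#' Paired positions draw from the paired distribution, unpaired positions
#' from the unpaired distribution (classes swapped with probability
#' `flip_prob`); dropout marks positions missing; the reagent mask is
#' applied last. Deterministic given `seed`.
#'
#' @param structure The generating [rna_structure()].
#' @param seq Matching [rna_sequence()].
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @param condition Condition label.
#' @return A [reactivity_profile()].
#' @export
simulate_profile <- function(structure, seq, params = sim_params(), seed = 1,
                             condition = "sim") {
  n <- structure$n
  if (n != length(seq)) stop("structure/sequence length mismatch", call. = FALSE)
  paired <- pairing_vector(structure) != 0L
  values <- withr::with_seed(seed, {
    cls <- paired
    if (params$flip_prob > 0) {
      flip <- stats::runif(n) < params$flip_prob
      cls <- xor(cls, flip)
    }
    v <- numeric(n)
    v[cls] <- draw_reactivities(params$paired, sum(cls))
    v[!cls] <- draw_reactivities(params$unpaired, sum(!cls))
    if (params$dropout > 0) {
      v[stats::runif(n) < params$dropout] <- -999
    }
    v
  })
  prof <- reactivity_profile(values, condition = condition)
  mask_by_reagent(prof, params$reagent, seq)
}

#' Simulate a panel of probing conditions
#'
#' Independent profiles per condition, all generated from `structure`;
#' optional outlier conditions are generated from decoy structures
#' instead. Labels encode provenance (`cond1..condN`, `decoy1..`).
#'
#' @param structure Generating [rna_structure()].
#' @param seq Matching [rna_sequence()].
#' @param n_conditions Number of faithful conditions.
#' @param params A [sim_params()] or list of them (one per condition).
#' @param outliers Optional list of `list(structure = , count = )` decoy
#'   specifications.
#' @param seed Master seed; per-condition seeds are derived from it.
#' @return A [condition_set()].
#' @export
simulate_condition_panel <- function(structure, seq, n_conditions,
                                     params = sim_params(), outliers = list(),
                                     seed = 1) {
  if (n_conditions < 1) stop("need at least one condition", call. = FALSE)
  if (inherits(params, "sim_params")) {
    params <- rep(list(params), n_conditions)
  }
  profiles <- lapply(seq_len(n_conditions), function(di) {
    simulate_profile(structure, seq, params[[di]],
                     seed = stage_seed(seed, di),
                     condition = paste0("cond", di))
  })
  oi <- 0L
  for (spec in outliers) {
    for (rep_i in seq_len(spec$count)) {
      oi <- oi + 1L
      p <- if (inherits(params, "sim_params")) params else params[[1]]
      profiles <- c(profiles, list(
        simulate_profile(spec$structure, seq, p,
                         seed = stage_seed(seed, 500L + oi),
                         condition = paste0("decoy", oi))))
    }
  }
  condition_set(profiles)
}

#' Simulate a mutate-and-map style mutant panel
#'
#' Emulates probing of single-point mutants: each mutant profile is
#' generated from the reference structure with a small fraction of
#' positions' pairing status locally flipped (a structural perturbation
#' proxy — mutant sequences are not refolded), plus the wild-type profile.
#'
#' @param structure Reference [rna_structure()].
#' @param seq Matching [rna_sequence()].
#' @param n_mutants Number of mutants (0 gives a WT-only panel).
#' @param local_rewire_rate Per-position probability of a paired/unpaired
#'   status flip in a mutant.
#' @param params A [sim_params()].
#' @param seed Master seed.
#' @return A [condition_set()] with labels `WT`, `M1`, `M2`, ...
#' @export
simulate_mutant_panel <- function(structure, seq, n_mutants = 0,
                                  local_rewire_rate = 0.05,
                                  params = sim_params(), seed = 1) {
  profiles <- list(simulate_profile(structure, seq, params,
                                    seed = stage_seed(seed, 1L),
                                    condition = "WT"))
  n <- structure$n
  paired <- pairing_vector(structure) != 0L
  for (mi in seq_len(n_mutants)) {
    status <- withr::with_seed(stage_seed(seed, 100L + mi), {
      flip <- stats::runif(n) < local_rewire_rate
      xor(paired, flip)
    })
    # simulate from the perturbed pairing status directly
    values <- withr::with_seed(stage_seed(seed, 200L + mi), {
      v <- numeric(n)
      v[status] <- draw_reactivities(params$paired, sum(status))
      v[!status] <- draw_reactivities(params$unpaired, sum(!status))
      if (params$dropout > 0) v[stats::runif(n) < params$dropout] <- -999
      v
    })
    prof <- reactivity_profile(values, condition = paste0("M", mi))
    profiles <- c(profiles, list(mask_by_reagent(prof, params$reagent, seq)))
  }
  condition_set(profiles)
}

#' Write a simulated panel as FASTA + reactivity files
#'
#' The files are indistinguishable from real inputs: one FASTA and one
#' two-column reactivity file per condition, plus a small JSON provenance
#' manifest (labelled as synthetic).
#'
#' @param conditions A [condition_set()].
#' @param seq The [rna_sequence()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_panel <- function(conditions, seq, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_rna_fasta(seq, file.path(dir, "sequence.fa"))
  for (p in conditions) {
    write_reactivity_file(p, file.path(dir, paste0(p$condition, ".shape")))
  }
  manifest <- list(synthetic = TRUE, sequence = attr(seq, "id"),
                   conditions = names(conditions))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
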