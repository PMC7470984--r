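#' @useDynLib multifold, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# build the C++ folding context for one condition
fold_context <- function(seq, profile = NULL,
                         schema = pseudo_energy_schema(),
                         model = energy_model(), RT = RT_37C) {
  codes <- seq_codes(seq)
  n <- length(codes)
  g <- if (is.null(profile)) rep(0, n) else profile_bonus(profile, schema)
  if (!is.null(profile) && length(profile) != n) {
    stop("profile/sequence length mismatch", call. = FALSE)
  }
  if (schema$application_mode == "deigan_paired") {
    pairfac <- exp(-g / RT)
    q <- rep(1, n)
  } else {
    pairfac <- rep(1, n)
    q <- exp(-g / RT)
  }
  fold <- cpp_fold(codes, model$stack, model$hairpin, model$internal,
                   model$multi, RT, pairfac, q)
  fold$seq <- seq
  fold$profile <- profile
  fold$schema <- schema
  fold$model <- model
  fold
}

#' Partition function of the (pseudo-)Boltzmann ensemble
#'
#' Computes `Z = sum over structures S of exp(-E_d(S)/RT)` by a McCaskill-type
#' dynamic program over the bundled energy model, where `E_d` includes the
#' pseudo-energy terms of `profile` (if given). The sum runs over all
#' structures satisfying the package's structural invariants (canonical
#' pairs AU/UA/CG/GC/GU/UG, minimum hairpin 3, no crossings).
#'
#' @param seq An [rna_sequence()].
#' @param profile Optional [reactivity_profile()].
#' @param schema A [pseudo_energy_schema()].
#' @param model An [energy_model()].
#' @param RT Thermal energy in kcal/mol.
#' @return A `fold_result` object; its element `Z` is the partition
#'   function. Pass it to [sample_structures()] or [dotplot()] to avoid
#'   recomputation of the energy setup.
#' @export
partition_function <- function(seq, profile = NULL,
                               schema = pseudo_energy_schema(),
                               model = energy_model(), RT = RT_37C) {
  fold <- fold_context(seq, profile, schema, model, RT)
  class(fold) <- "fold_result"
  fold
}

#' @export
print.fold_result <- function(x, ...) {
  cat("<fold_result> n =", x$n, " Z =", format(x$Z), "\n")
  invisible(x)
}

#' Stochastic sampling of the (pseudo-)Boltzmann ensemble
#'
#' Draws `m` independent structures by stochastic backtracking through the
#' partition-function tables, so each structure `S` appears with
#' probability `exp(-E_d(S)/RT) / Z`. Deterministic given `seed`.
#'
#' @param seq An [rna_sequence()] or a `fold_result` from
#'   [partition_function()].
#' @param profile Optional [reactivity_profile()] (ignored if `seq` is a
#'   `fold_result`).
#' @param m Sample size (default 1000).
#' @param seed Integer seed.
#' @param condition Condition label; defaults to the profile's (or
#'   `"thermo"` for probing-free sampling).
#' @inheritParams partition_function
#' @return A `sample_set`: list with `structures` (list of
#'   [rna_structure()]), `energies` (pseudo free energies `E_d(S)`),
#'   `energies_turner` (thermodynamic-only energies `E(S)`), `condition`,
#'   `m`, `seed`.
#' @export
sample_structures <- function(seq, profile = NULL, m = 1000, seed = 1,
                              condition = NULL,
                              schema = pseudo_energy_schema(),
                              model = energy_model(), RT = RT_37C) {
  if (m <= 0) stop("sample size must be positive", call. = FALSE)
  fold <- if (inherits(seq, "fold_result")) seq else
    fold_context(seq, profile, schema, model, RT)
  if (is.null(condition)) {
    condition <- if (is.null(fold$profile)) "thermo" else fold$profile$condition
  }
  partners <- withr::with_seed(seed, cpp_sample(fold, as.integer(m)))
  n <- fold$n
  e_turner <- cpp_loop_energies(partners, seq_codes(fold$seq),
                                fold$model$stack, fold$model$hairpin,
                                fold$model$internal, fold$model$multi)
  if (is.null(fold$profile)) {
    e_pseudo <- e_turner
  } else {
    g <- profile_bonus(fold$profile, fold$schema)
    paired <- partners > 0L
    e_pseudo <- if (fold$schema$application_mode == "deigan_paired") {
      e_turner + as.numeric(paired %*% g)
    } else {
      e_turner + as.numeric((!paired) %*% g)
    }
  }
  idx <- seq_len(n)
  structures <- lapply(seq_len(m), function(s) {
    pt <- partners[s, ]
    sel <- which(pt > idx)
    new_rna_structure(n, cbind(sel, pt[sel]))
  })
  structure(list(structures = structures, energies = e_pseudo,
                 energies_turner = e_turner, condition = condition,
                 m = m, seed = seed),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set> '", x$condition, "': ", x$m, " structures (seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Base-pair probability dot plot
#'
#' The matrix of Boltzmann pair probabilities `P(i, j | d)` of the
#' (pseudo-)Boltzmann ensemble for one condition, computed exactly by the
#' outside algorithm.
#'
#' @inheritParams sample_structures
#' @return An `rna_dotplot`: list with `n`, `p` (upper-triangular
#'   probability matrix), and `condition`.
#' @export
dotplot <- function(seq, profile = NULL, condition = NULL,
                    schema = pseudo_energy_schema(),
                    model = energy_model(), RT = RT_37C) {
  fold <- if (inherits(seq, "fold_result")) seq else
    fold_context(seq, profile, schema, model, RT)
  if (is.null(condition)) {
    condition <- if (is.null(fold$profile)) "thermo" else fold$profile$condition
  }
  p <- cpp_pair_probs(fold)
  structure(list(n = fold$n, p = p, condition = condition),
            class = "rna_dotplot")
}

#' @export
print.rna_dotplot <- function(x, ...) {
  cat("<rna_dotplot> '", x$condition, "': n = ", x$n, ", ",
      sum(x$p > 1e-6), " pairs with probability > 1e-6\n", sep = "")
  invisible(x)
}

#' Write a dot plot as TSV
#'
#' Upper-triangle entries only, 1-based, columns `i`, `j`, `prob`.
#'
#' @param dp An `rna_dotplot`.
#' @param path Output path.
#' @param min_prob Drop entries below this probability.
#' @return `path`, invisibly.
#' @export
write_dotplot_tsv <- function(dp, path, min_prob = 0) {
  idx <- which(upper.tri(dp$p) & dp$p > min_prob, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  lines <- sprintf("%d\t%d\t%.10g", idx[, 1], idx[, 2], dp$p[idx])
  writeLines(c("i\tj\tprob", lines), path)
  invisible(path)
}

#' Write a sample set as dot-bracket lines
#'
#' One line per sampled structure: dot-bracket, tab, pseudo free energy.
#'
#' @param ss A `sample_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_set <- function(ss, path) {
  lines <- vapply(seq_along(ss$structures), function(k) {
    sprintf("%s\t%.6f", as_dotbracket(ss$structures[[k]]), ss$energies[k])
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
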