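#' Thermodynamic constants
#'
#' `RT` at the 37 degree C probing temperature:
#' 0.0019872 kcal/(mol K) * 310.15 K = 0.61633 kcal/mol.
#'
#' @export
RT_37C <- 0.0019872 * 310.15

# pair type codes used by the engine (0 = not pairable)
PAIR_TYPES <- c("CG", "GC", "AU", "UA", "GU", "UG")

pair_type_code <- function(a, b) {
  # a, b are residue codes A=1 C=2 G=3 U=4 N=5
  key <- a * 10L + b
  # CG=23? careful: C=2,G=3 -> 23; GC=32; AU=14; UA=41; GU=34; UG=43
  match(key, c(23L, 32L, 14L, 41L, 34L, 43L), nomatch = 0L)
}

#' Load the bundled nearest-neighbor energy model
#'
#' A deliberately small stacking model: 36 tabulated stacking terms (one
#' per outer/inner pair-type combination) and linear loop penalties
#' (hairpin, internal/bulge, multiloop), in kcal/mol. It is loop
#' decomposable, so partition functions, base-pair probabilities and
#' stochastic sampling are computed exactly by dynamic programming. It is a
#' compact model in its own right, not a full Turner 2004 parameter set;
#' all ensemble machinery in this package is validated by exhaustive
#' enumeration under the same model, so downstream correctness does not
#' rest on the biological fidelity of the table.
#'
#' @param path Optional path to an alternative parameter TSV with columns
#'   `param`, `key1`, `key2`, `value`.
#' @return An object of class `energy_model`: list with `stack` (6x6
#'   matrix, rows = outer pair type, cols = inner), `hairpin`, `internal`,
#'   `multi` penalty vectors.
#' @export
energy_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_params.tsv", package = "multifold")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  st <- tab[tab$param == "stack", ]
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  stack[cbind(match(st$key1, PAIR_TYPES), match(st$key2, PAIR_TYPES))] <- st$value
  get1 <- function(p, k) tab$value[tab$param == p & tab$key1 == k]
  model <- list(
    stack = stack,
    hairpin = c(init = get1("hairpin", "init"), per_nt = get1("hairpin", "per_nt")),
    internal = c(init = get1("internal", "init"), per_nt = get1("internal", "per_nt")),
    multi = c(init = get1("multi", "init"), per_branch = get1("multi", "per_branch"),
              per_nt = get1("multi", "per_nt"))
  )
  structure(model, class = "energy_model")
}

#' Free energy of a structure under the bundled model
#'
#' Decomposes the structure into loops and sums tabulated stacking terms
#' for adjacent (stacked) pairs plus linear loop penalties. The open chain
#' has energy 0 by definition; the exterior loop is free.
#'
#' @param s An [rna_structure()].
#' @param seq Matching [rna_sequence()].
#' @param model An [energy_model()].
#' @return Free energy in kcal/mol.
#' @export
structure_energy <- function(s, seq, model = energy_model()) {
  if (s$n != length(seq)) stop("structure/sequence length mismatch", call. = FALSE)
  if (!NROW(s$pairs)) return(0)
  codes <- seq_codes(seq)
  pt <- pairing_vector(s)
  e <- 0
  for (r in seq_len(NROW(s$pairs))) {
    i <- s$pairs[r, 1]; j <- s$pairs[r, 2]
    t_out <- pair_type_code(codes[i], codes[j])
    if (t_out == 0L) {
      stop("non-pairable residues ", unclass(seq)[i], unclass(seq)[j],
           " at (", i, ",", j, ")", call. = FALSE)
    }
    # children: direct nested pairs inside (i, j)
    kids <- matrix(integer(0), ncol = 2)
    unpaired <- 0L
    k <- i + 1L
    while (k < j) {
      if (pt[k] > k) {
        kids <- rbind(kids, c(k, pt[k]))
        k <- pt[k] + 1L
      } else {
        unpaired <- unpaired + 1L
        k <- k + 1L
      }
    }
    if (NROW(kids) == 0L) {
      e <- e + model$hairpin["init"] + model$hairpin["per_nt"] * unpaired
    } else if (NROW(kids) == 1L) {
      if (unpaired == 0L) {  # stacked helix continuation
        t_in <- pair_type_code(codes[kids[1, 1]], codes[kids[1, 2]])
        e <- e + model$stack[t_out, t_in]
      } else {
        e <- e + model$internal["init"] + model$internal["per_nt"] * unpaired
      }
    } else {
      e <- e + model$multi["init"] +
        model$multi["per_branch"] * (NROW(kids) + 1L) +
        model$multi["per_nt"] * unpaired
    }
  }
  unname(e)
}

#' Pseudo-energy schema
#'
#' Converts a reactivity into a per-position free-energy term
#' `dG(i) = m * ln(r_i + 1) + b` (kcal/mol), with defaults `m = 1.3`,
#' `b = -0.4`. `application_mode` controls where the term is applied when
#' evaluating a structure: `"deigan_paired"` (default) adds `dG(i)` once
#' for every paired position, so pairing an unreactive base (r near 0) is
#' rewarded; `"literal_unpaired"` adds it for every unpaired position.
#'
#' @param m Slope, kcal/mol.
#' @param b Intercept, kcal/mol.
#' @param application_mode `"deigan_paired"` or `"literal_unpaired"`.
#' @return An object of class `pseudo_energy_schema`.
#' @export
pseudo_energy_schema <- function(m = 1.3, b = -0.4,
                                 application_mode = c("deigan_paired",
                                                      "literal_unpaired")) {
  application_mode <- match.arg(application_mode)
  structure(list(m = m, b = b, application_mode = application_mode),
            class = "pseudo_energy_schema")
}

#' Per-position pseudo-energy bonus
#'
#' @param r Reactivity value(s); `NA` for invalid positions (term is 0).
#' @param schema A [pseudo_energy_schema()].
#' @return `m * ln(r + 1) + b` in kcal/mol; 0 where `r` is `NA`.
#' @export
pseudo_energy_bonus <- function(r, schema = pseudo_energy_schema()) {
  if (any(!is.na(r) & r < 0)) stop("valid reactivities must be >= 0", call. = FALSE)
  out <- schema$m * log(r + 1) + schema$b
  out[is.na(r)] <- 0
  out
}

# per-position bonus vector for a profile (0 at invalid positions)
profile_bonus <- function(profile, schema) {
  if (is.null(profile)) return(NULL)
  pseudo_energy_bonus(profile$values, schema)
}

#' Pseudo free energy of a structure under a probing condition
#'
#' `E_d(S)` is the bundled-model free energy plus the per-position
#' pseudo-energy terms for the probing condition `d`: in the default
#' `deigan_paired` mode, the sum runs over every paired position of `S`;
#' in `literal_unpaired` mode, over every unpaired position. With
#' `profile = NULL` this is just the thermodynamic energy.
#'
#' @param s An [rna_structure()].
#' @param seq Matching [rna_sequence()].
#' @param profile A [reactivity_profile()] or `NULL`.
#' @param schema A [pseudo_energy_schema()].
#' @param model An [energy_model()].
#' @return Pseudo free energy `E_d(S)` in kcal/mol.
#' @export
pseudo_free_energy <- function(s, seq, profile = NULL,
                               schema = pseudo_energy_schema(),
                               model = energy_model()) {
  e <- structure_energy(s, seq, model)
  if (is.null(profile)) return(e)
  if (length(profile) != s$n) stop("profile/structure length mismatch", call. = FALSE)
  g <- profile_bonus(profile, schema)
  paired <- pairing_vector(s) != 0L
  if (schema$application_mode == "deigan_paired") {
    e + sum(g[paired])
  } else {
    e + sum(g[!paired])
  }
}
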