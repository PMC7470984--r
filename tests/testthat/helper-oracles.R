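# Independent oracles and fixtures, kept free of the code paths they check.

# exhaustive enumeration of all nested structures over a sequence
# (canonical pairs, hairpin >= 3), independent of the DP engine
enum_structures <- function(seq) {
  codes <- match(unclass(seq), c("A", "C", "G", "U", "N"))
  n <- length(codes)
  pairable <- function(a, b) (codes[a] * 10 + codes[b]) %in% c(23, 32, 14, 41, 34, 43)
  memo <- new.env()
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1, j)
    for (l in (i + 4):j) {
      if (l > j || l - i < 4 || !pairable(i, l)) next
      for (a in rec(i + 1, l - 1)) for (b in rec(l + 1, j)) {
        out <- c(out, list(rbind(c(i, l), a, b)))
      }
    }
    memo[[key]] <- out
    out
  }
  lapply(rec(1L, n), function(p) rna_structure(n, p))
}

# exact ensemble (Z, pair probabilities) by enumeration + R-side energies
oracle_ensemble <- function(seq, profile = NULL,
                            schema = pseudo_energy_schema(),
                            model = energy_model(), RT = RT_37C) {
  structs <- enum_structures(seq)
  E <- vapply(structs, pseudo_free_energy, numeric(1), seq = seq,
              profile = profile, schema = schema, model = model)
  w <- exp(-E / RT)
  Z <- sum(w)
  n <- length(seq)
  P <- matrix(0, n, n)
  for (k in seq_along(structs)) {
    p <- structs[[k]]$pairs
    if (NROW(p)) P[p] <- P[p] + w[k] / Z
  }
  list(structs = structs, E = E, Z = Z, P = P)
}

# uniform-greedy random nested structure: repeatedly draw uniformly from
# the admissible pairs compatible with what is already chosen
random_nested_structure <- function(n, npairs = Inf) {
  cand <- which(outer(seq_len(n), seq_len(n), function(i, j) j - i >= 4),
                arr.ind = TRUE)
  taken <- matrix(integer(0), ncol = 2)
  while (NROW(cand) && NROW(taken) < npairs) {
    r <- cand[sample.int(NROW(cand), 1), , drop = FALSE]
    taken <- rbind(taken, r)
    i <- r[1]; j <- r[2]
    k <- cand[, 1]; l <- cand[, 2]
    shares <- k %in% c(i, j) | l %in% c(i, j)
    cross <- (k > i & k < j & l > j) | (k < i & l > i & l < j)
    cand <- cand[!shares & !cross, , drop = FALSE]
  }
  rna_structure(n, taken)
}

# random index-disjoint (possibly crossing) pair set with j - i >= 4
random_disjoint_pairs <- function(n, npairs) {
  pairs <- matrix(integer(0), ncol = 2)
  free <- seq_len(n)
  for (t in seq_len(npairs)) {
    ok <- FALSE
    for (attempt in 1:50) {
      ij <- sort(sample(free, 2))
      if (ij[2] - ij[1] >= 4) { ok <- TRUE; break }
    }
    if (!ok) break
    pairs <- rbind(pairs, ij)
    free <- setdiff(free, ij)
  }
  pairs
}

is_noncrossing <- function(pairs) {
  if (NROW(pairs) < 2) return(TRUE)
  for (a in seq_len(NROW(pairs) - 1)) {
    for (b in (a + 1):NROW(pairs)) {
      i <- pairs[a, 1]; j <- pairs[a, 2]
      k <- pairs[b, 1]; l <- pairs[b, 2]
      if (i > k) { tmp <- i; i <- k; k <- tmp; tmp <- j; j <- l; l <- tmp }
      if (k < j && j < l) return(FALSE)
    }
  }
  TRUE
}

# brute-force maximum non-crossing subset cardinality over all 2^p subsets
# (vectorized over subset masks; still an exhaustive search)
brute_max_noncrossing <- function(pairs) {
  p <- NROW(pairs)
  if (p == 0) return(0L)
  masks <- 0:(2^p - 1)
  bits <- 2^(seq_len(p) - 1)
  popcount <- rowSums(outer(masks, bits, function(m, b) bitwAnd(m, b) > 0))
  valid <- rep(TRUE, length(masks))
  if (p > 1) {
    for (a in seq_len(p - 1)) {
      for (b in (a + 1):p) {
        if (!is_noncrossing(pairs[c(a, b), , drop = FALSE])) {
          both <- bits[a] + bits[b]
          valid[bitwAnd(masks, both) == both] <- FALSE
        }
      }
    }
  }
  as.integer(max(popcount[valid]))
}

# exhaustive MEA oracle: maximize the expected-accuracy objective over all
# nested structures with arbitrary admissible pairs (j - i >= 4)
brute_mea_objective <- function(fp, gamma = 1) {
  n <- fp$n
  memo <- new.env()
  rec <- function(i, j) {
    if (i > j) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1, j) + fp$unpaired[i]
    if (j - i >= 4) {
      for (l in (i + 4):j) {
        best <- max(best, 2 * gamma * fp$pair[i, l] + rec(i + 1, l - 1) + rec(l + 1, j))
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1, n)
}

mea_objective <- function(s, fp, gamma = 1) {
  up <- pairing_vector(s) == 0L
  val <- sum(fp$unpaired[up])
  if (NROW(s$pairs)) val <- val + sum(2 * gamma * fp$pair[s$pairs])
  val
}

# three-hairpin reference used in recovery experiments: 60 nt, 21 pairs
make_three_hairpin <- function() {
  stems <- c("GGCAGGC", "GCGGCCG", "GGCGCGG")
  revcomp <- function(s) {
    chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  units <- vapply(stems, function(s) paste0(s, "AAAA", revcomp(s)), character(1))
  seqstr <- paste(units, collapse = "AAA")
  pairs <- NULL
  off <- 0
  for (u in 1:3) {
    for (k in 1:7) pairs <- rbind(pairs, c(off + k, off + 19 - k))
    off <- off + 21
  }
  n <- nchar(seqstr)
  # decoy: a plausible but wrong conformation (two long shifted hairpins)
  decoy <- rbind(cbind(3:9, 33 - (3:9)), cbind(34:40, 92 - (34:40)))
  list(seq = rna_sequence(seqstr, id = "threehairpin"),
       ref = rna_structure(n, pairs),
       decoy = rna_structure(n, decoy))
}

# fake sample set with prescribed structures/energies (for scoring tests)
fake_sample_set <- function(structures, energies, condition,
                            energies_turner = energies) {
  structure(list(structures = structures, energies = energies,
                 energies_turner = energies_turner, condition = condition,
                 m = length(structures), seed = 0L),
            class = "sample_set")
}
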