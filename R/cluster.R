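#' Pool sample sets across probing conditions
#'
#' Agglomerates per-condition samples into one multiset while keeping track
#' of each structure's condition of origin, its pseudo free energy
#' `E_d(S)` and its thermodynamic-only energy `E(S)`. Also precomputes the
#' Boltzmann condition probability of every sampled instance,
#' `P_d(S) = exp(-E_d(S)/RT) / Z*_d`, where `Z*_d` sums over the sampled
#' multiset of condition `d` (so the `m` instances of a condition carry
#' total probability 1).
#'
#' @param sample_sets List of `sample_set` objects (one per condition).
#' @param RT Thermal energy, kcal/mol.
#' @return A `pooled_sample` object.
#' @export
pool_samples <- function(sample_sets, RT = RT_37C) {
  if (inherits(sample_sets, "sample_set")) sample_sets <- list(sample_sets)
  structures <- list()
  condition <- character(0)
  e_pseudo <- numeric(0)
  e_turner <- numeric(0)
  cond_prob <- numeric(0)
  for (ss in sample_sets) {
    p <- multiset_probability(ss$energies, RT)
    structures <- c(structures, ss$structures)
    condition <- c(condition, rep(ss$condition, ss$m))
    e_pseudo <- c(e_pseudo, ss$energies)
    e_turner <- c(e_turner, ss$energies_turner)
    cond_prob <- c(cond_prob, p)
  }
  n <- structures[[1]]$n
  structure(list(structures = structures, condition = condition,
                 e_pseudo = e_pseudo, e_turner = e_turner,
                 cond_prob = cond_prob, n = n,
                 conditions = vapply(sample_sets, function(s) s$condition,
                                     character(1))),
            class = "pooled_sample")
}

# softmax of -E/RT over a sampled multiset (each instance counted once)
multiset_probability <- function(energies, RT = RT_37C) {
  w <- exp(-(energies - min(energies)) / RT)
  w / sum(w)
}

#' @export
print.pooled_sample <- function(x, ...) {
  cat("<pooled_sample>", length(x$structures), "structures from",
      length(x$conditions), "condition(s)\n")
  invisible(x)
}

# binary indicator embedding over the union of observed pairs; squared
# Euclidean distance between rows equals the base-pair distance
pair_indicator_matrix <- function(structures, n) {
  keys <- lapply(structures, function(s) {
    if (!NROW(s$pairs)) integer(0) else s$pairs[, 1] * (n + 1L) + s$pairs[, 2]
  })
  universe <- sort(unique(unlist(keys)))
  mat <- matrix(0L, nrow = length(structures),
                ncol = max(1L, length(universe)))
  if (length(universe)) {
    for (r in seq_along(keys)) {
      mat[r, match(keys[[r]], universe)] <- 1L
    }
  }
  mat
}

#' Partition pooled structures into k clusters
#'
#' Structures are embedded as binary indicator vectors over the union of
#' observed base pairs, so that squared Euclidean distance equals the
#' base-pair distance, and partitioned with k-means (restarts controlled by
#' `restarts`, all randomness from `seed`). Requesting more clusters than
#' there are distinct structures yields one cluster per distinct structure.
#'
#' @param pool A [pool_samples()] result.
#' @param k Number of clusters (>= 1).
#' @param seed Integer seed.
#' @param restarts Number of k-means restarts (best within-cluster cost kept).
#' @return Integer vector of cluster labels (1..k'), one per pooled item,
#'   with `k' <= k` non-empty clusters relabelled consecutively.
#' @export
cluster_k <- function(pool, k, seed = 1, restarts = 3) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  nitems <- length(pool$structures)
  if (k == 1L) return(rep(1L, nitems))
  emb <- pair_indicator_matrix(pool$structures, pool$n)
  distinct <- !duplicated(emb)
  ndistinct <- sum(distinct)
  if (k >= ndistinct) {
    # one cluster per distinct structure
    key <- apply(emb, 1, paste, collapse = "")
    return(as.integer(factor(key, levels = unique(key))))
  }
  # duplicate-heavy binary embeddings can exhaust Hartigan-Wong's
  # quick-transfer stage; the resulting partition is still valid
  fit <- withr::with_seed(seed, suppressWarnings(
    stats::kmeans(emb, centers = k, nstart = restarts, iter.max = 100)))
  labels <- fit$cluster
  as.integer(factor(labels, levels = sort(unique(labels))))
}

#' Cluster probability of structure features
#'
#' For a cluster `C`, the probability of a feature `f` (a base pair or an
#' unpaired position) is the thermodynamic Boltzmann weight of the
#' deduplicated member structures containing `f`, normalized over the
#' deduplicated set:
#' `P_C(f) = sum_{S in C', f in S} exp(-E(S)/RT) / sum_{S' in C'} exp(-E(S')/RT)`
#' with `C'` the non-redundant set of structures in `C` and `E` the
#' thermodynamic (not pseudo) energy.
#'
#' @param pool A [pool_samples()] result.
#' @param indices Member indices of the cluster within the pool.
#' @param RT Thermal energy, kcal/mol.
#' @return A `feature_probs` object: list with `n`, `pair` (n x n
#'   upper-triangular probability matrix) and `unpaired` (length-n vector).
#'   For every position, pair and unpaired probabilities sum to 1.
#' @export
feature_probabilities <- function(pool, indices = seq_along(pool$structures),
                                  RT = RT_37C) {
  if (!length(indices)) stop("cluster is empty", call. = FALSE)
  db <- vapply(pool$structures[indices], as_dotbracket, character(1))
  first <- !duplicated(db)
  dedup_idx <- indices[first]
  e <- pool$e_turner[dedup_idx]
  w <- exp(-(e - min(e)) / RT)
  w <- w / sum(w)
  n <- pool$n
  pair <- matrix(0, n, n)
  unpaired <- numeric(n)
  for (t in seq_along(dedup_idx)) {
    s <- pool$structures[[dedup_idx[t]]]
    if (NROW(s$pairs)) pair[s$pairs] <- pair[s$pairs] + w[t]
    up <- pairing_vector(s) == 0L
    unpaired[up] <- unpaired[up] + w[t]
  }
  structure(list(n = n, pair = pair, unpaired = unpaired),
            class = "feature_probs")
}

#' Maximum expected accuracy structure of a feature-probability table
#'
#' Finds the structure maximizing
#' `sum_{(i,j) in S} 2*gamma*P(i,j) + sum_{i unpaired in S} P_unpaired(i)`
#' by interval dynamic programming, subject to the package's structural
#' invariants. Ties are resolved toward leaving positions unpaired (and
#' then toward the smallest opening position), so the result is
#' deterministic and zero-probability pairs are never introduced.
#'
#' @param fp A [feature_probabilities()] result.
#' @param gamma Pair-weight factor (default 1).
#' @return An [rna_structure()].
#' @export
mea_centroid <- function(fp, gamma = 1) {
  n <- fp$n
  u <- fp$unpaired
  P <- fp$pair
  if (n < 5) return(rna_structure(n))
  B <- matrix(0, n + 1, n + 1)  # B[i, j+? ]: use B[i, j] for interval [i, j]; j<i -> 0
  bval <- function(i, j) if (j < i) 0 else B[i, j]
  for (span in 0:(n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- bval(i, j - 1) + u[j]
      if (span >= 4) {
        ks <- i:(j - 4)
        left <- vapply(ks, function(k) bval(i, k - 1), numeric(1))
        inner <- vapply(ks, function(k) bval(k + 1, j - 1), numeric(1))
        cand <- left + 2 * gamma * P[cbind(ks, j)] + inner
        best <- max(best, max(cand))
      }
      B[i, j] <- best
    }
  }
  # traceback
  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n))
  eps <- 1e-12
  while (length(stack)) {
    iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    while (j >= i) {
      target <- bval(i, j)
      if (abs(bval(i, j - 1) + u[j] - target) <= eps) {
        j <- j - 1L
        next
      }
      found <- FALSE
      for (k in i:(j - 4L)) {
        val <- bval(i, k - 1) + 2 * gamma * P[k, j] + bval(k + 1, j - 1)
        if (abs(val - target) <= eps) {
          pairs <- rbind(pairs, c(k, j))
          if (k + 1L <= j - 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
          j <- k - 1L
          found <- TRUE
          break
        }
      }
      if (!found) j <- j - 1L  # numerical guard; should not trigger
    }
  }
  rna_structure(n, pairs)
}

#' Are two structures highly similar?
#'
#' @param s1,s2 [rna_structure()] objects over the same length.
#' @param delta Maximum number of differing base pairs (default 1).
#' @return `TRUE` iff [basepair_distance()] is at most `delta`.
#' @export
highly_similar <- function(s1, s2, delta = 1) {
  basepair_distance(s1, s2) <= delta
}

# assemble cluster summaries for a given assignment
build_clusters <- function(pool, assignment, gamma = 1, RT = RT_37C) {
  labels <- sort(unique(assignment))
  clusters <- lapply(labels, function(lb) {
    idx <- which(assignment == lb)
    fp <- feature_probabilities(pool, idx, RT)
    centroid <- mea_centroid(fp, gamma)
    stability <- sum(pool$cond_prob[idx])
    list(indices = idx, centroid = centroid, stability = stability,
         size = length(idx),
         cond_mass = vapply(pool$conditions, function(d)
           sum(pool$cond_prob[idx][pool$condition[idx] == d]), numeric(1)))
  })
  clusters
}

#' Cluster a pooled sample with automatic choice of k
#'
#' Runs [cluster_k()] for increasing `k` starting at `k_start` until a
#' stopping criterion fires: (i) two significantly populated clusters of
#' the current iteration have highly similar centroids, or (ii) every
#' significantly populated cluster of the previous iteration has a
#' centroid highly similar to one of the current iteration's centroids.
#' On a trigger at `k`, the clustering of `k - 1` (the last stable one) is
#' returned; a trigger at `k_start` yields the trivial single-cluster
#' clustering. If no trigger occurs, the `k_max` clustering is returned
#' with a warning. A cluster is significantly populated when its stability
#' (accumulated Boltzmann condition probability) strictly exceeds
#' `epsilon` (default: number of conditions / 3).
#'
#' @param pool A [pool_samples()] result.
#' @param k_start,k_max Range of cluster counts scanned (defaults 2 and 10).
#' @param delta Centroid similarity threshold in base pairs (default 1).
#' @param epsilon Stability threshold; default `max(1, |D|)/3`.
#' @param gamma MEA pair weight.
#' @param seed Master seed for the clustering stages.
#' @param restarts k-means restarts.
#' @param RT Thermal energy, kcal/mol.
#' @return A `clustering` object: list with `clusters` (each holding
#'   `indices`, `centroid`, `stability`, `size`, `cond_mass`), `k` (number
#'   of non-empty clusters returned), `assignment`, and `epsilon`.
#' @export
select_k <- function(pool, k_start = 2, k_max = 10, delta = 1,
                     epsilon = NULL, gamma = 1, seed = 1, restarts = 3,
                     RT = RT_37C) {
  n_cond <- max(1L, length(pool$conditions))
  if (is.null(epsilon)) epsilon <- n_cond / 3
  make_result <- function(assignment) {
    clusters <- build_clusters(pool, assignment, gamma, RT)
    structure(list(clusters = clusters, k = length(clusters),
                   assignment = assignment, epsilon = epsilon),
              class = "clustering")
  }
  trivial <- function() make_result(rep(1L, length(pool$structures)))

  prev_assignment <- NULL
  prev_sig_centroids <- NULL
  for (k in k_start:k_max) {
    assignment <- cluster_k(pool, k, seed = stage_seed(seed, k), restarts = restarts)
    clusters <- build_clusters(pool, assignment, gamma, RT)
    sig <- Filter(function(cl) cl$stability > epsilon, clusters)
    # criterion (i): two significant clusters with highly similar centroids
    crit1 <- FALSE
    if (length(sig) >= 2) {
      for (a in seq_len(length(sig) - 1)) {
        for (b in (a + 1):length(sig)) {
          if (highly_similar(sig[[a]]$centroid, sig[[b]]$centroid, delta)) {
            crit1 <- TRUE
          }
        }
      }
    }
    # criterion (ii): all previous significant centroids matched now
    crit2 <- FALSE
    if (!is.null(prev_sig_centroids) && length(prev_sig_centroids) > 0) {
      all_centroids <- lapply(clusters, `[[`, "centroid")
      crit2 <- all(vapply(prev_sig_centroids, function(pc) {
        any(vapply(all_centroids, highly_similar, logical(1),
                   s2 = pc, delta = delta))
      }, logical(1)))
    }
    if (crit1 || crit2) {
      if (is.null(prev_assignment)) return(trivial())
      return(make_result(prev_assignment))
    }
    prev_assignment <- assignment
    prev_sig_centroids <- lapply(sig, `[[`, "centroid")
  }
  warning("no stopping criterion fired before k_max = ", k_max,
          "; returning the k_max clustering", call. = FALSE)
  make_result(prev_assignment)
}

#' @export
print.clustering <- function(x, ...) {
  cat("<clustering> k =", x$k, "clusters; stabilities:",
      paste(sprintf("%.3f", vapply(x$clusters, `[[`, numeric(1), "stability")),
            collapse = ", "), "\n")
  invisible(x)
}
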