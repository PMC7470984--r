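#' Ensemble distance between two dot plots
#'
#' The squared Euclidean distance between base-pair probability matrices:
#' `Dist(d, d') = sum_{i<j} (P(i,j|d) - P(i,j|d'))^2`.
#'
#' @param dp1,dp2 `rna_dotplot` objects over the same length.
#' @return Non-negative real.
#' @export
ensemble_distance <- function(dp1, dp2) {
  if (dp1$n != dp2$n) stop("dot plots have different sizes", call. = FALSE)
  ut <- upper.tri(dp1$p)
  sum((dp1$p[ut] - dp2$p[ut])^2)
}

#' Pairwise ensemble distances between probing conditions
#'
#' Computes the dot plot of every condition's pseudo-Boltzmann ensemble
#' and all pairwise ensemble distances. Optionally appends the probing-free
#' (purely thermodynamic) ensemble as a pseudo-condition labelled
#' `"thermo"`.
#'
#' @param seq An [rna_sequence()].
#' @param conditions A [condition_set()] with at least 2 profiles (or 1 if
#'   `include_probing_free`).
#' @param include_probing_free Append the probing-free ensemble.
#' @inheritParams partition_function
#' @return A `condition_distances` object: list with `D` (labelled square
#'   matrix of squared-Euclidean distances) and `dotplots`.
#' @export
distance_matrix <- function(seq, conditions, include_probing_free = FALSE,
                            schema = pseudo_energy_schema(),
                            model = energy_model(), RT = RT_37C) {
  profiles <- unclass(conditions)
  dps <- lapply(profiles, function(p) dotplot(seq, p, schema = schema,
                                              model = model, RT = RT))
  if (include_probing_free) {
    dps <- c(dps, list(dotplot(seq, NULL, condition = "thermo",
                               schema = schema, model = model, RT = RT)))
  }
  labels <- vapply(dps, `[[`, character(1), "condition")
  if (length(dps) < 2) stop("need at least 2 conditions", call. = FALSE)
  k <- length(dps)
  D <- matrix(0, k, k, dimnames = list(labels, labels))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      D[a, b] <- D[b, a] <- ensemble_distance(dps[[a]], dps[[b]])
    }
  }
  structure(list(D = D, dotplots = dps), class = "condition_distances")
}

#' @export
print.condition_distances <- function(x, ...) {
  cat("<condition_distances> for", nrow(x$D), "conditions\n")
  print(round(x$D, 4))
  invisible(x)
}

#' 2D embedding of conditions from ensemble distances
#'
#' Classical multidimensional scaling (principal coordinates) of the
#' conditions, run on the square roots of the squared-Euclidean ensemble
#' distances. Because dot plots are points in Euclidean space under this
#' metric, the embedding is exact (up to rotation/reflection) whenever two
#' dimensions suffice.
#'
#' @param x A `condition_distances` object or a square matrix of squared
#'   distances.
#' @param dims Number of embedding dimensions (default 2).
#' @return A tibble with columns `condition`, `x`, `y` (and further axes
#'   if `dims > 2`).
#' @export
embed_2d <- function(x, dims = 2) {
  D <- if (inherits(x, "condition_distances")) x$D else as.matrix(x)
  k <- nrow(D)
  dims <- min(dims, k - 1)
  # rank-deficient inputs (e.g. coincident conditions) have fewer positive
  # eigenvalues than requested axes; missing axes are padded with zeros
  coords <- suppressWarnings(stats::cmdscale(stats::as.dist(sqrt(D)), k = dims))
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  while (ncol(coords) < 2) coords <- cbind(coords, 0)  # degenerate spectra
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("cond", seq_len(k))
  out <- tibble::tibble(condition = labels, x = coords[, 1], y = coords[, 2])
  if (ncol(coords) > 2) {
    for (d in 3:ncol(coords)) out[[paste0("dim", d)]] <- coords[, d]
  }
  out
}

#' Group probing conditions by k-means on the embedding
#'
#' @param x A `condition_distances` object or squared-distance matrix.
#' @param k Number of groups.
#' @param seed Integer seed.
#' @param dims Embedding dimensions used for clustering.
#' @return A tibble with columns `condition` and `group`.
#' @export
cluster_conditions <- function(x, k, seed = 1, dims = 2) {
  emb <- embed_2d(x, dims = dims)
  coords <- as.matrix(emb[, setdiff(names(emb), "condition")])
  if (k < 1 || k > nrow(coords)) stop("invalid k", call. = FALSE)
  if (k == nrow(coords)) {
    group <- seq_len(nrow(coords))
  } else if (k == 1) {
    group <- rep(1L, nrow(coords))
  } else {
    fit <- withr::with_seed(seed,
      stats::kmeans(coords, centers = k, nstart = 5, iter.max = 100))
    group <- as.integer(fit$cluster)
  }
  tibble::tibble(condition = emb$condition, group = group)
}

#' Write a distance matrix as TSV
#'
#' @param cd A `condition_distances` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(cd, path) {
  D <- cd$D
  header <- paste(c("condition", colnames(D)), collapse = "\t")
  rows <- vapply(seq_len(nrow(D)), function(a) {
    paste(c(rownames(D)[a], sprintf("%.10g", D[a, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Scatter plot of the condition embedding
#'
#' @param emb A tibble from [embed_2d()] (or a `condition_distances`).
#' @return A ggplot object.
#' @export
plot_condition_map <- function(emb) {
  if (inherits(emb, "condition_distances")) emb <- embed_2d(emb)
  ggplot2::ggplot(emb, ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$condition)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "PCo 1", y = "PCo 2",
                  title = "Conditions embedded by ensemble distance") +
    ggplot2::theme_minimal()
}

#' Heat-map style plot of a dot plot
#'
#' @param dp An `rna_dotplot`.
#' @param min_prob Drop probabilities below this value.
#' @return A ggplot object.
#' @export
plot_dotplot <- function(dp, min_prob = 1e-4) {
  idx <- which(upper.tri(dp$p) & dp$p >= min_prob, arr.ind = TRUE)
  df <- tibble::tibble(i = idx[, 1], j = idx[, 2], prob = dp$p[idx])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "j", y = "i", fill = "P(i,j)",
                  title = paste0("Base-pair probabilities (",
                                 dp$condition, ")")) +
    ggplot2::theme_minimal()
}
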