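#' Boltzmann condition probabilities over a sampled multiset
#'
#' Each sampled instance of condition `d` has probability
#' `P_d(S) = exp(-E_d(S)/RT) / Z*_d`, where `Z*_d` sums the Boltzmann
#' factors over the sampled multiset (every instance contributes once, so
#' repeated structures are counted with their multiplicity and the
#' probabilities over the sample sum to 1).
#'
#' @param sample_set A `sample_set` from [sample_structures()].
#' @param RT Thermal energy, kcal/mol.
#' @return Numeric vector of per-instance probabilities.
#' @export
condition_probability <- function(sample_set, RT = RT_37C) {
  multiset_probability(sample_set$energies, RT)
}

#' Score clusters by stability and cross-condition support
#'
#' Stability of a cluster is its accumulated Boltzmann condition
#' probability across conditions,
#' `Stability(C) = sum_d sum_{S in C inter S_d} P_d(S)`; over all clusters
#' the stabilities sum to the number of conditions. A condition `d`
#' supports a cluster when the cluster's accumulated probability within
#' `d` is at least `tau`; `Support(C)` counts supporting conditions. With
#' the default `tau = 1/(k + 1)` (`k` the number of clusters), every
#' condition supports at least one cluster. A cluster is significantly
#' populated when its stability strictly exceeds `epsilon` (default
#' `|D|/3`, so at most three clusters qualify).
#'
#' @param clustering A `clustering` from [select_k()] (or `build_clusters`
#'   output wrapped the same way).
#' @param tau Support threshold; default `1/(k + 1)`.
#' @param epsilon Stability threshold; default the clustering's.
#' @return A tibble with one row per cluster: `cluster`, `size`,
#'   `stability`, `support`, `significant`, `centroid` (dot-bracket), plus
#'   the underlying cluster list as attribute `"clusters"`.
#' @export
score_clusters <- function(clustering, tau = NULL, epsilon = NULL) {
  k <- clustering$k
  if (is.null(tau)) tau <- 1 / (k + 1)
  if (is.null(epsilon)) epsilon <- clustering$epsilon
  clusters <- clustering$clusters
  stability <- vapply(clusters, `[[`, numeric(1), "stability")
  support <- vapply(clusters, function(cl) sum(cl$cond_mass >= tau), numeric(1))
  out <- tibble::tibble(
    cluster = seq_along(clusters),
    size = vapply(clusters, `[[`, numeric(1), "size"),
    stability = stability,
    support = as.integer(support),
    significant = stability > epsilon,
    centroid = vapply(clusters, function(cl) as_dotbracket(cl$centroid),
                      character(1))
  )
  attr(out, "clusters") <- clusters
  attr(out, "tau") <- tau
  attr(out, "epsilon") <- epsilon
  out
}

#' Pareto-optimal clusters under (stability, support)
#'
#' Removes every cluster strictly dominated by another (at least as good
#' on both metrics, strictly better on one); the survivors are ranked by
#' stability (descending), with support as tie-break.
#'
#' @param scores A data frame with columns `stability` and `support`
#'   (e.g. from [score_clusters()]).
#' @return The Pareto-optimal rows, ranked.
#' @export
pareto_select <- function(scores) {
  if (!NROW(scores)) return(scores)
  st <- scores$stability
  su <- scores$support
  dominated <- vapply(seq_along(st), function(a) {
    any(st >= st[a] & su >= su[a] & (st > st[a] | su > su[a]))
  }, logical(1))
  out <- scores[!dominated, , drop = FALSE]
  out[order(-out$stability, -out$support), , drop = FALSE]
}

#' Predict dominant secondary structures from probing data
#'
#' The end-to-end pipeline: for every probing condition, sample `m`
#' structures from its pseudo-Boltzmann ensemble; pool the samples;
#' cluster with automatic choice of k ([select_k()]); score clusters by
#' stability and support; keep the Pareto-optimal clusters; return their
#' maximum expected accuracy centroids, ranked by stability. With an
#' empty condition set the thermodynamic ensemble alone is used
#' (probing-free mode).
#'
#' @param seq An [rna_sequence()].
#' @param conditions A [condition_set()] (possibly empty), a single
#'   [reactivity_profile()], or a list of profiles.
#' @param config A [run_config()]; individual entries may be overridden
#'   by `...`.
#' @param ... Overrides for config entries (e.g. `m = 500`, `seed = 7`).
#' @return A `multifold_prediction`: tibble with one row per returned
#'   structure (`rank`, `structure` dot-bracket, `stability`, `support`,
#'   `cluster`, `size`), with attributes `"structures"` (list of
#'   [rna_structure()]), `"scores"` (all clusters' scores) and
#'   `"clustering"`.
#' @export
predict_structures <- function(seq, conditions = condition_set(),
                               config = run_config(), ...) {
  config <- utils::modifyList(config, list(...))
  if (inherits(conditions, "reactivity_profile")) {
    conditions <- condition_set(list(conditions))
  } else if (is.list(conditions) && !inherits(conditions, "condition_set")) {
    conditions <- condition_set(conditions)
  }
  model <- config$model %||% energy_model()
  schema <- pseudo_energy_schema(config$m_slope, config$b_intercept,
                                 config$application_mode)
  RT <- config$RT
  probing_free <- length(conditions) == 0L
  profiles <- if (probing_free) list(NULL) else unclass(conditions)
  sample_sets <- lapply(seq_along(profiles), function(di) {
    sample_structures(seq, profiles[[di]], m = config$m,
                      seed = stage_seed(config$seed, di),
                      schema = schema, model = model, RT = RT)
  })
  pool <- pool_samples(sample_sets, RT = RT)
  n_cond <- length(sample_sets)
  clustering <- select_k(pool, k_start = config$k_start, k_max = config$k_max,
                         delta = config$delta, epsilon = n_cond / 3,
                         gamma = config$mea_gamma,
                         seed = stage_seed(config$seed, 1000L),
                         restarts = config$restarts, RT = RT)
  scores <- score_clusters(clustering)
  front <- pareto_select(scores)
  clusters <- attr(scores, "clusters")
  structures <- lapply(front$cluster, function(ci) clusters[[ci]]$centroid)
  out <- tibble::tibble(
    rank = seq_len(NROW(front)),
    structure = front$centroid,
    stability = front$stability,
    support = front$support,
    cluster = front$cluster,
    size = front$size
  )
  attr(out, "structures") <- structures
  attr(out, "scores") <- scores
  attr(out, "clustering") <- clustering
  class(out) <- c("multifold_prediction", class(out))
  out
}

#' Write a prediction report
#'
#' Dot-bracket lines annotated with stability and support, plus a JSON
#' cluster report (per-cluster size, per-condition probability mass,
#' centroid, stability, support).
#'
#' @param prediction A `multifold_prediction`.
#' @param path Output path for the dot-bracket report.
#' @param json_path Optional path for the JSON cluster report.
#' @return `path`, invisibly.
#' @export
write_prediction <- function(prediction, path, json_path = NULL) {
  lines <- sprintf("%s\tstability=%.4f\tsupport=%d", prediction$structure,
                   prediction$stability, prediction$support)
  writeLines(lines, path)
  if (!is.null(json_path)) {
    scores <- attr(prediction, "scores")
    clusters <- attr(scores, "clusters")
    report <- lapply(seq_along(clusters), function(ci) {
      cl <- clusters[[ci]]
      list(cluster = ci, size = cl$size, stability = cl$stability,
           support = scores$support[ci], significant = scores$significant[ci],
           centroid = as_dotbracket(cl$centroid),
           condition_mass = as.list(cl$cond_mass))
    })
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
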