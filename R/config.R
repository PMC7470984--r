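#' Run configuration
#'
#' Collects every tunable parameter of the prediction pipeline with its
#' default: sample size `m = 1000` per condition; pseudo-energy slope
#' `m_slope = 1.3` and intercept `b_intercept = -0.4` kcal/mol applied in
#' `deigan_paired` mode; `RT = 0.61633` kcal/mol (37 C); centroid
#' similarity `delta = 1` base pair; cluster-count scan `k_start = 2` to
#' `k_max = 10`; MEA weight `mea_gamma = 1`; 3 k-means restarts; the
#' stability threshold rule `epsilon = |D|/3` and support threshold rule
#' `tau = 1/(k+1)` are derived at run time. One master `seed` fans out to
#' deterministic per-stage seeds.
#'
#' @param ... Overrides of the defaults.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  config <- list(
    m = 1000L,
    m_slope = 1.3,
    b_intercept = -0.4,
    application_mode = "deigan_paired",
    RT = RT_37C,
    delta = 1,
    k_start = 2L,
    k_max = 10L,
    mea_gamma = 1,
    restarts = 3L,
    seed = 1L,
    engine = "bundled",
    normalization = "boxplot",
    literal_iqr = FALSE,
    model = NULL
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown)) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  config <- utils::modifyList(config, overrides)
  structure(config, class = c("run_config", "list"))
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; all other entries override the defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- config[!vapply(config, is.null, logical(1))]
  yaml::write_yaml(unclass(out), path, precision = 17)
  invisible(path)
}

#' Hash of a run configuration
#'
#' Two runs with equal config hashes and equal inputs produce equal
#' outputs; the hash is echoed in run logs.
#'
#' @param config A [run_config()].
#' @return Character hash.
#' @export
config_hash <- function(config) {
  rlang::hash(config[order(names(config))])
}

# deterministic per-stage seed derivation from the master seed; kept
# below 2^31 so it is always a valid R integer seed
stage_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 2654435761 + as.numeric(stage)) %%
               2147483647)
}
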