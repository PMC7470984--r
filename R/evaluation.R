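#' Confusion counts of a predicted structure
#'
#' Base pairs are classified over all `n(n-1)/2` unordered position pairs:
#' TP = pairs in both prediction and reference, FP = predicted only,
#' FN = reference only, TN = the rest. Strict pair identity (no slippage
#' credit).
#'
#' @param predicted,reference [rna_structure()] objects over the same
#'   length.
#' @return Named numeric vector `c(TP, FP, TN, FN)`.
#' @export
confusion <- function(predicted, reference) {
  if (predicted$n != reference$n) {
    stop("structures have different lengths", call. = FALSE)
  }
  kp <- pair_keys(predicted)
  kr <- pair_keys(reference)
  tp <- length(intersect(kp, kr))
  fp <- length(kp) - tp
  fn <- length(kr) - tp
  total <- predicted$n * (predicted$n - 1) / 2
  c(TP = tp, FP = fp, TN = total - tp - fp - fn, FN = fn)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in
#' `[-1, 1]`; defined as 0 when any factor of the denominator vanishes.
#' 0 is the expected value for a uniform-random predictor.
#'
#' @param counts Output of [confusion()].
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Sensitivity, PPV and their geometric mean
#'
#' `Sens = TP/(TP+FN)` (fraction of reference pairs recovered),
#' `PPV = TP/(TP+FP)` (fraction of predicted pairs that are correct),
#' `GM = sqrt(Sens * PPV)`; components with vanishing denominators are 0.
#'
#' @param counts Output of [confusion()].
#' @return Named vector `c(GM, Sens, PPV)`.
#' @export
gm_sens_ppv <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
  ppv <- if (tp + fp == 0) 0 else tp / (tp + fp)
  c(GM = sqrt(sens * ppv), Sens = sens, PPV = ppv)
}

#' Evaluate predictions against a reference structure
#'
#' @param predictions A list of [rna_structure()], a single structure, or
#'   a `multifold_prediction`.
#' @param reference The reference [rna_structure()]; if it contains
#'   crossing pairs (built with `allow_crossing = TRUE`), the maximum
#'   non-crossing subset is used ([remove_pseudoknots()]).
#' @return A tibble with one row per prediction: confusion counts, `mcc`,
#'   `sens`, `ppv`, `gm`.
#' @export
evaluate_predictions <- function(predictions, reference) {
  if (inherits(predictions, "multifold_prediction")) {
    predictions <- attr(predictions, "structures")
  }
  if (inherits(predictions, "rna_structure")) predictions <- list(predictions)
  reference <- remove_pseudoknots(reference)
  rows <- lapply(seq_along(predictions), function(k) {
    cts <- confusion(predictions[[k]], reference)
    g <- gm_sens_ppv(cts)
    tibble::tibble(prediction = k, TP = cts[["TP"]], FP = cts[["FP"]],
                   TN = cts[["TN"]], FN = cts[["FN"]], mcc = mcc(cts),
                   sens = g[["Sens"]], ppv = g[["PPV"]], gm = g[["GM"]])
  })
  do.call(rbind, rows)
}
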