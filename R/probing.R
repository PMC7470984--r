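#' Reactivity profile for one probing condition
#'
#' Per-position chemical reactivities for a sequence of length `n`, plus a
#' validity mask. A probing "condition" is a reagent/technology/ionic
#' context combination producing one profile. Invalid (missing) positions
#' carry no reactivity information and later receive a pseudo-energy of 0.
#'
#' @param values Numeric vector of length `n`; entries at invalid positions
#'   are ignored.
#' @param valid Logical mask of the same length; defaults to marking any
#'   negative or non-finite value missing (negative values are the
#'   community missing-data sentinel, e.g. -999).
#' @param condition Condition label.
#' @return An object of class `reactivity_profile` with fields `values`
#'   (NA at invalid positions), `valid`, and `condition`.
#' @export
reactivity_profile <- function(values, valid = NULL, condition = "cond") {
  values <- as.numeric(values)
  if (is.null(valid)) valid <- is.finite(values) & values >= 0
  valid <- as.logical(valid) & is.finite(values) & values >= 0
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid, condition = condition),
            class = "reactivity_profile")
}

#' @export
print.reactivity_profile <- function(x, ...) {
  cat("<reactivity_profile> '", x$condition, "': ", length(x$values),
      " positions, ", sum(x$valid), " valid\n", sep = "")
  invisible(x)
}

#' @export
length.reactivity_profile <- function(x) length(x$values)

#' Turn a profile into a tibble
#'
#' @param x A `reactivity_profile`.
#' @param ... Unused.
#' @return A tibble with columns `position`, `reactivity`, `valid`,
#'   `condition`.
#' @export
as_tibble.reactivity_profile <- function(x, ...) {
  tibble::tibble(position = seq_along(x$values), reactivity = x$values,
                 valid = x$valid, condition = x$condition)
}

#' Read a two-column reactivity file
#'
#' The de-facto SHAPE convention: whitespace-separated lines of 1-based
#' position and reactivity; a negative reactivity (commonly -999) marks the
#' position as missing, as does absence of a position from the file. Lines
#' starting with `#` are comments.
#'
#' @param path Path to the reactivity file.
#' @param seq The [rna_sequence()] the profile belongs to.
#' @param condition Condition label (defaults to the file name).
#' @return A [reactivity_profile()].
#' @export
read_reactivity_file <- function(path, seq, condition = NULL) {
  if (is.null(condition)) condition <- sub("\\.[^.]*$", "", basename(path))
  n <- length(seq)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  values <- rep(-1, n)
  for (ln in lines) {
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 2) stop("malformed reactivity line: '", ln, "'", call. = FALSE)
    pos <- suppressWarnings(as.integer(f[1]))
    val <- suppressWarnings(as.numeric(f[2]))
    if (is.na(pos) || is.na(val)) {
      stop("non-numeric field in reactivity line: '", ln, "'", call. = FALSE)
    }
    if (pos < 1 || pos > n) {
      stop("reactivity position ", pos, " outside [1, ", n, "]", call. = FALSE)
    }
    values[pos] <- val
  }
  reactivity_profile(values, condition = condition)
}

#' Write a profile in two-column reactivity format
#'
#' Invalid positions are written with the -999 sentinel, so that reading
#' the file back reproduces the profile.
#'
#' @param profile A [reactivity_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reactivity_file <- function(profile, path) {
  v <- ifelse(profile$valid, profile$values, -999)
  writeLines(sprintf("%d\t%.8g", seq_along(v), v), path)
  invisible(path)
}

#' Box-plot normalization of reactivities
#'
#' The standard SHAPE normalization: outliers are removed from the scaling
#' set by the box-plot rule (values above `Q3 + 1.5 * IQR`), the remaining
#' values are divided by the mean of their top 10%, and the removed
#' outliers are capped at the maximum retained normalized value. With
#' `literal_iqr = TRUE` the outlier cut-off is `1.5 * IQR` itself rather
#' than `Q3 + 1.5 * IQR`.
#'
#' @param profile A [reactivity_profile()] (or bare numeric vector of valid
#'   reactivities).
#' @param literal_iqr Use the literal `> 1.5 * IQR` cut-off.
#' @return Object of the same type with normalized values.
#' @export
normalize_boxplot <- function(profile, literal_iqr = FALSE) {
  if (inherits(profile, "reactivity_profile")) {
    v <- profile$values[profile$valid]
    out <- normalize_boxplot_values(v, literal_iqr)
    values <- profile$values
    values[profile$valid] <- out
    return(reactivity_profile(values, valid = profile$valid,
                              condition = profile$condition))
  }
  normalize_boxplot_values(as.numeric(profile), literal_iqr)
}

normalize_boxplot_values <- function(v, literal_iqr = FALSE) {
  if (length(v) < 10) stop("need at least 10 valid reactivities", call. = FALSE)
  if (any(!is.finite(v) | v < 0)) stop("reactivities must be finite and >= 0", call. = FALSE)
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  if (iqr > 0) {
    cut <- if (literal_iqr) 1.5 * iqr else q[2] + 1.5 * iqr
    keep <- v <= cut
  } else {
    keep <- rep(TRUE, length(v))  # degenerate spread: skip outlier removal
  }
  kept <- v[keep]
  if (!length(kept) || max(kept) == 0) {
    stop("degenerate profile: cannot derive a normalization scale", call. = FALSE)
  }
  ntop <- max(1L, ceiling(length(kept) * 0.10))
  scale <- mean(sort(kept, decreasing = TRUE)[seq_len(ntop)])
  if (scale <= 0) stop("degenerate profile: zero normalization scale", call. = FALSE)
  out <- v / scale
  cap <- max(kept / scale)
  out[!keep] <- cap
  out
}

#' Invalidate positions a reagent cannot probe
#'
#' DMS reports on unpaired A and C; CMCT on G and U; SHAPE reagents probe
#' the ribose and are sequence-agnostic. Positions a reagent cannot probe
#' are marked invalid so they contribute a zero pseudo-energy term.
#'
#' @param profile A [reactivity_profile()].
#' @param reagent One of `"DMS"`, `"CMCT"`, `"SHAPE"`.
#' @param seq Matching [rna_sequence()].
#' @return A masked [reactivity_profile()].
#' @export
mask_by_reagent <- function(profile, reagent, seq) {
  if (length(profile) != length(seq)) {
    stop("profile/sequence length mismatch", call. = FALSE)
  }
  reagent <- toupper(reagent)
  res <- unclass(seq)
  keep <- switch(reagent,
    DMS = res %in% c("A", "C"),
    CMCT = res %in% c("G", "U"),
    SHAPE = rep(TRUE, length(res)),
    stop("unknown reagent '", reagent, "' (use DMS, CMCT or SHAPE)", call. = FALSE)
  )
  reactivity_profile(profile$values, valid = profile$valid & keep,
                     condition = profile$condition)
}

#' Bundle profiles into a condition set
#'
#' @param ... [reactivity_profile()] objects (or a single list of them).
#'   Labels must be distinct. An empty set denotes probing-free mode.
#' @return An object of class `condition_set` (a named list of profiles).
#' @export
condition_set <- function(...) {
  profiles <- list(...)
  if (length(profiles) == 1L && is.list(profiles[[1]]) &&
      !inherits(profiles[[1]], "reactivity_profile")) {
    profiles <- profiles[[1]]
  }
  labels <- vapply(profiles, function(p) p$condition, character(1))
  if (anyDuplicated(labels)) stop("condition labels must be unique", call. = FALSE)
  names(profiles) <- labels
  structure(profiles, class = "condition_set")
}

#' @export
print.condition_set <- function(x, ...) {
  cat("<condition_set> with", length(x), "condition(s):",
      paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
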