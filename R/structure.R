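#' RNA secondary structure
#'
#' A secondary structure over `n` positions is a set of base pairs `(i, j)`
#' with `i < j`. The default constructor enforces the nested-structure
#' invariants used throughout the package: each position belongs to at most
#' one pair, hairpin loops contain at least 3 unpaired positions
#' (`j - i >= 4`), and no two pairs cross. Crossing pairs (pseudoknots) may
#' be represented explicitly with `allow_crossing = TRUE`, e.g. as input to
#' [remove_pseudoknots()].
#'
#' @param n Sequence length.
#' @param pairs Two-column integer matrix (or empty) of base pairs; rows may
#'   be given in any order and orientation.
#' @param allow_crossing Permit crossing pairs (raw pair set variant).
#' @return An object of class `rna_structure` with fields `n` and `pairs`
#'   (rows sorted by `i`).
#' @examples
#' rna_structure(9, rbind(c(1, 9), c(2, 8)))
#' @export
rna_structure <- function(n, pairs = NULL, allow_crossing = FALSE) {
  n <- as.integer(n)
  if (is.null(pairs) || NROW(pairs) == 0) {
    pairs <- matrix(integer(0), ncol = 2)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2)
    swap <- pairs[, 1] > pairs[, 2]
    pairs[swap, ] <- pairs[swap, 2:1]
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  s <- structure(list(n = n, pairs = pairs), class = "rna_structure")
  validate_structure(s, allow_crossing = allow_crossing)
  s
}

# trusted fast path (used for sampler output, which is nested by construction)
new_rna_structure <- function(n, pairs) {
  colnames(pairs) <- c("i", "j")
  structure(list(n = as.integer(n), pairs = pairs), class = "rna_structure")
}

validate_structure <- function(s, allow_crossing = FALSE) {
  p <- s$pairs
  if (NROW(p) == 0) return(invisible(s))
  if (any(p < 1L) || any(p > s$n)) stop("pair index out of range", call. = FALSE)
  idx <- c(p[, 1], p[, 2])
  if (anyDuplicated(idx)) stop("position in more than one pair", call. = FALSE)
  if (any(p[, 2] - p[, 1] < 4L)) {
    stop("hairpin loop smaller than 3 unpaired positions (j - i < 4)",
         call. = FALSE)
  }
  if (!allow_crossing && NROW(p) > 1) {
    for (a in seq_len(NROW(p) - 1)) {
      i <- p[a, 1]; j <- p[a, 2]
      b <- (a + 1):NROW(p)
      k <- p[b, 1]; l <- p[b, 2]
      # rows sorted by i, so i < k always; crossing iff i < k < j < l
      if (any(k < j & j < l)) stop("crossing base pairs", call. = FALSE)
    }
  }
  invisible(s)
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> n =", x$n, "with", NROW(x$pairs), "pairs\n")
  if (x$n <= 200) cat(as_dotbracket(x), "\n")
  invisible(x)
}

#' @export
format.rna_structure <- function(x, ...) as_dotbracket(x)

# pairing partner vector: 0 = unpaired
pairing_vector <- function(s) {
  pt <- integer(s$n)
  if (NROW(s$pairs)) {
    pt[s$pairs[, 1]] <- s$pairs[, 2]
    pt[s$pairs[, 2]] <- s$pairs[, 1]
  }
  pt
}

#' Parse a dot-bracket string
#'
#' Only the round-bracket alphabet `"()."` is accepted; unbalanced strings
#' are rejected.
#'
#' @param text Dot-bracket string.
#' @return An [rna_structure()].
#' @examples
#' parse_dotbracket("((...))")
#' @export
parse_dotbracket <- function(text) {
  ch <- strsplit(text, "")[[1]]
  bad <- setdiff(unique(ch), c("(", ")", "."))
  if (length(bad)) stop("unsupported characters in dot-bracket: ",
                        paste(bad, collapse = ""), call. = FALSE)
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (pos in seq_along(ch)) {
    if (ch[pos] == "(") {
      stack <- c(stack, pos)
    } else if (ch[pos] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
      pairs <- rbind(pairs, c(stack[length(stack)], pos))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
  rna_structure(length(ch), pairs)
}

#' Render a structure as dot-bracket
#'
#' @param s An [rna_structure()].
#' @return Dot-bracket string.
#' @export
as_dotbracket <- function(s) {
  ch <- rep(".", s$n)
  if (NROW(s$pairs)) {
    ch[s$pairs[, 1]] <- "("
    ch[s$pairs[, 2]] <- ")"
  }
  paste(ch, collapse = "")
}

#' Base-pair distance between two structures
#'
#' The number of base pairs by which two structures differ: the cardinality
#' of the symmetric difference of their pair sets. This is the metric used
#' for structural clustering.
#'
#' @param s1,s2 [rna_structure()] objects over the same length.
#' @return Non-negative integer.
#' @export
basepair_distance <- function(s1, s2) {
  if (s1$n != s2$n) stop("structures have different lengths", call. = FALSE)
  k1 <- pair_keys(s1); k2 <- pair_keys(s2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

pair_keys <- function(s) {
  if (!NROW(s$pairs)) return(integer(0))
  s$pairs[, 1] * (s$n + 1L) + s$pairs[, 2]
}

#' Extract a maximum non-crossing subset of base pairs
#'
#' Given a raw (possibly pseudoknotted) pair set in which every position
#' occurs in at most one pair, returns a maximum-cardinality subset of
#' mutually non-crossing pairs, computed by interval dynamic programming.
#' Ties are broken toward the lexicographically smallest pair set, so the
#' output is deterministic. Typical use: converting a crystallographic
#' pair list with pseudoknots into a nested reference structure.
#'
#' @param raw An `rna_structure` built with `allow_crossing = TRUE` (or any
#'   structure; non-crossing input is returned unchanged).
#' @return A nested [rna_structure()].
#' @export
remove_pseudoknots <- function(raw) {
  p <- raw$pairs
  n <- raw$n
  if (!NROW(p)) return(rna_structure(n))
  partner <- integer(n)
  partner[p[, 1]] <- p[, 2]  # only stores i -> j for i < j
  # memoised max pair count over interval [i, j]
  best <- matrix(NA_integer_, n + 1L, n + 1L)
  score <- function(i, j) {
    if (i >= j) return(0L)
    if (!is.na(best[i, j])) return(best[i, j])
    res <- score(i + 1L, j)                    # i unpaired
    l <- partner[i]
    if (l != 0L && l <= j) {
      res <- max(res, 1L + score(i + 1L, l - 1L) + score(l + 1L, j))
    }
    best[i, j] <<- res
    res
  }
  score(1L, n)
  # traceback; on ties prefer keeping the pair at the leftmost position,
  # which yields the lexicographically smallest pair set
  keep <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    while (i < j) {
      l <- partner[i]
      if (l != 0L && l <= j &&
          score(i, j) == 1L + score(i + 1L, l - 1L) + score(l + 1L, j)) {
        keep <- rbind(keep, c(i, l))
        if (l + 1L < j) stack[[length(stack) + 1L]] <- c(l + 1L, j)
        j <- l - 1L
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  rna_structure(n, keep)
}

#' Read a connectivity-table (CT) file
#'
#' Standard 6-column CT format: a header line with the sequence length,
#' then one row per position: index, residue, i-1, i+1, pairing partner
#' (0 if unpaired), index again.
#'
#' @param path Path to a CT file.
#' @param allow_crossing Keep crossing pairs (raw pair set) instead of
#'   rejecting them.
#' @return A list with elements `seq` ([rna_sequence()]) and
#'   `structure` ([rna_structure()]).
#' @export
read_ct <- function(path, allow_crossing = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  head_n <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1]))
  if (is.na(head_n)) stop("malformed CT header", call. = FALSE)
  body <- lines[-1][seq_len(head_n)]
  fields <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  if (ncol(fields) < 6) stop("malformed CT body", call. = FALSE)
  res <- fields[, 2]
  partner <- as.integer(fields[, 5])
  idx <- as.integer(fields[, 1])
  if (!identical(idx, seq_len(head_n))) stop("CT positions not consecutive", call. = FALSE)
  sel <- which(partner > idx)
  pairs <- cbind(idx[sel], partner[sel])
  list(seq = rna_sequence(res, id = basename(path)),
       structure = rna_structure(head_n, pairs, allow_crossing = allow_crossing))
}

#' Write a connectivity-table (CT) file
#'
#' @param s An [rna_structure()].
#' @param seq Matching [rna_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct <- function(s, seq, path) {
  if (s$n != length(seq)) stop("structure/sequence length mismatch", call. = FALSE)
  pt <- pairing_vector(s)
  i <- seq_len(s$n)
  rows <- sprintf("%5d %s %7d %4d %4d %4d", i, unclass(seq), i - 1L,
                  ifelse(i == s$n, 0L, i + 1L), pt, i)
  writeLines(c(sprintf("%5d  %s", s$n, attr(seq, "id")), rows), path)
  invisible(path)
}
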