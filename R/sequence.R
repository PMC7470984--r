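#' RNA sequence object
#'
#' A light container for a single RNA sequence. Residues are upper-cased and
#' DNA thymine is mapped to uracil on construction, so downstream code only
#' ever sees the alphabet `A, C, G, U, N`.
#'
#' @param residues Character scalar (e.g. `"GGGAAACCC"`) or character vector
#'   of single letters.
#' @param id Sequence identifier.
#' @return An object of class `rna_sequence`: a character vector of single
#'   residues with attributes `id` and length accessor via [length()].
#' @examples
#' rna_sequence("GGGAAACCC", id = "toy")
#' @export
rna_sequence <- function(residues, id = "rna") {
  if (length(residues) == 1L && nchar(residues) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  residues <- toupper(as.character(residues))
  residues[residues == "T"] <- "U"
  bad <- setdiff(unique(residues), c("A", "C", "G", "U", "N"))
  if (length(bad) > 0) {
    stop("invalid residues in sequence '", id, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(residues) < 1L) stop("sequence must have length >= 1", call. = FALSE)
  structure(residues, id = id, class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat("<rna_sequence> ", attr(x, "id"), " (", length(x), " nt)\n", sep = "")
  cat(paste(unclass(x), collapse = ""), "\n")
  invisible(x)
}

#' Read the first sequence of a FASTA file
#'
#' @param path Path to a FASTA file. Only the first record is used.
#' @return An [rna_sequence()].
#' @export
read_rna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 1L) stop("no sequences in ", path, call. = FALSE)
  rna_sequence(as.character(set[[1]]), id = names(set)[1])
}

#' Write a sequence to FASTA
#'
#' @param seq An [rna_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(seq, path) {
  writeLines(c(paste0(">", attr(seq, "id")), paste(unclass(seq), collapse = "")),
             path)
  invisible(path)
}

# integer codes used by the folding engine: A=1 C=2 G=3 U=4 N=5
seq_codes <- function(seq) {
  match(unclass(seq), c("A", "C", "G", "U", "N"))
}
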