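#' @useDynLib ucatestbed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

# Internal sequence representation: named character vector of residue strings.
# Alignments: named character vector of equal-length gapped strings with class
# "aa_alignment" and attribute "source".

as_sequence_strings <- function(x) {
  if (inherits(x, "AAStringSet")) {
    out <- as.character(x)
  } else if (is.matrix(x)) {
    out <- apply(x, 1, paste, collapse = "")
  } else {
    out <- as.character(x)
    names(out) <- names(x)
  }
  out
}

# Residues as integers 1..20 in AA_ALPHABET order; gap/unknown = NA.
seq_to_int <- function(s) {
  m <- match(strsplit(toupper(s), "")[[1]], AA_ALPHABET)
  m
}

int_to_seq <- function(v) {
  out <- rep("-", length(v))
  ok <- !is.na(v)
  out[ok] <- AA_ALPHABET[v[ok]]
  paste(out, collapse = "")
}

validate_residues <- function(seqs) {
  seqs <- as_sequence_strings(seqs)
  bad <- vapply(seqs, function(s) {
    any(is.na(match(setdiff(strsplit(toupper(s), "")[[1]], "-"), AA_ALPHABET)))
  }, logical(1))
  if (any(bad)) {
    stop("unknown residue symbol in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  invisible(seqs)
}

#' Read and write protein FASTA files
#'
#' Thin wrappers around Biostrings returning/accepting named character
#' vectors, the package's working representation of sequence sets.
#'
#' @param path File path.
#' @param seqs Named character vector of sequences (may contain gaps).
#' @return `read_fasta()`: a named character vector.
#' @export
read_fasta <- function(path) {
  as.character(Biostrings::readAAStringSet(path))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_sequence_strings(seqs)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path, width = 70L)
  invisible(path)
}

# Alignment constructor; rows = named gapped strings of equal length.
new_alignment <- function(rows, source = "external") {
  rows <- as_sequence_strings(rows)
  n <- unique(nchar(rows))
  if (length(n) != 1L) stop("alignment rows must have equal length")
  structure(rows, class = "aa_alignment", source = source)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("amino-acid alignment: %d sequences x %d columns (source: %s)\n",
              length(x), nchar(x[[1]]), attr(x, "source")))
  w <- min(60L, nchar(x[[1]]))
  for (i in seq_along(x)) {
    cat(sprintf("  %-12s %s%s\n", names(x)[i], substr(x[i], 1, w),
                if (nchar(x[i]) > w) "..." else ""))
  }
  invisible(x)
}

# Alignment as integer matrix (rows x columns), NA for gaps.
alignment_matrix <- function(aln) {
  rows <- as_sequence_strings(aln)
  nc <- nchar(rows[[1]])
  m <- matrix(NA_integer_, length(rows), nc, dimnames = list(names(rows), NULL))
  for (i in seq_along(rows)) m[i, ] <- seq_to_int(rows[[i]])
  m
}

degap <- function(s) gsub("-", "", s, fixed = TRUE)
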