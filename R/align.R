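# Progressive multiple alignment: k-mer distances -> UPGMA guide tree ->
# profile-profile global affine alignment up the tree ("once a gap, always a
# gap"). A competent stand-in for production aligners, not a reimplementation
# of any of them: single progressive pass, no iterative refinement.

#' Log-odds amino-acid score matrix from a substitution model
#'
#' Score of aligning residues i, j is `round(scale * log2(P_ij(t) / pi_j))`,
#' the log-odds of common descent at divergence `t` against random pairing,
#' in half-bit units by default. The default divergence is chosen so the
#' matrix statistics match the scale the default affine penalties (-11 open,
#' -1 extend) are conventionally paired with: at `t = 1.5` the rtREV
#' log-odds matrix has relative entropy ~0.7 bits and expected random-pair
#' score ~ -1 half-bit, closely matching BLOSUM62.
#'
#' @param model An [substitution_model()] (rate heterogeneity ignored here).
#' @param t Divergence (expected substitutions/site) of the target pairs.
#' @param scale Multiplier before integer rounding (2 = half-bits).
#' @return An integer-valued symmetric 20 x 20 matrix.
#' @export
aa_score_matrix <- function(model = substitution_model("rtREV"), t = 1.5,
                            scale = 2) {
  P <- transition_probabilities(model, t, rate = 1)
  odds <- P / rep(model$frequencies, each = 20)
  s <- scale * log2(odds)
  s <- (s + t(s)) / 2
  s <- round(s)
  dimnames(s) <- list(AA_ALPHABET, AA_ALPHABET)
  s
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh with affine gap penalties and deterministic
#' tie-breaking (match preferred over a gap in the second sequence, preferred
#' over a gap in the first).
#'
#' @param s1,s2 Residue strings.
#' @param score_matrix 20 x 20 substitution scores (default:
#'   [aa_score_matrix()] of rtREV at distance 1).
#' @param gap_open Score of the first residue of a gap (negative).
#' @param gap_extend Score of each further gap residue (negative).
#' @return A list: `alignment` (2-row `aa_alignment`) and `score`.
#' @export
pairwise_align <- function(s1, s2, score_matrix = NULL, gap_open = -11,
                           gap_extend = -1) {
  seqs <- c(s1 = unname(s1), s2 = unname(s2))
  if (all(nchar(seqs) == 0)) stop("both sequences empty")
  validate_residues(seqs)
  if (is.null(score_matrix)) score_matrix <- default_score_matrix()
  x1 <- seq_to_int(seqs[[1]])
  x2 <- seq_to_int(seqs[[2]])
  sc <- matrix(0, length(x1), length(x2))
  if (length(x1) && length(x2)) {
    sc <- score_matrix[x1, x2, drop = FALSE]
  }
  res <- .affine_align_path(sc, gap_open, gap_extend)
  rows <- apply_path_pair(seqs[[1]], seqs[[2]], res$path)
  nm <- c(names(s1), names(s2))
  if (length(nm) != 2L || any(!nzchar(nm))) nm <- c("s1", "s2")
  names(rows) <- nm
  list(alignment = new_alignment(rows, source = "progressive"),
       score = res$score)
}

# path codes: 0 = match, 1 = gap in second (consumes first), 2 = gap in first
apply_path_pair <- function(s1, s2, path) {
  a1 <- character(length(path)); a2 <- character(length(path))
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  i <- 0L; j <- 0L
  for (k in seq_along(path)) {
    if (path[k] == 0L) {
      i <- i + 1L; j <- j + 1L
      a1[k] <- c1[i]; a2[k] <- c2[j]
    } else if (path[k] == 1L) {
      i <- i + 1L
      a1[k] <- c1[i]; a2[k] <- "-"
    } else {
      j <- j + 1L
      a1[k] <- "-"; a2[k] <- c2[j]
    }
  }
  c(paste(a1, collapse = ""), paste(a2, collapse = ""))
}

# Cache the default score matrix (rtREV log-odds, BLOSUM62-like scale).
.align_cache <- new.env(parent = emptyenv())
default_score_matrix <- function() {
  if (is.null(.align_cache$S)) {
    .align_cache$S <- aa_score_matrix()
  }
  .align_cache$S
}

# Fractional common k-mer distance between two sequences.
kmer_distance_matrix <- function(seqs, k = 3L) {
  n <- length(seqs)
  kmers <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(table(character(0)))
    table(substring(s, 1:(L - k + 1L), k:L))
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ti <- kmers[[i]]; tj <- kmers[[j]]
    shared <- intersect(names(ti), names(tj))
    common <- sum(pmin(as.integer(ti[shared]), as.integer(tj[shared])))
    denom <- max(1L, min(nchar(seqs[i]), nchar(seqs[j])) - k + 1L)
    D[i, j] <- D[j, i] <- 1 - common / denom
  }
  D
}

# 20 x L residue-frequency profile of an alignment (gap mass excluded;
# columns divided by the number of rows).
alignment_profile <- function(aln) {
  m <- alignment_matrix(aln)
  L <- ncol(m)
  prof <- matrix(0, 20, L)
  for (i in seq_len(nrow(m))) {
    ok <- which(!is.na(m[i, ]))
    if (length(ok)) {
      prof[cbind(m[i, ok], ok)] <- prof[cbind(m[i, ok], ok)] + 1
    }
  }
  prof / nrow(m)
}

# Merge two alignments along a DP path into one alignment.
merge_alignments <- function(aln1, aln2, path) {
  m1 <- do.call(rbind, strsplit(as_sequence_strings(aln1), ""))
  m2 <- do.call(rbind, strsplit(as_sequence_strings(aln2), ""))
  L <- length(path)
  out1 <- matrix("-", nrow(m1), L)
  out2 <- matrix("-", nrow(m2), L)
  i <- 0L; j <- 0L
  for (k in seq_len(L)) {
    if (path[k] != 2L) { i <- i + 1L; out1[, k] <- m1[, i] }
    if (path[k] != 1L) { j <- j + 1L; out2[, k] <- m2[, j] }
  }
  rows <- c(apply(out1, 1, paste, collapse = ""),
            apply(out2, 1, paste, collapse = ""))
  names(rows) <- c(names(as_sequence_strings(aln1)),
                   names(as_sequence_strings(aln2)))
  new_alignment(rows, source = "progressive")
}

#' Progressive multiple sequence alignment
#'
#' UPGMA guide tree from fractional common k-mer distances, then
#' profile-profile global affine alignment up the guide tree. Deterministic
#' under a fixed input order; gaps once introduced are never removed.
#'
#' @param seqs Named character vector of >= 1 sequences.
#' @param score_matrix,gap_open,gap_extend As in [pairwise_align()].
#' @param k K-mer length for guide-tree distances.
#' @return An `aa_alignment` with rows in the input order.
#' @export
progressive_msa <- function(seqs, score_matrix = NULL, gap_open = -11,
                            gap_extend = -1, k = 3L) {
  seqs <- as_sequence_strings(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  validate_residues(seqs)
  if (length(seqs) == 1L) return(new_alignment(seqs, source = "progressive"))
  if (is.null(score_matrix)) score_matrix <- default_score_matrix()

  D <- kmer_distance_matrix(seqs, k = k)
  hc <- stats::hclust(stats::as.dist(D), method = "average")

  nodes <- vector("list", nrow(hc$merge))
  leaf_aln <- function(i) new_alignment(seqs[i], source = "progressive")
  get_node <- function(v) if (v < 0) leaf_aln(-v) else nodes[[v]]
  res_mat <- function(a) {
    m <- alignment_matrix(a)
    m[is.na(m)] <- 0L
    m
  }
  for (s in seq_len(nrow(hc$merge))) {
    a1 <- get_node(hc$merge[s, 1])
    a2 <- get_node(hc$merge[s, 2])
    res <- .affine_align_profiles(res_mat(a1), res_mat(a2), score_matrix,
                                  gap_open, gap_extend)
    nodes[[s]] <- merge_alignments(a1, a2, res$path)
  }
  final <- nodes[[nrow(hc$merge)]]
  rows <- as_sequence_strings(final)[names(seqs)]
  new_alignment(rows, source = "progressive")
}

#' Stack equal-length sequences as a gap-free alignment
#'
#' The "unaligned" control mode: column i is position i of every sequence.
#' Only defined for indel-free (equal-length) data.
#'
#' @param seqs Named character vector.
#' @return An `aa_alignment` with `source = "identity"`.
#' @export
identity_alignment <- function(seqs) {
  seqs <- as_sequence_strings(seqs)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("identity alignment requires equal-length sequences")
  }
  validate_residues(seqs)
  new_alignment(seqs, source = "identity")
}

#' Fraction of gap cells in an alignment
#'
#' @param alignment An `aa_alignment` (or named character vector of
#'   equal-length gapped strings).
#' @return A number in `[0, 1]`.
#' @export
gap_fraction <- function(alignment) {
  rows <- as_sequence_strings(alignment)
  total <- sum(nchar(rows))
  gaps <- sum(nchar(rows) - nchar(gsub("-", "", rows, fixed = TRUE)))
  gaps / total
}
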