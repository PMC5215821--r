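# The fixed-alignment model-selection test of common ancestry: compare the
# one-tree (all sequences) hypothesis against independent trees per group by
# delta AIC = AIC(group1) + AIC(group2) + ... - AIC(joint), positive values
# favoring common ancestry. Run either on a progressive alignment of the
# sequences ("aligned" mode) or on the raw equal-length stacking
# ("unaligned" mode), the control that exposes the alignment-induced bias.

#' Split a global alignment into per-group sub-alignments
#'
#' Every sub-alignment keeps all global columns; columns that are all-gap
#' within a group are retained (they contribute exactly 0 to that group's
#' log-likelihood), so all hypotheses are scored on identical data.
#'
#' @param alignment An `aa_alignment` or named character vector.
#' @param groups Named list of character vectors of row labels, forming a
#'   partition of the rows.
#' @return Named list of `aa_alignment` objects.
#' @export
split_alignment <- function(alignment, groups) {
  rows <- as_sequence_strings(alignment)
  labs <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(labs) || !setequal(labs, names(rows))) {
    stop("groups must partition the alignment rows")
  }
  lapply(groups, function(g)
    new_alignment(rows[g], source = attr(alignment, "source") %||% "external"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Free parameters per fitted tree: (2n - 3) branch lengths (1 for a pair),
# + 1 gamma shape if present, + 19 frequencies under +F when counted per tree.
count_parameters <- function(tree, model, count_frequencies = TRUE) {
  k <- n_free_branches(tree)
  if (!is.null(model$gamma_shape)) k <- k + 1L
  if (isTRUE(model$plus_f) && count_frequencies) k <- k + 19L
  k
}

ic_penalty <- function(logl, k, n, criterion) {
  switch(criterion,
    AIC = 2 * k - 2 * logl,
    AICc = 2 * k - 2 * logl + 2 * k * (k + 1) / max(n - k - 1, 1),
    BIC = k * log(n) - 2 * logl
  )
}

#' Run the fixed-alignment delta-AIC test of common ancestry
#'
#' Fits, by maximum likelihood on fixed topologies, one tree over all
#' sequences (the common-ancestry hypothesis) and one tree per group (the
#' independent-origins hypothesis), all scored on the same alignment, and
#' compares them by an information criterion.
#'
#' @param seqs Named character vector of sequences (unaligned residue
#'   strings).
#' @param groups Named list of sequence-label vectors partitioning `seqs`.
#' @param model An [substitution_model()]. With `refit_frequencies = TRUE`
#'   (default) a `+F` fit is used: frequencies observed in the scored
#'   alignment, counted as 19 free parameters per tree.
#' @param mode `"aligned"` (run [progressive_msa()] first) or `"unaligned"`
#'   ([identity_alignment()]; requires equal-length sequences).
#' @param topologies Named list of fixed topologies: one per group plus
#'   `"joint"`. If `NULL`, neighbor-joining topologies are estimated from
#'   pairwise distances on the scored alignment.
#' @param criterion `"AIC"` (default), `"AICc"` or `"BIC"`; the sample size
#'   for AICc/BIC is the number of alignment columns.
#' @param shared_frequencies If `TRUE`, frequency parameters are counted once
#'   per hypothesis instead of once per tree.
#' @param refit_frequencies Replace model frequencies by the alignment's
#'   observed frequencies (`+F`).
#' @param ... Passed to [fit_ml()].
#' @return A `uca_aic_result`: per-hypothesis tibble (`label`, `logL`, `K`,
#'   `AIC`), `delta_aic`, `delta_aic_per_site`, `mode`, `decision`
#'   (`"UCA"` iff `delta_aic > 0`), `alignment`, and the fitted trees.
#' @export
run_uca_aic_test <- function(seqs, groups, model = substitution_model("rtREV", gamma_shape = 0.8),
                             mode = c("aligned", "unaligned"),
                             topologies = NULL,
                             criterion = c("AIC", "AICc", "BIC"),
                             shared_frequencies = FALSE,
                             refit_frequencies = TRUE, ...) {
  mode <- match.arg(mode)
  criterion <- match.arg(criterion)
  seqs <- as_sequence_strings(seqs)
  aln <- if (mode == "aligned") progressive_msa(seqs) else identity_alignment(seqs)
  n_col <- nchar(aln[[1]])

  if (refit_frequencies) {
    model <- substitution_model(
      if (model$name == "custom") "custom" else model$name,
      exchangeabilities = if (model$name == "custom") model$exchangeabilities else NULL,
      frequencies = empirical_frequencies(aln),
      gamma_shape = model$gamma_shape, n_categories = model$n_categories,
      plus_f = TRUE)
  }

  subs <- split_alignment(aln, groups)
  fit_one <- function(sub_aln, topo, label) {
    rows <- as_sequence_strings(sub_aln)
    if (is.null(topo)) topo <- nj_topology(sub_aln)
    fit <- fit_ml(rows, topo, model, ...)
    k <- count_parameters(topo, model, count_frequencies = !shared_frequencies)
    list(label = label, fit = fit, K = k)
  }

  topo_for <- function(label) if (is.null(topologies)) NULL else topologies[[label]]
  fits <- c(
    lapply(names(groups), function(g) fit_one(subs[[g]], topo_for(g), g)),
    list(fit_one(aln, topo_for("joint"), "joint"))
  )

  tab <- dplyr::bind_rows(lapply(fits, function(f)
    tibble::tibble(label = f$label, logL = f$fit$log_likelihood, K = f$K)))
  tab$AIC <- ic_penalty(tab$logL, tab$K, n_col, criterion)

  io <- tab[tab$label != "joint", ]
  joint <- tab[tab$label == "joint", ]
  if (shared_frequencies && isTRUE(model$plus_f)) {
    # the shared frequency vector enters once per hypothesis, not per tree
    delta <- ic_penalty(sum(io$logL), sum(io$K) + 19L, n_col, criterion) -
      ic_penalty(joint$logL, joint$K + 19L, n_col, criterion)
  } else {
    delta <- sum(io$AIC) - joint$AIC
  }
  structure(
    list(hypotheses = tab,
         delta_aic = delta,
         delta_aic_per_site = delta / n_col,
         n_columns = n_col,
         mode = mode,
         criterion = criterion,
         decision = if (delta > 0) "UCA" else "IO",
         alignment = aln,
         fits = stats::setNames(lapply(fits, `[[`, "fit"),
                                vapply(fits, `[[`, "", "label"))),
    class = "uca_aic_result"
  )
}

#' Neighbor-joining topology from an alignment
#'
#' Pairwise Poisson-corrected distances over shared ungapped sites, then
#' ape's NJ (BIONJ-free, classic). Used when no fixed topology is supplied.
#'
#' @param alignment An `aa_alignment`.
#' @return An unrooted `phylo` (branch lengths floored at 0).
#' @export
nj_topology <- function(alignment) {
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("no resolvable topology for a single sequence")
  if (n == 2L) {
    return(parse_newick(sprintf("(%s:0.5,%s:0.5);",
                                rownames(m)[1], rownames(m)[2])))
  }
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    p <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0
    p <- min(p, 0.94)
    D[i, j] <- D[j, i] <- -(19 / 20) * log(1 - 20 * p / 19)
  }
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length <- pmax(tr$edge.length, 1e-6)
  tr
}

#' Delta AIC per alignment column
#'
#' @param result A `uca_aic_result`.
#' @return `delta_aic / n_columns`.
#' @export
delta_aic_per_site <- function(result) {
  stopifnot(inherits(result, "uca_aic_result"))
  if (result$n_columns <= 0) stop("no alignment columns")
  result$delta_aic / result$n_columns
}

#' @export
print.uca_aic_result <- function(x, ...) {
  cat(sprintf("common-ancestry %s test (%s mode): delta = %.2f (%.4f/site) -> %s\n",
              x$criterion, x$mode, x$delta_aic, x$delta_aic_per_site,
              x$decision))
  print(x$hypotheses)
  invisible(x)
}

#' @export
tidy.uca_aic_result <- function(x, ...) x$hypotheses

#' @export
glance.uca_aic_result <- function(x, ...) {
  tibble::tibble(
    delta_aic = x$delta_aic,
    delta_aic_per_site = x$delta_aic_per_site,
    n_columns = x$n_columns,
    mode = x$mode,
    criterion = x$criterion,
    decision = x$decision,
    gap_fraction = gap_fraction(x$alignment)
  )
}
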