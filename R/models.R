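#' Amino-acid substitution models
#'
#' Construct a time-reversible amino-acid replacement model from a named
#' preset (`"rtREV"`, `"LG"`) or from custom exchangeabilities and equilibrium
#' frequencies, optionally with discrete-gamma rate heterogeneity and
#' empirical (`+F`) frequencies.
#'
#' @param name `"rtREV"`, `"LG"` or `"custom"`.
#' @param exchangeabilities For `name = "custom"`: a symmetric non-negative
#'   matrix with zero diagonal, or the strict lower triangle in column-major
#'   order.
#' @param frequencies Equilibrium frequencies (must sum to 1). For presets,
#'   overrides the published frequencies (this is how `+F` models are built:
#'   pass frequencies observed in the data, see [empirical_frequencies()]).
#' @param gamma_shape Shape of the gamma distribution of rates across sites,
#'   or `NULL` for rate homogeneity.
#' @param n_categories Number of discrete gamma categories (default 4).
#' @param plus_f Logical flag recording whether `frequencies` came from data.
#'
#' @return An object of class `aa_model` with elements `name`,
#'   `exchangeabilities` (20 x 20 symmetric), `frequencies`, `gamma_shape`,
#'   `n_categories`, `plus_f`, the scaled rate matrix `Q`, and its spectral
#'   decomposition used for fast transition probabilities.
#' @export
#' @examples
#' m <- substitution_model("LG", gamma_shape = 0.7)
#' range(rowSums(transition_probabilities(m, 0.5)))
substitution_model <- function(name = c("rtREV", "LG", "custom"),
                               exchangeabilities = NULL,
                               frequencies = NULL,
                               gamma_shape = NULL,
                               n_categories = 4L,
                               plus_f = FALSE) {
  name <- match.arg(name)
  if (name == "custom") {
    if (is.null(exchangeabilities) || is.null(frequencies)) {
      stop("custom models need `exchangeabilities` and `frequencies`")
    }
  } else {
    ex <- switch(name, rtREV = RTREV_EXCH, LG = LG_EXCH)
    fr <- switch(name, rtREV = RTREV_FREQ, LG = LG_FREQ)
    if (is.null(exchangeabilities)) exchangeabilities <- ex
    if (!is.null(frequencies)) plus_f <- TRUE else frequencies <- fr
  }
  S <- as_exchangeability_matrix(exchangeabilities)
  pi <- as.numeric(frequencies)
  k <- nrow(S)
  if (length(pi) != k) stop("frequencies must have one entry per state")
  if (any(pi < 0)) stop("frequencies must be non-negative")
  if (abs(sum(pi) - 1) > 1e-8) stop("frequencies must sum to 1")
  pi <- pi / sum(pi)
  if (!is.null(gamma_shape)) {
    stopifnot(is.numeric(gamma_shape), length(gamma_shape) == 1L)
    if (gamma_shape <= 0) stop("gamma_shape must be positive")
  }
  n_categories <- as.integer(n_categories)
  if (n_categories < 1L) stop("n_categories must be >= 1")

  model <- structure(
    list(name = name, exchangeabilities = S, frequencies = pi,
         gamma_shape = gamma_shape, n_categories = n_categories,
         plus_f = plus_f),
    class = "aa_model"
  )
  model$Q <- build_rate_matrix(model)
  model$eig <- reversible_eigen(model$Q, pi)
  model
}

# Accept either a full symmetric matrix or the strict lower triangle
# (column-major), as in PAML .dat files.
as_exchangeability_matrix <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) stop("exchangeability matrix must be square")
    if (max(abs(x - t(x))) > 1e-12) stop("exchangeability matrix must be symmetric")
    S <- x
  } else {
    x <- as.numeric(x)
    k <- (1 + sqrt(1 + 8 * length(x))) / 2
    if (abs(k - round(k)) > 1e-9) stop("exchangeability vector length is not a triangular number")
    k <- as.integer(round(k))
    S <- matrix(0, k, k)
    S[lower.tri(S)] <- x
    S <- S + t(S)
  }
  if (any(S < 0)) stop("exchangeabilities must be non-negative")
  diag(S) <- 0
  S
}

#' Build the scaled instantaneous rate matrix
#'
#' Q[i, j] = s[i, j] * pi[j] for i != j, diagonal set so rows sum to zero, and
#' the whole matrix rescaled so the expected substitution rate at equilibrium,
#' -sum(pi * diag(Q)), equals 1: branch lengths are then expected
#' substitutions per site.
#'
#' @param model An `aa_model` (or any list with `exchangeabilities` and
#'   `frequencies`).
#' @return A square rate matrix.
#' @export
build_rate_matrix <- function(model) {
  S <- model$exchangeabilities
  pi <- model$frequencies
  Q <- S * rep(pi, each = nrow(S))
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate model: zero expected rate")
  Q / scale
}

# Spectral decomposition of a reversible Q via the symmetric similarity
# transform B = diag(sqrt(pi)) Q diag(1/sqrt(pi)); guarantees a real spectrum.
reversible_eigen <- function(Q, pi) {
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       right = e$vectors / sp,      # rows scaled: diag(1/sp) %*% U
       left = t(e$vectors * sp))    # t(diag(sp) %*% U)
}

#' Discrete-gamma category rates
#'
#' Equal-probability discretization of a mean-one gamma distribution using the
#' mean of each category (quantile slice), renormalized so the category rates
#' average exactly 1.
#'
#' @param alpha Gamma shape (> 0). Rate heterogeneity decreases as alpha grows.
#' @param n_categories Number of categories (>= 1).
#' @return Numeric vector of category rates, weakly increasing, mean 1.
#' @export
discrete_gamma_rates <- function(alpha, n_categories = 4L) {
  stopifnot(length(alpha) == 1L, is.finite(alpha))
  if (alpha <= 0) stop("alpha must be positive")
  n <- as.integer(n_categories)
  if (n < 1L) stop("n_categories must be >= 1")
  if (n == 1L) return(1)
  # mean of X ~ Gamma(alpha, rate = alpha) over each inter-quantile slice:
  # E[X; X in (a,b)] = P(Gamma(alpha+1, alpha) in (a,b)) * (alpha+1-1)/alpha...
  # with unit mean, E[X | slice] * (1/n) = F_{alpha+1}(b) - F_{alpha+1}(a).
  q <- stats::qgamma(seq(0, 1, length.out = n + 1L), shape = alpha, rate = alpha)
  Fi <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  rates <- n * diff(Fi)
  rates / mean(rates)
}

#' Transition probability matrix P(t) = exp(Q r t)
#'
#' @param model An `aa_model`.
#' @param t Branch length (expected substitutions per site, >= 0).
#' @param rate Site-rate multiplier (e.g. a discrete-gamma category rate).
#' @return A stochastic matrix (rows sum to 1).
#' @export
transition_probabilities <- function(model, t, rate = 1) {
  if (!is.finite(t) || t < 0) stop("branch length t must be >= 0")
  e <- model$eig
  P <- e$right %*% (exp(e$values * t * rate) * e$left)
  # eigendecomposition round-off can leave tiny negatives
  if (any(P < 0)) {
    if (min(P) < -1e-10) stop("transition probabilities significantly negative")
    P[P < 0] <- 0
  }
  dimnames(P) <- dimnames(model$Q)
  P
}

#' Observed amino-acid frequencies of a sequence set or alignment
#'
#' Counts residues over all sequences (gaps ignored) with no pseudocount.
#'
#' @param x A character vector of sequences, or an alignment matrix.
#' @return A frequency vector in the standard residue order, summing to 1.
#' @export
empirical_frequencies <- function(x) {
  chars <- unlist(strsplit(toupper(unlist(as_sequence_strings(x))), ""))
  chars <- chars[chars != "-"]
  counts <- table(factor(chars, levels = AA_ALPHABET))
  n <- sum(counts)
  if (n == 0) stop("no residues found")
  as.numeric(counts) / n
}

#' Read a PAML-style .dat rate matrix file
#'
#' Expects the strict lower triangle of the exchangeability matrix (19 rows)
#' followed by 20 equilibrium frequencies, whitespace separated; blank lines
#' and anything after the frequencies are ignored.
#'
#' @param path File path.
#' @return A list with `exchangeabilities` (lower-triangle vector,
#'   column-major) and `frequencies`.
#' @export
read_paml_dat <- function(path) {
  vals <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#",
               nlines = -1)
  if (length(vals) < 210) stop("expected at least 190 exchangeabilities + 20 frequencies")
  tri_row <- vals[1:190]        # PAML files list the triangle row-wise
  freqs <- vals[191:210]
  S <- matrix(0, 20, 20)
  k <- 1
  for (i in 2:20) for (j in 1:(i - 1)) { S[i, j] <- tri_row[k]; k <- k + 1 }
  S <- S + t(S)
  list(exchangeabilities = S[lower.tri(S)], frequencies = freqs)
}
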