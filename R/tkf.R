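# TKF91 birth-death indel model: closed-form pair-HMM per branch.
#
# A sequence under TKF91 is a chain of mortal links (residues) behind one
# immortal link; each link spawns insertions at rate lambda, mortal links die
# at rate mu, and lambda < mu keeps the equilibrium length finite (geometric
# with parameter lambda/mu). Along a branch of length t the induced pairwise
# alignment follows a 3-state (match/delete/insert) HMM whose transition
# probabilities have closed forms in alpha = exp(-mu t), beta and gamma below.

#' TKF91 indel model
#'
#' @param lambda Insertion rate per link (> 0).
#' @param mu Deletion rate per mortal link; must exceed `lambda`.
#' @return An `indel_model` list.
#' @export
indel_model <- function(lambda, mu) {
  stopifnot(is.numeric(lambda), is.numeric(mu))
  if (!(lambda > 0 && mu > lambda)) stop("TKF91 requires 0 < lambda < mu")
  structure(list(lambda = lambda, mu = mu), class = "indel_model")
}

#' TKF91 pair-HMM for one branch
#'
#' Closed-form transition structure of the match/delete/insert pair-HMM
#' induced by TKF91 over a branch of length `t`. The transition matrix rows
#' are the probabilities of the next alignment column given the previous
#' state *when ancestral positions remain*; `end` gives the complementary
#' termination weights once the ancestor is exhausted (rows of `trans` sum to
#' 1, and `end` equals the joint M+D mass reassigned to termination).
#'
#' @param indel An [indel_model()].
#' @param t Branch length (>= 0, in expected substitutions/site; the indel
#'   rates are per the same time unit).
#' @return A `tkf_hmm` list: `alpha`, `beta`, `gamma`, `trans` (3 x 3,
#'   states M, D, I; start behaves like M), `end` (length 3), `lambda`,
#'   `mu`, `t`.
#' @export
tkf91_pair_hmm <- function(indel, t) {
  stopifnot(inherits(indel, "indel_model"))
  if (!is.finite(t) || t < 0) stop("branch length must be >= 0")
  lam <- indel$lambda; mu <- indel$mu
  if (t < 1e-12) {
    a <- 1; b <- 0; g <- 0
  } else {
    elm <- exp((lam - mu) * t)
    a <- exp(-mu * t)
    b <- lam * (1 - elm) / (mu - lam * elm)
    g <- 1 - mu * (1 - elm) / ((1 - exp(-mu * t)) * (mu - lam * elm))
    g <- max(0, min(1, g))
  }
  # rows: from M (and start), D, I; cols: to M, D, I (ancestor remaining)
  trans <- rbind(
    M = c((1 - b) * a, (1 - b) * (1 - a), b),
    D = c((1 - g) * a, (1 - g) * (1 - a), g),
    I = c((1 - b) * a, (1 - b) * (1 - a), b)
  )
  colnames(trans) <- c("M", "D", "I")
  end <- c(M = 1 - b, D = 1 - g, I = 1 - b)
  structure(list(alpha = a, beta = b, gamma = g, trans = trans, end = end,
                 lambda = lam, mu = mu, t = t),
            class = "tkf_hmm")
}

# Log transition matrix in the DP convention: rows/cols M, D, I. Entering M
# or D consumes an ancestral position, so those transitions carry the
# "ancestor remaining" structure; entering I does not. End weights apply at
# ancestor exhaustion.
tkf_log_trans <- function(hmm) {
  lt <- log(hmm$trans)
  lt[!is.finite(lt)] <- -Inf
  lt
}

#' Equilibrium TKF91 sequence-length distribution
#'
#' @param indel An [indel_model()].
#' @param n Vector of lengths.
#' @return P(length = n) = (1 - lambda/mu) (lambda/mu)^n.
#' @export
tkf91_length_pmf <- function(indel, n) {
  g <- indel$lambda / indel$mu
  (1 - g) * g^n
}

# Log equilibrium probability of a root sequence: geometric length plus
# stationary residues.
root_log_prior <- function(seq_int, indel, log_pi) {
  g <- indel$lambda / indel$mu
  log(1 - g) + length(seq_int) * log(g) + sum(log_pi[seq_int])
}

# Structure (indel) log-probability of an alignment path under a tkf_hmm.
# Path codes: 0 = M, 1 = D, 2 = I; the start behaves like M.
tkf_path_logprob <- function(path, hmm) {
  lt <- tkf_log_trans(hmm)
  lend <- log(hmm$end)
  if (length(path) == 0L) return(lend[["M"]])
  st <- path + 1L
  from <- c(1L, st[-length(st)])
  unname(sum(lt[cbind(from, st)]) + lend[st[length(st)]])
}

# Substitution/emission log-probability of the child residues along a path:
# matches from the (rate-mixed) transition matrix given the parent residue,
# inserts from the equilibrium frequencies.
emission_logprob <- function(path, x, y, log_pmix, log_pi) {
  if (length(path) == 0L) return(0)
  ii <- cumsum(path != 2L)   # parent index consumed at M/D
  jj <- cumsum(path != 1L)   # child index consumed at M/I
  mi <- path == 0L
  out <- 0
  if (any(mi)) out <- out + sum(log_pmix[cbind(x[ii[mi]], y[jj[mi]])])
  ins <- path == 2L
  if (any(ins)) out <- out + sum(log_pi[y[jj[ins]]])
  out
}

# Rate-mixed match transition matrix for a branch: mean over gamma categories
# of P(t * r_c). Each aligned pair marginalizes the rate mixture
# independently (see the methods vignette).
mixed_transition_matrix <- function(model, t, alpha = model$gamma_shape,
                                    rates = NULL) {
  if (is.null(rates)) {
    rates <- if (is.null(alpha)) 1
             else discrete_gamma_rates(alpha, model$n_categories)
  }
  P <- 0
  for (r in rates) P <- P + transition_probabilities(model, t, r)
  P / length(rates)
}

#' Exact alignment-marginalized pair log-likelihood under TKF91
#'
#' Log probability of observing two sequences joined by one branch,
#' marginalized over all pairwise alignments by the forward algorithm: the
#' first sequence is drawn from TKF91/substitution-model equilibrium, the
#' second from the TKF91 transducer with match emissions P(t) and insert
#' emissions pi. Serves as the exact two-taxon reference for the MCMC
#' sampler.
#'
#' @param s1,s2 Residue strings (may be empty).
#' @param model An [substitution_model()].
#' @param indel An [indel_model()].
#' @param t Branch length.
#' @return Log-likelihood (numeric).
#' @export
pair_marginal_loglik <- function(s1, s2, model, indel, t) {
  validate_residues(c(a = s1, b = s2))
  x <- seq_to_int(s1); y <- seq_to_int(s2)
  hmm <- tkf91_pair_hmm(indel, t)
  log_pi <- log(model$frequencies)
  pmix <- mixed_transition_matrix(model, t)
  eM <- matrix(1, length(x), length(y))
  if (length(x) && length(y)) eM <- pmix[x, y, drop = FALSE]
  logZ <- .pairhmm_logZ(eM, model$frequencies[y], hmm$trans, hmm$end)
  root_log_prior(x, indel, log_pi) + logZ
}

# Sample a descendant sequence plus alignment from the TKF91 transducer given
# an ancestor; returns path codes, child integer sequence, and the log
# probability of the draw (structure + emissions). Used as an MCMC proposal.
sample_transducer <- function(x, hmm, pmix, pi) {
  path <- integer(0)
  y <- integer(0)
  state <- 1L  # start behaves like M
  i <- 0L
  n <- length(x)
  repeat {
    p_ins <- if (state == 2L) hmm$gamma else hmm$beta
    if (stats::runif(1) < p_ins) {
      res <- sample.int(20L, 1L, prob = pi)
      y <- c(y, res)
      path <- c(path, 2L)
      state <- 3L
      next
    }
    if (i == n) break
    i <- i + 1L
    if (stats::runif(1) < hmm$alpha) {
      res <- sample.int(20L, 1L, prob = pmix[x[i], ])
      y <- c(y, res)
      path <- c(path, 0L)
      state <- 1L
    } else {
      path <- c(path, 1L)
      state <- 2L
    }
  }
  list(path = path, y = y)
}
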