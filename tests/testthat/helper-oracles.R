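# Independent oracles used across the suite. These deliberately avoid the
# package's own fast code paths: brute-force enumerations, quadrature,
# direct stochastic simulation.

lse2 <- function(a, b) {
  m <- max(a, b)
  if (!is.finite(m)) return(m)
  m + log(exp(a - m) + exp(b - m))
}

# Exhaustive-likelihood oracle: sums over all internal-node state
# assignments, per site, for an arbitrary (small) rooted tree.
enum_loglik <- function(aln, tree, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  aln <- unclass(aln)[tree$tip.label]
  data <- matrix(unlist(lapply(aln,
                               ucatestbed:::seq_to_int)),
                 nrow = length(aln), byrow = TRUE,
                 dimnames = list(tree$tip.label, NULL))
  rates <- if (is.null(model$gamma_shape)) 1 else
    discrete_gamma_rates(model$gamma_shape, model$n_categories)
  edge <- tree$edge
  n_tip <- length(tree$tip.label)
  internals <- setdiff(unique(c(edge)), seq_len(n_tip))
  root <- n_tip + 1L
  pi <- model$frequencies
  total <- 0
  for (s in seq_len(ncol(data))) {
    site_lik <- 0
    for (r in rates) {
      Ps <- lapply(seq_len(nrow(edge)), function(e)
        transition_probabilities(model, tree$edge.length[e], r))
      lik_r <- 0
      grid <- as.matrix(expand.grid(rep(list(1:20), length(internals))))
      for (g in seq_len(nrow(grid))) {
        states <- integer(max(edge))
        states[seq_len(n_tip)] <- data[, s]
        states[internals] <- grid[g, ]
        p <- pi[states[root]]
        ok <- TRUE
        for (e in seq_len(nrow(edge))) {
          a <- states[edge[e, 1]]; b <- states[edge[e, 2]]
          if (is.na(b)) next  # gap: marginalizes out (skip tip factor)
          p <- p * Ps[[e]][a, b]
        }
        lik_r <- lik_r + p
      }
      site_lik <- site_lik + lik_r / length(rates)
    }
    total <- total + log(site_lik)
  }
  total
}

# Brute-force global affine alignment score by enumerating all monotone
# alignments (as pair-HMM style paths) of two short sequences.
enum_align_score <- function(s1, s2, S, gap_open, gap_extend) {
  x <- ucatestbed:::seq_to_int(s1)
  y <- ucatestbed:::seq_to_int(s2)
  n <- length(x); m <- length(y)
  best <- -Inf
  rec <- function(i, j, prev, acc) {
    if (i == n && j == m) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1, j + 1, 0L, acc + S[x[i + 1], y[j + 1]])
    if (i < n) rec(i + 1, j, 1L,
                   acc + if (prev == 1L) gap_extend else gap_open)
    if (j < m) rec(i, j + 1, 2L,
                   acc + if (prev == 2L) gap_extend else gap_open)
  }
  rec(0L, 0L, -1L, 0)
  best
}

# Exhaustive TKF91 pair enumeration: joint log-probability of two sequences
# summed over all alignments, and per-homology-set posterior probabilities.
enum_tkf_pair <- function(s1, s2, model, indel, t) {
  x <- ucatestbed:::seq_to_int(s1)
  y <- ucatestbed:::seq_to_int(s2)
  hmm <- tkf91_pair_hmm(indel, t)
  lp <- log(ucatestbed:::mixed_transition_matrix(model, t))
  lpi <- log(model$frequencies)
  n <- length(x); m <- length(y)
  keys <- character(0); logps <- numeric(0); total <- -Inf
  rec <- function(i, j, path) {
    if (i == n && j == m) {
      lpp <- ucatestbed:::tkf_path_logprob(path, hmm) +
        ucatestbed:::emission_logprob(path, x, y, lp, lpi)
      ri <- cumsum(path != 2L); ci <- cumsum(path != 1L); mm <- path == 0L
      key <- paste(sprintf("%d-%d", ri[mm], ci[mm]), collapse = ",")
      if (!nzchar(key)) key <- "(none)"
      k <- match(key, keys)
      if (is.na(k)) {
        keys <<- c(keys, key); logps <<- c(logps, lpp)
      } else {
        logps[k] <<- lse2(logps[k], lpp)
      }
      total <<- lse2(total, lpp)
    }
    if (i < n && j < m) rec(i + 1, j + 1, c(path, 0L))
    if (i < n) rec(i + 1, j, c(path, 1L))
    if (j < m) rec(i, j + 1, c(path, 2L))
  }
  rec(0L, 0L, integer(0))
  list(logZ = total,
       log_joint = total + ucatestbed:::root_log_prior(x, indel, lpi),
       posterior = stats::setNames(exp(logps - total), keys))
}

# Gillespie simulation of the TKF91 birth-death length process (immortal
# link + n mortal links: birth rate (n+1)*lambda, death rate n*mu).
gillespie_tkf_lengths <- function(lambda, mu, n0, t_total, n_samples,
                                  sample_every) {
  lens <- integer(n_samples)
  n <- n0
  t <- 0
  k <- 0L
  next_sample <- sample_every
  while (k < n_samples) {
    rate <- (n + 1) * lambda + n * mu
    t <- t + stats::rexp(1, rate)
    while (t >= next_sample && k < n_samples) {
      k <- k + 1L
      lens[k] <- n
      next_sample <- next_sample + sample_every
    }
    n <- if (stats::runif(1) < (n + 1) * lambda / rate) n + 1L else n - 1L
  }
  lens
}

# Induced leaf-leaf homology set for a two-leaf coestimation state.
compose_pair_homology <- function(state_snapshot, final_state, tips) {
  st <- final_state
  eA <- st$edge_of[which(st$tree$tip.label == tips[1])]
  eB <- st$edge_of[which(st$tree$tip.label == tips[2])]
  map_of <- function(path) {
    ri <- cumsum(path != 2L); ci <- cumsum(path != 1L)
    out <- rep(NA_integer_, if (length(ri)) max(ri) else 0)
    mm <- path == 0L
    out[ri[mm]] <- ci[mm]
    out
  }
  mA <- map_of(state_snapshot$paths[[eA]])
  mB <- map_of(state_snapshot$paths[[eB]])
  n <- min(length(mA), length(mB))
  ok <- which(!is.na(mA[seq_len(n)]) & !is.na(mB[seq_len(n)]))
  if (!length(ok)) return("(none)")
  paste(sprintf("%d-%d", mA[ok], mB[ok]), collapse = ",")
}

# Small fixed quartets shared across tests.
quartet_E <- function() parse_newick(
  "((E1:0.4,E2:0.4):0.2,(E3:0.4,E4:0.4):0.2);")
quartet_B <- function() parse_newick(
  "((B1:0.4,B2:0.4):0.2,(B3:0.4,B4:0.4):0.2);")
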