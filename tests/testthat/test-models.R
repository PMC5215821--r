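test_that("rate matrix construction satisfies its defining identities", {
  # 2-state toy: pi = (0.3, 0.7), s = 1 -> Q = c * [[-0.7, 0.7], [0.3, -0.3]]
  # with c = 1 / (2 * 0.3 * 0.7) from the unit-rate normalization
  toy <- list(exchangeabilities = matrix(c(0, 1, 1, 0), 2),
              frequencies = c(0.3, 0.7))
  Q <- build_rate_matrix(toy)
  c0 <- 1 / (2 * 0.3 * 0.7)
  expect_equal(Q, c0 * matrix(c(-0.7, 0.3, 0.7, -0.3), 2), tolerance = 1e-12)

  # uniform exchangeabilities and frequencies: all off-diagonals equal
  uni <- list(exchangeabilities = matrix(1, 20, 20) - diag(20),
              frequencies = rep(1 / 20, 20))
  Qu <- build_rate_matrix(uni)
  offs <- Qu[row(Qu) != col(Qu)]
  expect_lt(diff(range(offs)), 1e-14)
  expect_equal(-sum(uni$frequencies * diag(Qu)), 1)

  for (nm in c("rtREV", "LG")) {
    m <- substitution_model(nm)
    expect_equal(max(abs(rowSums(m$Q))), 0, tolerance = 1e-12)
    expect_equal(-sum(m$frequencies * diag(m$Q)), 1, tolerance = 1e-12)
    # detailed balance pi_i Q_ij = pi_j Q_ji
    flux <- m$frequencies * m$Q
    expect_lt(max(abs(flux - t(flux))), 1e-14)
    expect_equal(sum(m$frequencies), 1, tolerance = 1e-12)
    expect_true(all(m$frequencies >= 0))
    expect_lt(max(abs(m$exchangeabilities - t(m$exchangeabilities))), 1e-12)
  }

  expect_error(substitution_model("custom",
                                  exchangeabilities = matrix(1, 2, 2) - diag(2),
                                  frequencies = c(0.6, 0.6)),
               "sum to 1")
  bad <- matrix(-1, 2, 2) - diag(2)
  expect_error(substitution_model("custom", exchangeabilities = bad,
                                  frequencies = c(0.5, 0.5)),
               "non-negative")
})

test_that("discrete-gamma rates match a quadrature oracle and limits", {
  expect_equal(discrete_gamma_rates(1e6, 4), rep(1, 4), tolerance = 1e-2)
  expect_identical(discrete_gamma_rates(2, 1), 1)

  # mean of each inter-quantile slice of Gamma(alpha, alpha) by quadrature
  alpha <- 0.5
  q <- qgamma(seq(0, 1, 0.25), shape = alpha, rate = alpha)
  oracle <- vapply(1:4, function(i) {
    4 * integrate(function(x) x * dgamma(x, alpha, rate = alpha),
                  q[i], q[i + 1], rel.tol = 1e-10)$value
  }, numeric(1))
  expect_equal(discrete_gamma_rates(alpha, 4), oracle / mean(oracle),
               tolerance = 1e-6)

  # weakly increasing with category index, mean exactly 1
  for (a in c(0.2, 0.8, 3)) {
    r <- discrete_gamma_rates(a, 6)
    expect_true(all(diff(r) >= 0))
    expect_equal(mean(r), 1)
  }
  expect_error(discrete_gamma_rates(0, 4), "positive")
  expect_error(discrete_gamma_rates(-1, 4), "positive")
})

test_that("transition probabilities behave like a reversible CTMC", {
  m <- substitution_model("rtREV", gamma_shape = 0.7)
  expect_equal(transition_probabilities(m, 0), diag(20),
               tolerance = 1e-12, ignore_attr = TRUE)
  # stationarity at large t
  P <- transition_probabilities(m, 500)
  expect_lt(max(abs(P - rep(m$frequencies, each = 20))), 1e-6)
  # Taylor expansion at small t
  t0 <- 1e-4
  expect_lt(max(abs(transition_probabilities(m, t0) - (diag(20) + m$Q * t0))),
            1e-7)
  # rows sum to 1, entries non-negative
  for (t in c(0.01, 0.5, 3)) {
    P <- transition_probabilities(m, t)
    expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(all(P >= 0))
  }
  # detailed balance of P(t) and Chapman-Kolmogorov
  for (t in c(0.1, 1, 10)) {
    P <- transition_probabilities(m, t)
    expect_lt(max(abs(m$frequencies * P - t(m$frequencies * P))), 1e-12)
  }
  expect_lt(max(abs(transition_probabilities(m, 0.4) %*%
                      transition_probabilities(m, 1.1) -
                      transition_probabilities(m, 1.5))), 1e-8)
  expect_error(transition_probabilities(m, -0.1), ">= 0")
})

test_that("PAML-style .dat files round-trip into models", {
  m <- substitution_model("rtREV")
  S <- m$exchangeabilities
  lines <- character(0)
  for (i in 2:20) lines <- c(lines, paste(S[i, 1:(i - 1)], collapse = " "))
  lines <- c(lines, "", paste(m$frequencies, collapse = " "))
  f <- tempfile(fileext = ".dat")
  writeLines(lines, f)
  parsed <- read_paml_dat(f)
  m2 <- substitution_model("custom",
                           exchangeabilities = parsed$exchangeabilities,
                           frequencies = parsed$frequencies)
  expect_equal(m2$Q, m$Q, tolerance = 1e-12)
})

test_that("empirical frequencies reflect residue counts, gaps excluded", {
  f <- empirical_frequencies(c(a = "AAR-", b = "AR--"))
  expect_equal(sum(f), 1)
  expect_equal(f[1], 3 / 5)   # A
  expect_equal(f[2], 2 / 5)   # R
  expect_equal(sum(f[3:20]), 0)
})
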