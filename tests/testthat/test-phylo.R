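test_that("Newick parsing and writing round-trip trees exactly", {
  tr <- parse_newick("((A:0.1,B:0.2):0.05,C:0.3);")
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(nrow(tr$edge), 4L)  # 3 terminal + 1 internal branch
  expect_equal(sort(tr$edge.length), c(0.05, 0.1, 0.2, 0.3))

  set.seed(99)
  for (i in 1:100) {
    tr <- ape::rtree(8)
    back <- parse_newick(write_newick(tr))
    expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE,
                                     tolerance = 1e-9))
  }

  expect_error(parse_newick("(A:0.1,A:0.2);"), "duplicate")
  expect_error(parse_newick("((A:0.1,B:0.2);"), "parenthes")
})

test_that("pruning log-likelihood equals exhaustive state enumeration", {
  set.seed(4)
  cases <- list(
    list(tree = "(A:0.2,B:0.5);", aln = c(A = "ARN", B = "AQ-")),
    list(tree = "((A:0.1,B:0.3):0.2,C:0.4);", aln = c(A = "AR", B = "AN", C = "RC")),
    list(tree = "((A:0.15,B:0.25):0.1,(C:0.3,D:0.45):0.2);",
         aln = c(A = "KWS", B = "K-S", C = "RWS", D = "KW-"))
  )
  models <- list(substitution_model("LG"),
                 substitution_model("rtREV", gamma_shape = 0.6,
                                    n_categories = 3))
  for (cs in cases) {
    tr <- parse_newick(cs$tree)
    for (m in models) {
      got <- log_likelihood(cs$aln, tr, m)
      expect_equal(got$log_likelihood, enum_loglik(cs$aln, tr, m),
                   tolerance = 1e-10)
      expect_equal(got$log_likelihood, sum(got$per_site_log_likelihoods),
                   tolerance = 1e-8)
      expect_lt(got$log_likelihood, 0)
    }
  }
})

test_that("pruning agrees with an independent implementation on larger data", {
  m <- substitution_model("LG")
  qt <- quartet_E()
  set.seed(7)
  seqs <- evolve_sequences(qt, m, 300)
  ours <- log_likelihood(seqs, qt, m)$log_likelihood
  pd <- phangorn::phyDat(t(vapply(seqs, function(s) strsplit(s, "")[[1]],
                                  character(300))), type = "AA")
  theirs <- phangorn::pml(qt, pd, model = "LG")$logLik
  expect_equal(ours, theirs, tolerance = 1e-8)
})

test_that("gaps marginalize: all-gap column contributes exactly zero", {
  m <- substitution_model("LG", gamma_shape = 0.9)
  tr <- parse_newick("((A:0.1,B:0.3):0.2,C:0.4);")
  base <- log_likelihood(c(A = "AR", B = "AN", C = "RC"), tr, m)
  gapped <- log_likelihood(c(A = "AR-", B = "AN-", C = "RC-"), tr, m)
  expect_equal(gapped$per_site_log_likelihoods[3], 0, tolerance = 1e-12)
  expect_equal(gapped$log_likelihood, base$log_likelihood)
})

test_that("single-leaf likelihood is the stationary log-probability", {
  m <- substitution_model("rtREV")
  tr <- parse_newick("(A:0.7);")
  s <- c(A = "ARNDC")
  got <- log_likelihood(s, tr, m)
  expect_equal(got$log_likelihood,
               sum(log(m$frequencies[ucatestbed:::seq_to_int(s)])),
               tolerance = 1e-12)
})

test_that("likelihood is invariant to root placement (pulley principle)", {
  m <- substitution_model("LG", gamma_shape = 0.8)
  tr <- parse_newick(
    "((A:0.2,B:0.3):0.1,(C:0.25,D:0.15):0.2,E:0.4);")
  set.seed(10)
  seqs <- evolve_sequences(tr, m, 50)
  ref <- log_likelihood(seqs, tr, m)$log_likelihood
  un <- ape::unroot(tr)
  for (og in un$tip.label) {
    rerooted <- ape::root(un, outgroup = og, resolve.root = TRUE)
    expect_equal(log_likelihood(seqs, rerooted, m)$log_likelihood, ref,
                 tolerance = 1e-8)
  }
})

test_that("errors: label mismatch and zero-length alignments are rejected", {
  m <- substitution_model("LG")
  tr <- parse_newick("(A:0.1,B:0.1);")
  expect_error(log_likelihood(c(A = "AR", X = "AR"), tr, m), "differ")
  expect_error(log_likelihood(c(A = "", B = ""), tr, m), "zero-length")
})

test_that("ML fitting: boundary, grid oracle, and monotone ascent", {
  m <- substitution_model("LG")
  # identical sequences -> ML total path length at the zero boundary
  tr <- parse_newick("(A:0.3,B:0.3);")
  s <- c(A = "ARNDCQEGHILKMFPSTWYV", B = "ARNDCQEGHILKMFPSTWYV")
  fit <- fit_ml(s, tr, m, optimize = "branch_lengths")
  expect_lt(sum(fit$fitted_branch_lengths), 1e-5)

  # two-sequence ML distance vs a 1-D grid + golden-section oracle
  m2 <- substitution_model("rtREV", gamma_shape = 0.8)
  set.seed(5)
  tr2 <- parse_newick("(A:0.25,B:0.25);")
  seqs <- evolve_sequences(tr2, m2, 10000)
  fit2 <- fit_ml(seqs, tr2, m2, optimize = "branch_lengths")
  ml_hat <- sum(fit2$fitted_branch_lengths)
  f <- function(d) log_likelihood(seqs, parse_newick(
    sprintf("(A:%.10f,B:%.10f);", d / 2, d / 2)), m2)$log_likelihood
  grid <- seq(0.2, 1.0, by = 0.02)
  vals <- vapply(grid, f, numeric(1))
  i0 <- which.max(vals)
  oracle <- optimize(f, interval = grid[c(i0 - 1, i0 + 1)],
                     maximum = TRUE, tol = 1e-8)$maximum
  expect_equal(ml_hat, oracle, tolerance = 1e-4)
  # never decreases the starting log-likelihood
  expect_gte(fit2$log_likelihood, f(0.5) - 1e-9)
})

test_that("gamma shape is recovered from long simulated alignments", {
  m <- substitution_model("rtREV", gamma_shape = 0.8)
  qt <- quartet_E()
  set.seed(6)
  seqs <- evolve_sequences(qt, m, 6591)
  fit <- fit_ml(seqs, qt, m)
  expect_lt(abs(fit$fitted_alpha - 0.8), 0.15)
  expect_true(fit$converged)
})

test_that("independent origins equal the infinite-branch limit", {
  m <- substitution_model("rtREV")   # homogeneous rates: exact factorization
  qa <- quartet_E(); qb <- quartet_B()
  set.seed(3)
  seqs <- c(evolve_sequences(qa, m, 100), evolve_sequences(qb, m, 100))
  gaps <- vapply(c(1, 5, 20, 50), function(t)
    io_limit_gap(seqs, qa, qb, t, m), numeric(1))
  expect_lt(gaps[4], 1e-6)
  expect_true(all(diff(gaps) < 0))

  # per-column factorization at large t (t = 100: per-column residuals
  # scale as exp(lambda2 * t) and need the longer branch to clear 1e-8)
  joint <- ucatestbed:::join_trees(qa, qb, 100)
  ps_joint <- log_likelihood(seqs, joint, m)$per_site_log_likelihoods
  ps_a <- log_likelihood(seqs[qa$tip.label], qa, m)$per_site_log_likelihoods
  ps_b <- log_likelihood(seqs[qb$tip.label], qb, m)$per_site_log_likelihoods
  expect_lt(max(abs(ps_joint - (ps_a + ps_b))), 1e-8)

  expect_error(io_limit_gap(seqs, qa, qa, 1, m), "overlap")
})
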