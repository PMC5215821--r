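test_that("TKF91 pair-HMM closed forms normalize and hit their limits", {
  im <- indel_model(0.03, 0.04)
  h <- tkf91_pair_hmm(im, 0.5)
  expect_equal(rowSums(h$trans), rep(1, 3), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_true(all(h$trans >= 0))
  # termination weights complement the insert mass
  expect_equal(unname(h$end), 1 - unname(h$trans[, "I"]), tolerance = 1e-12)

  # t = 0: match-dominated limit
  h0 <- tkf91_pair_hmm(im, 0)
  expect_equal(h0$alpha, 1)
  expect_equal(h0$beta, 0)
  expect_equal(h0$gamma, 0)
  # numerically tiny t agrees with the limit
  ht <- tkf91_pair_hmm(im, 1e-9)
  expect_lt(abs(ht$beta), 1e-7)

  expect_error(indel_model(0.05, 0.04), "lambda < mu")
  expect_error(indel_model(0.04, 0.04), "lambda < mu")
  expect_error(tkf91_pair_hmm(im, -1), ">= 0")
})

test_that("equilibrium length distribution is geometric (simulation oracle)", {
  lambda <- 0.6; mu <- 1.0
  set.seed(20)
  lens <- gillespie_tkf_lengths(lambda, mu, n0 = 2L, t_total = NULL,
                                n_samples = 4000, sample_every = 5)
  # compare observed length frequencies with the geometric pmf
  for (n in 0:4) {
    p <- tkf91_length_pmf(indel_model(lambda, mu), n)
    obs <- mean(lens == n)
    expect_lt(abs(obs - p), 4 * sqrt(p * (1 - p) / length(lens)) + 0.01)
  }
  expect_equal(sum(tkf91_length_pmf(indel_model(lambda, mu), 0:2000)), 1,
               tolerance = 1e-6)
})

test_that("pair marginal likelihood equals exhaustive alignment enumeration", {
  m <- substitution_model("LG")
  mg <- substitution_model("LG", gamma_shape = 0.8)
  im <- indel_model(0.03, 0.05)
  cases <- list(c("AR", "A"), c("C", "CW"), c("", "R"), c("ARN", "AWN"),
                c("KWS", "K"))
  for (model in list(m, mg)) {
    for (cs in cases) {
      ex <- enum_tkf_pair(cs[1], cs[2], model, im, 0.6)
      got <- pair_marginal_loglik(cs[1], cs[2], model, im, 0.6)
      expect_equal(got, ex$log_joint, tolerance = 1e-10,
                   info = paste(cs, collapse = "/"))
    }
  }
  # two empty sequences: equilibrium empty root, no-insert transducer
  h <- tkf91_pair_hmm(im, 0.6)
  expect_equal(pair_marginal_loglik("", "", m, im, 0.6),
               log(1 - im$lambda / im$mu) + log(1 - h$beta),
               tolerance = 1e-12)
  # marginal (log-sum over alignments) exceeds the single best alignment
  ex <- enum_tkf_pair("ARN", "AWN", m, im, 0.6)
  best_single <- ex$log_joint + log(max(ex$posterior))
  expect_gt(pair_marginal_loglik("ARN", "AWN", m, im, 0.6), best_single)
})

test_that("sampler alignment posterior matches exact enumeration on toys", {
  m <- substitution_model("LG")
  tr <- parse_newick("(A:0.3,B:0.4);")
  seqs <- c(A = "AR", B = "AN")
  run <- run_mcmc(seqs, tr, m, n_iter = 3000, seed = 42, lambda0 = 0.05,
                  rho0 = 0.6, sample_branch_lengths = FALSE,
                  sample_alpha = FALSE, sample_indel = FALSE,
                  keep_states = TRUE)
  keep <- run$states[1001:3000]
  sets <- vapply(keep, compose_pair_homology, "",
                 final_state = run$final_state, tips = c("A", "B"))
  # exact posterior of leaf-leaf homology at the summed branch length
  # (TKF91 transducers compose along the path through the root)
  ex <- enum_tkf_pair("AR", "AN", m, indel_model(0.05, 0.05 / 0.6),
                      0.7)$posterior
  for (key in names(ex)[ex > 0.02]) {
    obs <- mean(sets == key)
    se <- sqrt(ex[[key]] * (1 - ex[[key]]) / length(sets))
    expect_lt(abs(obs - ex[[key]]), 3 * se + 0.01)
  }
})

test_that("MCMC is deterministic under a fixed seed and validates config", {
  m <- substitution_model("LG", gamma_shape = 0.8)
  tr <- parse_newick("(A:0.2,B:0.3);")
  set.seed(30)
  seqs <- evolve_sequences(tr, m, 40)
  r1 <- run_mcmc(seqs, tr, m, n_iter = 150, seed = 9)
  r2 <- run_mcmc(seqs, tr, m, n_iter = 150, seed = 9)
  expect_identical(r1$trace, r2$trace)
  r3 <- run_mcmc(seqs, tr, m, n_iter = 150, seed = 10)
  expect_false(identical(r3$trace$log_likelihood, r1$trace$log_likelihood))

  expect_error(run_mcmc(seqs, tr, m, n_iter = 0, seed = 1), "n_iter")
  expect_error(run_mcmc(seqs, tr, m, n_iter = 10, seed = 1, rho0 = 0.1),
               "prior support")
  m_bad <- m; m_bad$gamma_shape <- -1
  expect_error(run_mcmc(seqs, tr, m_bad, n_iter = 10, seed = 1),
               "alpha")
})

test_that("a proposal with unchanged posterior density is always accepted", {
  m <- substitution_model("LG", gamma_shape = 0.8)
  tr <- parse_newick("(A:0.2,B:0.3);")
  set.seed(31)
  seqs <- evolve_sequences(tr, m, 30)
  st <- ucatestbed:::new_mcmc_state(seqs, tr, m, 0.02, 0.7, 0.8,
                                    ucatestbed:::mcmc_priors_default())
  st$accept_global <- 0L
  for (i in 1:25) {
    st <- ucatestbed:::global_move(st, function(s) s)  # identity proposal
  }
  expect_equal(st$accept_global, 25L)
})

test_that("branch-length posterior concentrates near truth (fixed alignment)", {
  m <- substitution_model("LG", gamma_shape = 0.8)
  tr <- parse_newick("(A:0.25,B:0.25);")
  set.seed(11)
  seqs <- evolve_sequences(tr, m, 2000)
  run <- run_mcmc(seqs, tr, m, n_iter = 1200, seed = 7,
                  sample_alignment = FALSE)
  post <- run$trace$tree_length[301:1200]
  expect_lt(abs(median(post) - 0.5) / 0.5, 0.15)
})

test_that("harmonic-mean estimator: closed forms, bound, and guards", {
  expect_equal(as.numeric(harmonic_mean_logml(rep(-100, 50), burn_in = 0)),
               -100)
  # two samples {-10, -20}: -log((e^10 + e^20) / 2)
  expect_equal(as.numeric(harmonic_mean_logml(c(-10, -20), burn_in = 0)),
               -(log(exp(10) + exp(20)) - log(2)), tolerance = 1e-10)
  set.seed(40)
  ll <- rnorm(200, -500, 5)
  h <- harmonic_mean_logml(ll, burn_in = 0.25)
  expect_lte(as.numeric(h), max(ll[51:200]))
  expect_true(is.finite(attr(h, "ess")))
  expect_error(harmonic_mean_logml(numeric(0)), "post-burn-in")
})

test_that("the Bayes-factor decision uses the ten-unit band exactly", {
  eps <- 1e-9
  expect_identical(ucatestbed:::bf_decision(10 + eps), "UCA")
  expect_identical(ucatestbed:::bf_decision(10 - eps), "inconclusive")
  expect_identical(ucatestbed:::bf_decision(-10 + eps), "inconclusive")
  expect_identical(ucatestbed:::bf_decision(-10 - eps), "IO")
  expect_identical(ucatestbed:::bf_decision(0), "inconclusive")
})

test_that("low-divergence common-ancestry data yield a strong UCA verdict", {
  m <- substitution_model("LG", gamma_shape = 0.8)
  qa <- parse_newick("((E1:0.1,E2:0.1):0.05,(E3:0.1,E4:0.1):0.05);")
  qb <- parse_newick("((B1:0.1,B2:0.1):0.05,(B3:0.1,B4:0.1):0.05);")
  truth <- join_trees(qa, qb, 0.05)
  topo <- list(E = qa, B = qb, joint = join_trees(qa, qb, 0.3))
  set.seed(601)
  seqs <- evolve_sequences(truth, m, 60)
  bf <- run_delta_bf_test(seqs, list(E = qa$tip.label, B = qb$tip.label),
                          topo, m, n_iter = 800, seed = 81)
  expect_gt(bf$delta_bf, 10)
  expect_identical(bf$decision, "UCA")
  expect_equal(bf$delta_bf,
               bf$logml[["joint"]] - bf$logml[["E"]] - bf$logml[["B"]])
  expect_equal(bf$delta_bf_per_site,
               bf$delta_bf / bf$posterior_median_alignment_length)
})

test_that("delta-BF test validates its groups and topologies", {
  m <- substitution_model("LG", gamma_shape = 0.8)
  qa <- quartet_E(); qb <- quartet_B()
  set.seed(33)
  seqs <- c(evolve_sequences(qa, m, 30), evolve_sequences(qb, m, 30))
  topo <- list(E = qa, B = qb,
               joint = ucatestbed:::join_trees(qa, qb, 1))
  expect_error(run_delta_bf_test(seqs, list(E = qa$tip.label, B = character(0)),
                                 topo, m, n_iter = 10),
               "empty group")
  expect_error(run_delta_bf_test(seqs, list(E = qa$tip.label), topo, m,
                                 n_iter = 10),
               "partition")
  expect_error(run_delta_bf_test(seqs,
                                 list(E = qa$tip.label, B = qb$tip.label),
                                 topo[c("E", "joint")], m, n_iter = 10),
               "topologies")
})
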