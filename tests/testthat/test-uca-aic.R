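make_io_replicate <- function(n_sites = 300, seed = 1) {
  cfg <- scenario_preset("fig2-scaled", seed = seed, n_replicates = 1,
                         n_sites = n_sites)
  list(rep = generate_scenario(cfg)[[1]], cfg = cfg)
}

test_that("split_alignment partitions rows and keeps every column", {
  aln <- identity_alignment(c(E1 = "ARND", E2 = "ARNC", B1 = "WYVA",
                              B2 = "WYVC"))
  subs <- split_alignment(aln, list(E = c("E1", "E2"), B = c("B1", "B2")))
  expect_equal(names(subs), c("E", "B"))
  expect_equal(nchar(subs$E[[1]]), 4L)
  expect_equal(nchar(subs$B[[1]]), 4L)
  # identity partition
  all_rows <- split_alignment(aln, list(all = names(aln)))
  expect_identical(as.character(all_rows$all), as.character(aln))
  expect_error(split_alignment(aln, list(E = c("E1", "E2"), B = "B1")),
               "partition")
  expect_error(split_alignment(aln, list(E = names(aln), B = "B1")),
               "partition")
})

test_that("columns gapped across a whole group stay and contribute zero", {
  m <- substitution_model("LG", gamma_shape = 0.7)
  # column 3 is all-gap in the E rows, informative in B rows
  aln <- c(E1 = "AR-D", E2 = "AN-C", B1 = "WYVA", B2 = "WYCC")
  subs <- split_alignment(identity_alignment(aln),
                          list(E = c("E1", "E2"), B = c("B1", "B2")))
  expect_equal(nchar(subs$E[[1]]), 4L)
  tr <- parse_newick("(E1:0.2,E2:0.2);")
  with_gap <- log_likelihood(unclass(subs$E)[1:2], tr, m)
  dropped <- log_likelihood(c(E1 = "ARD", E2 = "ANC"), tr, m)
  expect_equal(with_gap$log_likelihood, dropped$log_likelihood,
               tolerance = 1e-12)
  expect_equal(with_gap$per_site_log_likelihoods[3], 0, tolerance = 1e-12)
})

test_that("degenerate partition: single group equals the joint hypothesis", {
  x <- make_io_replicate(150, seed = 2)
  seqs <- x$rep$groups$E
  topo <- x$cfg$trees$E
  res <- run_uca_aic_test(seqs, list(all = names(seqs)),
                          x$cfg$model, mode = "unaligned",
                          topologies = list(all = topo, joint = topo))
  expect_equal(res$delta_aic, 0, tolerance = 1e-6)
})

test_that("delta AIC is invariant to row relabeling and group order", {
  x <- make_io_replicate(200, seed = 3)
  cfg <- x$cfg
  groups <- lapply(cfg$trees, function(t) t$tip.label)
  topo <- c(cfg$trees, list(joint = ucatestbed:::join_trees(cfg$trees$E,
                                                            cfg$trees$B, 1)))
  seqs <- x$rep$combined
  r1 <- run_uca_aic_test(seqs, groups, cfg$model, mode = "unaligned",
                         topologies = topo)
  r2 <- run_uca_aic_test(rev(seqs), rev(groups), cfg$model,
                         mode = "unaligned", topologies = topo)
  expect_equal(r2$delta_aic, r1$delta_aic, tolerance = 1e-6)
})

test_that("alignment step flips the verdict on independent-origins data", {
  x <- make_io_replicate(400, seed = 4)
  cfg <- x$cfg
  groups <- lapply(cfg$trees, function(t) t$tip.label)
  topo <- c(cfg$trees, list(joint = ucatestbed:::join_trees(cfg$trees$E,
                                                            cfg$trees$B, 1)))
  un <- run_uca_aic_test(x$rep$combined, groups, cfg$model,
                         mode = "unaligned", topologies = topo)
  al <- run_uca_aic_test(x$rep$combined, groups, cfg$model,
                         mode = "aligned", topologies = topo)
  expect_lt(un$delta_aic, 0)
  expect_identical(un$decision, "IO")
  expect_gt(al$delta_aic, 0)
  expect_identical(al$decision, "UCA")
  expect_gte(al$delta_aic, un$delta_aic)

  # internal consistency of the reported table
  for (r in list(un, al)) {
    expect_equal(r$hypotheses$AIC, 2 * r$hypotheses$K - 2 * r$hypotheses$logL)
    io <- r$hypotheses[r$hypotheses$label != "joint", ]
    joint <- r$hypotheses[r$hypotheses$label == "joint", ]
    expect_equal(r$delta_aic, sum(io$AIC) - joint$AIC)
    expect_equal(delta_aic_per_site(r), r$delta_aic / r$n_columns)
  }
  # parameter counts: quartet 2n-3 branches + alpha + 19 (+F per tree)
  expect_equal(un$hypotheses$K, c(25, 25, 33))

  # information-criterion variants agree in sign
  for (crit in c("AICc", "BIC")) {
    un2 <- run_uca_aic_test(x$rep$combined, groups, cfg$model,
                            mode = "unaligned", topologies = topo,
                            criterion = crit)
    al2 <- run_uca_aic_test(x$rep$combined, groups, cfg$model,
                            mode = "aligned", topologies = topo,
                            criterion = crit)
    expect_lt(un2$delta_aic, 0)
    expect_gt(al2$delta_aic, 0)
  }
})

test_that("NJ topology mode and parameter-count toggles work", {
  x <- make_io_replicate(200, seed = 6)
  cfg <- x$cfg
  groups <- lapply(cfg$trees, function(t) t$tip.label)
  res <- run_uca_aic_test(x$rep$combined, groups, cfg$model,
                          mode = "unaligned", topologies = NULL)
  expect_s3_class(res, "uca_aic_result")
  expect_true(res$decision %in% c("UCA", "IO"))

  shared <- run_uca_aic_test(x$rep$combined, groups, cfg$model,
                             mode = "unaligned", topologies = NULL,
                             shared_frequencies = TRUE)
  # shared counting removes 19 parameters from the IO side net of the joint
  expect_equal(shared$delta_aic, res$delta_aic - 2 * 19, tolerance = 1e-6)
})
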