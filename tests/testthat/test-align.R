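test_that("pairwise affine alignment matches the exhaustive oracle", {
  S <- aa_score_matrix()
  # all pairs of short sequences over a reduced 3-letter alphabet
  letters3 <- c("A", "R", "N")
  set.seed(11)
  pool <- unique(vapply(1:40, function(i) {
    paste(sample(letters3, sample(1:4, 1), replace = TRUE), collapse = "")
  }, character(1)))
  for (s1 in pool[1:8]) for (s2 in pool[9:16]) {
    got <- pairwise_align(s1, s2, S, gap_open = -11, gap_extend = -1)
    expect_equal(got$score, enum_align_score(s1, s2, S, -11, -1),
                 info = paste(s1, s2))
    # de-gapping reproduces the inputs
    rows <- as.character(got$alignment)
    expect_identical(gsub("-", "", rows[1], fixed = TRUE), s1)
    expect_identical(gsub("-", "", rows[2], fixed = TRUE), s2)
  }
})

test_that("pairwise alignment boundary and error cases", {
  S <- aa_score_matrix()
  # identical sequences: gap-free, score = sum of diagonal scores
  s <- "ARNDW"
  got <- pairwise_align(s, s, S)
  expect_false(any(grepl("-", as.character(got$alignment), fixed = TRUE)))
  expect_equal(got$score,
               sum(diag(S)[ucatestbed:::seq_to_int(s)]))
  # empty vs length-n: n gap columns, affine run score
  n <- 6
  got2 <- pairwise_align("", strrep("A", n), S, gap_open = -11,
                         gap_extend = -1)
  expect_equal(nchar(as.character(got2$alignment)[1]), n)
  expect_equal(got2$score, -11 + (n - 1) * -1)
  expect_error(pairwise_align("AZX1", "AR", S), "unknown residue")
})

test_that("progressive MSA: de-gap invariant, column order, determinism", {
  m <- substitution_model("rtREV", gamma_shape = 0.8)
  cfg <- scenario_preset("fig2-scaled", seed = 3, n_replicates = 1,
                         n_sites = 400)
  rep1 <- generate_scenario(cfg)[[1]]
  aln <- progressive_msa(rep1$combined)
  rows <- as.character(aln)
  expect_identical(gsub("-", "", rows, fixed = TRUE), unname(rep1$combined))
  expect_identical(names(aln), names(rep1$combined))
  expect_equal(length(unique(nchar(rows))), 1L)
  # homology-matrix consistency: residue indices strictly increase along rows
  for (r in rows) {
    idx <- which(strsplit(r, "")[[1]] != "-")
    expect_true(all(diff(idx) > 0))
  }
  # deterministic under fixed input order
  expect_identical(as.character(progressive_msa(rep1$combined)), rows)

  # single sequence returned unchanged
  one <- progressive_msa(rep1$combined[1])
  expect_identical(as.character(one), unname(rep1$combined[1]))
})

test_that("alignment gap load: none for identical data, bounded for IO data", {
  # zero divergence: zero gaps
  m <- substitution_model("rtREV")
  tr <- parse_newick("((A:0,B:0):0,(C:0,D:0):0);")
  set.seed(13)
  same <- evolve_sequences(tr, m, 300)
  expect_equal(gap_fraction(progressive_msa(same)), 0)

  # low-divergence common-ancestry data: < 1% gaps
  tr2 <- parse_newick("((A:0.05,B:0.05):0.02,(C:0.05,D:0.05):0.02);")
  set.seed(14)
  low <- evolve_sequences(tr2, substitution_model("rtREV", gamma_shape = 0.8),
                          500)
  expect_lt(gap_fraction(progressive_msa(low)), 0.01)

  # IO-simulated eight-sequence replicate: hard upper bound on gap load
  cfg <- scenario_preset("fig2-scaled", seed = 8, n_replicates = 2)
  for (rep in generate_scenario(cfg)) {
    g <- gap_fraction(progressive_msa(rep$combined))
    expect_lte(g, 0.15)
    expect_gt(g, 0)
  }
})

test_that("identity alignment stacks equal-length sequences unchanged", {
  s <- c(a = "ARND", b = "WYVC")
  aln <- identity_alignment(s)
  expect_identical(as.character(aln), unname(s))
  expect_identical(attr(aln, "source"), "identity")
  expect_identical(as.character(identity_alignment(s[1])), unname(s[1]))
  expect_error(identity_alignment(c(a = "ARND", b = "AR")), "equal-length")
})

test_that("gap_fraction counts gap cells over total cells", {
  expect_equal(gap_fraction(c(a = "ARND", b = "WYVC")), 0)
  expect_equal(gap_fraction(c(a = "AAAA", b = "----")), 0.5)
  expect_equal(gap_fraction(c(a = "AR-D", b = "W-VC", c = "ARND")), 2 / 12)
})
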