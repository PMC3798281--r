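test_that("uniform random generation has the requested shape and is reproducible", {
  s <- generate_uniform_random(10, 25, seed = 11)
  expect_length(s, 10)
  expect_true(all(nchar(s) == 25))
  expect_identical(s, generate_uniform_random(10, 25, seed = 11))
  expect_false(identical(s, generate_uniform_random(10, 25, seed = 12)))
  expect_error(generate_uniform_random(0, 10, seed = 1), "must be an integer")
  expect_error(generate_uniform_random(1, 0, seed = 1), "must be an integer")
  one <- generate_uniform_random(1, 1, seed = 1)
  expect_equal(nchar(one), c(rand00001 = 1L))
})

test_that("pooled composition of uniform sequences approaches 5% per residue", {
  s <- generate_uniform_random(2000, 100, seed = 21)
  comp <- compute_composition(s)
  expect_true(all(abs(comp - 0.05) < 0.01))
})

test_that("composition-matched generation recovers the target frequencies", {
  target <- reference_composition()
  s <- generate_composition_matched(10000, 100, target, seed = 31)
  comp <- compute_composition(s)
  expect_true(all(abs(comp - target) < 0.005))
})

test_that("degenerate composition gives homopolymers and invalid input is rejected", {
  p <- stats::setNames(c(1, rep(0, 19)), aa_alphabet())
  s <- generate_composition_matched(5, 12, p, seed = 1)
  expect_true(all(s == strrep("A", 12)))
  bad <- stats::setNames(rep(0.06, 20), aa_alphabet())
  expect_error(generate_composition_matched(5, 12, bad, seed = 1), "sum to 1")
})

test_that("scrambling preserves length and residue multiset on random inputs", {
  seqs <- generate_composition_matched(20, 40, reference_composition(), seed = 41)
  for (j in seq_along(seqs)) {
    out <- scramble_sequence(seqs[j], copies = 3, seed = 100 + j)
    expect_true(all(nchar(out) == 40))
    for (o in out)
      expect_identical(residue_multiset(o), residue_multiset(seqs[[j]]))
  }
  expect_identical(scramble_sequence(seqs[1], 3, seed = 7),
                   scramble_sequence(seqs[1], 3, seed = 7))
})

test_that("scrambling a homopolymer is the identity and copies scale as requested", {
  out <- scramble_sequence(c(p = "AAAAAA"), copies = 5, seed = 1)
  expect_true(all(out == "AAAAAA"))
  out100 <- scramble_sequence(c(p = "ACDEFGHIKL"), copies = 100, seed = 2)
  expect_length(out100, 100)
})

test_that("the rejection scrambler is an empirically uniform permutation generator", {
  out <- scramble_sequence(c(p = "ACD"), copies = 1200, seed = 3)
  counts <- table(out)
  expect_length(counts, 6L)  # all 3! permutations occur
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 1e-6)
})

test_that("compute_composition counts exactly", {
  comp <- compute_composition(c(a = "AA", b = "CC"))
  expect_equal(unname(comp["A"]), 0.5)
  expect_equal(unname(comp["C"]), 0.5)
  expect_equal(sum(comp), 1)
  # scrambles share the parent profile
  parent <- c(p = "ACDEFGHIKLMNPQRSTVWY")
  out <- scramble_sequence(parent, 5, seed = 4)
  expect_equal(compute_composition(out), compute_composition(parent))
  expect_error(compute_composition(character(0)), "length")
})

test_that("composition chi-square follows the counts-per-1000 convention", {
  uni <- stats::setNames(rep(0.05, 20), aa_alphabet())
  expect_equal(composition_chi_square(reference_composition(), uni), 160.84)
  expect_equal(composition_chi_square(uni, uni), 0)
  # two-category toy: (60, 40) vs (50, 50) per 100 -> (100^2/500)*2 = 40 per 1000
  o <- stats::setNames(c(0.6, 0.4, rep(0, 18)), aa_alphabet())
  e <- stats::setNames(c(0.5, 0.5, rep(0, 18)), aa_alphabet())
  expect_equal(composition_chi_square(o, e), 40)
  # mass on a zero-expected category is degenerate
  o2 <- stats::setNames(c(0.5, 0.25, 0.25, rep(0, 17)), aa_alphabet())
  expect_error(composition_chi_square(o2, e), "zero-expected")
})

test_that("chi-square is non-negative and asymmetric in its arguments", {
  a <- reference_composition()
  b <- reference_composition("idp")
  expect_gte(composition_chi_square(a, b), 0)
  expect_false(isTRUE(all.equal(composition_chi_square(a, b),
                                composition_chi_square(b, a))))
})

test_that("k-means composition split recovers planted composition groups", {
  mk <- function(enriched, n, seed) {
    p <- rep((1 - 0.15) / 19, 20)
    names(p) <- aa_alphabet()
    p[enriched] <- 0.15
    generate_composition_matched(n, 400, p / sum(p), seed)
  }
  lys <- mk("K", 15, seed = 51)
  ala <- mk("A", 15, seed = 52)
  seqs <- c(lys, ala)
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  cl <- kmeans_composition_split(seqs, k = 2, seed = 1)
  expect_length(unique(cl[1:15]), 1L)
  expect_length(unique(cl[16:30]), 1L)
  expect_false(cl[1] == cl[16])
  # duplicates land together; k = 1 puts everything together
  dup <- c(x = seqs[[1]], y = seqs[[1]], z = seqs[[20]])
  cld <- kmeans_composition_split(dup, k = 2, seed = 1)
  expect_equal(cld[["x"]], cld[["y"]])
  expect_length(unique(kmeans_composition_split(seqs, k = 1)), 1L)
  expect_error(kmeans_composition_split(seqs[1:3], k = 5), "exceeds")
})

test_that("two-sample propensity comparison matches the closed-form Welch statistic", {
  a <- withr::with_seed(61, rnorm(30, 0, 1))
  b <- withr::with_seed(62, rnorm(40, 0.5, 2))
  res <- compare_propensity_distributions(a, b)
  expect_equal(res$statistic, welch_t_oracle(a, b), tolerance = 1e-10)
  same <- compare_propensity_distributions(a, a)
  expect_equal(same$statistic, 0)
  degen <- compare_propensity_distributions(rep(2, 5), rep(2, 8))
  expect_equal(degen$statistic, 0)
  expect_equal(degen$p_value, 1)
})

test_that("the t-test detects a one-sigma shift at n = 200 across seeded replicates", {
  hits <- vapply(1:50, function(s) {
    a <- withr::with_seed(1000 + s, rnorm(200, 0, 1))
    b <- withr::with_seed(2000 + s, rnorm(200, 1, 1))
    compare_propensity_distributions(a, b)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("FASTA round trip preserves sequence sets", {
  seqs <- generate_uniform_random(5, 30, seed = 71)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_set(seqs, f)
  expect_identical(read_fasta_set(f), seqs)
})

test_that("ambiguous residues are rejected by default and droppable on request", {
  expect_error(as_sequence_set(c(s = "ACDXEF")), "non-standard")
  expect_identical(unname(as_sequence_set(c(s = "ACDXEF"), drop_ambiguous = TRUE)),
                   "ACDEF")
})
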