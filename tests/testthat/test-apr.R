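test_that("APR interval validation enforces coordinates, length and source", {
  ok <- apr_intervals(data.frame(seq_id = "s", start = 5, end = 12,
                                 source = "tango", score = 1.5))
  expect_s3_class(ok, "apr_table")
  expect_error(apr_intervals(data.frame(seq_id = "s", start = 8, end = 5)),
               "start <= end")
  expect_error(apr_intervals(data.frame(seq_id = "s", start = 1, end = 4)),
               "minimum length")
  expect_error(apr_intervals(data.frame(seq_id = "s", start = 1, end = 8,
                                        source = "oracle")), "source")
  expect_error(apr_intervals(data.frame(seq_id = "s", start = 1, end = 10),
                             seqlen = c(s = 8)), "beyond sequence length")
})

test_that("APR TSV round trip preserves the table", {
  aprs <- apr_intervals(data.frame(seq_id = c("a", "b"), start = c(3, 10),
                                   end = c(9, 16), source = "waltz",
                                   score = c(1, 2)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_apr_tsv(aprs, f)
  expect_equal(read_apr_tsv(f), aprs)
})

test_that("aggregation propensity is score per residue", {
  expect_equal(aggregation_propensity(0, 100), 0)
  expect_equal(aggregation_propensity(648, 100), 6.48)
  expect_equal(aggregation_propensity(10, 4), 2.5)
  expect_error(aggregation_propensity(1, 0), "seqlen")
})

test_that("APR proportion follows the coverage formula and rejects overlaps", {
  aprs <- apr_intervals(data.frame(seq_id = "s", start = c(10, 30),
                                   end = c(15, 37)))  # lengths 6 and 8
  expect_equal(apr_proportion(100, aprs), 14)
  expect_equal(apr_proportion(148, aprs[1, ]), 100 * 6 / 148, tolerance = 1e-12)
  expect_equal(apr_proportion(100, aprs[0, ]), 0)
  full <- apr_intervals(data.frame(seq_id = "s", start = 1, end = 60))
  expect_equal(apr_proportion(60, full), 100)
  overlap <- apr_intervals(data.frame(seq_id = "s", start = c(1, 5),
                                      end = c(10, 14)))
  expect_error(apr_proportion(100, overlap), "overlap")
})

test_that("gate-keeper profile counts planted flanks and truncates at termini", {
  # flanks D,A,K before and P,G,E after a 6-residue APR at 4..9
  s <- c(x = "DAKVVVVVVPGEAAAA")
  aprs <- apr_intervals(data.frame(seq_id = "x", start = 4, end = 9))
  gp <- gatekeeper_profile(s, aprs)
  expect_equal(gp$per_apr_counts, 4L)  # D, K, P, E
  expect_equal(unname(gp$position_freq_pct[c("pb3", "pb1", "pe1", "pe3")]),
               c(100, 100, 100, 100))
  expect_equal(unname(gp$position_freq_pct[c("pb2", "pe2")]), c(0, 0))
  # APR at position 1: no preceding positions in any denominator
  s2 <- c(y = "VVVVVVPGE")
  gp2 <- gatekeeper_profile(s2, apr_intervals(data.frame(seq_id = "y", start = 1, end = 6)))
  expect_equal(unname(gp2$position_totals[c("pb1", "pb2", "pb3")]), c(0L, 0L, 0L))
  expect_true(is.na(gp2$position_freq_pct["pb1"]))
  expect_equal(gp2$per_apr_counts, 2L)  # P and E
})

test_that("gate-keeper frequencies are invariant under sequence reversal", {
  set <- make_sequences_with_aprs(30, 80, aprs_per_seq = 1, apr_len = 7,
                                  gatekeeper_rates = c(pb1 = 0.5, pe2 = 0.5),
                                  seed = 5)
  gp <- gatekeeper_profile(set$seqs, set$aprs)
  rev_seqs <- vapply(set$seqs, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), character(1))
  L <- nchar(set$seqs[set$aprs$seq_id])
  rev_aprs <- apr_intervals(data.frame(seq_id = set$aprs$seq_id,
                                       start = L - set$aprs$end + 1L,
                                       end = L - set$aprs$start + 1L))
  gp_rev <- gatekeeper_profile(rev_seqs, rev_aprs)
  mirror <- c(pb3 = "pe3", pb2 = "pe2", pb1 = "pe1",
              pe1 = "pb1", pe2 = "pb2", pe3 = "pb3")
  expect_equal(unname(gp_rev$position_counts[mirror]),
               unname(gp$position_counts))
  expect_equal(gp_rev$mean_per_apr, gp$mean_per_apr)
})

test_that("surrogate predictor recovers a planted hydrophobic stretch", {
  s <- c(x = paste0("DEDEKRKEDE", strrep("V", 10), "EDEKRKEDED"))
  p <- surrogate_predict_aprs(s, window = 6, threshold = 2.0)
  expect_equal(nrow(p$intervals), 1L)
  expect_lte(abs(p$intervals$start - 11), 2)
  expect_lte(abs(p$intervals$end - 20), 2)
  expect_identical(p$intervals$source, "surrogate")
  expect_gt(p$total_score, 0)
})

test_that("surrogate predictor edge cases: hydrophilic input, infinite threshold, short input", {
  polyE <- c(e = strrep("E", 40))
  expect_equal(nrow(surrogate_predict_aprs(polyE, threshold = 0.1)$intervals), 0L)
  p <- surrogate_predict_aprs(c(x = strrep("V", 30)), threshold = Inf)
  expect_equal(p$total_score, 0)
  expect_equal(nrow(p$intervals), 0L)
  short <- surrogate_predict_aprs(c(x = "VVV"), window = 6)
  expect_equal(nrow(short$intervals), 0L)
})

test_that("surrogate intervals never overlap and every window claim is verifiable", {
  kd <- aprtools:::kyte_doolittle()
  seqs <- generate_composition_matched(25, 120, reference_composition(), seed = 81)
  for (j in seq_along(seqs)) {
    p <- surrogate_predict_aprs(seqs[j], window = 6, threshold = 1.5)
    iv <- p$intervals
    if (nrow(iv) >= 2) expect_true(all(iv$start[-1] > iv$end[-nrow(iv)]))
    for (r in seq_len(nrow(iv))) {
      vals <- kd[strsplit(seqs[[j]], "", fixed = TRUE)[[1]]]
      wm <- vapply(iv$start[r]:(iv$end[r] - 5L),
                   function(s) mean(vals[s:(s + 5L)]), numeric(1))
      expect_gte(max(wm), 1.5)  # at least one qualifying window per interval
    }
  }
})

test_that("dataset summary matches a hand-computed three-sequence fixture", {
  mk <- function(id, L, iv) list(seq_id = id, seqlen = L, total_score = 0,
                                 intervals = iv)
  iv1 <- apr_intervals(data.frame(seq_id = "a", start = 1, end = 6))
  iv2 <- apr_intervals(data.frame(seq_id = "b", start = c(5, 21), end = c(12, 30)))
  empty <- iv1[0, ]
  preds <- list(mk("a", 100, iv1), mk("b", 60, iv2), mk("c", 50, empty))
  s <- dataset_summary(preds)
  expect_equal(s$pct_with_apr, 100 * 2 / 3)
  expect_equal(s$n_aprs, 3L)
  expect_equal(s$mean_seqlen, 80)          # mean(100, 60); APR-less excluded
  expect_equal(s$mean_apr_len, mean(c(6, 8, 10)))
  expect_equal(s$mean_apr_prop, mean(c(6, 30)))  # 6/100, 18/60 as percent
  # single sequence, one APR of 6 in 100 residues
  s1 <- dataset_summary(list(mk("a", 100, iv1)))
  expect_equal(s1$mean_apr_len, 6)
  expect_equal(s1$mean_apr_prop, 6)
  # nothing predicted anywhere
  s0 <- dataset_summary(list(mk("c", 50, empty)))
  expect_equal(s0$pct_with_apr, 0)
  expect_true(is.na(s0$mean_apr_len))
})
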