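test_that("ballot_percent reproduces the reference cut-off percentages", {
  expect_equal(ballot_percent(3328, 4096), 81.25)
  expect_equal(ballot_percent(4085, 4096), 99.73)
  expect_equal(ballot_percent(0, 4096), 0)
  expect_equal(ballot_percent(4096, 4096), 100)
  expect_equal(ballot_percent(1, 3), 33.33)   # half-up at 2 decimals
  expect_equal(ballot_percent(1, 8), 12.5)
  expect_error(ballot_percent(1, 0), "positive")
  expect_error(ballot_percent(5, 4), "\\[0, rounds\\]")
})

test_that("vote_tally validates its invariants", {
  t1 <- vote_tally(c(a = 5L, b = 0L), rounds = 8L)
  expect_equal(unname(t1$eligibility), c(8L, 8L))
  expect_error(vote_tally(c(a = 9L), rounds = 8L), "<=")
})

test_that("select_hkgs applies the dual thresholds and the standard bypass", {
  part <- structure(list(standard = "p_std",
                         putative = c("p_tubb3", "p_put_hi"),
                         non_hkg = c("p_atg9a", "p_edge", "p_low")),
                    class = "ProbePartition")
  counts <- c(p_tubb3 = 2287L, p_put_hi = 3328L, p_atg9a = 4093L,
              p_edge = 4085L, p_low = 10L)
  tally <- vote_tally(counts, rounds = 4096L)
  map <- c(p_std = "STD", p_tubb3 = "TUBB3", p_put_hi = "PUTHI",
           p_atg9a = "ATG9A", p_edge = "EDGE", p_low = "LOW")
  preds <- select_hkgs(tally, part, putative_cutoff = 3328L,
                       nonhkg_cutoff = 4085L, map = map)
  sel <- setNames(preds$selected, preds$gene_id)
  expect_false(sel[["TUBB3"]])          # 2287 below the putative cut-off
  expect_true(sel[["PUTHI"]])           # inclusive cut-off: 3328 selected
  expect_true(sel[["ATG9A"]])           # 4093 > 4085
  expect_false(sel[["EDGE"]])           # strict: exactly 4085 rejected
  expect_true(sel[["STD"]])             # standard pool bypasses thresholds
  expect_true(is.na(preds$vote_count[preds$gene_id == "STD"]))
  expect_equal(preds$ballot_percent[preds$gene_id == "ATG9A"], 99.93)

  # conservation: selected = standard + putative picks + non-HKG picks
  expect_equal(sum(sel), 1L + 1L + 1L)
  expect_error(select_hkgs(tally, structure(list(standard = "p_std",
                                                 putative = "p_tubb3",
                                                 non_hkg = character(0)),
                                            class = "ProbePartition"),
                           3328L, 4085L, map),
               "absent from partition")
  expect_error(select_hkgs(tally, part, 5000L, 4085L, map), "\\[0, rounds\\]")
})

test_that("gene aggregation takes the best probe and raising cutoffs shrinks selection", {
  part <- structure(list(standard = character(0),
                         putative = c("pA1", "pA2", "pB1"),
                         non_hkg = character(0)),
                    class = "ProbePartition")
  tally <- vote_tally(c(pA1 = 100L, pA2 = 180L, pB1 = 150L), rounds = 256L)
  map <- c(pA1 = "GA", pA2 = "GA", pB1 = "GB")
  preds <- select_hkgs(tally, part, 160L, 200L, map)
  expect_equal(nrow(preds), 2L)
  rowA <- preds[preds$gene_id == "GA", ]
  expect_equal(rowA$best_probe_id, "pA2")
  expect_equal(rowA$vote_count, 180L)

  n_sel <- vapply(seq(0L, 256L, by = 16L), function(cut) {
    sum(select_hkgs(tally, part, cut, 256L, map)$selected)
  }, integer(1))
  expect_true(all(diff(n_sel) <= 0L))
})

test_that("count_histogram filters by pool and min_count and conserves totals", {
  part <- structure(list(standard = character(0),
                         putative = c("a", "b"),
                         non_hkg = c("c", "d")),
                    class = "ProbePartition")
  tally <- vote_tally(c(a = 5L, b = 5L, c = 2L, d = 7L), rounds = 8L)
  h <- count_histogram(tally, part, "all", min_count = 3L)
  expect_equal(h, c(`5` = 2L, `7` = 1L))
  expect_equal(sum(h), sum(tally$counts >= 3L))
  expect_equal(count_histogram(tally, part, "putative", min_count = 6L),
               setNames(integer(0), character(0)))
  expect_equal(count_histogram(tally, part, "non_hkg", min_count = 0L),
               c(`2` = 1L, `7` = 1L))
})

test_that("run_voting is deterministic, bounded, and recovers planted structure", {
  pools <- generate_labeled_pools(12, 4, 4, 40, 3, seed = 404)
  ft <- featurize(preprocess_set(pools$set)$set)
  spec <- classifier_spec(2, 1 / 128)
  t1 <- run_voting(ft, pools$partition, rounds = 24L, n_neg = 16L,
                   spec = spec, seed = 11)
  t2 <- run_voting(ft, pools$partition, rounds = 24L, n_neg = 16L,
                   spec = spec, seed = 11)
  expect_identical(t1, t2)
  expect_true(all(t1$counts >= 0L & t1$counts <= t1$rounds))
  expect_setequal(names(t1$counts), c(pools$partition$putative,
                                      pools$partition$non_hkg))

  # different seed: strongly correlated ballots on well-separated data
  t3 <- run_voting(ft, pools$partition, rounds = 24L, n_neg = 16L,
                   spec = spec, seed = 12)
  rho <- suppressWarnings(cor(as.numeric(t1$counts),
                              as.numeric(t3$counts[names(t1$counts)]),
                              method = "spearman"))
  expect_gte(rho, 0.9)

  truth <- pools$truth[names(t1$counts)]
  bp <- ballot_percent(t1$counts, t1$rounds)
  expect_gte(median(bp[truth]), 80)
  expect_lte(median(bp[!truth]), 20)

  expect_error(run_voting(ft, pools$partition, rounds = 2L, n_neg = 60L,
                          spec = spec, seed = 1), "exceed")
})
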