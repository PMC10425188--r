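test_that("residue scores follow the precision/recall definitions", {
  tr <- "iiabcdefgii"
  expect_equal(as.numeric(residue_scores(tr, tr)[, c("precision", "recall", "f1")]),
               c(1, 1, 1))
  # all-i prediction: recall 0, undefined precision reported as 0
  alli <- strrep("i", nchar(tr))
  expect_equal(as.numeric(residue_scores(tr, alli)[, c("precision", "recall", "f1")]),
               c(0, 0, 0))
  # 10-residue runs overlapping by 5 -> 0.5 everywhere
  obs <- paste0(strrep("a", 10), strrep("i", 10))         # positions 1-10
  prd <- paste0(strrep("i", 5), strrep("a", 10), strrep("i", 5))  # 6-15
  sc <- residue_scores(obs, prd)
  expect_equal(as.numeric(sc[, c("precision", "recall", "f1")]),
               c(0.5, 0.5, 0.5))
  expect_error(residue_scores("ii", "iii"), "mismatch")
})

test_that("segment matching applies the half-length-of-longer rule", {
  seg <- function(s, e) tibble::tibble(start = s, end = e,
                                       registers = strrep("a", e - s + 1))
  # overlap 5 vs longest 10 -> TP
  m <- segment_scores(seg(1, 10), seg(1, 5))
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  # overlap 4 vs longest 10 -> FP + FN
  m2 <- segment_scores(seg(1, 10), seg(1, 4))
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 1, 1))
  # real-valued half: overlap 5 of a 9-long observed passes (5 >= 4.5)
  m3 <- segment_scores(seg(1, 9), seg(5, 9))
  expect_equal(m3$tp, 1)
  # identical sets -> perfect
  two <- tibble::tibble(start = c(1, 20), end = c(10, 30),
                        registers = c(strrep("a", 10), strrep("a", 11)))
  expect_equal(as.numeric(segment_scores(two, two)[, c("precision", "recall", "f1")]),
               c(1, 1, 1))
  # each observed segment is consumable once
  m4 <- segment_scores(seg(1, 10),
                       tibble::tibble(start = c(1, 6), end = c(5, 10),
                                      registers = c("aaaaa", "aaaaa")))
  expect_equal(c(m4$tp, m4$fp, m4$fn), c(1, 1, 0))
  expect_error(segment_scores(two, tibble::tibble(start = c(1, 5),
                                                  end = c(6, 9),
                                                  registers = c("a", "a"))),
               "overlap")
})

test_that("segment scores are symmetric under swapping obs/pred with PRE<->REC", {
  set.seed(21)
  for (rep in 1:200) {
    a <- random_track(60)
    b <- random_track(60)
    f <- segment_scores(a, b)
    r <- segment_scores(b, a)
    expect_equal(f$precision, r$recall)
    expect_equal(f$recall, r$precision)
    expect_equal(f$f1, r$f1)
  }
})

test_that("SOV matches the hand-coded formula oracle and its edge cases", {
  tr <- "iiabcdefgaii"
  expect_equal(sov(tr, tr, "observed"), 100)
  expect_equal(sov(tr, tr, "predicted"), 100)
  # disjoint single segments
  obs <- paste0(strrep("a", 10), strrep("i", 10))
  prd <- paste0(strrep("i", 10), strrep("a", 10))
  expect_equal(sov(obs, prd, "observed"), 0)
  # worked instance: obs 1-10, pred 3-12 on L = 14
  obs2 <- paste0(strrep("a", 10), strrep("i", 4))
  prd2 <- paste0("ii", strrep("a", 10), "ii")
  expect_equal(sov(obs2, prd2, "observed"), oracle_sov(obs2, prd2))
  expect_equal(sov(obs2, prd2, "predicted"), oracle_sov(prd2, obs2))
  # register relabeling leaves the binary measure unchanged
  obs3 <- gsub("a", "d", obs2)
  expect_equal(sov(obs3, prd2, "observed"), sov(obs2, prd2, "observed"))
  # random instances against the oracle
  set.seed(33)
  for (rep in 1:200) {
    a <- random_track(50)
    b <- random_track(50)
    expect_equal(sov(a, b, "observed"), oracle_sov(a, b), tolerance = 1e-12)
    expect_equal(sov(a, b, "predicted"), oracle_sov(b, a), tolerance = 1e-12)
  }
})

test_that("agreement on the cc class always scores SOV 100", {
  set.seed(14)
  for (rep in 1:100) {
    a <- random_track(40)
    b <- gsub("[a-g]", "d", a)   # same cc mask, relabeled registers
    expect_equal(sov(a, b, "observed"), 100)
    expect_equal(sov(a, b, "predicted"), 100)
  }
  # the delta term deliberately forgives small boundary shifts: a 10-residue
  # observed helix predicted as 1-12 still scores 100 in both directions
  obs <- paste0(strrep("a", 10), "iiii")
  prd <- paste0(strrep("a", 12), "ii")
  expect_equal(sov(obs, prd, "observed"), 100)
  expect_equal(sov(obs, prd, "predicted"), 100)
  expect_equal(oracle_sov(obs, prd), 100)
})

test_that("PR-AUC uses step interpolation over residue thresholds", {
  y <- c(rep(TRUE, 5), rep(FALSE, 15))
  # perfect separation
  expect_equal(pr_auc(y, c(runif(5, 0.8, 1), runif(15, 0, 0.5))), 1)
  # constant score collapses to prevalence
  expect_equal(pr_auc(y, rep(0.4, 20)), 0.25)
  # random instances against the threshold-sweep oracle
  set.seed(8)
  for (rep in 1:50) {
    yy <- runif(200) < 0.3
    if (!any(yy)) yy[1] <- TRUE
    pp <- round(runif(200), 2)  # force ties
    expect_equal(pr_auc(yy, pp), oracle_pr_auc(yy, pp), tolerance = 1e-9)
  }
  # label-track interface
  expect_equal(pr_auc(c("ia", "ai"), list(c(0.1, 0.9), c(0.8, 0.2))), 1)
})

test_that("MCC follows the closed form with the 0-denominator convention", {
  expect_equal(mcc(10, 10, 0, 0), 1)
  expect_equal(mcc(0, 0, 10, 10), -1)
  expect_equal(mcc(6, 3, 1, 2), 16 / sqrt(7 * 8 * 4 * 5))
  expect_equal(mcc(6, 3, 1, 2), 0.478, tolerance = 1e-3)
  expect_equal(mcc(0, 5, 0, 5), 0)   # empty prediction column
  # large counts do not overflow
  expect_equal(mcc(2e5L, 2e5L, 1L, 1L), 1, tolerance = 1e-4)
})

test_that("per-register MCC is one-vs-rest with x positions excluded", {
  tr <- "iiabcdefgaii"
  m <- per_register_mcc(tr, tr)
  expect_equal(m$mcc, rep(1, 7))
  m0 <- per_register_mcc(tr, strrep("i", nchar(tr)))
  expect_equal(m0$mcc, rep(0, 7))
  # oracle check on random tracks
  set.seed(91)
  for (rep in 1:30) {
    a <- random_track(40)
    b <- random_track(40)
    got <- per_register_mcc(a, b)
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    for (r in letters[1:7]) {
      expect_equal(got$mcc[got$register == r],
                   mcc(sum(av == r & bv == r), sum(av != r & bv != r),
                       sum(av != r & bv == r), sum(av == r & bv != r)))
    }
  }
  # x in the prediction drops the position from register scoring
  withx <- sub("c", "x", tr)
  mx <- per_register_mcc(tr, withx)
  expect_equal(mx$mcc[mx$register != "c"], rep(1, 6))
})

test_that("bootstrap comparison detects a planted gap and nothing else", {
  d <- coil_simulate(synth_config(n_records = 40, length_range = c(40L, 80L),
                                  helices_per_record_range = c(1L, 2L),
                                  embed_dim = 4L, seed = 77))
  pair <- simulate_method_pair(d, p_a = 0.05, p_b = 0.3, seed = 2)
  cmp <- bootstrap_compare(pair$results_a, pair$results_b, n_samples = 100L,
                           sample_size = 30L, seed = 11)
  expect_lt(cmp$p[cmp$measure == "f1_r"], 0.01)
  expect_lt(cmp$p[cmp$measure == "f1_s"], 0.01)
  expect_gt(cmp$mean_diff[cmp$measure == "f1_r"], 0)
  # identical inputs: zero differences, p ~ 1
  same <- bootstrap_compare(pair$results_a, pair$results_a, n_samples = 20L,
                            sample_size = 30L, seed = 11)
  expect_equal(same$mean_diff, rep(0, 8))
  expect_equal(same$p, rep(1, 8))
  # seeded reproducibility
  cmp2 <- bootstrap_compare(pair$results_a, pair$results_b, n_samples = 100L,
                            sample_size = 30L, seed = 11)
  expect_identical(cmp, cmp2)
  expect_error(bootstrap_compare(pair$results_a, pair$results_b,
                                 sample_size = 1000L, replace = FALSE),
               "replacement")
  # zero corruption reproduces the truth exactly
  perfect <- simulate_method_pair(d, p_a = 0, p_b = 0, seed = 5)
  expect_identical(perfect$results_a$pred, perfect$results_a$obs)
  expect_error(simulate_method_pair(d, p_a = -0.1, p_b = 0.5), "rates")
})

test_that("F1 is the harmonic mean of its own precision and recall", {
  set.seed(44)
  for (rep in 1:100) {
    a <- random_track(50)
    b <- random_track(50)
    rs <- residue_scores(a, b)
    if (rs$precision + rs$recall > 0) {
      expect_equal(rs$f1, 2 * rs$precision * rs$recall /
                     (rs$precision + rs$recall))
    }
    ss <- segment_scores(a, b)
    if (ss$precision + ss$recall > 0) {
      expect_equal(ss$f1, 2 * ss$precision * ss$recall /
                     (ss$precision + ss$recall))
    }
  }
})
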