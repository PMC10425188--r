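test_that("the automaton has the stated 20-state topology", {
  a <- build_cc_automaton()
  expect_length(a$states, 20L)
  expect_length(a$emitting, 18L)
  em <- a$emitting
  at <- function(f, t) a$trans[match(f, em), match(t, em)]
  # heptad cycle is the only register->register edge
  expect_true(at("1a", "1b"))
  expect_false(at("1a", "1c"))
  expect_true(at("1g", "1a"))
  expect_true(at("2d", "2e"))
  # H wiring: in from any register, out to any register, no self-loop
  expect_true(at("1c", "1H") && at("1H", "1f"))
  expect_false(at("1H", "1H"))
  expect_true(build_cc_automaton(h_self_loop = TRUE)$trans[
    match("1H", em), match("1H", em)])
  # background states self-loop; block 2 is entered only through i1
  expect_true(at("i0", "i0") && at("i1", "i1"))
  expect_true(at("i0", "1e") && at("i1", "2b"))
  expect_false(at("i0", "2a"))
  expect_false(at("1H", "i1"))
  # BEGIN: i0 or any block-1 register; END: everything but the H states
  expect_setequal(em[a$begin], c("i0", paste0("1", letters[1:7])))
  expect_false(a$end[match("1H", em)])
  expect_false(a$end[match("2H", em)])
  expect_true(all(a$end[match(c("i0", "i1", "1a", "2g"), em)]))
  # every emitting state lies on some BEGIN->END path
  fwd <- a$begin
  for (i in 1:40) fwd <- fwd | (colSums(a$trans[fwd, , drop = FALSE]) > 0)
  bwd <- a$end
  for (i in 1:40) bwd <- bwd | (rowSums(a$trans[, bwd, drop = FALSE]) > 0)
  expect_true(all(fwd & bwd))
})

test_that("label-path validity matches the grammar", {
  expect_true(is_valid_label_path("iiiabcdefgii"))
  expect_true(is_valid_label_path("abcdefg"))       # BEGIN->1a, 1g->END
  expect_true(is_valid_label_path("iiiabceii"))     # e reachable via H wildcard
  expect_true(is_valid_label_path("iiii"))
  expect_true(is_valid_label_path("iiabcdefgaiicdefgabii"))  # two helices
  expect_false(is_valid_label_path("ax"))           # H cannot end a path
  expect_false(is_valid_label_path(""))
  expect_false(is_valid_label_path("iqi"))          # illegal character
  # x is only generable inside a helix (wildcard states)
  expect_true(is_valid_label_path("iaxci"))
  expect_false(is_valid_label_path("ixi"))          # no register anchor to exit
})

test_that("forward-backward matches exhaustive enumeration and the semiring oracle", {
  set.seed(101)
  a <- build_cc_automaton()
  # zero weights: logZ = log(number of valid 3-step paths), posteriors
  # proportional to per-position valid-path state counts
  m0 <- crf_model()
  f3 <- matrix(0, 3, 8)
  fb0 <- forward_backward(m0, f3)
  expect_equal(fb0$log_partition, oracle_enum_logZ(m0, f3), tolerance = 1e-10)
  expect_equal(rowSums(fb0$posterior), rep(1, 3), tolerance = 1e-6)
  # random weights, exhaustive recursion at small L
  for (L in c(1L, 2L, 4L, 6L)) {
    m <- random_crf()
    f <- matrix(runif(8 * L), L, 8)
    fb <- forward_backward(m, f)
    expect_equal(fb$log_partition, oracle_enum_logZ(m, f), tolerance = 1e-8)
    expect_equal(rowSums(fb$posterior), rep(1, L), tolerance = 1e-6)
  }
  # the dense semiring oracle agrees with enumeration, then covers L <= 12
  m <- random_crf()
  f <- matrix(runif(8 * 5), 5, 8)
  expect_equal(oracle_semiring_logZ(m, f), oracle_enum_logZ(m, f),
               tolerance = 1e-10)
  for (L in c(8L, 12L)) {
    f <- matrix(runif(8 * L), L, 8)
    expect_equal(forward_backward(m, f)$log_partition,
                 oracle_semiring_logZ(m, f), tolerance = 1e-8)
  }
})

test_that("posterior-Viterbi returns the best grammar-valid posterior path", {
  set.seed(55)
  a <- build_cc_automaton()
  # overwhelming i evidence decodes to all-i
  m <- crf_model()
  m$node_w[match(c("i0", "i1"), a$emitting), 9L] <- 8   # bias column
  pv <- posterior_viterbi(m, matrix(0, 10, 8))
  expect_equal(pv$labels, strrep("i", 10))
  expect_equal(pv$cc_probability, 1 - rowSums(pv$posterior[, 1:2]),
               tolerance = 1e-9)
  # path score equals the max-plus oracle on log-posteriors
  for (L in c(1L, 3L, 7L, 12L)) {
    mr <- random_crf()
    f <- matrix(runif(8 * L), L, 8)
    pv <- posterior_viterbi(mr, f)
    lp <- log(pmax(pv$posterior, 1e-300))
    expect_equal(pv$path_score, oracle_maxplus_best(lp, a), tolerance = 1e-8)
    expect_true(is_valid_label_path(pv$labels))
  }
  # enumeration cross-check of the max-plus oracle itself
  mr <- random_crf()
  f <- matrix(runif(8 * 5), 5, 8)
  lp <- log(pmax(posterior_viterbi(mr, f)$posterior, 1e-300))
  expect_equal(oracle_maxplus_best(lp, a), oracle_enum_best(lp, a))
  # exact tie resolves to the lowest state index: with zero weights and
  # L = 1 every begin state has posterior 1/8; i0 is first in state order
  pv0 <- posterior_viterbi(crf_model(), matrix(0, 1, 8))
  expect_equal(max(abs(pv0$posterior[1, pv0$posterior[1, ] > 0] - 1 / 8)), 0,
               tolerance = 1e-12)
  expect_equal(pv0$states[1], "i0")
})

test_that("decoded register phase advances cyclically outside x positions", {
  set.seed(66)
  regs <- letters[1:7]
  for (rep in 1:40) {
    m <- random_crf(sd = 1)
    L <- sample(10:30, 1)
    pv <- posterior_viterbi(m, matrix(runif(8 * L), L, 8))
    lab <- strsplit(pv$labels, "")[[1]]
    for (t in seq_len(L - 1)) {
      if (lab[t] %in% regs && lab[t + 1] %in% regs) {
        expect_equal(match(lab[t + 1], regs) %% 7,
                     (match(lab[t], regs) + 1) %% 7)
      }
    }
  }
})

test_that("CRF training fits separable features and respects the prior", {
  set.seed(3)
  d <- coil_simulate(synth_config(n_records = 25, length_range = c(40L, 70L),
                                  helices_per_record_range = c(1L, 2L),
                                  seed = 17))
  lab_order <- c(letters[1:7], "i")
  feats <- lapply(d$labels, function(tr) {
    ch <- strsplit(tr, "")[[1]]
    F <- matrix(0, length(ch), 8)
    F[cbind(seq_along(ch), match(ch, lab_order))] <- 1
    F
  })
  fit <- train_crf(crf_model(), feats, d$labels, iterations = 40L)
  acc <- mean(unlist(Map(function(f, tr) {
    strsplit(posterior_viterbi(fit, f)$labels, "")[[1]] ==
      strsplit(tr, "")[[1]]
  }, feats, d$labels)))
  expect_gte(acc, 0.99)
  # a near-zero prior variance pins the weights near zero
  tight <- train_crf(crf_model(sigma2 = 1e-8), feats, d$labels,
                     iterations = 40L)
  expect_lt(max(abs(coilgram:::crf_pack(tight))),
            max(abs(coilgram:::crf_pack(fit))))
  # grammar-invalid track is refused with the offending id (x cannot open
  # a path: H states are not reachable from BEGIN)
  bad <- d$labels
  bad[3] <- sub("^.", "x", bad[3])
  expect_false(is_valid_label_path(bad[3]))
  expect_error(train_crf(crf_model(), feats, bad, ids = d$id),
               d$id[3], fixed = TRUE)
})

test_that("the concave objective reaches the same optimum from different starts", {
  set.seed(12)
  d <- coil_simulate(synth_config(n_records = 6, length_range = c(25L, 40L),
                                  seed = 23))
  feats <- lapply(d$labels, function(tr) {
    ch <- strsplit(tr, "")[[1]]
    F <- matrix(0, length(ch), 8)
    F[cbind(seq_along(ch), match(ch, lab_order <- c(letters[1:7], "i")))] <- 1
    F + matrix(runif(length(F), 0, 0.1), nrow(F))
  })
  m1 <- crf_model()
  m2 <- random_crf(sd = 0.3)
  f1 <- train_crf(m1, feats, d$labels, iterations = 500L)
  f2 <- train_crf(m2, feats, d$labels, iterations = 500L)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-6)
})

test_that("CRF text serialization round-trips exactly", {
  set.seed(9)
  m <- random_crf(feature_window = 3L)
  path <- withr::local_tempfile(fileext = ".crf")
  write_crf_model(m, path)
  m2 <- read_crf_model(path)
  expect_equal(m2$node_w, m$node_w)
  expect_equal(m2$trans_w, m$trans_w)
  expect_equal(m2$begin_w, m$begin_w)
  expect_equal(m2$end_w, m$end_w)
  expect_equal(m2$sigma2, m$sigma2)
  expect_equal(m2$feature_window, m$feature_window)
  f <- matrix(runif(8 * 9), 9, 8)
  expect_equal(posterior_viterbi(m2, f)$labels,
               posterior_viterbi(m, f)$labels)
})
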