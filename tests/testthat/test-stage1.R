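# Small architectures keep these fits fast; the full default architecture
# is exercised in the acceptance suite's end-to-end run.

tiny_cfg <- function(...) {
  stage1_config(window = 5L, n_filters = 8L, recurrent_units = 16L,
                hidden = 8L, dropout = 0.1, lr = 5e-3, batch_size = 4L,
                seed = 21L, ...)
}

test_that("the built model has the configured per-position widths", {
  cfg <- stage1_config(seed = 1L)
  m <- build_stage1(cfg, 48L)
  expect_equal(dim(m$params$conv.W), c(15L, 48L, 40L))        # D -> 40
  expect_equal(dim(m$params$lf.Wx), c(40L, 4L * 64L))         # 40 -> 2x64
  expect_equal(dim(m$params$fc1.W), c(128L, 64L))             # 128 -> 64
  expect_equal(dim(m$params$fc2.W), c(64L, 8L))               # 64 -> 8
  expect_equal(m$label_order, c(letters[1:7], "i"))
  expect_error(stage1_config(window = 14L), "odd")
  # identical seeds give identical initialization
  expect_identical(build_stage1(cfg, 48L)$params,
                   build_stage1(cfg, 48L)$params)
})

test_that("predictions are row-normalized distributions of the right shape", {
  m <- build_stage1(tiny_cfg(), 6L)
  P <- predict_stage1(m, matrix(rnorm(6 * 9), 9, 6))
  expect_equal(dim(P), c(9L, 8L))
  expect_equal(rowSums(P), rep(1, 9), tolerance = 1e-6)
  expect_true(all(P >= 0 & P <= 1))
  # length-1 sequence
  P1 <- predict_stage1(m, matrix(rnorm(6), 1, 6))
  expect_equal(dim(P1), c(1L, 8L))
  expect_error(predict_stage1(m, matrix(0, 3, 5)), "dimension")
  # softmax output alternative is also a distribution
  ms <- build_stage1(tiny_cfg(output_activation = "softmax"), 6L)
  expect_equal(rowSums(predict_stage1(ms, matrix(rnorm(30), 5, 6))),
               rep(1, 5), tolerance = 1e-6)
})

test_that("KL loss is zero only at the one-hot target", {
  Y <- rbind(c(1, 0, 0), c(0.2, 0.5, 0.3))
  Tgt <- rbind(c(1, 0, 0), c(0, 1, 0))
  kl <- coilgram:::kl_loss(Y, Tgt, valid = c(TRUE, TRUE))
  expect_gt(kl$loss, 0)
  kl0 <- coilgram:::kl_loss(Tgt, Tgt, valid = c(TRUE, TRUE))
  expect_equal(kl0$loss, 0, tolerance = 1e-9)
})

test_that("training fits a separable synthetic set and is deterministic", {
  d <- coil_simulate(synth_config(n_records = 16, length_range = c(30L, 50L),
                                  helices_per_record_range = c(1L, 1L),
                                  helix_length_range = c(8L, 20L),
                                  embed_dim = 8L, noise_sd = 0, seed = 13))
  fit <- train_stage1(build_stage1(tiny_cfg(), 8L), d, max_epochs = 50L)
  probs <- predict_stage1(fit, d$embedding)
  lab <- c(letters[1:7], "i")
  pred <- vapply(probs, function(P) {
    paste(lab[max.col(P, ties.method = "first")], collapse = "")
  }, character(1))
  f1 <- mean(vapply(seq_len(nrow(d)), function(k) {
    residue_scores(d$labels[k], pred[k])$f1
  }, numeric(1)))
  expect_gte(f1, 0.95)
  # argmax labels reproduce the training labels at >= 95% of positions
  acc <- mean(unlist(Map(function(p, t) {
    strsplit(p, "")[[1]] == strsplit(t, "")[[1]]
  }, pred, d$labels)))
  expect_gte(acc, 0.95)
  # identical data + seed => identical history and parameters
  fit2 <- train_stage1(build_stage1(tiny_cfg(), 8L), d, max_epochs = 50L)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model$params, fit2$model$params)
})

test_that("early stopping halts after the patience window and keeps the best checkpoint", {
  d <- coil_simulate(synth_config(n_records = 10, length_range = c(25L, 35L),
                                  embed_dim = 6L, noise_sd = 0.3, seed = 8))
  cfg <- tiny_cfg(early_stop_patience = 3L)
  fit <- train_stage1(build_stage1(cfg, 6L), d, max_epochs = 200L)
  h <- fit$history
  best <- which.min(h$val_loss)
  # ran at most patience epochs past the best epoch, and no further
  expect_lte(nrow(h), best + cfg$early_stop_patience)
  expect_equal(fit$model$best_epoch, best)
  expect_error(train_stage1(build_stage1(cfg, 6L), d[0, ]), "empty")
})

test_that("stage-1 gradients match finite differences", {
  set.seed(77)
  cfg <- stage1_config(window = 5L, n_filters = 5L, recurrent_units = 6L,
                       hidden = 4L, dropout = 0, seed = 3L)
  m <- build_stage1(cfg, 3L)
  batch <- coilgram:::make_seq_batch(
    list(matrix(rnorm(21), 7, 3), matrix(rnorm(12), 4, 3)),
    list(sample(1:8, 7, TRUE), sample(1:8, 4, TRUE)), 8L)
  lg <- coilgram:::stage1_loss_grad(m$params, batch, cfg, train = FALSE)
  for (nm in names(m$params)) {
    n <- length(m$params[[nm]])
    for (i in sample(n, min(3L, n))) {
      eps <- 1e-6
      up <- m$params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- m$params; dn[[nm]][i] <- dn[[nm]][i] - eps
      fd <- (coilgram:::stage1_loss_grad(up, batch, cfg, FALSE)$loss -
               coilgram:::stage1_loss_grad(dn, batch, cfg, FALSE)$loss) /
        (2 * eps)
      expect_equal(lg$grads[[nm]][i], fd, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("grid search ranks architectures by cross-validated residue F1", {
  d <- coil_simulate(synth_config(n_records = 12, length_range = c(25L, 40L),
                                  embed_dim = 6L, noise_sd = 0.2, seed = 31))
  gs <- stage1_grid_search(d, filters = c(4L, 8L), recurrent = 8L,
                           hidden = 6L, folds = 2L, max_epochs = 6L,
                           seed = 5L, window = 5L, dropout = 0,
                           batch_size = 4L, lr = 5e-3)
  expect_equal(nrow(gs$results), 2L)
  expect_true(all(diff(gs$results$mean_f1) <= 0))
  expect_s3_class(gs$best, "stage1_config")
  expect_equal(gs$best$n_filters, gs$results$filters[1])
})
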