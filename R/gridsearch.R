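# Cross-validation grid search over the architecture hyperparameters.
# Default grids are the full search sets of the method; pass reduced grids
# for desk-scale runs.

cv_folds <- function(n, folds, seed) {
  with_seed(seed, sample(rep_len(seq_len(folds), n)))
}

stage1_argmax_track <- function(P) {
  paste(stage1_label_order()[max.col(P, ties.method = "first")],
        collapse = "")
}

#' Grid search for the stage-1 architecture
#'
#' K-fold cross-validation over (filters, recurrent width, hidden units),
#' selecting the combination with the highest mean residue-level F1 of the
#' argmax labeling.
#'
#' @param data Tibble with `embedding` and `labels` columns.
#' @param filters,recurrent,hidden Grids to search.
#' @param folds Cross-validation folds.
#' @param max_epochs Stage-1 epoch cap per fit.
#' @param seed Integer seed (fold assignment and model init).
#' @param ... Passed to [stage1_config()] (e.g. `lr`, `batch_size`).
#' @return List with `results` (tibble: one row per combination, mean and
#'   sd of fold F1) and `best` (the winning `stage1_config`).
#' @export
stage1_grid_search <- function(data, filters = c(10L, 20L, 40L, 80L, 160L),
                               recurrent = c(32L, 64L, 128L, 256L),
                               hidden = c(12L, 32L, 64L, 128L, 256L),
                               folds = 10L, max_epochs = 20L, seed = 42L,
                               ...) {
  grid <- expand.grid(filters = filters, recurrent = recurrent,
                      hidden = hidden)
  fold <- cv_folds(nrow(data), folds, seed)
  D <- ncol(data$embedding[[1]])
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cfg <- stage1_config(n_filters = grid$filters[g],
                         recurrent_units = grid$recurrent[g],
                         hidden = grid$hidden[g], seed = seed, ...)
    f1 <- vapply(seq_len(folds), function(f) {
      tr <- data[fold != f, , drop = FALSE]
      te <- data[fold == f, , drop = FALSE]
      fit <- train_stage1(build_stage1(cfg, D), tr, max_epochs = max_epochs)
      probs <- predict_stage1(fit, te$embedding)
      pred <- vapply(probs, stage1_argmax_track, character(1))
      mean(vapply(seq_len(nrow(te)), function(k) {
        residue_scores(te$labels[k], pred[k])$f1
      }, numeric(1)))
    }, numeric(1))
    tibble(filters = grid$filters[g], recurrent = grid$recurrent[g],
           hidden = grid$hidden[g], mean_f1 = mean(f1), sd_f1 = sd(f1))
  })
  results <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$mean_f1))
  best <- stage1_config(n_filters = results$filters[1],
                        recurrent_units = results$recurrent[1],
                        hidden = results$hidden[1], seed = seed, ...)
  list(results = results, best = best)
}

#' Grid search for the oligomer-net hidden width
#'
#' K-fold cross-validation over the hidden-layer grid, selecting the width
#' maximizing the mean per-class MCC across the four oligomer states.
#'
#' @param x Pooled a/d input matrix (rows = helices).
#' @param class True classes.
#' @param hidden Grid of hidden widths.
#' @param folds Cross-validation folds.
#' @param epochs Training epochs per fit.
#' @param seed Integer seed.
#' @return List with `results` tibble and `best_hidden`.
#' @export
oligo_grid_search <- function(x, class, hidden = c(16L, 32L, 64L, 128L, 256L),
                              folds = 5L, epochs = 200L, seed = 42L) {
  fold <- cv_folds(nrow(x), folds, seed)
  rows <- lapply(hidden, function(h) {
    m <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      model <- train_oligo(build_oligo_net(ncol(x) / 2L, hidden = h,
                                           seed = seed),
                           x[tr, , drop = FALSE], class[tr], epochs = epochs)
      pred <- predict_oligo(model, x[!tr, , drop = FALSE])$class
      mean(per_class_mcc(class[!tr], pred)$mcc)
    }, numeric(1))
    tibble(hidden = h, mean_mcc = mean(m), sd_mcc = sd(m))
  })
  results <- dplyr::arrange(dplyr::bind_rows(rows),
                            dplyr::desc(.data$mean_mcc))
  list(results = results, best_hidden = results$hidden[1])
}

#' @importFrom stats sd
NULL
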