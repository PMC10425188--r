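# End-to-end pipeline: the three stages are trained separately (register
# scorer on embeddings, CRF on stage-1 probabilities, oligomer net on
# register-pooled embeddings) and chained at prediction time.

#' Train the full coiled-coil predictor
#'
#' Trains stage 1 (register scorer) on the embeddings, stage 2 (CRF) on
#' the stage-1 probability profiles, and stage 3 (oligomer-state net) on
#' a/d-pooled embeddings of the annotated helices.
#'
#' @param data Training tibble with `embedding`, `labels` and `helices`
#'   columns (as produced by [coil_simulate()], or assembled from files).
#' @param stage1 A [stage1_config()].
#' @param crf_iterations,crf_sigma2,crf_feature_window CRF training knobs.
#' @param oligo_hidden,oligo_epochs Oligomer-net knobs.
#' @param max_epochs Stage-1 epoch cap.
#' @param quiet Suppress progress messages.
#' @return A `coil_fit` object with elements `stage1`, `crf`, `oligo`.
#' @export
coil_fit <- function(data, stage1 = stage1_config(),
                     crf_iterations = 40L, crf_sigma2 = 0.05,
                     crf_feature_window = 1L,
                     oligo_hidden = 128L, oligo_epochs = 200L,
                     max_epochs = 50L, quiet = TRUE) {
  stopifnot(all(c("embedding", "labels", "helices") %in% names(data)))
  D <- ncol(data$embedding[[1]])
  log_step(quiet, "train stage1", n = nrow(data), input_dim = D,
           config_hash = config_hash(stage1))
  s1 <- train_stage1(build_stage1(stage1, D), data, max_epochs = max_epochs,
                     quiet = quiet)
  log_step(quiet, "train crf", sigma2 = crf_sigma2,
           iterations = crf_iterations)
  probs <- predict_stage1(s1, data$embedding)
  crf <- train_crf(crf_model(build_cc_automaton(), n_features = 8L,
                             feature_window = crf_feature_window,
                             sigma2 = crf_sigma2),
                   probs, data$labels, iterations = crf_iterations,
                   ids = data$id)
  log_step(quiet, "train oligo", hidden = oligo_hidden)
  pooled <- list(); classes <- character()
  for (k in seq_len(nrow(data))) {
    hx <- data$helices[[k]]
    for (j in seq_len(nrow(hx))) {
      v <- pool_ad(data$embedding[[k]], hx$start[j], hx$end[j],
                   hx$registers[j])
      if (!is.null(v)) {
        pooled[[length(pooled) + 1L]] <- v
        classes <- c(classes, hx$oligo_state[j])
      }
    }
  }
  if (!length(pooled)) abort("no annotated helices to train the oligomer stage")
  oligo <- train_oligo(build_oligo_net(D, hidden = oligo_hidden,
                                       seed = stage1$seed),
                       do.call(rbind, pooled), classes,
                       epochs = oligo_epochs)
  structure(list(stage1 = s1, crf = crf, oligo = oligo, input_dim = D),
            class = "coil_fit")
}

#' Predict coiled-coil domains, registers and oligomer states
#'
#' Runs the three stages in cascade on each record. Decoded helices
#' shorter than `min_helix` residues are relabeled to background when the
#' optional post-filter is enabled.
#'
#' @param fit A `coil_fit` (or a list with `stage1`, `crf`, `oligo`).
#' @param data Tibble with `id`, `sequence` and `embedding` columns.
#' @param min_helix Optional minimum decoded helix length (default NULL:
#'   report helices as decoded).
#' @return A `coil_prediction`: list of tibbles `residues` (one row per
#'   residue: `id`, `position`, `residue`, `cc_flag`, `register`,
#'   `cc_probability`, `segment_id`, `oligo_state`), `segments` (one row
#'   per predicted helix with oligomer probabilities and
#'   `mean_cc_probability`) and `proteins` (per-protein majority summary,
#'   derived from the segment calls).
#' @export
coil_predict <- function(fit, data, min_helix = NULL) {
  stopifnot(all(c("id", "sequence", "embedding") %in% names(data)))
  probs <- predict_stage1(fit$stage1, data$embedding)
  res_rows <- list(); seg_rows <- list()
  for (k in seq_len(nrow(data))) {
    dec <- posterior_viterbi(fit$crf, probs[[k]])
    lab <- label_chars(dec$labels)
    if (!is.null(min_helix)) {
      seg0 <- segments_from_track(dec$labels)
      drop <- seg0[seg0$end - seg0$start + 1L < min_helix, , drop = FALSE]
      for (j in seq_len(nrow(drop))) lab[drop$start[j]:drop$end[j]] <- "i"
    }
    segs <- segments_from_track(paste(lab, collapse = ""))
    seg_id <- rep("-", length(lab))
    oligo_st <- rep("-", length(lab))
    if (nrow(segs)) {
      segs$segment_id <- sprintf("%s_S%d", data$id[k], seq_len(nrow(segs)))
      segs$mean_cc_probability <- vapply(seq_len(nrow(segs)), function(j) {
        mean(dec$cc_probability[segs$start[j]:segs$end[j]])
      }, numeric(1))
      op <- matrix(NA_real_, nrow(segs), 4L,
                   dimnames = list(NULL, cc_oligo_states()))
      ocl <- rep(NA_character_, nrow(segs))
      for (j in seq_len(nrow(segs))) {
        v <- pool_ad(data$embedding[[k]], segs$start[j], segs$end[j],
                     segs$registers[j])
        if (!is.null(v)) {
          pr <- predict_oligo(fit$oligo, v)
          ocl[j] <- pr$class
          op[j, ] <- as.numeric(pr[1, cc_oligo_states()])
        }
        span <- segs$start[j]:segs$end[j]
        seg_id[span] <- segs$segment_id[j]
        oligo_st[span] <- ocl[j] %||% "-"
      }
      oligo_st[is.na(oligo_st)] <- "-"
      segs$oligo_state <- ocl
      segs <- dplyr::bind_cols(segs, as_tibble(as.data.frame(op)))
      segs$id <- data$id[k]
      seg_rows[[length(seg_rows) + 1L]] <- segs
    }
    res_rows[[k]] <- tibble(
      id = data$id[k],
      position = seq_along(lab),
      residue = label_chars(data$sequence[k]),
      cc_flag = as.integer(lab != "i"),
      register = ifelse(lab == "i", "-", lab),
      cc_probability = dec$cc_probability,
      segment_id = seg_id,
      oligo_state = ifelse(is.na(oligo_st), "-", oligo_st)
    )
  }
  segments <- if (length(seg_rows)) {
    dplyr::relocate(dplyr::bind_rows(seg_rows), "id", "segment_id")
  } else {
    tibble(id = character(), segment_id = character(), start = integer(),
           end = integer(), registers = character(),
           mean_cc_probability = numeric(), oligo_state = character())
  }
  proteins <- dplyr::summarise(
    dplyr::group_by(segments, .data$id),
    n_segments = dplyr::n(),
    majority_oligo_state = if (all(is.na(.data$oligo_state))) NA_character_
      else names(sort(table(.data$oligo_state), decreasing = TRUE))[1],
    .groups = "drop"
  )
  structure(list(residues = dplyr::bind_rows(res_rows), segments = segments,
                 proteins = proteins),
            class = "coil_prediction")
}

#' Evaluate a prediction against reference tracks
#'
#' @param prediction A `coil_prediction`.
#' @param truth Tibble with `id` and `labels`.
#' @return Long tibble of measures (see [evaluate_predictions()]).
#' @export
coil_evaluate <- function(prediction, truth) {
  pr <- prediction_tracks(prediction)
  evaluate_predictions(truth, pr)
}

#' Pair predicted oligomer states with annotated helices
#'
#' Matches each annotated helix to the predicted segment with the largest
#' overlap, keeping pairs whose overlap reaches half the annotated helix
#' length and that carry an oligomer call.
#'
#' @param prediction A `coil_prediction`.
#' @param data Tibble with `id` and `helices` (annotated spans with
#'   `oligo_state`).
#' @return Tibble with columns `id`, `observed`, `predicted`.
#' @export
oligo_state_comparison <- function(prediction, data) {
  rows <- list()
  for (k in seq_len(nrow(data))) {
    hx <- data$helices[[k]]
    seg <- prediction$segments[prediction$segments$id == data$id[k], ,
                               drop = FALSE]
    if (!nrow(seg) || !nrow(hx)) next
    for (j in seq_len(nrow(hx))) {
      ov <- pmin(seg$end, hx$end[j]) - pmax(seg$start, hx$start[j]) + 1L
      best <- which.max(ov)
      if (ov[best] >= (hx$end[j] - hx$start[j] + 1L) / 2 &&
            !is.na(seg$oligo_state[best])) {
        rows[[length(rows) + 1L]] <- tibble(
          id = data$id[k], observed = hx$oligo_state[j],
          predicted = seg$oligo_state[best])
      }
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(id = character(), observed = character(), predicted = character())
  }
}

# Per-sequence label tracks and probability vectors from a prediction.
prediction_tracks <- function(prediction) {
  r <- prediction$residues
  sp <- split(r, factor(r$id, levels = unique(r$id)))
  tibble(
    id = names(sp),
    labels = vapply(sp, function(d) {
      paste(ifelse(d$register == "-", "i", d$register), collapse = "")
    }, character(1)),
    cc_probability = lapply(sp, function(d) d$cc_probability)
  )
}

config_hash <- function(x) {
  v <- unlist(x, use.names = TRUE)
  sprintf("%08x", sum(utf8ToInt(paste(names(v), v, collapse = "|"))) %%
            .Machine$integer.max)
}

log_step <- function(quiet, step, ...) {
  if (quiet) return(invisible())
  kv <- list(...)
  message(sprintf("[coilgram] %s %s", step,
                  paste(names(kv), unlist(kv), sep = "=", collapse = " ")))
}
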