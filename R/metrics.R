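# Scoring: residue- and segment-level precision/recall/F1, the Zemla
# segment-overlap measures SOVo/SOVp, precision-recall AUC, Matthews
# correlation, and bootstrap significance testing. A residue counts as
# coiled-coil when its label is anything but "i" (registers and "x" alike).

as_label_vec <- function(x) {
  if (length(x) == 1L && nchar(x[1]) > 1L) label_chars(x) else as.character(x)
}

is_cc <- function(labels) as_label_vec(labels) != "i"

safe_div <- function(num, den) if (den > 0) num / den else 0

f1_of <- function(pre, rec) safe_div(2 * pre * rec, pre + rec)

#' Residue-level confusion counts for the coiled-coil class
#'
#' @param obs,pred Label tracks of equal length.
#' @return One-row tibble with `tp`, `fp`, `fn`, `tn`.
#' @export
residue_counts <- function(obs, pred) {
  o <- is_cc(obs); p <- is_cc(pred)
  if (length(o) != length(p)) abort("track length mismatch")
  tibble(tp = sum(o & p), fp = sum(!o & p), fn = sum(o & !p),
         tn = sum(!o & !p))
}

#' Residue-level precision, recall and F1
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic mean;
#' any 0/0 is reported as 0.
#'
#' @param obs,pred Label tracks of equal length (strings or character
#'   vectors); coiled-coil is any non-`i` label.
#' @return One-row tibble with `precision`, `recall`, `f1` and the counts.
#' @export
residue_scores <- function(obs, pred) {
  ct <- residue_counts(obs, pred)
  pre <- safe_div(ct$tp, ct$tp + ct$fp)
  rec <- safe_div(ct$tp, ct$tp + ct$fn)
  dplyr::bind_cols(tibble(precision = pre, recall = rec,
                          f1 = f1_of(pre, rec)), ct)
}

check_segments <- function(seg) {
  if (is.character(seg)) seg <- segments_from_track(seg)
  if (nrow(seg) > 1L) {
    ord <- order(seg$start)
    seg <- seg[ord, , drop = FALSE]
    if (any(seg$start[-1] <= seg$end[-nrow(seg)])) {
      abort("segments within a set must not overlap")
    }
  }
  seg
}

seg_overlap <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2) + 1L)
}

# Greedy left-to-right one-to-one matching under the half-length rule: a
# predicted segment is a true positive iff it overlaps a not-yet-consumed
# observed segment by at least half the length of the longer of the two
# (real-valued half; overlap 5 vs a length-9 segment passes, 5 >= 4.5).
match_segments <- function(obs, pred) {
  used <- rep(FALSE, nrow(obs))
  tp <- 0L
  for (k in seq_len(nrow(pred))) {
    lp <- pred$end[k] - pred$start[k] + 1L
    for (j in seq_len(nrow(obs))) {
      if (used[j]) next
      lo <- obs$end[j] - obs$start[j] + 1L
      ov <- seg_overlap(obs$start[j], obs$end[j], pred$start[k], pred$end[k])
      if (ov >= max(lo, lp) / 2) {
        used[j] <- TRUE
        tp <- tp + 1L
        break
      }
    }
  }
  list(tp = tp, fp = nrow(pred) - tp, fn = nrow(obs) - tp)
}

#' Segment-level precision, recall and F1 (half-length overlap rule)
#'
#' Segments are matched greedily in left-to-right order, each observed
#' segment consumable once; a prediction is correct only if its overlap
#' with the matched observed segment is at least half the length of the
#' longer of the two.
#'
#' @param obs,pred Label tracks or segment tibbles (`start`, `end`).
#' @return One-row tibble with `precision`, `recall`, `f1`, `tp`, `fp`,
#'   `fn`.
#' @export
segment_scores <- function(obs, pred) {
  m <- match_segments(check_segments(obs), check_segments(pred))
  pre <- safe_div(m$tp, m$tp + m$fp)
  rec <- safe_div(m$tp, m$tp + m$fn)
  tibble(precision = pre, recall = rec, f1 = f1_of(pre, rec),
         tp = m$tp, fp = m$fp, fn = m$fn)
}

# Per-sequence SOV accumulator: the summed pair terms and the normalizer N,
# additive over sequences. s1 = reference segments, s2 = the other set.
sov_parts <- function(ref, other) {
  ref <- check_segments(ref); other <- check_segments(other)
  num <- 0; N <- 0
  for (j in seq_len(nrow(ref))) {
    l1 <- ref$end[j] - ref$start[j] + 1L
    hit <- FALSE
    for (k in seq_len(nrow(other))) {
      l2 <- other$end[k] - other$start[k] + 1L
      minov <- seg_overlap(ref$start[j], ref$end[j],
                           other$start[k], other$end[k])
      if (minov == 0L) next
      hit <- TRUE
      maxov <- max(ref$end[j], other$end[k]) -
        min(ref$start[j], other$start[k]) + 1L
      delta <- min(maxov - minov, minov, floor(l1 / 2), floor(l2 / 2))
      num <- num + (minov + delta) / maxov * l1
      N <- N + l1
    }
    if (!hit) N <- N + l1
  }
  list(num = num, N = N)
}

#' Segment overlap score (SOV)
#'
#' The Zemla (1999) segment-overlap measure on the binary coiled-coil
#' labeling, restricted to the coiled-coil class, scaled to `[0, 100]`.
#' `reference = "observed"` gives SOVo, `"predicted"` gives SOVp (the roles
#' of the two segment sets are exchanged).
#'
#' @param obs,pred Label tracks of equal length.
#' @param reference Which track supplies the reference segments.
#' @return Numeric scalar in `[0, 100]`.
#' @export
sov <- function(obs, pred, reference = c("observed", "predicted")) {
  reference <- match.arg(reference)
  o <- as_label_vec(obs); p <- as_label_vec(pred)
  if (length(o) != length(p)) abort("track length mismatch")
  parts <- if (reference == "observed") sov_parts(obs, pred) else
    sov_parts(pred, obs)
  other_n <- if (reference == "observed") nrow(check_segments(pred)) else
    nrow(check_segments(obs))
  if (parts$N == 0) return(if (other_n == 0L) 100 else 0)
  100 * parts$num / parts$N
}

#' Area under the precision-recall curve
#'
#' Step interpolation over all distinct residue-level thresholds (average
#' precision): `sum_k (R_k - R_{k-1}) * P_k`.
#'
#' @param obs Binary vector (or label tracks; non-`i` = positive).
#' @param prob Per-residue coiled-coil probabilities in `[0, 1]`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
pr_auc <- function(obs, prob) {
  y <- if (is.character(obs)) {
    unlist(lapply(obs, function(t) is_cc(t)))
  } else {
    as.logical(obs)
  }
  prob <- unlist(prob)
  stopifnot(length(y) == length(prob), all(prob >= 0 & prob <= 1))
  np <- sum(y)
  if (np == 0L) return(0)
  ord <- order(prob, decreasing = TRUE)
  y <- y[ord]; prob <- prob[ord]
  cum_tp <- cumsum(y)
  cum_pp <- seq_along(y)
  last <- c(prob[-1] != prob[-length(prob)], TRUE)  # last index per threshold
  tp <- cum_tp[last]; pp <- cum_pp[last]
  rec <- tp / np
  pre <- tp / pp
  sum(diff(c(0, rec)) * pre)
}

#' Matthews correlation coefficient from a 2x2 confusion
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' when any factor of the denominator is 0.
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return Numeric scalar in `[-1, 1]`.
#' @export
mcc <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Per-register one-vs-rest MCC
#'
#' Computes the MCC of each register label `a`..`g` against all other
#' labels. Positions carrying `x` (register unassigned) in either track are
#' excluded, since they assert no register identity.
#'
#' @param obs,pred Label tracks of equal length.
#' @return Tibble with columns `register` and `mcc`.
#' @export
per_register_mcc <- function(obs, pred) {
  o <- as_label_vec(obs); p <- as_label_vec(pred)
  if (length(o) != length(p)) abort("track length mismatch")
  keep <- o != "x" & p != "x"
  o <- o[keep]; p <- p[keep]
  tibble(register = cc_registers(),
         mcc = vapply(cc_registers(), function(r) {
           mcc(tp = sum(o == r & p == r), tn = sum(o != r & p != r),
               fp = sum(o != r & p == r), fn = sum(o == r & p != r))
         }, numeric(1), USE.NAMES = FALSE))
}

#' Per-class MCC for oligomer-state predictions
#'
#' @param obs,pred Character vectors of classes from [cc_oligo_states()].
#' @return Tibble with columns `class` and `mcc`.
#' @export
per_class_mcc <- function(obs, pred) {
  stopifnot(length(obs) == length(pred))
  tibble(class = cc_oligo_states(),
         mcc = vapply(cc_oligo_states(), function(k) {
           mcc(tp = sum(obs == k & pred == k), tn = sum(obs != k & pred != k),
               fp = sum(obs != k & pred == k), fn = sum(obs == k & pred != k))
         }, numeric(1), USE.NAMES = FALSE))
}

# Pooled measures over a set of per-sequence (obs, pred) tracks; counts and
# SOV accumulators are additive over sequences.
pooled_measures <- function(obs, pred) {
  rc <- list(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  sc <- list(tp = 0L, fp = 0L, fn = 0L)
  so <- list(num = 0, N = 0); sp <- list(num = 0, N = 0)
  for (k in seq_along(obs)) {
    r <- residue_counts(obs[k], pred[k])
    rc <- Map(`+`, rc, r[1, c("tp", "fp", "fn", "tn")])
    os <- check_segments(obs[k]); ps <- check_segments(pred[k])
    m <- match_segments(os, ps)
    sc <- Map(`+`, sc, m)
    a <- sov_parts(os, ps); b <- sov_parts(ps, os)
    so <- list(num = so$num + a$num, N = so$N + a$N)
    sp <- list(num = sp$num + b$num, N = sp$N + b$N)
  }
  pre_r <- safe_div(rc$tp, rc$tp + rc$fp)
  rec_r <- safe_div(rc$tp, rc$tp + rc$fn)
  pre_s <- safe_div(sc$tp, sc$tp + sc$fp)
  rec_s <- safe_div(sc$tp, sc$tp + sc$fn)
  c(pre_r = pre_r, rec_r = rec_r, f1_r = f1_of(pre_r, rec_r),
    pre_s = pre_s, rec_s = rec_s, f1_s = f1_of(pre_s, rec_s),
    sov_o = if (so$N > 0) 100 * so$num / so$N else 100,
    sov_p = if (sp$N > 0) 100 * sp$num / sp$N else 100)
}

#' Bootstrap comparison of two methods with Welch's t-test
#'
#' Draws `n_samples` bootstrap samples of `sample_size` sequence ids (with
#' replacement), scores each sample for both methods with the pooled
#' residue- and segment-level measures, and runs a two-sided two-sample
#' Welch t-test per measure on the two score samples.
#'
#' @param results_a,results_b Tibbles with columns `id`, `obs`, `pred`
#'   (label tracks), covering the same id set.
#' @param n_samples Number of bootstrap samples (default 100).
#' @param sample_size Sequences per sample (default 300).
#' @param seed Integer seed.
#' @param replace Sample with replacement (default TRUE); when FALSE,
#'   `sample_size` must not exceed the population.
#' @return Tibble with one row per measure: means for both methods, mean
#'   difference (A - B), Welch `t` and `p`.
#' @export
bootstrap_compare <- function(results_a, results_b, n_samples = 100L,
                              sample_size = 300L, seed = 1L,
                              replace = TRUE) {
  if (!setequal(results_a$id, results_b$id)) {
    abort("the two result sets must cover the same sequence ids")
  }
  if (!replace && sample_size > nrow(results_a)) {
    abort("sample_size exceeds the population and replacement is disabled")
  }
  results_b <- results_b[match(results_a$id, results_b$id), , drop = FALSE]
  sa <- matrix(0, n_samples, 8L)
  sb <- matrix(0, n_samples, 8L)
  with_seed(seed, {
    for (s in seq_len(n_samples)) {
      ix <- sample(nrow(results_a), sample_size, replace = replace)
      sa[s, ] <- pooled_measures(results_a$obs[ix], results_a$pred[ix])
      sb[s, ] <- pooled_measures(results_b$obs[ix], results_b$pred[ix])
    }
  })
  measures <- c("pre_r", "rec_r", "f1_r", "pre_s", "rec_s", "f1_s",
                "sov_o", "sov_p")
  dplyr::bind_rows(lapply(seq_along(measures), function(j) {
    if (isTRUE(all.equal(sa[, j], sb[, j]))) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- t.test(sa[, j], sb[, j], var.equal = FALSE)
    }
    tibble(measure = measures[j], mean_a = mean(sa[, j]),
           mean_b = mean(sb[, j]), mean_diff = mean(sa[, j]) - mean(sb[, j]),
           t = unname(tt$statistic), p = tt$p.value)
  }))
}

#' Full evaluation report for a set of predictions
#'
#' Pools residue and segment counts over all sequences and reports every
#' scoring measure; when per-residue coiled-coil probabilities are given,
#' PR-AUC is included. Register MCCs are reported when both tracks carry
#' register detail.
#'
#' @param truth Tibble with `id` and `labels` (observed tracks).
#' @param pred Tibble with `id`, `labels` and optionally `cc_probability`
#'   (list-column of per-residue probabilities).
#' @return Long tibble with columns `measure` and `value`.
#' @export
evaluate_predictions <- function(truth, pred) {
  if (!setequal(truth$id, pred$id)) {
    abort("prediction and truth id sets differ")
  }
  pred <- pred[match(truth$id, pred$id), , drop = FALSE]
  pm <- pooled_measures(truth$labels, pred$labels)
  out <- tibble(measure = names(pm), value = unname(pm))
  if ("cc_probability" %in% names(pred)) {
    out <- dplyr::bind_rows(out, tibble(
      measure = "pr_auc",
      value = pr_auc(truth$labels, pred$cc_probability)
    ))
  }
  reg <- per_register_mcc(paste(truth$labels, collapse = ""),
                          paste(pred$labels, collapse = ""))
  dplyr::bind_rows(out, tibble(measure = paste0("mcc_", reg$register),
                               value = reg$mcc))
}
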