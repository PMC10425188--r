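# Independent oracles used to verify the package's dynamic programming and
# metric implementations. These deliberately use different formulations
# (explicit path enumeration, dense matrix semiring products, per-pair
# formula transliterations) from the implementations they check.

# Sum over all BEGIN -> END paths by explicit recursion (feasible L <= 6).
oracle_enum_logZ <- function(model, feats) {
  a <- model$automaton
  Phi <- coilgram:::crf_design(feats, model$feature_window)
  U <- Phi %*% t(model$node_w)
  L <- nrow(U)
  total <- 0
  rec <- function(s, t, acc) {
    if (t == L) {
      if (a$end[s]) total <<- total + exp(acc + model$end_w[s])
      return(invisible())
    }
    for (v in which(a$trans[s, ])) {
      rec(v, t + 1L, acc + model$trans_w[s, v] + U[t + 1L, v])
    }
  }
  for (s in which(a$begin)) rec(s, 1L, model$begin_w[s] + U[1L, s])
  log(total)
}

# Same sum via dense matrix products in plain probability space: the
# product over t of (A * psi_t) distributes the sum over every path.
oracle_semiring_logZ <- function(model, feats) {
  a <- model$automaton
  Phi <- coilgram:::crf_design(feats, model$feature_window)
  U <- Phi %*% t(model$node_w)
  A <- exp(model$trans_w) * a$trans
  v <- (exp(model$begin_w) * a$begin) * exp(U[1L, ])
  if (nrow(U) > 1L) {
    for (t in 2L:nrow(U)) v <- as.vector(v %*% A) * exp(U[t, ])
  }
  log(sum(v * exp(model$end_w) * a$end))
}

# Best BEGIN -> END path score over sum of per-position values (max-plus
# matrix recursion); used against posterior_viterbi's path score.
oracle_maxplus_best <- function(values, automaton) {
  a <- automaton
  L <- nrow(values)
  v <- ifelse(a$begin, values[1L, ], -Inf)
  if (L > 1L) {
    for (t in 2L:L) {
      v <- vapply(seq_along(v), function(s) {
        prev <- v[a$trans[, s]]
        if (!length(prev)) -Inf else max(prev) + values[t, s]
      }, numeric(1))
    }
  }
  max(ifelse(a$end, v, -Inf))
}

# Exhaustive-recursion best path score (feasible L <= 6).
oracle_enum_best <- function(values, automaton) {
  a <- automaton
  L <- nrow(values)
  best <- -Inf
  rec <- function(s, t, acc) {
    if (t == L) {
      if (a$end[s]) best <<- max(best, acc)
      return(invisible())
    }
    for (v in which(a$trans[s, ])) rec(v, t + 1L, acc + values[t + 1L, v])
  }
  for (s in which(a$begin)) rec(s, 1L, values[1L, s])
  best
}

# Zemla-style SOV written per-pair from the published formula.
oracle_sov <- function(ref_track, other_track) {
  segs <- function(tr) {
    v <- strsplit(tr, "")[[1]] != "i"
    r <- rle(v); e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    cbind(s[r$values], e[r$values])
  }
  S1 <- segs(ref_track); S2 <- segs(other_track)
  if (nrow(S1) == 0L) return(if (nrow(S2) == 0L) 100 else 0)
  total <- 0; N <- 0
  for (i in seq_len(nrow(S1))) {
    len1 <- S1[i, 2] - S1[i, 1] + 1L
    overlapped <- FALSE
    for (j in seq_len(nrow(S2))) {
      len2 <- S2[j, 2] - S2[j, 1] + 1L
      minov <- min(S1[i, 2], S2[j, 2]) - max(S1[i, 1], S2[j, 1]) + 1L
      if (minov <= 0L) next
      overlapped <- TRUE
      maxov <- max(S1[i, 2], S2[j, 2]) - min(S1[i, 1], S2[j, 1]) + 1L
      delta <- min(maxov - minov, minov, len1 %/% 2L, len2 %/% 2L)
      total <- total + (minov + delta) / maxov * len1
      N <- N + len1
    }
    if (!overlapped) N <- N + len1
  }
  100 * total / N
}

# PR-AUC by explicit threshold sweep.
oracle_pr_auc <- function(y, prob) {
  th <- sort(unique(prob), decreasing = TRUE)
  pre <- numeric(length(th)); rec <- numeric(length(th))
  for (k in seq_along(th)) {
    p <- prob >= th[k]
    pre[k] <- if (sum(p)) sum(y & p) / sum(p) else 0
    rec[k] <- sum(y & p) / sum(y)
  }
  sum(diff(c(0, rec)) * pre)
}

# Random grammar-valid label track built from explicit helix placement.
random_track <- function(L, max_helices = 3L) {
  lab <- rep("i", L)
  n <- sample(0:max_helices, 1L)
  pos <- 1L
  for (k in seq_len(n)) {
    if (pos + 9L > L) break
    start <- pos + sample(0:2, 1L)
    len <- sample(8:min(14L, L - start + 1L), 1L)
    phase <- sample(7L, 1L)
    lab[start:(start + len - 1L)] <-
      letters[1:7][(phase + seq_len(len) - 2L) %% 7L + 1L]
    pos <- start + len + 1L
  }
  paste(lab, collapse = "")
}

# CRF model with random weights (seeded by the caller).
random_crf <- function(sd = 0.5, feature_window = 1L) {
  m <- crf_model(feature_window = feature_window)
  a <- m$automaton
  m$node_w[] <- rnorm(length(m$node_w), sd = sd)
  m$trans_w[a$trans] <- rnorm(sum(a$trans), sd = sd)
  m$begin_w[a$begin] <- rnorm(sum(a$begin), sd = sd)
  m$end_w[a$end] <- rnorm(sum(a$end), sd = sd)
  m
}
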