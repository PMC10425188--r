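# Grammar-constrained hidden CRF over the 20-state coiled-coil automaton.
#
# Emitting states (fixed order, used everywhere for tie-breaking):
#   i0, i1, 1a..1g, 1H, 2a..2g, 2H        (18 states)
# plus non-emitting BEGIN and END. i-states emit label "i", register states
# emit their register, H-states are wildcards that match any register label
# and are reported as "x" on decoding. The first block models the first
# coiled-coil helix of a protein, the second block all later ones; i0 is
# the N-terminal background, i1 the background between/after helices.

#' Build the 20-state coiled-coil automaton
#'
#' States: BEGIN, END, two self-looping background states `i0`/`i1`, and
#' two identical 8-state helix blocks `1a..1g,1H` and `2a..2g,2H`. Within a
#' block the only register-to-register edge follows the heptad cycle
#' (a->b->...->g->a); the wildcard H state is entered from any register and
#' exits to any register, absorbing a single irregular position per
#' excursion (no self-loop unless `h_self_loop = TRUE`). Paths start in
#' `i0` or any block-1 register and every state except `1H`/`2H` may end
#' the sequence. Block entry is allowed at any register phase.
#'
#' @param h_self_loop Allow H states to loop on themselves.
#' @return A `cc_automaton` object.
#' @export
build_cc_automaton <- function(h_self_loop = FALSE) {
  regs <- cc_registers()
  emitting <- c("i0", "i1",
                paste0("1", c(regs, "H")),
                paste0("2", c(regs, "H")))
  S <- length(emitting)
  label_of <- setNames(c("i", "i", regs, "*", regs, "*"), emitting)
  idx <- function(nm) match(nm, emitting)
  trans <- matrix(FALSE, S, S, dimnames = list(emitting, emitting))
  add <- function(from, to) trans[idx(from), idx(to)] <<- TRUE
  for (k in c("1", "2")) {
    kr <- paste0(k, regs)
    kH <- paste0(k, "H")
    for (r in seq_along(regs)) {
      nxt <- kr[if (r == length(regs)) 1L else r + 1L]
      add(kr[r], nxt)          # heptad cycle
      add(kr[r], kH)           # irregular position
      add(kH, kr[r])           # resume at any register
      add(kr[r], "i1")         # leave the helix
    }
    if (h_self_loop) add(kH, kH)
  }
  add("i0", "i0")
  for (r in paste0("1", regs)) add("i0", r)
  add("i1", "i1")
  for (r in paste0("2", regs)) add("i1", r)
  begin <- setNames(emitting %in% c("i0", paste0("1", regs)), emitting)
  end <- setNames(!emitting %in% c("1H", "2H"), emitting)
  structure(list(states = c("BEGIN", "END", emitting), emitting = emitting,
                 label_of = label_of, trans = trans, begin = begin,
                 end = end, h_self_loop = h_self_loop),
            class = "cc_automaton")
}

#' All allowed transitions of an automaton as an edge list
#'
#' Includes the BEGIN-> and ->END edges.
#'
#' @param automaton A `cc_automaton`.
#' @return Tibble with columns `from` and `to`.
#' @export
automaton_edges <- function(automaton) {
  ix <- which(automaton$trans, arr.ind = TRUE)
  em <- automaton$emitting
  dplyr::arrange(
    dplyr::bind_rows(
      tibble(from = "BEGIN", to = em[automaton$begin]),
      tibble(from = em[ix[, 1]], to = em[ix[, 2]]),
      tibble(from = em[automaton$end], to = "END")
    ),
    .data$from, .data$to
  )
}

# Logical matrix: which emitting states may sit under each label character.
state_match <- function(automaton, lab) {
  wild <- automaton$label_of == "*"
  vapply(lab, function(l) {
    if (l == "i") automaton$label_of == "i"
    else if (l == "x") wild
    else automaton$label_of == l | wild
  }, logical(length(automaton$emitting)))
}

#' Is a label track generable by the automaton?
#'
#' True iff some BEGIN -> ... -> END state path emits exactly this label
#' sequence (wildcard H states match any register label).
#'
#' @param labels Label string or character vector.
#' @param automaton A `cc_automaton` (default: [build_cc_automaton()]).
#' @return Logical scalar.
#' @export
is_valid_label_path <- function(labels, automaton = build_cc_automaton()) {
  lab <- if (length(labels) == 1L && nchar(labels[1]) > 1L) {
    label_chars(labels)
  } else {
    as.character(labels)
  }
  if (!length(lab)) return(FALSE)
  if (!all(lab %in% cc_labels())) return(FALSE)
  M <- state_match(automaton, lab)
  reach <- automaton$begin & M[, 1]
  if (length(lab) > 1L) {
    for (t in 2L:length(lab)) {
      if (!any(reach)) return(FALSE)
      reach <- (colSums(automaton$trans[reach, , drop = FALSE]) > 0) & M[, t]
    }
  }
  any(reach & automaton$end)
}

#' Create an (untrained) CRF model
#'
#' Node potentials are linear in the stage-1 label probabilities observed
#' at offsets within `feature_window` of each position (plus a per-state
#' bias); transition, start and end potentials are free weights on the
#' allowed automaton edges. Weights start at zero; the training objective
#' is concave so the start point only affects the optimizer path.
#'
#' @param automaton A `cc_automaton`.
#' @param n_features Per-position feature count (8 stage-1 probabilities).
#' @param feature_window Odd window of feature offsets feeding each
#'   position's node potential.
#' @param sigma2 Gaussian-prior variance of the L2 penalty `|w|^2/(2*sigma2)`.
#' @return A `crf_model` object.
#' @export
crf_model <- function(automaton = build_cc_automaton(), n_features = 8L,
                      feature_window = 1L, sigma2 = 0.05) {
  if (feature_window %% 2L == 0L) abort("feature_window must be odd")
  S <- length(automaton$emitting)
  P <- n_features * feature_window + 1L  # + bias
  structure(list(automaton = automaton,
                 n_features = as.integer(n_features),
                 feature_window = as.integer(feature_window),
                 sigma2 = sigma2,
                 node_w = matrix(0, S, P),
                 trans_w = matrix(0, S, S),
                 begin_w = numeric(S),
                 end_w = numeric(S)),
            class = "crf_model")
}

# Windowed design matrix: row t holds the features at offsets
# -(w-1)/2 .. +(w-1)/2 around t (zero-padded), then a bias 1.
crf_design <- function(features, feature_window) {
  L <- nrow(features)
  hw <- (feature_window - 1L) %/% 2L
  cols <- lapply(-hw:hw, function(o) {
    M <- matrix(0, L, ncol(features))
    src <- seq_len(L) + o
    ok <- src >= 1L & src <= L
    M[ok, ] <- features[src[ok], , drop = FALSE]
    M
  })
  cbind(do.call(cbind, cols), 1)
}

# Scaled-space forward-backward on one sequence. `allow` (L x S logical)
# optionally clamps the lattice to states compatible with a label track.
# Returns per-position posteriors, pairwise transition expectations, and
# the log partition function.
crf_fb <- function(model, Phi, allow = NULL, want_pair = TRUE) {
  a <- model$automaton
  S <- length(a$emitting)
  L <- nrow(Phi)
  U <- Phi %*% t(model$node_w)           # L x S node potentials
  shift <- apply(U, 1L, max)
  psi <- exp(U - shift)
  if (!is.null(allow)) psi <- psi * allow
  A <- exp(model$trans_w) * a$trans
  pi0 <- exp(model$begin_w) * a$begin
  tau <- exp(model$end_w) * a$end
  alpha <- matrix(0, L, S)
  logc <- numeric(L)
  v <- pi0 * psi[1L, ]
  c1 <- sum(v)
  if (c1 <= 0) abort("no valid path through the lattice")
  alpha[1L, ] <- v / c1
  logc[1L] <- log(c1)
  if (L > 1L) {
    for (t in 2L:L) {
      v <- (alpha[t - 1L, ] %*% A) * psi[t, ]
      ct <- sum(v)
      if (ct <= 0) abort("no valid path through the lattice")
      alpha[t, ] <- v / ct
      logc[t] <- log(ct)
    }
  }
  enddot <- sum(alpha[L, ] * tau)
  if (enddot <= 0) abort("no valid path through the lattice")
  logZ <- sum(logc) + log(enddot) + sum(shift)
  beta <- matrix(0, L, S)
  beta[L, ] <- tau / sum(tau)
  if (L > 1L) {
    for (t in (L - 1L):1L) {
      v <- A %*% (psi[t + 1L, ] * beta[t + 1L, ])
      beta[t, ] <- v / sum(v)
    }
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  pair <- NULL
  E_begin <- post[1L, ]
  E_end <- post[L, ]
  if (want_pair && L > 1L) {
    pair <- matrix(0, S, S)
    for (t in 2L:L) {
      xi <- outer(alpha[t - 1L, ], psi[t, ] * beta[t, ]) * A
      pair <- pair + xi / sum(xi)
    }
  }
  list(post = post, logZ = logZ, pair = pair, E_begin = E_begin,
       E_end = E_end)
}

#' Forward-backward posteriors and log partition function
#'
#' @param model A `crf_model`.
#' @param features L x n_features matrix (stage-1 label probabilities).
#' @return List with `posterior` (L x 18 matrix, rows summing to 1, columns
#'   named by emitting state) and `log_partition`.
#' @export
forward_backward <- function(model, features) {
  Phi <- crf_design(features, model$feature_window)
  fb <- crf_fb(model, Phi, want_pair = FALSE)
  colnames(fb$post) <- model$automaton$emitting
  list(posterior = fb$post, log_partition = fb$logZ)
}

crf_pack <- function(model) {
  a <- model$automaton
  c(as.vector(model$node_w), model$trans_w[a$trans],
    model$begin_w[a$begin], model$end_w[a$end])
}

crf_unpack <- function(model, w) {
  a <- model$automaton
  S <- length(a$emitting)
  P <- ncol(model$node_w)
  n1 <- S * P
  model$node_w <- matrix(w[seq_len(n1)], S, P)
  off <- n1
  ne <- sum(a$trans)
  model$trans_w[a$trans] <- w[off + seq_len(ne)]; off <- off + ne
  nb <- sum(a$begin)
  model$begin_w[a$begin] <- w[off + seq_len(nb)]; off <- off + nb
  model$end_w[a$end] <- w[off + seq_len(sum(a$end))]
  model
}

#' Train the CRF on (feature matrix, label track) pairs
#'
#' Maximizes the penalized conditional log-likelihood
#' `sum log P(labels | features) - |w|^2 / (2*sigma2)` by L-BFGS. The
#' gradient is the difference between feature expectations over the
#' clamped lattice (state paths consistent with the labels; H wildcards
#' free over registers) and the free lattice. Every training track must be
#' generable by the automaton.
#'
#' @param model A `crf_model`.
#' @param features List of L x n_features matrices.
#' @param tracks Character vector of label tracks (same length/order).
#' @param iterations L-BFGS iteration budget.
#' @param sigma2 Optional override of the model's prior variance.
#' @param ids Optional record ids used in error messages.
#' @return The trained `crf_model` (with `objective`, the final penalized
#'   log-likelihood, attached).
#' @export
train_crf <- function(model, features, tracks, iterations = 40L,
                      sigma2 = NULL, ids = NULL) {
  stopifnot(inherits(model, "crf_model"), length(features) == length(tracks))
  if (!is.null(sigma2)) model$sigma2 <- sigma2
  if (is.null(ids)) ids <- as.character(seq_along(tracks))
  a <- model$automaton
  ok <- vapply(tracks, is_valid_label_path, logical(1), automaton = a)
  if (!all(ok)) {
    abort(sprintf("grammar-invalid training track(s): %s",
                  paste(ids[!ok], collapse = ", ")))
  }
  Phis <- lapply(features, crf_design, feature_window = model$feature_window)
  allows <- lapply(tracks, function(tr) t(state_match(a, label_chars(tr))))
  cache <- new.env(parent = emptyenv())
  evaluate <- function(w) {
    full <- digest_num(w)
    if (!is.null(cache$full) && identical(cache$full, full)) {
      return(list(obj = cache$obj, grad = cache$grad))
    }
    m <- crf_unpack(model, w)
    S <- length(a$emitting)
    gn <- matrix(0, S, ncol(m$node_w))
    gt <- matrix(0, S, S)
    gb <- numeric(S); ge <- numeric(S)
    obj <- 0
    for (k in seq_along(Phis)) {
      fr <- crf_fb(m, Phis[[k]])
      cl <- crf_fb(m, Phis[[k]], allow = allows[[k]])
      obj <- obj + cl$logZ - fr$logZ
      dpost <- cl$post - fr$post
      gn <- gn + crossprod(dpost, Phis[[k]])
      if (!is.null(fr$pair)) gt <- gt + cl$pair - fr$pair
      gb <- gb + cl$E_begin - fr$E_begin
      ge <- ge + cl$E_end - fr$E_end
    }
    obj <- obj - sum(w^2) / (2 * m$sigma2)
    grad <- c(as.vector(gn), gt[a$trans], gb[a$begin], ge[a$end]) -
      w / m$sigma2
    cache$full <- full; cache$obj <- obj; cache$grad <- grad
    list(obj = obj, grad = grad)
  }
  w0 <- crf_pack(model)
  opt <- optim(w0,
               fn = function(w) -evaluate(w)$obj,
               gr = function(w) -evaluate(w)$grad,
               method = "L-BFGS-B",
               control = list(maxit = as.integer(iterations)))
  model <- crf_unpack(model, opt$par)
  model$objective <- -opt$value
  model
}

digest_num <- function(w) sum(w * seq_along(w)) + sum(w^2)

#' Posterior-Viterbi decoding
#'
#' Computes per-position state posteriors by forward-backward, then the
#' grammar-valid BEGIN -> END path maximizing the sum of log posteriors
#' (ties broken toward the lowest state index). H states are emitted as
#' label `x`; the per-residue coiled-coil probability is the summed
#' posterior of all non-`i` states.
#'
#' @param model A trained `crf_model`.
#' @param features L x n_features matrix.
#' @return List with `states` (state-name vector), `labels` (label string),
#'   `cc_probability` (numeric vector), `path_score` (sum of log
#'   posteriors) and `posterior` (L x 18 matrix).
#' @export
posterior_viterbi <- function(model, features) {
  a <- model$automaton
  fb <- forward_backward(model, features)
  post <- fb$posterior
  L <- nrow(post); S <- ncol(post)
  lp <- log(pmax(post, 1e-300))
  V <- matrix(-Inf, L, S)
  bp <- matrix(0L, L, S)
  V[1L, a$begin] <- lp[1L, a$begin]
  if (L > 1L) {
    for (t in 2L:L) {
      for (s in seq_len(S)) {
        prev <- which(a$trans[, s])
        if (!length(prev)) next
        sc <- V[t - 1L, prev]
        j <- which.max(sc)
        if (sc[j] > -Inf) {
          V[t, s] <- sc[j] + lp[t, s]
          bp[t, s] <- prev[j]
        }
      }
    }
  }
  fin <- ifelse(a$end, V[L, ], -Inf)
  s <- which.max(fin)
  path <- integer(L)
  path[L] <- s
  if (L > 1L) for (t in L:2L) path[t - 1L] <- bp[t, path[t]]
  lab <- model$automaton$label_of[path]
  lab[lab == "*"] <- "x"
  cc <- rowSums(post[, a$label_of != "i", drop = FALSE])
  list(states = a$emitting[path], labels = paste(lab, collapse = ""),
       cc_probability = unname(cc), path_score = max(fin),
       posterior = post)
}

# ---- text serialization ----------------------------------------------------

#' Write a CRF model to a human-diffable text file
#'
#' Sections: header (sigma2, feature window, H self-loop flag), the
#' automaton edge list, the state/label map, and the weight tables.
#'
#' @param model A `crf_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crf_model <- function(model, path) {
  a <- model$automaton
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# coilgram CRF model")
  wl("sigma2\t%.17g", model$sigma2)
  wl("feature_window\t%d", model$feature_window)
  wl("n_features\t%d", model$n_features)
  wl("h_self_loop\t%d", as.integer(a$h_self_loop))
  wl("[labels]")
  for (s in a$emitting) wl("%s\t%s", s, a$label_of[[s]])
  wl("[edges]")
  ed <- automaton_edges(a)
  for (k in seq_len(nrow(ed))) wl("%s\t%s", ed$from[k], ed$to[k])
  wl("[node_weights]")
  for (si in seq_along(a$emitting)) {
    wl("%s\t%s", a$emitting[si],
       paste(format(model$node_w[si, ], digits = 17), collapse = "\t"))
  }
  wl("[transition_weights]")
  ix <- which(a$trans, arr.ind = TRUE)
  for (k in seq_len(nrow(ix))) {
    wl("%s\t%s\t%.17g", a$emitting[ix[k, 1]], a$emitting[ix[k, 2]],
       model$trans_w[ix[k, 1], ix[k, 2]])
  }
  wl("[begin_weights]")
  for (s in which(a$begin)) wl("%s\t%.17g", a$emitting[s], model$begin_w[s])
  wl("[end_weights]")
  for (s in which(a$end)) wl("%s\t%.17g", a$emitting[s], model$end_w[s])
  invisible(path)
}

#' Read a CRF model written by [write_crf_model()]
#'
#' @param path Path to the model file.
#' @return A `crf_model`.
#' @export
read_crf_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  kv <- function(key) {
    ln <- grep(paste0("^", key, "\t"), lines, value = TRUE)[1]
    strsplit(ln, "\t", fixed = TRUE)[[1]][2]
  }
  h_self <- as.integer(kv("h_self_loop")) == 1L
  model <- crf_model(build_cc_automaton(h_self_loop = h_self),
                     n_features = as.integer(kv("n_features")),
                     feature_window = as.integer(kv("feature_window")),
                     sigma2 = as.numeric(kv("sigma2")))
  a <- model$automaton
  sect <- function(name) {
    i0 <- match(paste0("[", name, "]"), lines)
    rest <- lines[-seq_len(i0)]
    nxt <- grep("^\\[", rest)
    if (length(nxt)) rest[seq_len(nxt[1] - 1L)] else rest
  }
  for (ln in sect("node_weights")) {
    p <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    model$node_w[match(p[1], a$emitting), ] <- as.numeric(p[-1])
  }
  for (ln in sect("transition_weights")) {
    p <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    model$trans_w[match(p[1], a$emitting), match(p[2], a$emitting)] <-
      as.numeric(p[3])
  }
  for (ln in sect("begin_weights")) {
    p <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    model$begin_w[match(p[1], a$emitting)] <- as.numeric(p[2])
  }
  for (ln in sect("end_weights")) {
    p <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    model$end_w[match(p[1], a$emitting)] <- as.numeric(p[2])
  }
  model
}
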