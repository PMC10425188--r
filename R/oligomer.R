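# Oligomerization-state classification. The interface between helices in a
# coiled coil is formed by the hydrophobic a/d registers, so the classifier
# sees only the embedding rows at (predicted) a and d positions of a helix:
# their two means, concatenated, feed a single-hidden-layer network over
# the four classes.

#' Pool embedding rows at a/d registers of one helix
#'
#' Averages the embedding rows at `a`-labeled positions and, separately, at
#' `d`-labeled positions of the segment, and concatenates the two means.
#' `x` positions (register unassigned) never contribute.
#'
#' @param emb L x D embedding matrix for the whole protein.
#' @param start,end 1-based inclusive helix span.
#' @param registers Label slice for the span (string or character vector).
#' @return Numeric vector of length 2D, or NULL (with a warning) when the
#'   segment has no `a` or no `d` position.
#' @export
pool_ad <- function(emb, start, end, registers) {
  reg <- if (length(registers) == 1L && nchar(registers[1]) > 1L) {
    label_chars(registers)
  } else {
    as.character(registers)
  }
  stopifnot(length(reg) == end - start + 1L, start >= 1L, end <= nrow(emb))
  rows <- emb[start:end, , drop = FALSE]
  ia <- reg == "a"
  id <- reg == "d"
  if (!any(ia) || !any(id)) {
    warn(sprintf("degenerate segment [%d,%d]: no '%s' position; oligomer state unset",
                 start, end, if (any(ia)) "d" else "a"))
    return(NULL)
  }
  c(colMeans(rows[ia, , drop = FALSE]), colMeans(rows[id, , drop = FALSE]))
}

#' Build an untrained oligomer-state network
#'
#' Feed-forward net `2D -> hidden -> 4` with softmax output over the
#' classes of [cc_oligo_states()].
#'
#' @param input_dim Embedding dimension D (the input is 2D).
#' @param hidden Hidden-layer width (default 128).
#' @param seed Integer seed for Glorot initialization.
#' @return An `oligo_model` object.
#' @export
build_oligo_net <- function(input_dim, hidden = 128L, seed = 42L) {
  stopifnot(input_dim > 0, hidden > 0)
  D2 <- 2L * as.integer(input_dim)
  params <- with_seed(seed, list(
    W1 = glorot(D2, hidden), b1 = numeric(hidden),
    W2 = glorot(hidden, 4L), b2 = numeric(4L)
  ))
  structure(list(params = params, input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden), seed = as.integer(seed),
                 class_order = cc_oligo_states()),
            class = "oligo_model")
}

oligo_forward <- function(params, X) {
  Z1 <- dense_forward(X, params$W1, params$b1)
  A1 <- relu(Z1)
  Z2 <- dense_forward(A1, params$W2, params$b2)
  E <- exp(Z2 - apply(Z2, 1L, max))
  list(Y = E / rowSums(E), A1 = A1, Z1 = Z1)
}

#' Train the oligomer-state network
#'
#' Full-batch cross-entropy minimization with Adam; deterministic given the
#' model's seed.
#'
#' @param model An `oligo_model`.
#' @param x Matrix of pooled a/d input vectors (rows = helices, 2D columns).
#' @param class Character vector of true classes (subset of
#'   [cc_oligo_states()]).
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @return The trained `oligo_model` with a `history` tibble attached.
#' @export
train_oligo <- function(model, x, class, epochs = 200L, lr = 5e-3) {
  stopifnot(inherits(model, "oligo_model"))
  x <- as.matrix(x)
  if (nrow(x) == 0L) abort("training set is empty")
  ci <- match(class, model$class_order)
  if (anyNA(ci)) abort("unknown oligomer class label")
  if (length(unique(ci)) < 2L) {
    abort("training set contains a single class; at least two are required")
  }
  Tgt <- matrix(0, nrow(x), 4L)
  Tgt[cbind(seq_len(nrow(x)), ci)] <- 1
  params <- model$params
  st <- adam_init(params)
  hist <- numeric(epochs)
  n <- nrow(x)
  for (ep in seq_len(epochs)) {
    fwd <- oligo_forward(params, x)
    loss <- -sum(Tgt * log(pmax(fwd$Y, 1e-12))) / n
    dZ2 <- (fwd$Y - Tgt) / n
    d2 <- dense_backward(dZ2, fwd$A1, params$W2)
    dZ1 <- d2$dM * (fwd$Z1 > 0)
    d1 <- dense_backward(dZ1, x, params$W1)
    up <- adam_step(params, list(W1 = d1$dW, b1 = d1$db,
                                 W2 = d2$dW, b2 = d2$db), st, lr = lr)
    params <- up$params; st <- up$state
    hist[ep] <- loss
  }
  model$params <- params
  model$history <- tibble(epoch = seq_len(epochs), train_loss = hist)
  model
}

#' Predict oligomerization states
#'
#' @param model A trained `oligo_model`.
#' @param x A single input vector or a matrix of rows.
#' @return Tibble with `class` and the four per-class probability columns;
#'   ties resolve to the earlier class in [cc_oligo_states()] order.
#' @export
predict_oligo <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != 2L * model$input_dim) {
    abort(sprintf("input has %d columns; expected %d", ncol(x),
                  2L * model$input_dim))
  }
  Y <- oligo_forward(model$params, x)$Y
  cls <- model$class_order[apply(Y, 1L, which.max)]
  out <- as_tibble(as.data.frame(Y))
  names(out) <- model$class_order
  dplyr::bind_cols(tibble(class = cls), out)
}
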