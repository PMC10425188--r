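# Stage 1: per-residue register scoring. A convolutional layer (sliding
# window over the sequence) feeds a bidirectional LSTM, then a per-position
# feed-forward head maps to a probability distribution over the 8 labels
# (registers a-g plus i). Trained by minimizing the Kullback-Leibler
# divergence to one-hot targets with Adam and early stopping.

#' Stage-1 model configuration
#'
#' Defaults are the selected hyperparameters of the method: a 15-residue
#' convolution window with 40 filters, a recurrent layer with 128 output
#' units per position (bidirectional, 64 per direction), a 64-unit hidden
#' dense layer, dropout 0.25 between blocks, KL-divergence loss under Adam,
#' and early stopping with patience 10.
#'
#' @param window Odd convolution window length in residues.
#' @param n_filters Number of convolution filters.
#' @param recurrent_units Total recurrent output width per position (split
#'   across the two directions); must be even.
#' @param hidden Hidden units of the per-position dense head.
#' @param n_labels Output labels (8: registers a-g plus i).
#' @param dropout Dropout rate between blocks, in `[0, 1)`.
#' @param output_activation `"sigmoid_norm"` (sigmoid then row
#'   renormalization, the default reading of the architecture) or
#'   `"softmax"`.
#' @param early_stop_patience Epochs without validation improvement before
#'   training stops.
#' @param lr Adam learning rate.
#' @param batch_size Sequences per minibatch (padded with a mask).
#' @param val_fraction Fraction of records held out for validation when no
#'   explicit validation set is supplied.
#' @param seed Integer seed controlling initialization, the validation
#'   split, shuffling and dropout.
#' @return A `stage1_config` list.
#' @export
stage1_config <- function(window = 15L, n_filters = 40L,
                          recurrent_units = 128L, hidden = 64L,
                          n_labels = 8L, dropout = 0.25,
                          output_activation = c("sigmoid_norm", "softmax"),
                          early_stop_patience = 10L, lr = 2e-3,
                          batch_size = 16L, val_fraction = 0.1,
                          seed = 42L) {
  if (window %% 2L == 0L) abort("window must be odd")
  if (recurrent_units %% 2L != 0L) abort("recurrent_units must be even")
  stopifnot(n_filters > 0, hidden > 0, n_labels > 0,
            dropout >= 0, dropout < 1)
  structure(list(window = as.integer(window),
                 n_filters = as.integer(n_filters),
                 recurrent_units = as.integer(recurrent_units),
                 hidden = as.integer(hidden),
                 n_labels = as.integer(n_labels),
                 dropout = dropout,
                 output_activation = match.arg(output_activation),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr = lr, batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "stage1_config")
}

stage1_label_order <- function() c(cc_registers(), "i")

#' Build an untrained stage-1 model
#'
#' Parameter initialization is Glorot-uniform, seeded from
#' `config$seed`, with the LSTM forget-gate bias started at 1.
#'
#' @param config A [stage1_config()].
#' @param input_dim Embedding feature dimension D.
#' @return A `stage1_model` object.
#' @export
build_stage1 <- function(config, input_dim) {
  stopifnot(inherits(config, "stage1_config"), input_dim > 0)
  D <- as.integer(input_dim)
  Fn <- config$n_filters
  H <- config$recurrent_units %/% 2L
  hid <- config$hidden
  K <- config$n_labels
  w <- config$window
  params <- with_seed(config$seed, {
    p <- list(
      conv.W = glorot(w * D, Fn, dims = c(w, D, Fn)),
      conv.b = numeric(Fn),
      lf.Wx = glorot(Fn, 4L * H), lf.Wh = glorot(H, 4L * H),
      lf.b = rep(c(0, 1, 0, 0), each = H),
      lb.Wx = glorot(Fn, 4L * H), lb.Wh = glorot(H, 4L * H),
      lb.b = rep(c(0, 1, 0, 0), each = H),
      fc1.W = glorot(2L * H, hid), fc1.b = numeric(hid),
      fc2.W = glorot(hid, K), fc2.b = numeric(K)
    )
    p
  })
  structure(list(params = params, config = config, input_dim = D,
                 label_order = stage1_label_order()),
            class = "stage1_model")
}

# Pad a list of L_i x D embedding matrices (and optional label-index
# vectors) into batch arrays with a validity mask.
make_seq_batch <- function(embs, lab_idx = NULL, n_labels = 8L) {
  B <- length(embs)
  lens <- vapply(embs, nrow, 0L)
  T <- max(lens)
  D <- ncol(embs[[1]])
  X <- array(0, dim = c(B, T, D))
  mask <- matrix(0, B, T)
  for (b in seq_len(B)) {
    X[b, seq_len(lens[b]), ] <- embs[[b]]
    mask[b, seq_len(lens[b])] <- 1
  }
  Tgt <- NULL
  valid <- as.vector(mask) > 0
  if (!is.null(lab_idx)) {
    Tm <- matrix(0, B * T, n_labels)
    vv <- matrix(FALSE, B, T)
    for (b in seq_len(B)) {
      li <- lab_idx[[b]]
      ok <- which(!is.na(li))
      Tm[(ok - 1L) * B + b, ] <- 0
      Tm[cbind((ok - 1L) * B + b, li[ok])] <- 1
      vv[b, ok] <- TRUE
    }
    Tgt <- Tm
    valid <- as.vector(vv)
  }
  list(X = X, mask = mask, Tgt = Tgt, valid = valid, B = B, T = T,
       lens = lens)
}

# Full forward pass; returns probabilities and (optionally) every cache
# needed for backprop. Dropout masks are drawn from the current RNG when
# train = TRUE.
stage1_forward <- function(params, X, mask, config, train = FALSE) {
  B <- dim(X)[1]; T <- dim(X)[2]
  H <- config$recurrent_units %/% 2L
  cv <- conv1d_forward(X, params$conv.W, params$conv.b)
  A1 <- relu(cv$out)
  dm1 <- if (train) dropout_mask(dim(A1), config$dropout) else NULL
  A1d <- if (is.null(dm1)) A1 else A1 * dm1
  lf <- lstm_forward(A1d, mask, params$lf.Wx, params$lf.Wh, params$lf.b,
                     reverse = FALSE)
  lb <- lstm_forward(A1d, mask, params$lb.Wx, params$lb.Wh, params$lb.b,
                     reverse = TRUE)
  A2 <- array(0, dim = c(B, T, 2L * H))
  A2[, , seq_len(H)] <- lf$out
  A2[, , H + seq_len(H)] <- lb$out
  dm2 <- if (train) dropout_mask(dim(A2), config$dropout) else NULL
  A2d <- if (is.null(dm2)) A2 else A2 * dm2
  M2 <- flat_bt(A2d)
  Z1 <- dense_forward(M2, params$fc1.W, params$fc1.b)
  A3 <- relu(Z1)
  Z2 <- dense_forward(A3, params$fc2.W, params$fc2.b)
  act <- out_activation_forward(Z2, config$output_activation)
  list(Y = act$Y, act = act, cv = cv, A1 = A1, dm1 = dm1, A1d = A1d,
       lf = lf, lb = lb, dm2 = dm2, M2 = M2, Z1 = Z1, A3 = A3, B = B,
       T = T)
}

stage1_backward <- function(params, fwd, dY, config) {
  B <- fwd$B; T <- fwd$T
  H <- config$recurrent_units %/% 2L
  dZ2 <- out_activation_backward(dY, fwd$Y, fwd$act, config$output_activation)
  d2 <- dense_backward(dZ2, fwd$A3, params$fc2.W)
  dZ1 <- d2$dM * (fwd$Z1 > 0)
  d1 <- dense_backward(dZ1, fwd$M2, params$fc1.W)
  dA2 <- unflat_bt(d1$dM, B, T)
  if (!is.null(fwd$dm2)) dA2 <- dA2 * fwd$dm2
  blf <- lstm_backward(dA2[, , seq_len(H), drop = FALSE], fwd$lf,
                       params$lf.Wx, params$lf.Wh)
  blb <- lstm_backward(dA2[, , H + seq_len(H), drop = FALSE], fwd$lb,
                       params$lb.Wx, params$lb.Wh)
  dA1 <- blf$dX + blb$dX
  if (!is.null(fwd$dm1)) dA1 <- dA1 * fwd$dm1
  dA1 <- dA1 * (fwd$cv$out > 0)
  bc <- conv1d_backward(dA1, fwd$cv, params$conv.W)
  list(conv.W = bc$dW, conv.b = bc$db,
       lf.Wx = blf$dWx, lf.Wh = blf$dWh, lf.b = blf$db,
       lb.Wx = blb$dWx, lb.Wh = blb$dWh, lb.b = blb$db,
       fc1.W = d1$dW, fc1.b = d1$db,
       fc2.W = d2$dW, fc2.b = d2$db)
}

stage1_loss_grad <- function(params, batch, config, train = TRUE) {
  fwd <- stage1_forward(params, batch$X, batch$mask, config, train = train)
  kl <- kl_loss(fwd$Y, batch$Tgt, batch$valid)
  grads <- stage1_backward(params, fwd, kl$dY, config)
  list(loss = kl$loss, grads = grads)
}

stage1_eval_loss <- function(params, batch, config) {
  fwd <- stage1_forward(params, batch$X, batch$mask, config, train = FALSE)
  kl_loss(fwd$Y, batch$Tgt, batch$valid)$loss
}

labels_to_idx <- function(labels, order = stage1_label_order()) {
  match(label_chars(labels), order)
}

#' Train a stage-1 model
#'
#' Minimizes the KL divergence between one-hot register targets and the
#' predicted distributions with Adam. Sequences are padded per minibatch
#' with a mask; masked positions (and any residue whose label is outside
#' the 8-label training alphabet) are excluded from the loss. The model
#' with minimal validation loss is returned; training stops once the
#' validation loss has not improved for `early_stop_patience` epochs.
#'
#' @param model A `stage1_model` from [build_stage1()].
#' @param data Training tibble with `embedding` and `labels` columns.
#' @param val Optional validation tibble of the same shape; when NULL a
#'   seeded fraction `config$val_fraction` of `data` is held out.
#' @param max_epochs Maximum number of epochs.
#' @param quiet Suppress per-epoch progress.
#' @return A `stage1_fit` with elements `model` (best checkpoint) and
#'   `history` (tibble of per-epoch train/validation loss).
#' @export
train_stage1 <- function(model, data, val = NULL, max_epochs = 50L,
                         quiet = TRUE) {
  stopifnot(inherits(model, "stage1_model"))
  if (nrow(data) == 0L) abort("training set is empty")
  config <- model$config
  with_seed(config$seed + 1L, {
    if (is.null(val)) {
      n_val <- max(1L, round(config$val_fraction * nrow(data)))
      if (nrow(data) < 2L) abort("need at least 2 records to hold out validation")
      vi <- sample(nrow(data), n_val)
      val <- data[vi, , drop = FALSE]
      data <- data[-vi, , drop = FALSE]
    }
    tr_idx <- lapply(data$labels, labels_to_idx)
    va_batch <- make_seq_batch(val$embedding, lapply(val$labels, labels_to_idx),
                               config$n_labels)
    params <- model$params
    st <- adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    hist <- list()
    bad <- 0L
    n <- nrow(data)
    for (epoch in seq_len(max_epochs)) {
      ord <- sample(n)
      tl <- 0; tn <- 0
      for (s in seq(1L, n, by = config$batch_size)) {
        ix <- ord[s:min(s + config$batch_size - 1L, n)]
        batch <- make_seq_batch(data$embedding[ix], tr_idx[ix], config$n_labels)
        lg <- stage1_loss_grad(params, batch, config, train = TRUE)
        up <- adam_step(params, lg$grads, st, lr = config$lr)
        params <- up$params; st <- up$state
        tl <- tl + lg$loss * sum(batch$valid); tn <- tn + sum(batch$valid)
      }
      vl <- stage1_eval_loss(params, va_batch, config)
      hist[[epoch]] <- tibble(epoch = epoch, train_loss = tl / tn,
                              val_loss = vl)
      if (!quiet) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, tl / tn, vl))
      }
      if (vl < best$loss - 1e-12) {
        best <- list(loss = vl, params = params, epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= config$early_stop_patience) break
      }
    }
    model$params <- best$params
    model$best_epoch <- best$epoch
    structure(list(model = model, history = dplyr::bind_rows(hist)),
              class = "stage1_fit")
  })
}

#' Per-residue label probabilities from a stage-1 model
#'
#' @param model A `stage1_model` (or `stage1_fit`).
#' @param embs A single L x D matrix or a list of them.
#' @return For a single matrix, an L x 8 matrix whose rows sum to 1 (columns
#'   in label order a-g, i); for a list, a list of such matrices.
#' @export
predict_stage1 <- function(model, embs) {
  if (inherits(model, "stage1_fit")) model <- model$model
  single <- is.matrix(embs)
  if (single) embs <- list(embs)
  if (ncol(embs[[1]]) != model$input_dim) {
    abort(sprintf("embedding dimension %d does not match model input %d",
                  ncol(embs[[1]]), model$input_dim))
  }
  config <- model$config
  out <- vector("list", length(embs))
  for (s in seq(1L, length(embs), by = 64L)) {
    ix <- s:min(s + 63L, length(embs))
    batch <- make_seq_batch(embs[ix])
    fwd <- stage1_forward(model$params, batch$X, batch$mask, config,
                          train = FALSE)
    Y <- fwd$Y
    for (j in seq_along(ix)) {
      rows <- (seq_len(batch$lens[j]) - 1L) * batch$B + j
      P <- Y[rows, , drop = FALSE]
      colnames(P) <- model$label_order
      out[[ix[j]]] <- P
    }
  }
  if (single) out[[1]] else out
}
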