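# broom-style tidiers for the fitted objects.

#' @export
tidy.stage1_fit <- function(x, ...) x$history

#' @export
glance.stage1_fit <- function(x, ...) {
  tibble(epochs_run = nrow(x$history),
         best_epoch = x$model$best_epoch,
         best_val_loss = min(x$history$val_loss),
         final_train_loss = x$history$train_loss[nrow(x$history)])
}

#' @export
tidy.crf_model <- function(x, ...) {
  a <- x$automaton
  em <- a$emitting
  hw <- (x$feature_window - 1L) %/% 2L
  offs <- rep(-hw:hw, each = x$n_features)
  feat <- rep(c(cc_registers(), "i"), x$feature_window)
  node <- dplyr::bind_rows(lapply(seq_along(em), function(s) {
    tibble(term = c(sprintf("node[%s, p(%s) @%+d]", em[s], feat, offs),
                    sprintf("node[%s, bias]", em[s])),
           weight = x$node_w[s, ])
  }))
  ix <- which(a$trans, arr.ind = TRUE)
  dplyr::bind_rows(
    node,
    tibble(term = sprintf("trans[%s -> %s]", em[ix[, 1]], em[ix[, 2]]),
           weight = x$trans_w[a$trans]),
    tibble(term = sprintf("begin[%s]", em[a$begin]),
           weight = x$begin_w[a$begin]),
    tibble(term = sprintf("end[%s]", em[a$end]),
           weight = x$end_w[a$end])
  )
}

#' @export
glance.crf_model <- function(x, ...) {
  a <- x$automaton
  tibble(n_states = length(a$states),
         n_edges = nrow(automaton_edges(a)),
         sigma2 = x$sigma2,
         feature_window = x$feature_window,
         objective = x$objective %||% NA_real_)
}

#' @export
tidy.oligo_model <- function(x, ...) {
  x$history %||% tibble(epoch = integer(), train_loss = numeric())
}

#' @export
glance.oligo_model <- function(x, ...) {
  tibble(hidden = x$hidden, input_dim = 2L * x$input_dim,
         n_classes = length(x$class_order),
         final_train_loss = if (!is.null(x$history)) {
           x$history$train_loss[nrow(x$history)]
         } else NA_real_)
}

#' @export
tidy.coil_prediction <- function(x, ...) x$residues

#' @export
glance.coil_prediction <- function(x, ...) {
  tibble(n_proteins = length(unique(x$residues$id)),
         n_segments = nrow(x$segments),
         cc_residue_fraction = mean(x$residues$cc_flag),
         mean_cc_probability = mean(x$residues$cc_probability))
}

#' @export
print.coil_prediction <- function(x, ...) {
  cat(sprintf("<coil_prediction: %d proteins, %d predicted helices>\n",
              length(unique(x$residues$id)), nrow(x$segments)))
  print(x$segments, ...)
  invisible(x)
}

#' @export
print.cc_automaton <- function(x, ...) {
  cat(sprintf("<cc_automaton: %d states, %d edges%s>\n", length(x$states),
              nrow(automaton_edges(x)),
              if (x$h_self_loop) ", H self-loop" else ""))
  invisible(x)
}
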