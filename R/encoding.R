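# Pluggable per-residue encoders. A real deployment would feed precomputed
# protein language model embeddings (e.g. 1024-dim ProtT5-style plus
# 1280-dim ESM2-style matrices, concatenated to 2304 features per residue)
# through the file-backed encoder; the one-hot and mock encoders make the
# whole pipeline exercisable without any external model.

#' One-hot encode a protein sequence
#'
#' Each residue maps to a 21-column indicator row (20 amino acids plus X);
#' X encodes to the all-zero row so unknown residues carry no signal.
#'
#' @param sequence Amino-acid string over [cc_amino_acids()].
#' @return L x 21 numeric matrix.
#' @export
encode_onehot <- function(sequence) {
  ch <- label_chars(sequence)
  aa <- cc_amino_acids()
  idx <- match(ch, aa)
  if (anyNA(idx)) {
    abort(sprintf("illegal residue character(s): %s",
                  paste(unique(ch[is.na(idx)]), collapse = ",")))
  }
  m <- matrix(0, nrow = length(ch), ncol = length(aa),
              dimnames = list(NULL, aa))
  keep <- aa[idx] != "X"
  m[cbind(which(keep), idx[keep])] <- 1
  m[, seq_along(aa), drop = FALSE]
}

#' Label-conditioned Gaussian mock embedding
#'
#' A stand-in for language-model embeddings used in tests and synthetic
#' benchmarks: row t is the profile mean vector of the residue's true label
#' plus isotropic Gaussian noise. Deterministic given `seed`.
#'
#' @param labels Per-residue label string (or character vector).
#' @param profile Named list or matrix mapping each label to a mean vector;
#'   a matrix must have one row per label (rownames = labels).
#' @param noise_sd Standard deviation of the additive noise.
#' @param seed Integer seed.
#' @return L x D numeric matrix.
#' @export
encode_mock <- function(labels, profile, noise_sd = 0, seed = 1L) {
  lab <- if (length(labels) == 1L && nchar(labels[1]) > 1L) {
    label_chars(labels)
  } else {
    as.character(labels)
  }
  if (is.matrix(profile)) {
    profile <- setNames(lapply(seq_len(nrow(profile)), function(k) profile[k, ]),
                        rownames(profile))
  }
  missing <- setdiff(unique(lab), names(profile))
  if (length(missing)) {
    abort(sprintf("profile is missing label(s): %s",
                  paste(missing, collapse = ",")))
  }
  mu <- do.call(rbind, profile[lab])
  if (noise_sd > 0) {
    mu <- mu + with_seed(seed, matrix(rnorm(length(mu), sd = noise_sd),
                                      nrow = nrow(mu)))
  }
  unname(mu)
}

#' Concatenate two per-residue embedding matrices
#'
#' Column order is (first encoder's columns, then the second's); combining a
#' 1024- and a 1280-dimensional encoder yields 2304 features per residue.
#'
#' @param e1,e2 Numeric matrices with equal row counts.
#' @return Matrix with `ncol(e1) + ncol(e2)` columns.
#' @export
concat_embeddings <- function(e1, e2) {
  if (nrow(e1) != nrow(e2)) {
    abort(sprintf("row count mismatch: %d vs %d", nrow(e1), nrow(e2)))
  }
  cbind(unname(e1), unname(e2))
}

#' Attach embeddings to a dataset
#'
#' Adds (or replaces) an `embedding` list-column. `encoder` selects the
#' source: `"onehot"`, or a directory path holding per-id `.emb`/`.tsv`
#' files written by [write_embedding()]. Row counts are checked against
#' sequence lengths at assembly.
#'
#' @param data Dataset tibble with `id` and `sequence`.
#' @param encoder `"onehot"` or an embedding directory path.
#' @return `data` with an `embedding` list-column.
#' @export
add_embeddings <- function(data, encoder = "onehot") {
  emb <- if (identical(encoder, "onehot")) {
    lapply(data$sequence, encode_onehot)
  } else {
    lapply(data$id, function(id) load_embedding(encoder, id))
  }
  bad <- which(vapply(emb, nrow, 0L) != nchar(data$sequence))
  if (length(bad)) {
    abort(sprintf("embedding row count does not match sequence length for: %s",
                  paste(data$id[bad], collapse = ",")))
  }
  data$embedding <- emb
  data
}

# Run code with a temporary RNG state seeded at `seed`; restores the
# caller's RNG so library calls never perturb user-level randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
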