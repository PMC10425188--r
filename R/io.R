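# File formats: FASTA sequences, two-line label files, per-id embedding
# directories (text .tsv or binary .emb), and model checkpoints.

#' Read protein sequences from a FASTA file
#'
#' The id of each record is the header token up to the first whitespace.
#'
#' @param path Path to a FASTA file (standard dialect, multi-line records).
#' @return Tibble with columns `id` and `sequence` (uppercased).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  tibble(id = unname(ids), sequence = unname(toupper(as.character(set))))
}

#' Write sequences to a FASTA file
#'
#' @param data Tibble with `id` and `sequence` columns.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(data))) {
    writeLines(paste0(">", data$id[k]), con)
    s <- data$sequence[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a per-residue label file
#'
#' The format mirrors the sequence/label pairing the models train on: two
#' lines per record, a `>id` header followed by the label string (same
#' length as the corresponding sequence).
#'
#' @param path Path to the label file.
#' @return Tibble with columns `id` and `labels`.
#' @export
read_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!all(hdr == rep(c(TRUE, FALSE), length.out = length(lines)))) {
    abort("malformed label file: expected alternating '>id' and label lines")
  }
  tibble(
    id = sub("\\s.*$", "", sub("^>", "", lines[hdr])),
    labels = lines[!hdr]
  )
}

#' Write a per-residue label file
#'
#' @param data Tibble with `id` and `labels` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(data))) {
    writeLines(c(paste0(">", data$id[k]), data$labels[k]), con)
  }
  invisible(path)
}

# ---- embedding directories -------------------------------------------------
# Layout: <dir>/<id>.emb (binary: two little-endian int32 giving rows and
# columns, then row-major float32 values) or <dir>/<id>.tsv (one row per
# residue, tab-separated floats). Loaders are auto-detected by extension;
# .emb wins when both exist.

#' Write one embedding matrix into an embedding directory
#'
#' @param emb Numeric matrix, rows = residues.
#' @param dir Directory (created if needed).
#' @param id Sequence id; becomes the file stem.
#' @param format `"emb"` (binary float32) or `"tsv"` (text).
#' @return The file path, invisibly.
#' @export
write_embedding <- function(emb, dir, id, format = c("emb", "tsv")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(id, ".", format))
  if (format == "emb") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.integer(dim(emb)), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(emb)), con, size = 4L, endian = "little")
  } else {
    write.table(emb, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Load one embedding matrix from an embedding directory
#'
#' @param dir Embedding directory.
#' @param id Sequence id to load.
#' @return Numeric matrix (rows = residues).
#' @export
load_embedding <- function(dir, id) {
  bin <- file.path(dir, paste0(id, ".emb"))
  txt <- file.path(dir, paste0(id, ".tsv"))
  if (file.exists(bin)) {
    con <- file(bin, "rb")
    on.exit(close(con))
    dm <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
    vals <- readBin(con, "numeric", n = dm[1] * dm[2], size = 4L,
                    endian = "little")
    matrix(vals, nrow = dm[1], ncol = dm[2], byrow = TRUE)
  } else if (file.exists(txt)) {
    m <- as.matrix(read.table(txt, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    m
  } else {
    abort(sprintf("no embedding found for id '%s' in %s", id, dir))
  }
}

# ---- checkpoints -----------------------------------------------------------

#' Save a fitted model checkpoint
#'
#' Single-file serialization of parameters, configuration and label/class
#' order. Used for stage-1 and oligomer-state models.
#'
#' @param model A fitted model object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint path.
#' @param label_order If non-NULL, the label (or class) order the caller
#'   expects; a mismatch with the stored order is an error.
#' @return The model object.
#' @export
load_checkpoint <- function(path, label_order = NULL) {
  model <- readRDS(path)
  if (!is.null(label_order)) {
    stored <- model$label_order %||% model$class_order %||%
      model$model$label_order
    if (!identical(stored, label_order)) {
      abort("checkpoint label order does not match the expected order")
    }
  }
  model
}
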