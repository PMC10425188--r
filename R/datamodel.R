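# Label alphabet and coordinate conventions
#
# Per-residue labels: the seven heptad registers "a".."g", "i" for residues
# outside any coiled-coil helix, and "x" for in-helix residues whose register
# could not be assigned (produced only by decoding, never by training data).
# Segments are 1-based inclusive [start, end] spans, the R/Bioconductor
# convention; the same convention is used in all serialized output.

#' Heptad register labels
#'
#' @return Character vector `c("a", ..., "g")`, the seven register positions
#'   of the canonical heptad repeat.
#' @export
cc_registers <- function() letters[1:7]

#' Full per-residue label alphabet
#'
#' Registers `a`--`g`, `i` (non-coiled-coil) and `x` (in-helix, register
#' unassigned; only ever produced by decoding).
#'
#' @return Character vector of length 9.
#' @export
cc_labels <- function() c(cc_registers(), "i", "x")

#' Oligomerization-state class labels
#'
#' The four states distinguished by the classifier, in the fixed order used
#' for probability vectors and tie-breaking.
#'
#' @return Character vector of length 4.
#' @export
cc_oligo_states <- function() {
  c("parallel_dimer", "antiparallel_dimer", "trimer", "tetramer")
}

#' Amino-acid alphabet (20 residues plus X for unknown)
#' @return Character vector of length 21; X is last.
#' @export
cc_amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q",
    "R", "S", "T", "V", "W", "Y", "X")
}

label_chars <- function(labels) strsplit(labels, "", fixed = TRUE)[[1]]

#' Extract coiled-coil segments from a per-residue label track
#'
#' A segment is a maximal run of non-`i` labels. Coordinates are 1-based
#' inclusive.
#'
#' @param labels Label string (or character vector of single characters) over
#'   the alphabet of [cc_labels()].
#' @return A tibble with columns `start`, `end` (1-based inclusive) and
#'   `registers` (the label slice for the span, as a string).
#' @export
#' @examples
#' segments_from_track("iiabcdefgii")
segments_from_track <- function(labels) {
  lab <- if (length(labels) == 1L && nchar(labels[1]) > 1L) {
    label_chars(labels)
  } else {
    as.character(labels)
  }
  cc <- lab != "i"
  if (!any(cc)) {
    return(tibble(start = integer(), end = integer(), registers = character()))
  }
  r <- rle(cc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(
    start = starts[keep],
    end = ends[keep],
    registers = vapply(which(keep), function(k) {
      paste(lab[starts[k]:ends[k]], collapse = "")
    }, character(1))
  )
}

#' Rebuild a label track from a set of segments
#'
#' Inverse of [segments_from_track()] for non-overlapping, sorted segments:
#' positions outside every segment get label `i`.
#'
#' @param segments Data frame with `start`, `end` (1-based inclusive) and
#'   `registers` columns.
#' @param length Total sequence length.
#' @return Label string of length `length`.
#' @export
track_from_segments <- function(segments, length) {
  lab <- rep("i", length)
  if (nrow(segments)) {
    if (any(segments$start < 1L | segments$end > length |
              segments$start > segments$end)) {
      abort("segment coordinates out of range")
    }
    ord <- order(segments$start)
    segments <- segments[ord, , drop = FALSE]
    if (nrow(segments) > 1L &&
          any(segments$start[-1] <= segments$end[-nrow(segments)])) {
      abort("segments overlap")
    }
    for (k in seq_len(nrow(segments))) {
      reg <- label_chars(segments$registers[k])
      span <- segments$start[k]:segments$end[k]
      if (length(reg) != length(span)) {
        abort("register slice length does not match segment span")
      }
      lab[span] <- reg
    }
  }
  paste(lab, collapse = "")
}

#' Validate a coiled-coil dataset
#'
#' Checks each record for an empty or illegal-character sequence, a
#' non-unique id, and (when a `labels` column is present) label/sequence
#' length agreement, illegal label characters, and `x` labels outside
#' helices. Violations are reported, never raised.
#'
#' @param data Tibble with columns `id`, `sequence` and optionally `labels`.
#' @return A tibble of violations with columns `id`, `type`, `message`;
#'   zero rows iff the dataset is consistent.
#' @export
validate_cc_data <- function(data) {
  stopifnot(is.data.frame(data), all(c("id", "sequence") %in% names(data)))
  out <- list()
  add <- function(id, type, message) {
    out[[length(out) + 1L]] <<- tibble(id = id, type = type, message = message)
  }
  dup <- unique(data$id[duplicated(data$id)])
  for (d in dup) add(d, "duplicate_id", "id appears more than once")
  aa <- cc_amino_acids()
  has_labels <- "labels" %in% names(data)
  for (k in seq_len(nrow(data))) {
    id <- data$id[k]
    seq <- data$sequence[k]
    if (is.na(id) || !nzchar(id)) add(sprintf("<row %d>", k), "empty_id", "id is empty")
    if (is.na(seq) || !nzchar(seq)) {
      add(id, "empty_sequence", "sequence has length 0")
      next
    }
    ch <- label_chars(seq)
    bad <- setdiff(unique(ch), aa)
    if (length(bad)) {
      add(id, "illegal_character",
          sprintf("illegal sequence character(s): %s", paste(bad, collapse = ",")))
    }
    if (has_labels && !is.na(data$labels[k])) {
      lab <- data$labels[k]
      if (nchar(lab) != nchar(seq)) {
        add(id, "length_mismatch",
            sprintf("labels length %d != sequence length %d", nchar(lab), nchar(seq)))
      }
      lch <- label_chars(lab)
      badl <- setdiff(unique(lch), cc_labels())
      if (length(badl)) {
        add(id, "illegal_label",
            sprintf("illegal label character(s): %s", paste(badl, collapse = ",")))
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble(id = character(), type = character(), message = character())
  }
}

#' Apply the training-set filters
#'
#' Keeps records whose length lies in `[min_len, max_len]` and, within kept
#' records, relabels helices (maximal non-`i` runs) shorter than `min_helix`
#' residues to `i`. The operation is idempotent and does not modify its
#' input.
#'
#' @param data Dataset tibble with `id`, `sequence` and `labels` columns.
#' @param min_len,max_len Protein length bounds (defaults 25 and 700).
#' @param min_helix Minimum helix length in residues (default 8).
#' @return The filtered dataset tibble.
#' @export
filter_training_data <- function(data, min_len = 25L, max_len = 700L,
                                 min_helix = 8L) {
  if (min_len > max_len) abort("min_len must not exceed max_len")
  stopifnot("labels" %in% names(data))
  len <- nchar(data$sequence)
  keep <- len >= min_len & len <= max_len
  out <- data[keep, , drop = FALSE]
  out$labels <- vapply(seq_len(nrow(out)), function(k) {
    seg <- segments_from_track(out$labels[k])
    seg <- seg[seg$end - seg$start + 1L >= min_helix, , drop = FALSE]
    track_from_segments(seg, nchar(out$sequence[k]))
  }, character(1))
  out
}
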