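# Synthetic benchmark generator: sequences with planted heptad helices
# (hydrophobic-biased a/d positions in a polar-biased background), register
# tracks, per-helix oligomer classes, and label-conditioned Gaussian
# embeddings in which the class signal lives only in the a/d rows --
# mirroring the biophysical observation that the oligomer state is carried
# by the hydrophobic interface residues.

HYDROPHOBIC <- c("L", "I", "V", "M", "F", "A")

#' Synthetic dataset configuration
#'
#' @param n_records Number of proteins.
#' @param length_range Protein length bounds (uniform draw).
#' @param helix_length_range Helix length bounds; the minimum must be >= 8,
#'   matching the training-set filter.
#' @param helices_per_record_range Bounds on helices per protein.
#' @param hydrophobic_ad_prob Probability that an a/d position carries one
#'   of L,I,V,M,F,A.
#' @param embed_dim Embedding feature dimension.
#' @param class_sep Norm scale of the label means and of the per-class
#'   offsets added to a/d rows (larger = easier).
#' @param noise_sd Per-component sd of the additive embedding noise.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_records = 200L, length_range = c(60L, 160L),
                         helix_length_range = c(8L, 60L),
                         helices_per_record_range = c(0L, 4L),
                         hydrophobic_ad_prob = 0.8, embed_dim = 32L,
                         class_sep = 3, noise_sd = 1, seed = 1L) {
  if (helix_length_range[1] < 8L) abort("minimum helix length must be >= 8")
  stopifnot(n_records > 0, length_range[1] <= length_range[2],
            helix_length_range[1] <= helix_length_range[2],
            helices_per_record_range[1] <= helices_per_record_range[2],
            hydrophobic_ad_prob >= 0, hydrophobic_ad_prob <= 1,
            embed_dim > 0, noise_sd >= 0)
  structure(list(n_records = as.integer(n_records),
                 length_range = as.integer(length_range),
                 helix_length_range = as.integer(helix_length_range),
                 helices_per_record_range = as.integer(helices_per_record_range),
                 hydrophobic_ad_prob = hydrophobic_ad_prob,
                 embed_dim = as.integer(embed_dim),
                 class_sep = class_sep, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Background residue distribution: uniform over the 20 letters with the
# hydrophobics down-weighted x0.5, renormalized -- keeps the coiled-coil
# signal in the register structure rather than composition alone.
background_probs <- function() {
  aa <- setdiff(cc_amino_acids(), "X")
  w <- setNames(rep(1, length(aa)), aa)
  w[HYDROPHOBIC] <- 0.5
  w / sum(w)
}

# Label/class mean vectors: one mean per label (a-g, i); additionally one
# offset per oligomer class, added only to a/d rows of helices of that
# class. All scaled so the expected mean norm equals class_sep.
synth_profile <- function(config) {
  with_seed(config$seed * 7L + 3L, {
    d <- config$embed_dim
    labs <- c(cc_registers(), "i")
    mu <- lapply(labs, function(l) rnorm(d, sd = config$class_sep / sqrt(d)))
    names(mu) <- labs
    off <- lapply(cc_oligo_states(), function(k) {
      rnorm(d, sd = config$class_sep / sqrt(d))
    })
    names(off) <- cc_oligo_states()
    list(label_mu = mu, class_offset = off)
  })
}

place_helices <- function(L, n, hl_range) {
  if (n == 0L) return(integer(0))
  if (n * hl_range[1] + (n - 1L) > L) {
    abort(sprintf("config infeasible: %d helices of length >= %d cannot fit in %d residues",
                  n, hl_range[1], L))
  }
  lens <- integer(n)
  budget <- L - (n - 1L)
  for (k in seq_len(n)) {
    hi <- min(hl_range[2], budget - (n - k) * hl_range[1])
    lens[k] <- sample(hl_range[1]:hi, 1L)
    budget <- budget - lens[k]
  }
  # budget now = total background; split across n+1 gaps (inner gaps get
  # one extra separator residue below)
  gaps <- diff(c(0L, sort(c(sample(0:budget, n, replace = TRUE), budget))))
  starts <- integer(n)
  pos <- 0L
  for (k in seq_len(n)) {
    pos <- pos + gaps[k] + (if (k > 1L) 1L else 0L)
    starts[k] <- pos + 1L
    pos <- pos + lens[k]
  }
  cbind(start = starts, end = starts + lens - 1L)
}

#' Generate a synthetic coiled-coil dataset
#'
#' Plants non-overlapping heptad helices (register phase uniform, cyclic
#' a->b->...->g) separated by at least one background residue, assigns each
#' helix one of the four oligomer classes, biases a/d positions toward
#' hydrophobic residues, and attaches label-conditioned Gaussian
#' embeddings. Every generated track is grammar-valid.
#'
#' @param config A [synth_config()] (or arguments passed on to it).
#' @param ... Overrides forwarded to [synth_config()] when `config` is
#'   missing.
#' @return Tibble with columns `id`, `sequence`, `labels`, `embedding`
#'   (list of L x D matrices) and `helices` (list of tibbles with `start`,
#'   `end`, `registers`, `oligo_state`).
#' @export
coil_simulate <- function(config = synth_config(...), ...) {
  stopifnot(inherits(config, "synth_config"))
  profile <- synth_profile(config)
  bg <- background_probs()
  aa_bg <- names(bg)
  with_seed(config$seed, {
    recs <- lapply(seq_len(config$n_records), function(r) {
      L <- sample(config$length_range[1]:config$length_range[2], 1L)
      # helices that can physically fit in L residues with 1-residue gaps
      n_feasible <- (L + 1L) %/% (config$helix_length_range[1] + 1L)
      n_lo <- config$helices_per_record_range[1]
      n_hi <- min(config$helices_per_record_range[2], n_feasible)
      if (n_lo > n_hi) {
        abort(sprintf("config infeasible: %d helices of length >= %d cannot fit in %d residues",
                      n_lo, config$helix_length_range[1], L))
      }
      n <- if (n_lo == n_hi) n_lo else sample(n_lo:n_hi, 1L)
      spans <- place_helices(L, n, config$helix_length_range)
      lab <- rep("i", L)
      oligo <- character(n)
      regs <- character(n)
      for (k in seq_len(n)) {
        span <- spans[k, "start"]:spans[k, "end"]
        phase <- sample(7L, 1L)
        rg <- cc_registers()[(phase + seq_along(span) - 2L) %% 7L + 1L]
        lab[span] <- rg
        regs[k] <- paste(rg, collapse = "")
        oligo[k] <- sample(cc_oligo_states(), 1L)
      }
      seqv <- sample(aa_bg, L, replace = TRUE, prob = bg)
      ad <- which(lab %in% c("a", "d"))
      if (length(ad)) {
        hyd <- runif(length(ad)) < config$hydrophobic_ad_prob
        seqv[ad[hyd]] <- sample(HYDROPHOBIC, sum(hyd), replace = TRUE)
      }
      emb <- do.call(rbind, profile$label_mu[ifelse(lab == "i", "i", lab)])
      for (k in seq_len(n)) {
        span <- spans[k, "start"]:spans[k, "end"]
        adk <- span[lab[span] %in% c("a", "d")]
        if (length(adk)) {
          emb[adk, ] <- emb[adk, , drop = FALSE] +
            rep(profile$class_offset[[oligo[k]]], each = length(adk))
        }
      }
      if (config$noise_sd > 0) {
        emb <- emb + matrix(rnorm(length(emb), sd = config$noise_sd),
                            nrow = nrow(emb))
      }
      helices <- if (n > 0L) {
        tibble(start = unname(spans[, "start"]), end = unname(spans[, "end"]),
               registers = regs, oligo_state = oligo)
      } else {
        tibble(start = integer(), end = integer(), registers = character(),
               oligo_state = character())
      }
      tibble(id = sprintf("SYN%04d", r),
             sequence = paste(seqv, collapse = ""),
             labels = paste(lab, collapse = ""),
             embedding = list(unname(emb)),
             helices = list(helices))
    })
    dplyr::bind_rows(recs)
  })
}

#' Export a synthetic dataset through the standard file formats
#'
#' Writes FASTA sequences, the two-line label file, and a per-id embedding
#' directory, so fixtures exercise the real I/O paths.
#'
#' @param data Output of [coil_simulate()].
#' @param dir Target directory (created if needed).
#' @param embedding_format `"emb"` (binary) or `"tsv"` (text).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(data, dir, embedding_format = "emb") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(data, file.path(dir, "sequences.fasta"))
  write_labels(data, file.path(dir, "labels.txt"))
  for (k in seq_len(nrow(data))) {
    write_embedding(data$embedding[[k]], file.path(dir, "embeddings"),
                    data$id[k], format = embedding_format)
  }
  invisible(dir)
}

# Corrupt a truth track: each true helix is deleted with probability rate;
# with the same probability a spurious short helix is inserted into a
# background gap (when one fits).
corrupt_track <- function(labels, rate) {
  seg <- segments_from_track(labels)
  L <- nchar(labels)
  keep <- runif(nrow(seg)) >= rate
  seg <- seg[keep, , drop = FALSE]
  if (runif(1) < rate) {
    occ <- rep(FALSE, L)
    for (k in seq_len(nrow(seg))) occ[seg$start[k]:seg$end[k]] <- TRUE
    # candidate start positions leaving a 1-residue buffer around helices
    len <- sample(8:15, 1L)
    cand <- which(vapply(seq_len(L - len + 1L), function(s) {
      lo <- max(1L, s - 1L); hi <- min(L, s + len)
      !any(occ[lo:hi])
    }, logical(1)))
    if (length(cand)) {
      s <- cand[sample(length(cand), 1L)]
      phase <- sample(7L, 1L)
      seg <- dplyr::bind_rows(seg, tibble(
        start = s, end = s + len - 1L,
        registers = paste(cc_registers()[(phase + seq_len(len) - 2L) %% 7L + 1L],
                          collapse = "")
      ))
      seg <- seg[order(seg$start), , drop = FALSE]
    }
  }
  track_from_segments(seg, L)
}

#' Paired method results with a planted quality gap
#'
#' Builds per-sequence predictions for two notional methods by corrupting
#' the true tracks at rates `p_a` and `p_b` (helix deletion and spurious
#' helix insertion); `p_b > p_a` plants a real quality gap for
#' [bootstrap_compare()] to detect.
#'
#' @param data Output of [coil_simulate()] (needs `id`, `labels`).
#' @param p_a,p_b Corruption rates in `[0, 1]` for methods A and B.
#' @param seed Integer seed.
#' @return List with tibbles `results_a` and `results_b`, each with
#'   columns `id`, `obs`, `pred`.
#' @export
simulate_method_pair <- function(data, p_a = 0.05, p_b = 0.3, seed = 1L) {
  if (p_a < 0 || p_a > 1 || p_b < 0 || p_b > 1) {
    abort("corruption rates must lie in [0, 1]")
  }
  with_seed(seed * 13L + 1L, {
    pa <- vapply(data$labels, corrupt_track, character(1), rate = p_a)
    pb <- vapply(data$labels, corrupt_track, character(1), rate = p_b)
    list(results_a = tibble(id = data$id, obs = data$labels, pred = unname(pa)),
         results_b = tibble(id = data$id, obs = data$labels, pred = unname(pb)))
  })
}
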