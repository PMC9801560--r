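# FASTA I/O, window extraction, undersampling, and the synthetic TSS
# benchmark generator.
#
# Window conventions (0-based offsets relative to the candidate site):
#   seq201: positions -100..+100, site at index 100 (length 201) - the
#           classifier's sequence view;
#   seq300: positions -150..+149, site at index 150 (length 300) - the PBD
#           window, trimmed to the 200 central probabilities downstream.

# evaluate code under a temporary seed, restoring the RNG state afterwards
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Read / write FASTA
#'
#' Thin validated wrappers around Biostrings. Sequences are uppercased;
#' records containing characters outside ACGT (ambiguity codes included)
#' are rejected with an error naming the offending records.
#'
#' @param path FASTA file path.
#' @return `read_fasta`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- names(seqs)[grepl("[^ACGT]", seqs)]
  if (length(bad) > 0) {
    stop(sprintf("records with characters outside ACGT: %s",
                 paste(bad, collapse = ", ")))
  }
  if (any(nchar(seqs) == 0)) stop("empty sequence records in FASTA")
  seqs
}

#' @rdname read_fasta
#' @param records Named character vector of ACGT sequences.
#' @export
write_fasta <- function(records, path) {
  if (is.null(names(records)) || any(names(records) == "")) {
    stop("all records must be named")
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(toupper(records)), path)
  invisible(path)
}

new_tss_dataset <- function(windows, profiles = NULL) {
  stopifnot(is.data.frame(windows),
            all(c("id", "label", "seq201", "seq300") %in% names(windows)))
  stopifnot(all(nchar(windows$seq201) == 201L),
            all(nchar(windows$seq300) == 300L),
            all(windows$label %in% c(-1, 1)))
  npos <- sum(windows$label == 1); nneg <- sum(windows$label == -1)
  structure(list(windows = windows, profiles = profiles,
                 ir = if (npos > 0) nneg / npos else NA_real_),
            class = "tss_dataset")
}

#' @export
print.tss_dataset <- function(x, ...) {
  npos <- sum(x$windows$label == 1); nneg <- sum(x$windows$label == -1)
  cat(sprintf("TSS window dataset: %d positives, %d negatives (IR %.1f:1)%s\n",
              npos, nneg, x$ir,
              if (!is.null(x$profiles)) ", with profiles" else ""))
  invisible(x)
}

.window_at <- function(genome, pos) {
  # pos is the 1-based genomic index of the candidate site
  list(seq201 = substr(genome, pos - 100, pos + 100),
       seq300 = substr(genome, pos - 150, pos + 149))
}

#' Extract labelled TSS windows from a genomic sequence
#'
#' One positive window per annotated TSS, plus `n_neg_per_gene` negatives
#' drawn uniformly at random (seeded, without replacement) from positions
#' between 100 bp downstream of the TSS and the gene end. Draws whose
#' windows would overrun the sequence are redrawn; genes whose negative
#' interval is infeasible are skipped with a warning.
#'
#' @param genome_seq A single ACGT string.
#' @param tss_positions 1-based TSS positions; each must admit full 201-
#'   and 300-base windows.
#' @param gene_ends 1-based gene end positions (`> TSS + 100`), parallel to
#'   `tss_positions`.
#' @param n_neg_per_gene Negatives per gene (default 10, giving the usual
#'   10:1 imbalance).
#' @param seed Integer seed.
#' @return A `tss_dataset`.
#' @export
extract_windows <- function(genome_seq, tss_positions, gene_ends,
                            n_neg_per_gene = 10, seed = NULL) {
  genome <- .check_sequence(genome_seq)
  genome <- paste(genome, collapse = "")
  G <- nchar(genome)
  stopifnot(length(tss_positions) == length(gene_ends))
  ok_window <- function(p) p - 150 >= 1 && p + 149 <= G
  if (!all(vapply(tss_positions, ok_window, logical(1)))) {
    stop("every TSS must admit full 201- and 300-base windows within the sequence")
  }
  .with_seed(seed, {
    rows <- list()
    for (g in seq_along(tss_positions)) {
      tss <- tss_positions[g]; gend <- gene_ends[g]
      if (gend <= tss + 100) {
        warning(sprintf("gene %d: negative interval empty (end <= TSS + 100), skipped", g))
        next
      }
      w <- .window_at(genome, tss)
      rows[[length(rows) + 1]] <- data.frame(
        id = sprintf("gene%03d_pos", g), label = 1,
        seq201 = w$seq201, seq300 = w$seq300, source_position = tss)
      lo <- tss + 100; hi <- gend
      cand <- lo:hi
      cand <- cand[vapply(cand, ok_window, logical(1))]
      if (length(cand) < n_neg_per_gene) {
        warning(sprintf("gene %d: negative interval too small, skipped", g))
        next
      }
      draws <- sample(cand, n_neg_per_gene)
      for (k in seq_along(draws)) {
        w <- .window_at(genome, draws[k])
        rows[[length(rows) + 1]] <- data.frame(
          id = sprintf("gene%03d_neg%02d", g, k), label = -1,
          seq201 = w$seq201, seq300 = w$seq300, source_position = draws[k])
      }
    }
    if (length(rows) == 0) stop("no gene yielded usable windows")
    new_tss_dataset(do.call(rbind, rows))
  })
}

#' Random undersampling of the majority class
#'
#' Keeps every minority instance and a seeded uniform subsample of the
#' majority class sized `round(target_ir * minority count)`, so learning
#' sees the requested imbalance ratio (1:1 by default).
#'
#' @param ds A `tss_dataset`.
#' @param target_ir Target majority:minority ratio (> 0).
#' @param seed Integer seed.
#' @return A `tss_dataset` (profiles, when present, are subset alongside).
#' @export
undersample <- function(ds, target_ir = 1.0, seed = NULL) {
  stopifnot(inherits(ds, "tss_dataset"), target_ir > 0)
  y <- ds$windows$label
  minority <- if (sum(y == 1) <= sum(y == -1)) 1 else -1
  n_min <- sum(y == minority)
  n_keep <- round(target_ir * n_min)
  maj_idx <- which(y != minority)
  if (n_keep > length(maj_idx)) {
    stop("target_ir exceeds the available majority/minority ratio")
  }
  keep <- .with_seed(seed, sort(c(which(y == minority), sample(maj_idx, n_keep))))
  subset_dataset(ds, keep)
}

#' Subset a dataset by row index
#' @param ds A `tss_dataset`.
#' @param idx Integer row indices into `ds$windows`.
#' @export
subset_dataset <- function(ds, idx) {
  new_tss_dataset(ds$windows[idx, , drop = FALSE],
                  if (!is.null(ds$profiles)) ds$profiles[idx, , drop = FALSE])
}

#' Synthetic TSS-like benchmark dataset
#'
#' Generates a seeded dataset emulating the structure of TSS window
#' benchmarks: fixed-length windows, a configurable class imbalance, and
#' positives carrying signal in both views. Positive windows receive (i) a
#' consensus motif planted near the window centre with a per-position
#' mutation rate, so the sequence view carries positional k-mer signal,
#' and (ii) elevated AT content in the central +/-30 bases, so the physics
#' view (AT pairs open far more readily than GC) carries signal. Negatives
#' are plain background. With `at_bias = 0` and `mutation_rate = 1` the
#' construction is null: positives are statistically indistinguishable
#' from negatives.
#'
#' The AT enrichment is delivered as a contiguous 31-base AT-rich block at
#' a uniformly jittered offset (+/-15 bases) around the site, rather than
#' an evenly spread bias: contiguity is what drives cooperative bubble
#' formation in the physics view, and the positional jitter mirrors how
#' AT-rich / nucleosome-depleted stretches vary in position relative to
#' real TSSs. The jitter also makes the two views *partially
#' complementary* - position-anchored k-mer matching dilutes under jitter,
#' while the spatially extended opening bump keeps profiles of different
#' positives overlapping. Complementarity is reinforced by anticorrelated
#' per-window modulation: some positives are motif-dominant (clean motif,
#' weak AT block) and others AT-dominant (degenerate motif, strong AT
#' block), with class means held at the nominal `mutation_rate` and
#' `at_bias`. Real promoters behave this way - only a fraction carry a
#' recognizable TATA-like core element - and it is this heterogeneity that
#' makes fusing the two views profitable, as neither alone ranks every
#' positive highly.
#'
#' @param n_pos,n_neg Class sizes (default 1:10 imbalance shape).
#' @param motif_spec List with `consensus` (ACGT string), `offset` (motif
#'   start relative to the site, default -30), and `mutation_rate` (mean
#'   per-position probability of replacing a motif base by a uniform
#'   random base; default 0.65, the degeneracy scale of real core-promoter
#'   elements), and optional `jitter` (uniform +/- placement jitter of the
#'   motif, default 0).
#' @param at_bias Mean extra AT probability mass in the positive central
#'   region (in `[0, 0.5]`); background bases are uniform, biased bases
#'   use `P(A) = P(T) = 0.25 + bias/2`. The default 0.085 puts the
#'   AT-dominant windows' block enrichment near 0.30 (AT fraction 0.8),
#'   strong cooperative-bubble territory without collapsing the block to
#'   a two-letter alphabet.
#' @param complementarity Amplitude in `[0, 1]` of the anticorrelated
#'   per-window modulation of the two signals (0 = homogeneous positives).
#' @param seed Integer seed; same seed, same dataset.
#' @return A `tss_dataset`.
#' @export
make_synthetic <- function(n_pos = 200, n_neg = 2000,
                           motif_spec = list(consensus = "TATAAA",
                                             offset = -30,
                                             mutation_rate = 0.65),
                           at_bias = 0.085, complementarity = 0.8,
                           seed = NULL) {
  if (at_bias < 0 || at_bias > 0.5) stop("at_bias must be in [0, 0.5]")
  if (complementarity < 0 || complementarity > 1) {
    stop("complementarity must be in [0, 1]")
  }
  motif <- .check_sequence(motif_spec$consensus)
  mrate <- motif_spec$mutation_rate %||% 0.65
  offset <- motif_spec$offset %||% -30
  mjit <- motif_spec$jitter %||% 0
  if (mrate < 0 || mrate > 1) stop("mutation_rate must be in [0, 1]")
  bases <- c("A", "C", "G", "T")
  p_bg <- rep(0.25, 4)
  centre <- 151                       # 1-based index of the site in seq300
  core <- (centre - 30):(centre + 30)
  mstart <- centre + offset
  if (mstart - mjit < 1 || mstart + length(motif) - 1 + mjit > 300) {
    stop("motif placement falls outside the 300-base window")
  }
  .with_seed(seed, {
    draw <- function(n, probs) sample(bases, n, replace = TRUE, prob = probs)
    gen_window <- function(positive) {
      s <- draw(300, p_bg)
      if (positive) {
        # anticorrelated signal split: s_i = +1 motif-dominant, -1 AT-dominant
        si <- sample(c(-1, 1), 1)
        match_i <- min(1, (1 - mrate) * (1 + si * complementarity))
        # contiguous AT-rich block, jittered; block bias scaled so the mean
        # enrichment over the +/-30 core equals the nominal at_bias
        bias_i <- min(0.5, at_bias * (61 / 31) * (1 - si * complementarity))
        off_i <- sample(-15:15, 1)
        block <- (centre + off_i - 15):(centre + off_i + 15)
        p_at <- c(0.25 + bias_i / 2, 0.25 - bias_i / 2,
                  0.25 - bias_i / 2, 0.25 + bias_i / 2)
        s[block] <- draw(length(block), p_at)
        mm <- motif
        mut <- stats::runif(length(mm)) >= match_i
        mm[mut] <- draw(sum(mut), p_bg)
        ms <- mstart + if (mjit > 0) sample(-mjit:mjit, 1) else 0
        s[ms:(ms + length(mm) - 1)] <- mm
      }
      paste(s, collapse = "")
    }
    seq300 <- c(vapply(seq_len(n_pos), function(i) gen_window(TRUE), character(1)),
                vapply(seq_len(n_neg), function(i) gen_window(FALSE), character(1)))
    windows <- data.frame(
      id = c(sprintf("pos%04d", seq_len(n_pos)), sprintf("neg%04d", seq_len(n_neg))),
      label = c(rep(1, n_pos), rep(-1, n_neg)),
      seq201 = substr(seq300, 51, 251),
      seq300 = seq300,
      source_position = NA_integer_)
    new_tss_dataset(windows)
  })
}

#' Dataset import/export as FASTA + labels table
#'
#' The 300-base PBD windows go to FASTA; ids, labels, and source positions
#' go to a tab-separated labels file (columns `id`, `label`,
#' `source_position`).
#'
#' @param ds A `tss_dataset`.
#' @param fasta_path,labels_path Output paths.
#' @export
write_dataset <- function(ds, fasta_path, labels_path) {
  stopifnot(inherits(ds, "tss_dataset"))
  recs <- ds$windows$seq300
  names(recs) <- ds$windows$id
  write_fasta(recs, fasta_path)
  utils::write.table(ds$windows[, c("id", "label", "source_position")],
                     labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ds)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(fasta_path, labels_path) {
  seqs <- read_fasta(fasta_path)
  lab <- utils::read.delim(labels_path)
  stopifnot(all(lab$id %in% names(seqs)))
  seq300 <- unname(seqs[lab$id])
  if (any(nchar(seq300) != 300L)) stop("PBD windows must be 300 bases long")
  new_tss_dataset(data.frame(id = lab$id, label = as.numeric(lab$label),
                             seq201 = substr(seq300, 51, 251),
                             seq300 = seq300,
                             source_position = lab$source_position))
}

#' Write trimmed profiles as a tab-separated table
#'
#' Long format: `sequence_id`, `position_index` (0-based within the
#' trimmed window), `temperature_K`, `m`, `probability`.
#'
#' @param profiles A list of `opening_profile` objects (or a single one).
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "opening_profile")) profiles <- list(profiles)
  tab <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(sequence_id = p$sequence_id,
               position_index = seq_along(p$values) - 1L,
               temperature_K = p$temperature, m = p$m,
               probability = p$values)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
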