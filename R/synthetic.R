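# Seeded generator of synthetic regulatory genomes: random sequence with
# planted motifs that causally drive multi-track coverage, Poisson count
# noise, and variants with known effect sizes.  Rates are computed by
# scanning the sequence itself, so reverse-complementing a window and
# exchanging strand-paired tracks reproduces the generative rates exactly
# -- the property that makes equivariance and augmentation tests
# meaningful.

#' Specification of a synthetic regulatory-genome corpus
#'
#' Two planted motif classes drive coverage through per-assay effect
#' kernels: a TSS-like motif produces a CAGE-like point source at its
#' start, an RNA-seq-like block downstream, a 3' RNA-seq-like point at
#' the block end, and broad accessibility; a GC-box-like motif produces a
#' smooth DNase-like peak.  A motif on the reverse strand drives the REV
#' track of each pair.  Observed counts are Poisson samples of the
#' deterministic rate field; the background rate is 0.5 counts/bin.
#'
#' @param n_windows number of windows.
#' @param window_len window length in bp.
#' @param bin_width bin width in bp.
#' @param background_rate background rate in counts per bin.
#' @param motifs_per_window planted motif instances per window.
#' @param crop_bins bins at each end kept free of planted motifs (and of
#'   variants), matching the loss crop.
#' @param seed corpus seed; the same seed reproduces the corpus exactly.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_windows = 64L, window_len = 8192L,
                           bin_width = 32L, background_rate = 0.5,
                           motifs_per_window = 6L, crop_bins = 8L,
                           seed = 1L) {
  # kernel masses give peak heights several-fold over background, as in
  # real coverage data (a DNase hypersensitive site or CAGE peak stands
  # well above the genomic floor)
  motifs <- list(
    tss = list(consensus = "TATATAAG",
               cage_mass = 30, cage_sd = 16,
               rna_amp_per_bin = 4, rna_len = 1024L,
               rna3p_mass = 20, rna3p_sd = 16,
               open_mass = 30, open_sd = 100),
    gcbox = list(consensus = "GGGCGGGG",
                 dnase_mass = 60, dnase_sd = 50,
                 open_mass = 30, open_sd = 150))
  structure(list(n_windows = as.integer(n_windows),
                 window_len = as.integer(window_len),
                 bin_width = as.integer(bin_width),
                 background_rate = background_rate,
                 motifs_per_window = as.integer(motifs_per_window),
                 crop_bins = as.integer(crop_bins),
                 motifs = motifs, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Track metadata of the synthetic corpus
#'
#' Eight tracks: strand-paired CAGE, RNA and 3' RNA, plus unstranded
#' DNase and an unstranded broad accessibility track.
#'
#' @param spec a [synthetic_spec].
#' @return a [track_meta] table.
#' @export
synthetic_track_meta <- function(spec = synthetic_spec()) {
  track_meta(
    track_id = c("cage_f", "cage_r", "rna_f", "rna_r", "rna3p_f", "rna3p_r",
                 "dnase", "open"),
    assay = c("CAGE", "CAGE", "RNA", "RNA", "RNA3P", "RNA3P",
              "DNASE", "OTHER"),
    strand = c("FWD", "REV", "FWD", "REV", "FWD", "REV",
               "UNSTRANDED", "UNSTRANDED"),
    pair_id = c("cage1", "cage1", "rna1", "rna1", "rna3p1", "rna3p1",
                NA, NA))
}

revcomp_string <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# 0-based start positions of exact matches of pattern in seq
match_starts <- function(seq, pattern) {
  hits <- as.integer(gregexpr(pattern, seq, fixed = TRUE)[[1]])
  hits[hits > 0] - 1L
}

# gaussian bump per-base field, total mass `mass`, clipped to the window
add_bump <- function(field, center0, mass, sd) {
  L <- length(field)
  lo <- max(0L, floor(center0 - 4 * sd)); hi <- min(L - 1L, ceiling(center0 + 4 * sd))
  if (hi < lo) return(field)
  pos <- lo:hi
  wt <- exp(-0.5 * ((pos - center0) / sd)^2)
  field[pos + 1L] <- field[pos + 1L] + mass * wt / sum(exp(-0.5 *
    ((seq(-ceiling(4 * sd), ceiling(4 * sd))) / sd)^2))
  field
}

add_block <- function(field, start0, len, amp_per_base) {
  L <- length(field)
  lo <- max(0L, start0); hi <- min(L - 1L, start0 + len - 1L)
  if (hi < lo) return(field)
  field[(lo + 1L):(hi + 1L)] <- field[(lo + 1L):(hi + 1L)] + amp_per_base
  field
}

#' Deterministic per-bin rate field implied by a sequence
#'
#' Scans both strands of the sequence for exact motif matches and
#' accumulates each assay's effect kernel; forward-strand matches drive
#' FWD tracks, reverse-strand matches drive REV tracks, unstranded tracks
#' receive strand-symmetric kernels from either.
#'
#' @param seq DNA string.
#' @param spec a [synthetic_spec].
#' @return (bins, 8) matrix of true rates (counts per bin).
#' @export
synthetic_rates <- function(seq, spec) {
  L <- nchar(seq)
  bw <- spec$bin_width
  fields <- matrix(0, L, 8L)
  colnames(fields) <- synthetic_track_meta(spec)$track_id
  m <- spec$motifs$tss
  mlen <- nchar(m$consensus)
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") m$consensus else revcomp_string(m$consensus)
    for (p in match_starts(seq, pat)) {
      if (strand == "+") {
        tss <- p                               # transcription start
        fields[, "cage_f"] <- add_bump(fields[, "cage_f"], tss,
                                       m$cage_mass, m$cage_sd)
        fields[, "rna_f"] <- add_block(fields[, "rna_f"], tss, m$rna_len,
                                       m$rna_amp_per_bin / bw)
        fields[, "rna3p_f"] <- add_bump(fields[, "rna3p_f"],
                                        tss + m$rna_len - 1L,
                                        m$rna3p_mass, m$rna3p_sd)
        fields[, "open"] <- add_bump(fields[, "open"], p + (mlen - 1) / 2,
                                     m$open_mass, m$open_sd)
      } else {
        tss <- p + mlen - 1L                   # start on the minus strand
        fields[, "cage_r"] <- add_bump(fields[, "cage_r"], tss,
                                       m$cage_mass, m$cage_sd)
        fields[, "rna_r"] <- add_block(fields[, "rna_r"],
                                       tss - m$rna_len + 1L, m$rna_len,
                                       m$rna_amp_per_bin / bw)
        fields[, "rna3p_r"] <- add_bump(fields[, "rna3p_r"],
                                        tss - m$rna_len + 1L,
                                        m$rna3p_mass, m$rna3p_sd)
        fields[, "open"] <- add_bump(fields[, "open"], p + (mlen - 1) / 2,
                                     m$open_mass, m$open_sd)
      }
    }
  }
  g <- spec$motifs$gcbox
  glen <- nchar(g$consensus)
  for (pat in unique(c(g$consensus, revcomp_string(g$consensus)))) {
    for (p in match_starts(seq, pat)) {
      fields[, "dnase"] <- add_bump(fields[, "dnase"], p + (glen - 1) / 2,
                                    g$dnase_mass, g$dnase_sd)
      fields[, "open"] <- add_bump(fields[, "open"], p + (glen - 1) / 2,
                                   g$open_mass, g$open_sd)
    }
  }
  bins <- bin_coverage(fields, bw)
  bins + spec$background_rate
}

# plant motif instances into a random background sequence
plant_window <- function(spec) {
  L <- spec$window_len
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  margin <- spec$crop_bins * spec$bin_width
  placed <- integer(0)
  for (i in seq_len(spec$motifs_per_window)) {
    mt <- spec$motifs[[sample(c("tss", "gcbox"), 1L)]]
    cons <- mt$consensus
    if (stats::runif(1) < 0.5) cons <- revcomp_string(cons)
    # keep effect kernels inside the window where it is long enough;
    # kernels clip symmetrically at the edges otherwise
    reach <- min(1536L, max(nchar(cons) + 1L, L - 2L * margin - 2L))
    avail <- L - 2L * margin - reach
    if (avail < 1L) stop("window too small for planted motifs")
    min_sep <- min(2048L, max(256L, avail %/% 3L))
    for (try in 1:50) {
      p0 <- sample.int(avail, 1L) + margin
      if (!length(placed) || all(abs(placed - p0) > min_sep)) break
    }
    chars[(p0 + 1L):(p0 + nchar(cons))] <- strsplit(cons, "")[[1]]
    placed <- c(placed, p0)
  }
  list(seq = paste(chars, collapse = ""), motif_starts = placed)
}

#' Generate a synthetic corpus of windows, rates and sampled counts
#'
#' @param spec a [synthetic_spec].
#' @param dir optional directory; when given, writes `windows.fa`, one
#'   BedGraph of binned counts per track under `tracks/`, `meta.tsv`, and
#'   ground-truth rate matrices under `truth/`.
#' @return list with `windows` (each: `name`, `seq`, `onehot`, `rates`,
#'   `counts`), `meta`, and the `spec`.
#' @export
generate_corpus <- function(spec = synthetic_spec(), dir = NULL) {
  if (max(vapply(spec$motifs, function(m) nchar(m$consensus), 1)) >
      spec$window_len) stop("motif longer than window")
  meta <- synthetic_track_meta(spec)
  windows <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_windows), function(i) {
      pw <- plant_window(spec)
      rates <- synthetic_rates(pw$seq, spec)
      counts <- matrix(stats::rpois(length(rates), rates), nrow(rates),
                       ncol(rates), dimnames = dimnames(rates))
      list(name = paste0("synthetic_w", i), seq = pw$seq,
           onehot = one_hot_encode(pw$seq), rates = rates, counts = counts,
           motif_starts = pw$motif_starts)
    })
  })
  corpus <- list(windows = windows, meta = meta, spec = spec)
  if (!is.null(dir)) write_corpus(corpus, dir)
  corpus
}

#' Write a synthetic corpus to standard file formats
#' @param corpus from [generate_corpus].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  seqs <- stats::setNames(vapply(corpus$windows, `[[`, "", "seq"),
                          vapply(corpus$windows, `[[`, "", "name"))
  write_fasta(seqs, file.path(dir, "windows.fa"))
  write_track_meta(corpus$meta, file.path(dir, "meta.tsv"))
  bw <- corpus$spec$bin_width
  for (j in seq_len(nrow(corpus$meta))) {
    tid <- corpus$meta$track_id[j]
    lines <- unlist(lapply(corpus$windows, function(w) {
      per_base <- rep(w$counts[, j] / bw, each = bw)
      tmp <- tempfile()
      on.exit(unlink(tmp), add = TRUE)
      write_bedgraph_window(per_base, w$name, 0L, tmp)
      readLines(tmp)
    }))
    writeLines(lines, file.path(dir, "tracks", paste0(tid, ".bedgraph")))
  }
  for (w in corpus$windows) {
    write_track_matrix(w$rates, file.path(dir, "truth",
                                          paste0(w$name, "_rates.tsv")))
  }
  invisible(dir)
}

#' Oracle predictor that returns the true generative rates
#'
#' Decodes a one-hot window back to sequence and recomputes the
#' deterministic rate field; useful as a ground-truth predictor for
#' validating the variant-scoring pipeline.
#'
#' @param spec a [synthetic_spec].
#' @param transform optional function applied to the rates (e.g.
#'   [squash]).
#' @return a [rate_oracle].
#' @export
synthetic_oracle <- function(spec, transform = identity) {
  rate_oracle(function(onehot) {
    transform(synthetic_rates(one_hot_decode(onehot), spec))
  })
}

#' Generate variants with known effects from a synthetic corpus
#'
#' Effect variants substitute one base inside a planted motif instance,
#' destroying the exact match and hence its coverage contribution; null
#' variants substitute a background base without creating or destroying
#' any match on either strand.  The truth table records the signed change
#' in total true rate over the window.
#'
#' @param corpus from [generate_corpus].
#' @param n_effect,n_null variant counts.
#' @param seed integer seed.
#' @param dir optional directory to write `variants.vcf` and `truth.tsv`.
#' @return data.frame with columns `id`, `window`, `pos` (0-based within
#'   window), `ref`, `alt`, `label` ("effect"/"null"), `true_effect`.
#' @export
generate_variants <- function(corpus, n_effect = 50L, n_null = 50L,
                              seed = 1L, dir = NULL) {
  spec <- corpus$spec
  margin <- spec$crop_bins * spec$bin_width
  mot_pats <- unlist(lapply(spec$motifs, function(m)
    c(m$consensus, revcomp_string(m$consensus))))
  rows <- with_seed(seed, {
    out <- list()
    make_variant <- function(label) {
      repeat {
        wi <- sample.int(length(corpus$windows), 1L)
        w <- corpus$windows[[wi]]
        chars <- strsplit(w$seq, "")[[1]]
        if (label == "effect") {
          if (!length(w$motif_starts)) next
          p0 <- sample(w$motif_starts, 1L)
          off <- sample.int(8L, 1L) - 1L          # within the consensus
          pos <- p0 + off
        } else {
          pos <- sample.int(nchar(w$seq) - 2L * margin, 1L) + margin - 1L
          if (length(w$motif_starts) &&
              any(pos >= w$motif_starts - 8L &
                  pos <= w$motif_starts + 16L)) next
        }
        ref <- chars[pos + 1L]
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        chars2 <- chars; chars2[pos + 1L] <- alt
        seq2 <- paste(chars2, collapse = "")
        delta <- sum(synthetic_rates(seq2, spec)) - sum(w$rates)
        if (label == "effect" && abs(delta) < 1e-9) next   # redundant site
        if (label == "null" && abs(delta) > 1e-9) next     # touched a match
        return(data.frame(window = w$name, window_idx = wi, pos = pos,
                          ref = ref, alt = alt, label = label,
                          true_effect = delta))
      }
    }
    for (i in seq_len(n_effect)) out[[length(out) + 1L]] <- make_variant("effect")
    for (i in seq_len(n_null)) out[[length(out) + 1L]] <- make_variant("null")
    out
  })
  variants <- do.call(rbind, rows)
  variants$id <- paste0("var", seq_len(nrow(variants)))
  variants <- variants[, c("id", "window", "window_idx", "pos", "ref",
                           "alt", "label", "true_effect")]
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf_variants(data.frame(chrom = variants$window,
                                  pos = variants$pos + 1L,
                                  ref = variants$ref, alt = variants$alt,
                                  id = variants$id),
                       file.path(dir, "variants.vcf"))
    utils::write.table(variants, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  variants
}
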