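# File I/O: FASTA windows, BedGraph coverage, VCF variants, TSV fixtures,
# YAML configs.  Coordinates are 0-based half-open throughout (BedGraph
# native); conversion to/from 1-based R containers happens here and only
# here.

#' Read sequences from a FASTA file
#' @param path FASTA file.
#' @return named character vector of uppercase DNA strings.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' Write sequences to a FASTA file
#' @param seqs named character vector of DNA strings.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read one track's coverage for a window from a BedGraph file
#'
#' Intervals are expanded to per-base coverage over
#' `[start, start + window_len)` and sum-pooled into bins.
#'
#' @param path BedGraph file (0-based half-open intervals).
#' @param chrom,start window location; `start` 0-based.
#' @param window_len window length in bp.
#' @param bin_width bin width in bp (use 1 for per-base values).
#' @return numeric vector of `window_len / bin_width` binned values.
#' @export
read_bedgraph_window <- function(path, chrom, start, window_len,
                                 bin_width = 32L) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  per_base <- numeric(window_len)
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  if (length(gr)) {
    # GRanges is 1-based closed; window is 0-based half-open
    s0 <- GenomicRanges::start(gr) - 1L
    e0 <- GenomicRanges::end(gr)
    v <- gr$score
    for (i in seq_along(v)) {
      lo <- max(s0[i], start) - start
      hi <- min(e0[i], start + window_len) - start
      if (hi > lo) per_base[(lo + 1L):hi] <- per_base[(lo + 1L):hi] + v[i]
    }
  }
  bin_coverage(per_base, bin_width)
}

#' Write per-base coverage for a window to a BedGraph file
#'
#' Runs of equal value are merged into single intervals.
#'
#' @param per_base numeric vector of per-base coverage.
#' @param chrom,start window location; `start` 0-based.
#' @param path output file.
#' @export
write_bedgraph_window <- function(per_base, chrom, start, path) {
  r <- rle(per_base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  df <- data.frame(chrom = chrom,
                   start = start + starts[keep],
                   end = start + ends[keep],
                   score = r$values[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read SNVs from a VCF file
#'
#' Only `CHROM`, `POS`, `REF`, `ALT` are used.  Symbolic alleles, indels
#' and multi-allelic records are rejected (this pipeline scores
#' single-base substitutions only).
#'
#' @param path VCF file.
#' @return `data.frame` with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   and `id`.
#' @export
read_vcf_variants <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(fix))) {
    ref <- fix$REF[i]; alt <- fix$ALT[i]
    if (is.na(ref) || is.na(alt) || grepl("[<>\\[\\]]", alt) ||
        grepl(",", alt, fixed = TRUE) ||
        nchar(ref) != 1L || nchar(alt) != 1L ||
        !ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T")) {
      stop("unsupported or malformed VCF record ", i, ": ",
           fix$CHROM[i], ":", fix$POS[i], " ", ref, ">", alt)
    }
  }
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
             ref = fix$REF, alt = fix$ALT,
             id = if ("ID" %in% names(fix)) fix$ID else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write SNVs to a minimal VCF file
#' @param variants `data.frame` with `chrom`, `pos` (1-based), `ref`, `alt`
#'   and optionally `id`.
#' @param path output file.
#' @export
write_vcf_variants <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  id <- if ("id" %in% names(variants)) variants$id else
    paste0("v", seq_len(nrow(variants)))
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                     variants$chrom, variants$pos, id,
                     variants$ref, variants$alt), con)
  invisible(path)
}

#' Read track metadata from TSV
#' @param path TSV with columns `track_id`, `assay`, `strand`, `pair_id`.
#' @return a [track_meta] table.
#' @export
read_track_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("track_id", "assay", "strand", "pair_id")
  if (!all(need %in% names(df))) {
    stop("track metadata must have columns ", paste(need, collapse = ", "))
  }
  track_meta(df$track_id, df$assay, df$strand, df$pair_id)
}

#' Write track metadata to TSV
#' @param meta a [track_meta] table.
#' @param path output file.
#' @export
write_track_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binned track matrix fixture from TSV
#' @param path TSV with one column per track, one row per bin.
#' @return numeric matrix (bins x tracks).
#' @export
read_track_matrix <- function(path) {
  as.matrix(utils::read.delim(path, check.names = FALSE))
}

#' Write a binned track matrix fixture to TSV
#' @param values numeric matrix (bins x tracks).
#' @param path output file.
#' @export
write_track_matrix <- function(values, path) {
  utils::write.table(values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a [data_config] from a YAML file
#' @param path YAML file keyed by the `data_config()` arguments.
#' @return a [data_config].
#' @export
read_data_config <- function(path) {
  do.call(data_config, yaml::read_yaml(path))
}

#' Write a [data_config] to a YAML file
#' @param cfg a [data_config].
#' @param path output file.
#' @export
write_data_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
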