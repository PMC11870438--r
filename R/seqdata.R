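# Sequence/coverage data structures, transforms, augmentation and splits.

#' Data-processing configuration
#'
#' Collects the constants that define how genomic windows and coverage
#' tracks are prepared for modeling: window length, bin width, the number
#' of bins cropped from each end before the loss, the maximum sequence
#' shift used for augmentation, the squash-transform parameters, and the
#' fold/split layout.
#'
#' Defaults mirror the full-scale setup (393,216-bp windows, 32-bp bins,
#' 2,048 cropped bins per end, shifts up to 3 nt, squash exponent 3/4 with
#' threshold 384, six folds grouped 4:1:1 into train:validation:test).
#'
#' @param window_len window length in bp.
#' @param bin_width output bin width in bp.
#' @param crop_bins number of bins cropped from each end before the loss.
#' @param shift_max maximum augmentation shift in bp.
#' @param squash_exponent exponent of the squash transform.
#' @param squash_threshold threshold of the squash transform.
#' @param clip_exponent optional soft-clip exponent applied to the
#'   above-threshold term of the squash transform; `NULL` (default) keeps
#'   the printed form, whose two branch terms sum back to the plain power.
#' @param n_folds number of cross-validation folds.
#' @param split_ratio integer triple (train, validation, test) in folds.
#' @return an object of class `data_config`.
#' @export
data_config <- function(window_len = 393216L, bin_width = 32L,
                        crop_bins = 2048L, shift_max = 3L,
                        squash_exponent = 3 / 4, squash_threshold = 384,
                        clip_exponent = NULL,
                        n_folds = 6L, split_ratio = c(4L, 1L, 1L)) {
  stopifnot(window_len %% bin_width == 0,
            2L * crop_bins < window_len %/% bin_width,
            squash_threshold > 0,
            length(split_ratio) == 3L,
            sum(split_ratio) == n_folds)
  structure(list(window_len = as.integer(window_len),
                 bin_width = as.integer(bin_width),
                 crop_bins = as.integer(crop_bins),
                 shift_max = as.integer(shift_max),
                 squash_exponent = squash_exponent,
                 squash_threshold = squash_threshold,
                 clip_exponent = clip_exponent,
                 n_folds = as.integer(n_folds),
                 split_ratio = as.integer(split_ratio)),
            class = "data_config")
}

#' One-hot encode a DNA sequence
#'
#' Columns are in canonical order A, C, G, T.  `N` (any case) encodes as an
#' all-zero row, the same convention used for shift-vacated positions, so a
#' row sum of 0 always means "no information at this base".
#'
#' @param seq a single DNA string over `{A,C,G,T,N}` (case-insensitive).
#' @return an (L, 4) numeric matrix.
#' @export
one_hot_encode <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T", "N"))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("non-IUPAC character '", chars[bad], "' at position ", bad)
  }
  m <- matrix(0, length(chars), 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  keep <- idx <= 4L
  m[cbind(which(keep), idx[keep])] <- 1
  m
}

#' Decode a one-hot matrix back to a DNA string
#' @param onehot (L, 4) matrix with rows one-hot or all-zero.
#' @return character scalar; all-zero rows decode to `N`.
#' @export
one_hot_decode <- function(onehot) {
  hit <- max.col(onehot, ties.method = "first")
  hit[rowSums(onehot) == 0] <- 5L
  paste(c("A", "C", "G", "T", "N")[hit], collapse = "")
}

#' Squash transform for coverage values
#'
#' The invertible monotone compression applied to raw coverage before
#' modeling, in its printed two-branch form
#' `min(x^e, T) + max(0, x^e - T)` with exponent `e = 3/4` and threshold
#' `T = 384` by default.  The two branches sum to `x^e` exactly; an
#' optional `clip_exponent` `c` replaces the above-threshold term with
#' `max(0, x^e - T)^c`, soft-clipping large values (off by default).
#'
#' @param x nonnegative numeric vector.
#' @param exponent,threshold transform parameters.
#' @param clip_exponent optional soft-clip exponent for the excess term.
#' @return squashed values, same shape as `x`.
#' @export
squash <- function(x, exponent = 3 / 4, threshold = 384,
                   clip_exponent = NULL) {
  if (any(x < 0)) stop("squash() requires nonnegative input")
  y <- x^exponent
  excess <- pmax(0, y - threshold)
  if (!is.null(clip_exponent)) excess <- excess^clip_exponent
  pmin(y, threshold) + excess
}

#' Inverse of the squash transform
#' @inheritParams squash
#' @export
unsquash <- function(x, exponent = 3 / 4, threshold = 384,
                     clip_exponent = NULL) {
  if (any(x < 0)) stop("unsquash() requires nonnegative input")
  excess <- pmax(0, x - threshold)
  if (!is.null(clip_exponent)) excess <- excess^(1 / clip_exponent)
  y <- pmin(x, threshold) + excess
  y^(1 / exponent)
}

#' Sum-pool per-base coverage into fixed-width bins
#'
#' Coverage is count-like and the loss is Poisson, so pooling is by sum:
#' total counts are conserved exactly.
#'
#' @param per_base numeric vector (length divisible by `bin_width`) or an
#'   (L, T) matrix pooled column-wise.
#' @param bin_width bin width in bp.
#' @return vector (or matrix) of length `L / bin_width`.
#' @export
bin_coverage <- function(per_base, bin_width) {
  if (is.matrix(per_base)) {
    return(apply(per_base, 2L, bin_coverage, bin_width = bin_width))
  }
  L <- length(per_base)
  if (L %% bin_width != 0) {
    stop("length ", L, " not divisible by bin width ", bin_width)
  }
  colSums(matrix(per_base, nrow = bin_width))
}

#' Track metadata table
#'
#' @param track_id character vector of track identifiers.
#' @param assay assay type, one of `"RNA"`, `"CAGE"`, `"DNASE"`, `"RNA3P"`,
#'   `"OTHER"`.
#' @param strand `"FWD"`, `"REV"` or `"UNSTRANDED"`.
#' @param pair_id identifier linking each FWD track to its REV partner;
#'   must be `NA` exactly for unstranded tracks.
#' @return a `data.frame` with class `track_meta`.
#' @export
track_meta <- function(track_id, assay, strand, pair_id = NA_character_) {
  assay <- match.arg(assay, c("RNA", "CAGE", "DNASE", "RNA3P", "OTHER"),
                     several.ok = TRUE)
  m <- data.frame(track_id = track_id,
                  assay = rep_len(assay, length(track_id)),
                  strand = rep_len(strand, length(track_id)),
                  pair_id = rep_len(pair_id, length(track_id)),
                  stringsAsFactors = FALSE)
  validate_track_meta(m)
  class(m) <- c("track_meta", "data.frame")
  m
}

validate_track_meta <- function(m) {
  stopifnot(all(m$strand %in% c("FWD", "REV", "UNSTRANDED")))
  stranded <- m$strand != "UNSTRANDED"
  if (any(is.na(m$pair_id[stranded]))) {
    stop("stranded tracks must carry a pair_id")
  }
  if (any(!is.na(m$pair_id[!stranded]))) {
    stop("unstranded tracks must not carry a pair_id")
  }
  for (pid in unique(m$pair_id[stranded])) {
    members <- m[!is.na(m$pair_id) & m$pair_id == pid, ]
    if (!(nrow(members) == 2L && setequal(members$strand, c("FWD", "REV")))) {
      stop("pair_id '", pid, "' is not a FWD/REV pair")
    }
  }
  invisible(m)
}

#' Binned coverage for one window: values plus track metadata
#'
#' @param values (B bins, T tracks) nonnegative matrix.
#' @param bin_width bin width in bp.
#' @param meta a [track_meta] table with one row per track.
#' @return an object of class `track_set`.
#' @export
track_set <- function(values, bin_width, meta) {
  stopifnot(is.matrix(values), ncol(values) == nrow(meta))
  if (any(values < 0)) stop("track values must be nonnegative")
  validate_track_meta(meta)
  structure(list(values = values, bin_width = as.integer(bin_width),
                 meta = meta),
            class = "track_set")
}

#' A fixed-length genomic window with one-hot encoded sequence
#' @param chrom chromosome name.
#' @param start 0-based half-open start coordinate in bp.
#' @param onehot (L, 4) one-hot matrix (see [one_hot_encode]).
#' @return object of class `sequence_window`.
#' @export
sequence_window <- function(chrom, start, onehot) {
  stopifnot(ncol(onehot) == 4L)
  structure(list(chrom = chrom, start = as.integer(start),
                 length = nrow(onehot), onehot = onehot),
            class = "sequence_window")
}

#' Crop bins from both ends of a track set
#'
#' The loss is evaluated only on the central region of each window; this
#' drops `crop` bins from each end.
#'
#' @param tracks a [track_set].
#' @param crop number of bins to remove per end.
#' @return the cropped [track_set] (metadata unchanged).
#' @export
crop_bins <- function(tracks, crop) {
  B <- nrow(tracks$values)
  crop <- as.integer(crop)
  if (2L * crop >= B) stop("cannot crop ", crop, " bins per end from ", B,
                           " bins")
  if (crop == 0L) return(tracks)
  tracks$values <- tracks$values[(crop + 1L):(B - crop), , drop = FALSE]
  tracks
}

# reverse complement of a one-hot matrix: reverse rows, swap A<->T, C<->G
revcomp_onehot <- function(onehot) {
  onehot[rev(seq_len(nrow(onehot))), c(4L, 3L, 2L, 1L), drop = FALSE]
}

# reverse bins and exchange FWD/REV partners (the output-side counterpart
# of reverse-complementing the input sequence)
revcomp_tracks <- function(values, meta) {
  out <- values[rev(seq_len(nrow(values))), , drop = FALSE]
  stranded <- which(meta$strand != "UNSTRANDED")
  if (length(stranded)) {
    partner <- match(meta$pair_id, meta$pair_id)
    for (i in stranded) {
      j <- setdiff(which(!is.na(meta$pair_id) & meta$pair_id == meta$pair_id[i]), i)
      partner[i] <- j
    }
    out[, stranded] <- out[, partner[stranded], drop = FALSE]
  }
  out
}

#' Reverse-complement augmentation of a (window, tracks) pair
#'
#' Reverse-complements the sequence, reverses the bin order of every track
#' and exchanges the values of each forward/reverse track pair (unstranded
#' tracks are reversed in bin order only).  Applying it twice is the
#' identity.
#'
#' @param win a [sequence_window].
#' @param tracks the matching [track_set].
#' @return list with elements `win` and `tracks`.
#' @export
revcomp_augment <- function(win, tracks) {
  validate_track_meta(tracks$meta)
  win$onehot <- revcomp_onehot(win$onehot)
  tracks$values <- revcomp_tracks(tracks$values, tracks$meta)
  list(win = win, tracks = tracks)
}

#' Shift augmentation of the input sequence
#'
#' Translates the one-hot rows by `shift` base pairs (positive = towards
#' higher coordinates), filling vacated rows with zeros.  The output bins
#' are deliberately left unchanged by the caller.
#'
#' @param win a [sequence_window].
#' @param shift integer in `[-shift_max, shift_max]`.
#' @param shift_max maximum allowed shift (bp).
#' @return the shifted [sequence_window].
#' @export
shift_augment <- function(win, shift, shift_max = 3L) {
  shift <- as.integer(shift)
  if (abs(shift) > shift_max) {
    stop("|shift| = ", abs(shift), " exceeds shift_max = ", shift_max)
  }
  if (shift == 0L) return(win)
  L <- nrow(win$onehot)
  out <- matrix(0, L, 4L, dimnames = dimnames(win$onehot))
  if (shift > 0L) {
    out[(shift + 1L):L, ] <- win$onehot[1L:(L - shift), ]
  } else {
    out[1L:(L + shift), ] <- win$onehot[(1L - shift):L, ]
  }
  win$onehot <- out
  win
}

#' Assign windows to folds and build the four train/val/test rotations
#'
#' Windows are shuffled (seeded) and cut into `n_folds` contiguous blocks
#' of near-equal size; four rotations then each hold out one fold for
#' validation and a different fold for testing, with the remaining folds
#' for training.  The four rotations have pairwise distinct test folds
#' (and distinct validation folds).
#'
#' @param n_windows number of windows.
#' @param cfg a [data_config].
#' @param seed integer seed controlling the shuffle.
#' @return list of 4 `split_assignment` objects, each with `fold_of_window`
#'   (integer vector, 1-based fold per window) and `role_of_fold`
#'   (character vector "TRAIN"/"VAL"/"TEST" per fold), plus `rotation`.
#' @export
make_splits <- function(n_windows, cfg = data_config(), seed = 1L) {
  n_windows <- as.integer(n_windows)
  k <- cfg$n_folds
  if (n_windows < k) stop("need at least ", k, " windows, got ", n_windows)
  perm <- with_seed(seed, sample.int(n_windows))
  sizes <- rep(n_windows %/% k, k)
  extra <- n_windows %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold <- integer(n_windows)
  fold[perm] <- rep(seq_len(k), times = sizes)
  lapply(0:3, function(r) {
    role <- rep("TRAIN", k)
    test_fold <- r + 1L
    val_fold <- (r + 1L) %% k + 1L
    role[test_fold] <- "TEST"
    role[val_fold] <- "VAL"
    structure(list(fold_of_window = fold, role_of_fold = role,
                   rotation = r),
              class = "split_assignment")
  })
}

#' Window indices playing a given role in a split rotation
#' @param split a `split_assignment` from [make_splits].
#' @param role one of `"TRAIN"`, `"VAL"`, `"TEST"`.
#' @return integer vector of window indices.
#' @export
split_windows <- function(split, role = c("TRAIN", "VAL", "TEST")) {
  role <- match.arg(role)
  which(split$role_of_fold[split$fold_of_window] == role)
}
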