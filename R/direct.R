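#' Randomly subsample track ids
#'
#' Sampling is without replacement and deterministic given \code{seed};
#' the caller's RNG stream is left untouched. Asking for more tracks than
#' exist returns the full population with a warning. A subsample of the
#' selected tracks is how the full-scale analysis bounds the cost of the
#' direct-connection step (9000 tracks in the reference analysis); on
#' phantoms the recommended default is the full population.
#'
#' @param ids integer vector of track ids.
#' @param n number of ids to draw (0 allowed).
#' @param seed RNG seed.
#' @return Integer vector, a subset of \code{ids}, in increasing order.
#' @export
subsample_tracks <- function(ids, n, seed) {
  stopifnot(n >= 0)
  if (n >= length(ids)) {
    if (n > length(ids))
      warnf("requested %d tracks but only %d available; taking all",
            n, length(ids))
    return(sort(ids))
  }
  sort(with_seed(seed, sample(ids, size = n, replace = FALSE)))
}

#' Cut a visit sequence into direct inter-structure segments
#'
#' A direct segment joins two distinct core nuclei with no third core
#' nucleus along the way. Operationally: visits to non-core labels
#' (internal capsule, named fiber paths, ...) are removed from the sequence
#' -- auxiliary structures are transparent and never break directness --
#' and one segment is emitted per consecutive pair of distinct core labels
#' in what remains. A path [STN, SNc, SNr] therefore yields (STN,SNc) and
#' (SNc,SNr) but never (STN,SNr), and a track that re-enters the same
#' structure with no other core nucleus between yields nothing.
#'
#' Segments are unordered pairs: tractography carries no directionality.
#' Every segment of a track counts, including repeats of the same pair
#' (a [GPe, GPi, GPe] path counts two GPe-GPi segments); set
#' \code{dedupe_per_track} to count each unordered pair at most once per
#' track.
#'
#' @param visits a visit data.frame from \code{\link{label_sequence}}.
#' @param core_five integer labels of the five core nuclei.
#' @param dedupe_per_track if TRUE, keep one segment per distinct unordered
#'   pair per track (default FALSE).
#' @return A data.frame with columns \code{a}, \code{b} (core labels,
#'   \code{a} the earlier structure on the track) and \code{from},
#'   \code{to}: the vertex index of the last vertex inside the first
#'   structure and the first vertex inside the second.
#' @export
cut_direct_segments <- function(visits, core_five, dedupe_per_track = FALSE) {
  v <- visits[visits$label %in% core_five, , drop = FALSE]
  m <- nrow(v)
  empty <- data.frame(a = integer(0), b = integer(0),
                      from = integer(0), to = integer(0))
  if (m < 2L) return(empty)
  a <- v$label[-m]
  b <- v$label[-1L]
  keep <- a != b
  seg <- data.frame(a = a[keep], b = b[keep],
                    from = v$last[-m][keep], to = v$first[-1L][keep])
  if (dedupe_per_track && nrow(seg) > 1L) {
    key <- paste(pmin(seg$a, seg$b), pmax(seg$a, seg$b))
    seg <- seg[!duplicated(key), , drop = FALSE]
  }
  seg
}

#' Count direct connections between the five core nuclei
#'
#' Builds the symmetric 5x5 count matrix over the core nuclei: entry (i, j)
#' is the number of direct segments with endpoints {i, j}. The diagonal is
#' structurally zero (same-structure re-entries emit no segment).
#'
#' @param segments a data.frame of segments (rbind of
#'   \code{\link{cut_direct_segments}} outputs) with columns \code{a},
#'   \code{b}.
#' @param structures a \code{\link{structure_set}} (fixes row/column order
#'   to its \code{core_five}).
#' @return 5x5 symmetric integer matrix with structure names as dimnames.
#' @export
direct_counts <- function(segments, structures) {
  core <- core_labels(structures)
  nm <- structures$core_five
  counts <- matrix(0L, 5L, 5L, dimnames = list(nm, nm))
  if (nrow(segments)) {
    i <- match(segments$a, core)
    j <- match(segments$b, core)
    if (any(is.na(i)) || any(is.na(j)) || any(i == j))
      stopf("segments contain non-core or degenerate endpoint pairs")
    tab <- unclass(table(factor(pmin(i, j), levels = 1:5),
                         factor(pmax(i, j), levels = 1:5)))
    counts <- counts + tab + t(tab)
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(nm, nm)
  }
  counts
}

#' Normalize direct counts per structure
#'
#' Each column j is expressed as a percentage of the total number of direct
#' segments touching structure j, so every nonzero column sums to exactly
#' 100. Because the column totals differ between structures, the percentage
#' matrix is generally asymmetric even though the counts are symmetric.
#' Columns with zero total are returned all-zero and flagged in the
#' \code{"zero_columns"} attribute.
#'
#' @param counts symmetric 5x5 count matrix from \code{\link{direct_counts}}.
#' @return 5x5 numeric percentage matrix; diagonal NA (no self-connections).
#' @export
normalize_direct <- function(counts) {
  if (!isTRUE(all.equal(counts, t(counts))))
    stopf("counts matrix must be symmetric")
  if (any(diag(counts) != 0)) stopf("counts diagonal must be zero")
  totals <- colSums(counts)
  pct <- sweep(counts, 2L, ifelse(totals > 0, totals, 1), "/") * 100
  pct[, totals == 0] <- 0
  diag(pct) <- NA_real_
  attr(pct, "zero_columns") <- colnames(counts)[totals == 0]
  pct
}

#' Direct-connection analysis of selected tracks
#'
#' Convenience wrapper: optionally subsamples the selected tracks, cuts
#' every visit sequence into direct segments, and returns counts and
#' structure-normalized percentages.
#'
#' @param sequences named list of visit data.frames (from
#'   \code{\link{select_seed_tracks}}).
#' @param structures a \code{\link{structure_set}}.
#' @param subsample number of tracks to subsample, or NULL for all.
#' @param seed RNG seed for the subsample step.
#' @param dedupe_per_track passed to \code{\link{cut_direct_segments}}.
#' @return A list with \code{segments} (with a \code{track} id column),
#'   \code{counts}, \code{percent}, \code{ids} (track ids analysed).
#' @export
direct_connectivity <- function(sequences, structures, subsample = NULL,
                                seed = 1L, dedupe_per_track = FALSE) {
  ids <- as.integer(names(sequences))
  if (!is.null(subsample)) {
    ids <- subsample_tracks(ids, subsample, seed)
    sequences <- sequences[as.character(ids)]
  }
  core <- core_labels(structures)
  segs <- lapply(sequences, cut_direct_segments, core_five = core,
                 dedupe_per_track = dedupe_per_track)
  nseg <- vapply(segs, nrow, 0L)
  segments <- do.call(rbind, segs)
  if (is.null(segments))
    segments <- data.frame(a = integer(0), b = integer(0),
                           from = integer(0), to = integer(0))
  segments$track <- rep.int(ids, nseg)
  rownames(segments) <- NULL
  counts <- direct_counts(segments, structures)
  list(segments = segments, counts = counts,
       percent = normalize_direct(counts), ids = ids)
}
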