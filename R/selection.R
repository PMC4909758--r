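#' Compress a streamline into its structure-visit sequence
#'
#' Each vertex is mapped to the voxel under it (nearest voxel centre;
#' out-of-grid vertices count as background) and maximal runs of consecutive
#' vertices inside one nonzero label are compressed into visits. Background
#' runs are omitted, so a track that exits a structure into background and
#' re-enters the same structure produces two visits with the same label.
#'
#' Intersection is vertex-based: a track visits a structure iff at least one
#' vertex maps into it. With the 0.05 mm tracking step against 0.5 mm voxels
#' this is lossless; for coarser tractograms apply \code{\link{densify}}
#' first, since a segment that cuts a voxel corner without placing a vertex
#' inside is not counted as a visit.
#'
#' @param points n x 3 matrix of streamline vertices (world mm), or a
#'   precomputed integer vector of per-vertex labels.
#' @param volume a \code{\link{label_volume}} (ignored when \code{points} is
#'   already a label vector).
#' @param min_visit_vertices minimum run length for a visit to count
#'   (default 1: a single-vertex touch is a visit).
#' @return A data.frame with columns \code{label}, \code{first}, \code{last}
#'   (1-based vertex spans), one row per visit, in track order.
#' @export
label_sequence <- function(points, volume = NULL, min_visit_vertices = 1L) {
  labs <- if (is.matrix(points)) {
    stopifnot(!is.null(volume))
    labels_at(points, volume)
  } else {
    as.integer(points)
  }
  r <- rle(labs)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  keep <- r$values != 0L & r$lengths >= min_visit_vertices
  data.frame(label = r$values[keep], first = first[keep], last = last[keep])
}

#' Does a visit sequence intersect a set of structures?
#'
#' @param visits a visit data.frame from \code{\link{label_sequence}}.
#' @param labels integer label set (composites already resolved, e.g. via
#'   \code{\link{resolve_labels}}).
#' @return TRUE iff any visit's label is in \code{labels}.
#' @export
intersects_structures <- function(visits, labels) {
  any(visits$label %in% labels)
}

#' Select tracks intersecting the seed structures
#'
#' Reduces a tractogram to the tracks whose visit sequence intersects any
#' seed structure (by default STN, SN or GP, with the composites SN and GP
#' expanded to their part labels). Visit sequences for all tracks are
#' computed once and returned for downstream reuse.
#'
#' @param tract a \code{\link{tractogram}}.
#' @param volume a \code{\link{label_volume}}.
#' @param structures a \code{\link{structure_set}}; its \code{seeds} define
#'   the selection.
#' @param min_visit_vertices passed to \code{\link{label_sequence}}.
#' @return A list with \code{selected} (integer ids of selected tracks),
#'   \code{sequences} (visit data.frames for selected tracks, named by id)
#'   and \code{n_total}.
#' @export
select_seed_tracks <- function(tract, volume, structures,
                               min_visit_vertices = 1L) {
  stopifnot(inherits(tract, "bg_tractogram"))
  seeds <- seed_labels(structures)
  if (length(seeds) == 0L) stopf("structure set has no seed structures")
  n <- n_streamlines(tract)
  seqs <- vector("list", n)
  if (n > 0L) {
    # One affine transform + grid lookup over all vertices, then per-track
    # run-length compression.
    npts <- vapply(tract$streamlines, nrow, 0L)
    all_pts <- do.call(rbind, tract$streamlines)
    all_labs <- labels_at(all_pts, volume)
    track_of <- rep.int(seq_len(n), npts)
    lab_split <- split(all_labs, track_of)
    seqs <- lapply(lab_split, label_sequence,
                   min_visit_vertices = min_visit_vertices)
  }
  hit <- vapply(seqs, intersects_structures, FALSE, labels = seeds)
  selected <- which(unname(hit))
  list(selected = selected,
       sequences = stats::setNames(seqs[selected], selected),
       n_total = n)
}
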