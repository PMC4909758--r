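#' Seed-target connectivity table
#'
#' For every seed structure s (by default the five core nuclei) and every
#' requested target t, counts the selected tracks that intersect both s and
#' t and expresses the count as a percentage of all selected tracks through
#' s. Both direct and indirect connections count: "connecting" means
#' co-intersection by the same track, wherever else the track goes.
#'
#' Each track is counted once per (seed, target) pair, even if it leaves the
#' seed at two different borders or traverses the target repeatedly. Because
#' one track usually connects a seed to several targets, a seed's column
#' generally sums to more than 100 percent. Composite targets (SN, GP,
#' structure halves) use union semantics: a track touching both SNc and SNr
#' counts once toward SN. Cells where the target's label set overlaps the
#' seed's are NA (a structure is not its own projection site).
#'
#' @param sequences named list of visit data.frames (from
#'   \code{\link{select_seed_tracks}}).
#' @param structures a \code{\link{structure_set}}.
#' @param seeds character vector of seed names (default: the core five).
#' @param targets character vector of target names (default: all labelled
#'   structures and composites).
#' @return An object of class \code{bg_connectivity_table}: a list with
#'   \code{percent} and \code{count} (targets x seeds matrices) and
#'   \code{total_tracks} (per-seed denominators).
#' @export
seed_target_table <- function(sequences, structures,
                              seeds = structures$core_five,
                              targets = NULL) {
  if (is.null(targets))
    targets <- c(names(structures$labels), names(structures$composites))
  known <- c(names(structures$labels), names(structures$composites))
  bad <- setdiff(c(seeds, targets), known)
  if (length(bad))
    stopf("unknown structure name(s) in table request: %s",
          paste(bad, collapse = ", "))
  track_labels <- lapply(sequences, function(v) unique(v$label))
  seed_sets <- lapply(seeds, function(s) resolve_labels(structures, s))
  target_sets <- lapply(targets, function(t) resolve_labels(structures, t))
  hits_seed <- function(set) vapply(track_labels,
                                    function(l) any(l %in% set), FALSE)
  seed_hit <- vapply(seed_sets, hits_seed,
                     logical(length(track_labels)))
  if (length(track_labels) == 0L)
    seed_hit <- matrix(FALSE, 0L, length(seeds))
  if (length(track_labels) == 1L)
    seed_hit <- matrix(seed_hit, 1L, length(seeds))
  target_hit <- vapply(target_sets, hits_seed,
                       logical(length(track_labels)))
  if (length(track_labels) == 0L)
    target_hit <- matrix(FALSE, 0L, length(targets))
  if (length(track_labels) == 1L)
    target_hit <- matrix(target_hit, 1L, length(targets))
  totals <- colSums(seed_hit)
  count <- matrix(0L, length(targets), length(seeds),
                  dimnames = list(targets, seeds))
  for (j in seq_along(seeds))
    count[, j] <- colSums(target_hit & seed_hit[, j])
  pct <- sweep(count, 2L, ifelse(totals > 0, totals, 1), "/") * 100
  pct[, totals == 0] <- NA_real_
  for (j in seq_along(seeds))   # a structure is not its own target
    for (i in seq_along(targets))
      if (length(intersect(target_sets[[i]], seed_sets[[j]])))
        pct[i, j] <- NA_real_
  structure(list(percent = pct, count = count,
                 total_tracks = stats::setNames(totals, seeds)),
            class = "bg_connectivity_table")
}

#' @export
print.bg_connectivity_table <- function(x, ...) {
  cat("Seed-target connectivity (% of tracks through each seed):\n")
  print(round(x$percent, 1))
  cat("Tracks per seed:\n")
  print(x$total_tracks)
  invisible(x)
}

#' Apply the minimum-connectivity inclusion rule
#'
#' A target row is retained iff its percentage reaches \code{threshold} for
#' at least one seed (the "at least 1 percent of the fibers connecting to
#' either of the nuclei" rule). Dropped targets are recorded in the
#' \code{"dropped"} attribute.
#'
#' @param table a \code{\link{seed_target_table}} result.
#' @param threshold percentage in [0, 100]; default 1.
#' @return The filtered \code{bg_connectivity_table}.
#' @export
apply_inclusion_threshold <- function(table, threshold = 1) {
  stopifnot(threshold >= 0, threshold <= 100)
  # rows that are NA against every seed carry no evidence either way
  # (every cell is a self-overlap), so the rule does not drop them
  keep <- apply(table$percent, 1L,
                function(p) all(is.na(p)) || any(p >= threshold,
                                                 na.rm = TRUE))
  out <- table
  out$percent <- table$percent[keep, , drop = FALSE]
  out$count <- table$count[keep, , drop = FALSE]
  attr(out, "dropped") <- rownames(table$percent)[!keep]
  out
}

#' Voxel-wise projection-fraction map
#'
#' For every voxel of a structure, the percentage of the selected tracks
#' traversing that voxel that also intersect the target: denominator = tracks
#' with at least one vertex in the voxel, numerator = those that also
#' intersect the target anywhere along their course. A track traversing a
#' voxel twice counts once in both terms. Structure voxels traversed by no
#' track carry NaN (a distinguished no-data value, never 0, so downstream
#' statistics are not biased); voxels outside the structure are NaN too.
#'
#' @param tract a \code{\link{tractogram}} (the selected tracks).
#' @param volume a \code{\link{label_volume}}.
#' @param structures a \code{\link{structure_set}}.
#' @param structure,target structure names (composites allowed).
#' @param ids optional track ids to restrict to (defaults to all tracks in
#'   \code{tract}).
#' @return A \code{\link{label_volume}}-shaped list of class
#'   \code{bg_voxel_map} with \code{values} (3D array, percent or NaN),
#'   \code{affine}, \code{structure}, \code{target}; write with
#'   \code{\link{write_voxel_map}}.
#' @export
voxel_projection_map <- function(tract, volume, structures, structure,
                                 target, ids = NULL) {
  s_labs <- resolve_labels(structures, structure)
  t_labs <- resolve_labels(structures, target)
  dims <- dim(volume$grid)
  den <- array(0L, dims)
  num <- array(0L, dims)
  sl <- tract$streamlines
  if (!is.null(ids)) sl <- sl[ids]
  for (pts in sl) {
    idx <- world_to_voxel(pts, volume)
    in_grid <- attr(idx, "in_grid")
    idx <- idx[in_grid, , drop = FALSE]
    if (nrow(idx) == 0L) next
    lin <- unique(1L + idx[, 1L] +
                    dims[1L] * (idx[, 2L] + dims[2L] * idx[, 3L]))
    labs <- volume$grid[lin]
    in_structure <- lin[labs %in% s_labs]
    if (length(in_structure) == 0L) next
    den[in_structure] <- den[in_structure] + 1L
    if (any(labs %in% t_labs))
      num[in_structure] <- num[in_structure] + 1L
  }
  values <- array(NaN, dims)
  svox <- which(array(volume$grid %in% s_labs, dims))
  traversed <- svox[den[svox] > 0L]
  values[traversed] <- 100 * num[traversed] / den[traversed]
  structure(list(values = values, affine = volume$affine,
                 voxel_size = volume$voxel_size,
                 structure = structure, target = target),
            class = "bg_voxel_map")
}

#' Write a voxel projection map as NIfTI
#'
#' The map is aligned to the label volume it was computed from; no-data
#' voxels are stored as NaN.
#'
#' @param map a \code{\link{voxel_projection_map}} result.
#' @param path output \code{.nii} / \code{.nii.gz} path.
#' @export
write_voxel_map <- function(map, path) {
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- map$voxel_size
  xf <- structure(map$affine, code = 2L)
  RNifti::qform(img) <- xf
  RNifti::sform(img) <- xf
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Split a structure into anteromedial and posterolateral halves
#'
#' Splits the voxels of one label by a plane through the structure's
#' voxel-centre centroid. By default the plane is normal to the structure's
#' first principal axis (its longest spatial extent, from PCA of the voxel
#' centres in world space), oriented so the positive side points anteriorly
#' (+y in RAS; ties broken toward -x, then +z): the anteromedial half.
#' Voxels exactly on the plane go to the anteromedial side. An axis-aligned
#' rule is available via \code{plane_rule}.
#'
#' @param volume a \code{\link{label_volume}}.
#' @param label the label to split (must have at least 3 voxels).
#' @param plane_rule \code{"principal"} (default) or \code{"x"}, \code{"y"},
#'   \code{"z"} for an axis-aligned world plane.
#' @param sublabels length-2 integer labels for the (anteromedial,
#'   posterolateral) halves; default: two fresh labels above the current
#'   maximum.
#' @return A new \code{\link{label_volume}} in which \code{label} is
#'   replaced by the two sublabels; attribute \code{"sublabels"} names them.
#' @export
split_structure <- function(volume, label, plane_rule = "principal",
                            sublabels = NULL) {
  vox <- which(volume$grid == label, arr.ind = TRUE)
  if (nrow(vox) < 3L)
    stopf("structure with label %d has fewer than 3 voxels", label)
  if (is.null(sublabels)) {
    mx <- max(volume$grid)
    sublabels <- c(mx + 1L, mx + 2L)
  }
  w <- voxel_to_world(vox - 1L, volume)
  centroid <- colMeans(w)
  if (identical(plane_rule, "principal")) {
    pc <- stats::prcomp(w, center = TRUE, scale. = FALSE)
    v <- pc$rotation[, 1L]
  } else {
    ax <- match(plane_rule, c("x", "y", "z"))
    if (is.na(ax)) stopf("unknown plane_rule: %s", plane_rule)
    v <- c(0, 0, 0); v[ax] <- 1
  }
  # orient toward anterior (+y), tie-break medial (-x) then superior (+z)
  s <- sign(v[2L])
  if (s == 0) s <- sign(-v[1L])
  if (s == 0) s <- sign(v[3L])
  if (s == 0) s <- 1
  v <- v * s
  side <- drop((w - matrix(centroid, nrow(w), 3L, byrow = TRUE)) %*% v)
  grid <- volume$grid
  grid[vox[side >= 0, , drop = FALSE]] <- sublabels[1L]
  grid[vox[side < 0, , drop = FALSE]] <- sublabels[2L]
  out <- label_volume(grid, affine = volume$affine)
  attr(out, "sublabels") <- stats::setNames(
    sublabels, c("anteromedial", "posterolateral"))
  out
}

#' Structure volume in cubic millimetres
#'
#' Voxel count times voxel volume. An absent label yields 0 with a warning.
#'
#' @param volume a \code{\link{label_volume}}.
#' @param label integer label (or vector of labels, summed).
#' @return Volume in mm^3.
#' @export
structure_volume <- function(volume, label) {
  n <- sum(volume$grid %in% label)
  if (n == 0L) warnf("label %s not present in volume",
                     paste(label, collapse = "+"))
  n * prod(volume$voxel_size)
}
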