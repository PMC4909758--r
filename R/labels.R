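#' Integer label volumes
#'
#' A label volume is a 3D grid of non-negative integer labels together with
#' a 4x4 affine mapping 0-based voxel indices to world-space millimetres
#' (voxel-centre convention, RAS). Label 0 is reserved for background; each
#' nonzero label is one structure.
#'
#' @param grid 3D integer array (non-negative).
#' @param affine 4x4 numeric voxel-index-to-world transform; must be
#'   invertible. Default: scaled identity from \code{voxel_size}.
#' @param voxel_size length-3 mm per axis, used only when \code{affine} is
#'   not given.
#' @return An object of class \code{bg_label_volume} with elements
#'   \code{grid}, \code{affine}, \code{voxel_size}.
#' @export
label_volume <- function(grid, affine = NULL, voxel_size = c(1, 1, 1)) {
  if (length(dim(grid)) != 3L) stopf("grid must be a 3D array")
  if (any(!is.finite(grid))) stopf("grid contains non-finite values")
  if (any(grid != round(grid))) stopf("grid contains non-integer labels")
  if (any(grid < 0)) stopf("grid contains negative labels")
  dims <- dim(grid)
  grid <- as.integer(grid)   # plain integer array, no foreign attributes
  dim(grid) <- dims
  if (is.null(affine)) {
    stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
    affine <- diag(c(voxel_size, 1))
  }
  affine <- unclass(as.matrix(affine))
  attributes(affine) <- list(dim = c(4L, 4L))
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stopf("affine must be a finite 4x4 matrix")
  if (abs(det(affine)) < 1e-12) stopf("affine is not invertible")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0)) stopf("voxel size must be strictly positive")
  structure(list(grid = grid, affine = affine, voxel_size = vs),
            class = "bg_label_volume")
}

#' @export
print.bg_label_volume <- function(x, ...) {
  labs <- sort(setdiff(unique(c(x$grid)), 0L))
  cat(sprintf("Label volume %s, voxel %s mm, labels: %s\n",
              paste(dim(x$grid), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              if (length(labs)) paste(labs, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Read / write a NIfTI-1 label volume
#'
#' \code{read_label_volume} accepts integer-typed data, or float-typed data
#' whose values are all exact integers (a common artefact of resampling
#' tools); anything else is rejected. NaNs or a non-invertible affine are
#' format errors.
#'
#' @param path a \code{.nii} or \code{.nii.gz} file.
#' @return \code{read_label_volume}: a \code{\link{label_volume}}.
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L)
    dim(arr) <- dim(arr)[1:3]
  if (any(is.na(arr))) stopf("NaNs in label data: %s", path)
  if (any(arr != round(arr)))
    stopf("non-integer values in label data: %s", path)
  aff <- unclass(RNifti::xform(img))
  label_volume(arr, affine = aff)
}

#' @rdname read_label_volume
#' @param volume a \code{\link{label_volume}}.
#' @return \code{write_label_volume}: \code{path}, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "bg_label_volume"))
  img <- RNifti::asNifti(volume$grid)
  RNifti::pixdim(img) <- volume$voxel_size
  xf <- structure(volume$affine, code = 2L)
  RNifti::qform(img) <- xf
  RNifti::sform(img) <- xf
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert between world coordinates and voxel indices
#'
#' Voxel indices are 0-based and follow the voxel-centre convention: the
#' affine maps index (0,0,0) to the centre of the first voxel. World points
#' are assigned to the nearest voxel centre, with ties at .5 rounded half
#' away from zero. Out-of-grid indices are returned as-is and flagged;
#' callers treat them as background.
#'
#' @param points n x 3 matrix (or length-3 vector) of world-mm coordinates.
#' @param volume a \code{\link{label_volume}}.
#' @return \code{world_to_voxel}: n x 3 integer matrix of 0-based voxel
#'   indices with a logical attribute \code{"in_grid"} (length n).
#' @export
world_to_voxel <- function(points, volume) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  stopifnot(ncol(points) == 3L, all(is.finite(points)))
  inv <- solve(volume$affine)
  cont <- cbind(points, 1) %*% t(inv)
  idx <- round_half_away(cont[, 1:3, drop = FALSE])
  storage.mode(idx) <- "integer"
  dims <- dim(volume$grid)
  in_grid <- idx[, 1L] >= 0L & idx[, 1L] < dims[1L] &
    idx[, 2L] >= 0L & idx[, 2L] < dims[2L] &
    idx[, 3L] >= 0L & idx[, 3L] < dims[3L]
  attr(idx, "in_grid") <- in_grid
  idx
}

#' @rdname world_to_voxel
#' @param idx n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @return \code{voxel_to_world}: n x 3 matrix of voxel-centre world
#'   coordinates in mm.
#' @export
voxel_to_world <- function(idx, volume) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3L)
  stopifnot(ncol(idx) == 3L)
  w <- cbind(idx, 1) %*% t(volume$affine)
  w[, 1:3, drop = FALSE]
}

# Label under each world point; out-of-grid points map to background 0.
labels_at <- function(points, volume) {
  idx <- world_to_voxel(points, volume)
  in_grid <- attr(idx, "in_grid")
  out <- integer(nrow(idx))
  if (any(in_grid))
    out[in_grid] <- volume$grid[idx[in_grid, , drop = FALSE] + 1L]
  out
}

#' Densify a streamline by linear interpolation
#'
#' Inserts equally spaced points on each segment whose length exceeds
#' \code{max_spacing}, preserving all original vertices and their order.
#' Used to guard voxel-label sampling when a tractogram's vertex spacing
#' exceeds the label-volume voxel size; tractograms stepped at 0.05 mm
#' against 0.5 mm voxels need no densification.
#'
#' @param points n x 3 matrix of streamline vertices (world mm).
#' @param max_spacing maximum allowed spacing between consecutive output
#'   vertices, mm; must be > 0.
#' @return m x 3 matrix, m >= n. Returned unchanged (same object) if all
#'   segments are already short enough.
#' @export
densify <- function(points, max_spacing) {
  stopifnot(is.matrix(points), ncol(points) == 3L, max_spacing > 0)
  n <- nrow(points)
  seg <- points[-1L, , drop = FALSE] - points[-n, , drop = FALSE]
  len <- sqrt(rowSums(seg * seg))
  k <- pmax(1L, ceiling(len / max_spacing))  # sub-segments per segment
  if (all(k == 1L)) return(points)
  pieces <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    t <- seq(0, 1, length.out = k[i] + 1L)[-(k[i] + 1L)]
    pieces[[i]] <- cbind(points[i, 1L] + t * seg[i, 1L],
                         points[i, 2L] + t * seg[i, 2L],
                         points[i, 3L] + t * seg[i, 3L])
  }
  rbind(do.call(rbind, pieces), points[n, , drop = FALSE])
}
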