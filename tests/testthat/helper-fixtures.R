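# Shared fixture builders. Everything is generated in code; nothing binary
# ships with the package.

# tiny identity-affine volume with labels placed explicitly:
# labels is a list of entries list(label, i, j, k) in 0-based indices
tiny_volume <- function(dims = c(10L, 10L, 10L), voxel_size = 1,
                        labels = list()) {
  grid <- array(0L, dims)
  for (l in labels) grid[l[2] + 1L, l[3] + 1L, l[4] + 1L] <- l[1]
  label_volume(grid, voxel_size = rep(voxel_size, 3L))
}

# straight streamline between two points at a given step
line_track <- function(from, to, step = 0.1) {
  densify(rbind(from, to), step)
}

# visits data.frame straight from a per-vertex label vector
visits_of <- function(labs) label_sequence(as.integer(labs))

# independent brute-force oracle for direct-segment cutting: for every
# ordered index pair (i, j), i < j, of core visits with distinct labels,
# a segment exists iff no core visit lies strictly between them
brute_force_segments <- function(labels_seq, core) {
  idx <- which(labels_seq %in% core)
  out <- list()
  for (ii in seq_along(idx)) {
    for (jj in seq_along(idx)) {
      if (jj <= ii) next
      i <- idx[ii]; j <- idx[jj]
      if (labels_seq[i] == labels_seq[j]) next
      between <- idx[idx > i & idx < j]
      if (length(between) == 0L)
        out[[length(out) + 1L]] <- sort(c(labels_seq[i], labels_seq[j]))
    }
  }
  if (length(out) == 0L)
    return(data.frame(a = integer(0), b = integer(0)))
  m <- do.call(rbind, out)
  data.frame(a = m[, 1L], b = m[, 2L])
}

# a small paper-like phantom shared by several test files (coarse step for
# speed; the full 0.05 mm step is exercised in the scale rehearsal)
small_phantom <- function(n_tracks = 110, seed = 42L, step = 0.2,
                          n_background = n_tracks %/% 10) {
  make_phantom(paper_like_spec(n_tracks = n_tracks,
                               n_background = n_background,
                               rng_seed = seed, step = step))
}
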