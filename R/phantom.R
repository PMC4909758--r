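#' Synthetic tractography phantoms with closed-form ground truth
#'
#' A phantom specification defines a label volume (analytic ellipsoid/box
#' geometries rasterized onto an isotropic grid), a set of streamline
#' bundles with known structure-visit paths, and the random seed and vertex
#' step controlling generation. Because the intended visit path of every
#' streamline is known, the connectivity tables the analysis should produce
#' are available in closed form (\code{\link{ground_truth_tables}}), making
#' every downstream stage testable by exact integer comparison.
#'
#' Defaults mirror the conditions of the post-mortem dataset the pipeline
#' targets: 0.5 mm isotropic voxels and a 0.05 mm vertex step.
#'
#' @param grid_shape voxels per axis (length 3).
#' @param voxel_size isotropic voxel edge in mm (default 0.5).
#' @param structures list of structure geometries, each a list with
#'   \code{name}, \code{label}, \code{type} ("ellipsoid" or "box"),
#'   \code{centre} (world mm) and \code{semi} (semi-axes / half-widths mm).
#' @param obstacle name of the structure streamlines may cross or circle
#'   (the "capsule"), or NULL.
#' @param bundles list of \code{\link{bundle_spec}}.
#' @param background optional list(\code{n}, \code{from}, \code{to},
#'   \code{jitter}): straight filler streamlines touching no structure.
#' @param rng_seed integer seed; generation is fully deterministic given it.
#' @param step vertex spacing in mm (default 0.05).
#' @param arc_clearance mm of clearance above the obstacle for arc detours
#'   (default 2).
#' @param core_five,composites,seeds passed to \code{\link{structure_set}}.
#' @return An object of class \code{bg_phantom_spec}.
#' @export
phantom_spec <- function(grid_shape, voxel_size = 0.5, structures,
                         obstacle = NULL, bundles = list(),
                         background = NULL, rng_seed = 1L, step = 0.05,
                         arc_clearance = 2,
                         core_five = c("STN", "SNc", "SNr", "GPe", "GPi"),
                         composites = list(SN = c("SNc", "SNr"),
                                           GP = c("GPe", "GPi")),
                         seeds = c("STN", "SN", "GP")) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            voxel_size > 0, step > 0)
  nms <- vapply(structures, `[[`, "", "name")
  if (anyDuplicated(nms)) stopf("duplicate structure names in spec")
  if (!is.null(obstacle) && !obstacle %in% nms)
    stopf("obstacle '%s' is not a defined structure", obstacle)
  for (b in bundles) {
    bad <- setdiff(b$visit_path, nms)
    if (length(bad))
      stopf("bundle references undefined structures: %s",
            paste(bad, collapse = ", "))
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, structures = structures,
                 obstacle = obstacle, bundles = bundles,
                 background = background, rng_seed = as.integer(rng_seed),
                 step = step, arc_clearance = arc_clearance,
                 core_five = core_five, composites = composites,
                 seeds = seeds),
            class = "bg_phantom_spec")
}

#' Bundle specification
#'
#' A bundle is a set of streamlines sharing one ordered structure-visit
#' path and one routing archetype: \code{"straight"} legs,
#' \code{"arc-around-obstacle"} (detour anteriorly, +y, around the obstacle
#' so that no vertex falls inside it), or \code{"through-obstacle"}
#' (straight legs that must place at least one vertex inside the obstacle).
#'
#' @param visit_path ordered character vector of structure names (length
#'   >= 2); repeats allowed (a path like c("GPe","STN","GPe") models a
#'   track leaving a seed at two different borders).
#' @param n_streamlines number of streamlines (>= 1).
#' @param route routing archetype (see above).
#' @param jitter sd in mm of the truncated-Gaussian waypoint perturbation;
#'   truncated so waypoints stay well inside their structures (>= 0).
#' @param offsets optional list of per-visit offsets (each length 3, mm)
#'   added to the structure centres before jitter; used to steer bundles
#'   through chosen entry corridors.
#' @return An object of class \code{bg_bundle_spec}.
#' @export
bundle_spec <- function(visit_path, n_streamlines, route = "straight",
                        jitter = 0.3, offsets = NULL) {
  stopifnot(length(visit_path) >= 2L, n_streamlines >= 1L, jitter >= 0)
  route <- match.arg(route,
                     c("straight", "arc-around-obstacle", "through-obstacle"))
  if (!is.null(offsets) && length(offsets) != length(visit_path))
    stopf("offsets must have one entry per visit_path element")
  structure(list(visit_path = visit_path,
                 n_streamlines = as.integer(n_streamlines),
                 route = route, jitter = jitter, offsets = offsets),
            class = "bg_bundle_spec")
}

struct_by_name <- function(spec, name) {
  for (s in spec$structures) if (s$name == name) return(s)
  stopf("unknown structure: %s", name)
}

# inside test for one geometry at a matrix of points
inside_geometry <- function(pts, geom) {
  d <- sweep(pts, 2L, geom$centre)
  if (geom$type == "ellipsoid") {
    rowSums(sweep(d, 2L, geom$semi, "/")^2) <= 1
  } else {  # box, half-open so face-sharing boxes have disjoint voxel sets
    (d[, 1L] >= -geom$semi[1L] & d[, 1L] < geom$semi[1L] &
       d[, 2L] >= -geom$semi[2L] & d[, 2L] < geom$semi[2L] &
       d[, 3L] >= -geom$semi[3L] & d[, 3L] < geom$semi[3L])
  }
}

#' Rasterize a phantom's structures onto its label grid
#'
#' A voxel gets a structure's label iff its centre lies inside the analytic
#' geometry (ellipsoid: closed inequality; box: half-open, so two boxes
#' sharing a face rasterize disjointly). Any voxel claimed by two
#' geometries is an error naming the colliding pair.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return A \code{\link{label_volume}} with affine
#'   \code{diag(voxel_size)}: voxel (0,0,0) centred at world (0,0,0).
#' @export
rasterize_structures <- function(spec) {
  dims <- spec$grid_shape
  vs <- spec$voxel_size
  ax <- lapply(dims, function(n) (seq_len(n) - 1) * vs)  # voxel centres
  grid <- array(0L, dims)
  owner <- character(0)
  for (s in spec$structures) {
    lo <- s$centre - s$semi - vs
    hi <- s$centre + s$semi + vs
    ii <- which(ax[[1L]] >= lo[1L] & ax[[1L]] <= hi[1L])
    jj <- which(ax[[2L]] >= lo[2L] & ax[[2L]] <= hi[2L])
    kk <- which(ax[[3L]] >= lo[3L] & ax[[3L]] <= hi[3L])
    if (!length(ii) || !length(jj) || !length(kk)) next
    pts <- as.matrix(expand.grid(x = ax[[1L]][ii], y = ax[[2L]][jj],
                                 z = ax[[3L]][kk]))
    ins <- inside_geometry(pts, s)
    if (!any(ins)) next
    sub <- as.matrix(expand.grid(i = ii, j = jj, k = kk))[ins, , drop = FALSE]
    prev <- grid[sub]
    if (any(prev != 0L)) {
      other <- names(which(owner == as.character(prev[prev != 0L][1L])))
      stopf("structures '%s' and '%s' overlap after rasterization",
            s$name, other[1L])
    }
    grid[sub] <- s$label
    owner[s$name] <- as.character(s$label)
  }
  label_volume(grid, voxel_size = rep(vs, 3L))
}

# segment-vs-axis-aligned-bbox intersection (slab method)
segment_hits_bbox <- function(p0, p1, lo, hi) {
  d <- p1 - p0
  tmin <- 0; tmax <- 1
  for (k in 1:3) {
    if (abs(d[k]) < 1e-12) {
      if (p0[k] < lo[k] || p0[k] > hi[k]) return(FALSE)
    } else {
      t1 <- (lo[k] - p0[k]) / d[k]
      t2 <- (hi[k] - p0[k]) / d[k]
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
      if (tmin > tmax) return(FALSE)
    }
  }
  TRUE
}

geometry_bbox <- function(geom) {
  list(lo = geom$centre - geom$semi, hi = geom$centre + geom$semi)
}

# truncated-Gaussian waypoint inside a structure: offset clamped so the
# point stays within 80% of the geometry's extent
jittered_waypoint <- function(geom, jitter, offset = c(0, 0, 0)) {
  p <- geom$centre + offset
  if (jitter > 0) {
    off <- stats::rnorm(3L, 0, jitter)
    off <- pmin(pmax(off, -2 * jitter), 2 * jitter)
    cand <- p + off
    if (geom$type == "ellipsoid") {
      r <- sqrt(sum(((cand - geom$centre) / geom$semi)^2))
      if (r > 0.8) cand <- geom$centre + (cand - geom$centre) * (0.8 / r)
    } else {
      cand <- pmin(pmax(cand, geom$centre - 0.8 * geom$semi),
                   geom$centre + 0.8 * geom$semi)
    }
    p <- cand
  }
  p
}

# control polyline for one leg under the bundle's routing rule
route_leg <- function(p0, p1, route, obstacle_bbox, clearance, grid_extent) {
  if (route != "arc-around-obstacle" || is.null(obstacle_bbox) ||
      !segment_hits_bbox(p0, p1, obstacle_bbox$lo, obstacle_bbox$hi))
    return(rbind(p0, p1))
  # detour anteriorly (+y) over the obstacle, entering and leaving the
  # obstacle's x-slab outside it
  y_clear <- obstacle_bbox$hi[2L] + clearance
  if (y_clear >= grid_extent[2L])
    stopf(paste("arc route impossible: no free corridor anterior to the",
                "obstacle within the grid"))
  margin <- 1.5
  xa <- obstacle_bbox$lo[1L] - margin
  xb <- obstacle_bbox$hi[1L] + margin
  if (p0[1L] > p1[1L]) { tmp <- xa; xa <- xb; xb <- tmp }
  a0 <- c(xa, y_clear, p0[3L])
  a1 <- c(xb, y_clear, p1[3L])
  rbind(p0, a0, a1, p1)
}

#' Synthesize the streamlines of one bundle
#'
#' Each streamline passes through every structure of the bundle's visit
#' path in order, with vertices spaced at most \code{spec$step} apart.
#' Every generated streamline is validated against its intent: its visit
#' sequence over non-obstacle structures must equal the visit path, arc
#' routes must place no vertex in the obstacle, and through routes at least
#' one; any violation (e.g. an arc with no free corridor) is a generation
#' error. Deterministic given \code{seed}.
#'
#' @param bundle a \code{\link{bundle_spec}}.
#' @param spec the parent \code{\link{phantom_spec}}.
#' @param volume the rasterized \code{\link{label_volume}} (computed if
#'   missing).
#' @param seed RNG seed (default: the spec's).
#' @return List of streamline point matrices.
#' @export
synthesize_bundle <- function(bundle, spec, volume = NULL,
                              seed = spec$rng_seed) {
  if (is.null(volume)) volume <- rasterize_structures(spec)
  geoms <- lapply(bundle$visit_path, struct_by_name, spec = spec)
  obs_bbox <- if (!is.null(spec$obstacle))
    geometry_bbox(struct_by_name(spec, spec$obstacle)) else NULL
  obstacle_label <- if (!is.null(spec$obstacle))
    struct_by_name(spec, spec$obstacle)$label else -1L
  grid_extent <- spec$grid_shape * spec$voxel_size
  name_of <- stats::setNames(
    vapply(spec$structures, `[[`, "", "name"),
    vapply(spec$structures, `[[`, 0, "label"))
  expect_names <- bundle$visit_path[
    bundle$visit_path != (spec$obstacle %||% "")]
  with_seed(seed, lapply(seq_len(bundle$n_streamlines), function(i) {
    wps <- lapply(seq_along(geoms), function(k)
      jittered_waypoint(geoms[[k]], bundle$jitter,
                        offset = if (is.null(bundle$offsets)) c(0, 0, 0)
                        else bundle$offsets[[k]]))
    ctrl <- wps[[1L]]
    for (k in seq_len(length(wps) - 1L)) {
      leg <- route_leg(wps[[k]], wps[[k + 1L]], bundle$route, obs_bbox,
                       spec$arc_clearance, grid_extent)
      ctrl <- rbind(ctrl, leg[-1L, , drop = FALSE])
    }
    dup <- c(FALSE, rowSums((ctrl[-1L, , drop = FALSE] -
                               ctrl[-nrow(ctrl), , drop = FALSE])^2) == 0)
    pts <- densify(ctrl[!dup, , drop = FALSE], spec$step)
    labs <- labels_at(pts, volume)
    n_obs <- sum(labs == obstacle_label)
    if (bundle$route %in% c("arc-around-obstacle", "straight") &&
        n_obs > 0L && !(spec$obstacle %||% "") %in% bundle$visit_path)
      stopf("%s-route streamline intersects the obstacle (bundle %s)",
            bundle$route, paste(bundle$visit_path, collapse = "-"))
    if (bundle$route == "through-obstacle" && n_obs == 0L &&
        !(spec$obstacle %in% bundle$visit_path))
      stopf("through-route streamline misses the obstacle (bundle %s)",
            paste(bundle$visit_path, collapse = "-"))
    visits <- label_sequence(labs)
    got <- name_of[as.character(
      visits$label[visits$label != obstacle_label])]
    # boundary aliasing at a jagged rasterized surface can make a track
    # exit and immediately re-enter the same structure; such same-label
    # re-visits change no downstream table, so collapse them before
    # comparing with the intent (the intent itself is never collapsed:
    # its repeats are separated by other structures)
    got <- rle(unname(got))$values
    if (!identical(got, rle(expect_names)$values))
      stopf("bundle %s realized visit sequence [%s] != intended [%s]",
            paste(bundle$visit_path, collapse = "-"),
            paste(got, collapse = ","), paste(expect_names, collapse = ","))
    pts
  }))
}

effective_visited <- function(bundle, spec) {
  v <- unique(bundle$visit_path)
  if (bundle$route == "through-obstacle" && !is.null(spec$obstacle))
    v <- unique(c(v, spec$obstacle))
  v
}

#' Closed-form ground-truth connectivity of a phantom
#'
#' Computes, from the bundle specifications alone (no geometry), the exact
#' tables the analysis pipeline must recover: a visit path contributes one
#' direct segment per consecutive pair of distinct core nuclei after
#' removing non-core names, and one seed-target connection per (seed,
#' other-visited-structure) pair, each track counted once per pair.
#' Through-obstacle routes count the obstacle among the visited structures.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return A list with \code{direct_counts} (5x5 symmetric), \code{percent}
#'   (its structure-normalized twin), \code{seed_totals},
#'   \code{seed_target_counts} (targets x core-five seeds),
#'   \code{n_tracks}, \code{n_background}, \code{n_selected} (tracks whose
#'   path intersects any seed structure).
#' @export
ground_truth_tables <- function(spec) {
  ss <- phantom_structure_set(spec)
  core <- spec$core_five
  direct <- matrix(0L, 5L, 5L, dimnames = list(core, core))
  for (b in spec$bundles) {
    cp <- b$visit_path[b$visit_path %in% core]
    if (length(cp) >= 2L) {
      a <- cp[-length(cp)]; d <- cp[-1L]
      for (k in which(a != d)) {
        direct[a[k], d[k]] <- direct[a[k], d[k]] + b$n_streamlines
        direct[d[k], a[k]] <- direct[d[k], a[k]] + b$n_streamlines
      }
    }
  }
  targets <- c(names(ss$labels), names(ss$composites))
  counts <- matrix(0L, length(targets), 5L,
                   dimnames = list(targets, core))
  totals <- stats::setNames(integer(5L), core)
  seed_sel_labels <- seed_labels(ss)
  n_selected <- 0L
  for (b in spec$bundles) {
    visited <- effective_visited(b, spec)
    vlabs <- resolve_labels(ss, visited)
    if (any(vlabs %in% seed_sel_labels))
      n_selected <- n_selected + b$n_streamlines
    for (s in core) {
      if (!s %in% visited) next
      totals[s] <- totals[s] + b$n_streamlines
      for (t in targets) {
        tl <- resolve_labels(ss, t)
        if (any(tl %in% vlabs))
          counts[t, s] <- counts[t, s] + b$n_streamlines
      }
    }
  }
  n_tracks <- sum(vapply(spec$bundles, `[[`, 0L, "n_streamlines"))
  list(direct_counts = direct, percent = normalize_direct(direct),
       seed_totals = totals, seed_target_counts = counts,
       n_tracks = n_tracks,
       n_background = if (is.null(spec$background)) 0L
       else as.integer(spec$background$n),
       n_selected = n_selected)
}

#' @rdname ground_truth_tables
#' @export
phantom_structure_set <- function(spec) {
  labs <- stats::setNames(vapply(spec$structures, `[[`, 0, "label"),
                          vapply(spec$structures, `[[`, "", "name"))
  structure_set(labs, core_five = spec$core_five,
                composites = spec$composites, seeds = spec$seeds)
}

#' Build a complete phantom
#'
#' Rasterizes the structures, synthesizes every bundle (plus optional
#' background streamlines touching no structure), and returns the label
#' volume, tractogram, structure set and closed-form ground truth. Fully
#' deterministic given the spec's seed. Optionally writes the TCK, NIfTI
#' and ground-truth JSON to a directory.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param out_dir optional output directory for \code{phantom.tck},
#'   \code{labels.nii.gz}, \code{structures.yaml}, \code{ground_truth.json}.
#' @return List with \code{volume}, \code{tract}, \code{structures},
#'   \code{truth}, \code{spec}.
#' @export
make_phantom <- function(spec, out_dir = NULL) {
  volume <- rasterize_structures(spec)
  streamlines <- list()
  for (i in seq_along(spec$bundles)) {
    streamlines <- c(streamlines,
                     synthesize_bundle(spec$bundles[[i]], spec, volume,
                                       seed = spec$rng_seed + i))
  }
  if (!is.null(spec$background)) {
    bg <- spec$background
    jit <- bg$jitter %||% 0.3
    bg_lines <- with_seed(spec$rng_seed + length(spec$bundles) + 1L,
                          lapply(seq_len(bg$n), function(i) {
      off <- if (jit > 0)
        pmin(pmax(stats::rnorm(3L, 0, jit), -2 * jit), 2 * jit)
      else c(0, 0, 0)
      densify(rbind(bg$from + off, bg$to + off), spec$step)
    }))
    for (pts in bg_lines)
      if (any(labels_at(pts, volume) != 0L))
        stopf("background streamline intersects a structure")
    streamlines <- c(streamlines, bg_lines)
  }
  tract <- tractogram(streamlines,
                      header = list(tool = "bgtract phantom",
                                    phantom_seed = spec$rng_seed,
                                    step = spec$step))
  truth <- ground_truth_tables(spec)
  ss <- phantom_structure_set(spec)
  out <- list(volume = volume, tract = tract, structures = ss,
              truth = truth, spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tck(tract, file.path(out_dir, "phantom.tck"))
    write_label_volume(volume, file.path(out_dir, "labels.nii.gz"))
    write_structure_set(ss, file.path(out_dir, "structures.yaml"))
    jsonlite::write_json(
      list(direct_counts = truth$direct_counts,
           seed_totals = truth$seed_totals,
           seed_target_counts = truth$seed_target_counts,
           n_tracks = truth$n_tracks, n_selected = truth$n_selected),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE,
      digits = NA, matrix = "rowmajor")
  }
  out
}
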