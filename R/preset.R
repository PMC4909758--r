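#' The "paper-like" phantom preset
#'
#' Five ellipsoidal nuclei whose analytic volumes follow the reported
#' segmentation volumes (STN 100.5, SNc 138.8, SNr 142.6, GPe 611.9, GPi
#' 271.8 mm^3), a box-shaped "capsule" obstacle separating the pallidum
#' from the STN/SN block, and one bundle for each connection class the
#' analysis must handle: straight within-block connections, arcs circling
#' anteriorly around the capsule, connections crossing straight through it,
#' a pass-through path (STN-SNc-SNr), a double-exit path (GPe-STN-GPe,
#' a track leaving a seed at two different borders), and background
#' streamlines touching nothing (removed by seed selection). The grid is
#' 0.5 mm isotropic and streamline vertices are stepped at 0.05 mm, the
#' resolution and step of the dataset the pipeline targets.
#'
#' @param n_tracks total number of bundle streamlines, split over the 11
#'   bundle classes in fixed proportions (default 1100).
#' @param n_background number of background streamlines (default
#'   \code{n_tracks \%/\% 10}).
#' @param rng_seed integer seed.
#' @param step vertex spacing, mm.
#' @param jitter waypoint jitter, mm.
#' @return A \code{\link{phantom_spec}}.
#' @export
paper_like_spec <- function(n_tracks = 1100, n_background = n_tracks %/% 10,
                            rng_seed = 1L, step = 0.05, jitter = 0.3) {
  vols <- c(STN = 100.5, SNc = 138.8, SNr = 142.6, GPe = 611.9, GPi = 271.8)
  r <- (3 * vols / (4 * pi))^(1 / 3)
  centres <- list(STN = c(8, 18, 12), SNc = c(8, 9, 8), SNr = c(8, 9, 16),
                  GPe = c(23, 9, 12), GPi = c(25, 21, 12))
  structures <- c(
    lapply(names(vols), function(nm)
      list(name = nm, label = match(nm, names(vols)),
           type = "ellipsoid", centre = centres[[nm]],
           semi = rep(unname(r[nm]), 3L))),
    list(list(name = "capsule", label = 9L, type = "box",
              centre = c(14.5, 11.5, 12), semi = c(1.5, 9.5, 10))))
  frac <- c(0.12, 0.12, 0.14, 0.18, 0.08, 0.06, 0.06, 0.08, 0.06,
            0.06, 0.04)
  n <- round(frac * n_tracks)
  n[length(n)] <- max(1L, n_tracks - sum(n[-length(n)]))
  bundles <- list(
    bundle_spec(c("STN", "SNc"), n[1], "straight", jitter),
    bundle_spec(c("STN", "SNr"), n[2], "straight", jitter),
    bundle_spec(c("SNc", "SNr"), n[3], "straight", jitter),
    bundle_spec(c("GPe", "GPi"), n[4], "straight", jitter),
    bundle_spec(c("STN", "GPi"), n[5], "arc-around-obstacle", jitter),
    bundle_spec(c("STN", "GPe"), n[6], "arc-around-obstacle", jitter),
    bundle_spec(c("STN", "GPe"), n[7], "through-obstacle", jitter),
    bundle_spec(c("SNr", "GPe"), n[8], "through-obstacle", jitter),
    bundle_spec(c("SNc", "GPi"), n[9], "arc-around-obstacle", jitter),
    bundle_spec(c("STN", "SNc", "SNr"), n[10], "straight", jitter),
    bundle_spec(c("GPe", "STN", "GPe"), n[11], "arc-around-obstacle",
                jitter,
                offsets = list(c(0, -3, 0), c(0, 0, 0), c(0, 3, 0))))
  background <- if (n_background > 0)
    list(n = n_background, from = c(28, 27, 3), to = c(28, 27, 21),
         jitter = jitter)
  phantom_spec(grid_shape = c(64, 64, 48), voxel_size = 0.5,
               structures = structures, obstacle = "capsule",
               bundles = bundles, background = background,
               rng_seed = rng_seed, step = step)
}

#' Randomized phantom specifications
#'
#' Draws a random but always-valid phantom from the preset's geometry
#' family: a random subset of the 11 bundle classes (always at least two),
#' random per-bundle streamline counts, jitter and vertex step, and mildly
#' shrunken nucleus radii. Used for property-style testing: for every such
#' spec, the pipeline's tables must match \code{\link{ground_truth_tables}}
#' exactly.
#'
#' @param seed integer seed controlling both the spec draw and the
#'   phantom's own generation seed.
#' @param max_per_bundle upper bound on streamlines per bundle (default 12).
#' @return A \code{\link{phantom_spec}}.
#' @export
random_phantom_spec <- function(seed, max_per_bundle = 12L) {
  with_seed(seed, {
    base <- paper_like_spec(n_tracks = 110, n_background = 0,
                            rng_seed = seed,
                            step = stats::runif(1, 0.1, 0.25),
                            jitter = stats::runif(1, 0.1, 0.35))
    shrink <- stats::runif(length(base$structures), 0.88, 1.0)
    for (i in seq_along(base$structures))
      if (base$structures[[i]]$type == "ellipsoid")
        base$structures[[i]]$semi <- base$structures[[i]]$semi * shrink[i]
    keep <- which(stats::runif(length(base$bundles)) < 0.7)
    if (length(keep) < 2L) keep <- sample(seq_along(base$bundles), 2L)
    bundles <- base$bundles[keep]
    for (i in seq_along(bundles))
      bundles[[i]]$n_streamlines <- sample.int(max_per_bundle, 1L) + 2L
    base$bundles <- bundles
    base
  })
}
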