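test_that("rasterization matches a brute-force voxel-centre count for an ellipsoid", {
  spec <- phantom_spec(grid_shape = c(20, 20, 20), voxel_size = 0.5,
                       structures = list(
                         list(name = "STN", label = 1L, type = "ellipsoid",
                              centre = c(5, 5, 5), semi = c(1.5, 1.5, 1.5)),
                         list(name = "SNc", label = 2L, type = "ellipsoid",
                              centre = c(2, 2, 2), semi = c(1, 1, 1)),
                         list(name = "SNr", label = 3L, type = "ellipsoid",
                              centre = c(8, 2, 2), semi = c(1, 1, 1)),
                         list(name = "GPe", label = 4L, type = "ellipsoid",
                              centre = c(2, 8, 2), semi = c(1, 1, 1)),
                         list(name = "GPi", label = 5L, type = "ellipsoid",
                              centre = c(2, 2, 8), semi = c(1, 1, 1))))
  vol <- rasterize_structures(spec)
  # brute force: test every voxel centre against the sphere inequality
  centres <- as.matrix(expand.grid(x = (0:19) * 0.5, y = (0:19) * 0.5,
                                   z = (0:19) * 0.5))
  inside <- rowSums(sweep(centres, 2, c(5, 5, 5))^2) <= 1.5^2
  expect_equal(sum(vol$grid == 1L), sum(inside))
  expect_gt(sum(inside), 0)
})

test_that("two boxes sharing a face rasterize disjointly; overlaps are errors", {
  box <- function(nm, lab, cx) list(name = nm, label = lab, type = "box",
                                    centre = c(cx, 2, 2), semi = c(1, 1, 1))
  spec <- phantom_spec(grid_shape = c(16, 8, 8), voxel_size = 0.5,
                       structures = list(box("STN", 1L, 2), box("SNc", 2L, 4),
                                         box("SNr", 3L, 6),
                                         list(name = "GPe", label = 4L,
                                              type = "box",
                                              centre = c(2, 2, 6.5),
                                              semi = c(1, 1, 1)),
                                         list(name = "GPi", label = 5L,
                                              type = "box",
                                              centre = c(6, 2, 6.5),
                                              semi = c(1, 1, 1))))
  vol <- rasterize_structures(spec)
  expect_equal(sum(vol$grid == 1L), sum(vol$grid == 2L))

  spec$structures[[2]]$centre <- c(3, 2, 2)  # overlaps box 1
  expect_error(rasterize_structures(spec), "overlap")
})

test_that("volume conservation: structure volumes plus background fill the grid", {
  ph <- small_phantom(n_tracks = 12, seed = 5L)
  counted <- sum(vapply(sort(unique(c(ph$volume$grid))), function(l)
    sum(ph$volume$grid == l), 0))
  expect_equal(counted, prod(dim(ph$volume$grid)))
})

test_that("the paper-like preset reproduces the reported structure volume ratios within 10%", {
  ph <- small_phantom(n_tracks = 12, seed = 5L)
  vols <- vapply(1:5, function(l) structure_volume(ph$volume, l), 0)
  reported <- c(100.5, 138.8, 142.6, 611.9, 271.8)
  rel <- (vols / sum(vols)) / (reported / sum(reported)) - 1
  expect_true(all(abs(rel) < 0.10))
})

test_that("ellipsoid volumes are within a voxel shell of the analytic value", {
  ph <- small_phantom(n_tracks = 12, seed = 5L)
  vs <- ph$volume$voxel_size[1]
  for (l in 1:5) {
    s <- ph$spec$structures[[l]]
    r <- s$semi[1]
    v_in <- 4 / 3 * pi * (r - vs)^3   # shell bounds for a sphere
    v_out <- 4 / 3 * pi * (r + vs)^3
    v <- structure_volume(ph$volume, l)
    expect_gt(v, v_in)
    expect_lt(v, v_out)
  }
})

test_that("phantom generation is deterministic: same spec and seed give byte-identical TCK files", {
  spec <- paper_like_spec(n_tracks = 20, rng_seed = 8L, step = 0.2)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.tck"); f2 <- file.path(d, "b.tck")
  write_tck(make_phantom(spec)$tract, f1)
  write_tck(make_phantom(spec)$tract, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("a spec with zero bundles yields an empty tractogram and all-zero ground truth", {
  spec <- paper_like_spec(n_tracks = 12, n_background = 0, rng_seed = 1L)
  spec$bundles <- list()
  ph <- make_phantom(spec)
  expect_equal(n_streamlines(ph$tract), 0L)
  expect_true(all(ph$truth$direct_counts == 0L))
  expect_true(all(ph$truth$seed_target_counts == 0L))
  expect_equal(ph$truth$n_selected, 0L)
})

test_that("route archetypes honour the obstacle: arcs never touch it, through-routes must", {
  spec <- paper_like_spec(n_tracks = 20, rng_seed = 3L, step = 0.2)
  vol <- rasterize_structures(spec)
  cap <- 9L
  arc <- bundle_spec(c("STN", "GPi"), 8, "arc-around-obstacle", 0.3)
  for (pts in synthesize_bundle(arc, spec, vol, seed = 21L)) {
    # per-vertex oracle: map every vertex and check the obstacle label
    expect_false(any(labels_at(pts, vol) == cap))
  }
  thr <- bundle_spec(c("STN", "GPe"), 8, "through-obstacle", 0.3)
  for (pts in synthesize_bundle(thr, spec, vol, seed = 22L)) {
    expect_gt(sum(labels_at(pts, vol) == cap), 0)
  }
})

test_that("an arc route with no free corridor raises a generation error", {
  spec <- paper_like_spec(n_tracks = 12, rng_seed = 1L, step = 0.2)
  # stretch the capsule to the grid's anterior edge: no corridor remains
  spec$structures[[6]]$centre[2] <- 16
  spec$structures[[6]]$semi[2] <- 15.9
  arc <- bundle_spec(c("STN", "GPi"), 2, "arc-around-obstacle", 0.1)
  expect_error(synthesize_bundle(arc, spec, seed = 1L), "corridor")
})

test_that("pass-through bundles visit the intermediate structure strictly between the endpoints", {
  spec <- paper_like_spec(n_tracks = 20, rng_seed = 3L, step = 0.2)
  vol <- rasterize_structures(spec)
  b <- bundle_spec(c("STN", "SNc", "SNr"), 5, "straight", 0.2)
  for (pts in synthesize_bundle(b, spec, vol, seed = 31L)) {
    v <- label_sequence(pts, vol)
    core <- v$label[v$label %in% 1:5]
    expect_equal(rle(core)$values, c(1L, 2L, 3L))
  }
})

test_that("ground-truth tables follow the closed-form counting rules", {
  spec <- paper_like_spec(n_tracks = 12, n_background = 0, rng_seed = 1L)
  spec$bundles <- list(bundle_spec(c("STN", "GPe"), 7))
  gt <- ground_truth_tables(spec)
  expect_equal(gt$direct_counts["STN", "GPe"], 7L)
  expect_equal(gt$direct_counts["GPe", "STN"], 7L)
  expect_equal(sum(gt$direct_counts), 14L)

  spec$bundles <- list(bundle_spec(c("STN", "SNc", "SNr"), 5))
  gt <- ground_truth_tables(spec)
  expect_equal(gt$direct_counts["STN", "SNc"], 5L)
  expect_equal(gt$direct_counts["SNc", "SNr"], 5L)
  expect_equal(gt$direct_counts["STN", "SNr"], 0L)

  # auxiliary structures are transparent to directness
  spec$bundles <- list(bundle_spec(c("GPe", "capsule", "SNr"), 4))
  gt <- ground_truth_tables(spec)
  expect_equal(gt$direct_counts["GPe", "SNr"], 4L)
  # ... and the pipeline agrees on the generated phantom
  ph <- make_phantom(spec)
  res <- run_pipeline(list(phantom = spec))
  expect_identical(res$direct$counts, gt$direct_counts)
})
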