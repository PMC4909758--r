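ss <- structure_set(c(STN = 1, SNc = 2, SNr = 3, GPe = 4, GPi = 5,
                      capsule = 9))

# build named sequences from per-track label vectors
seqs_from <- function(...) {
  l <- lapply(list(...), visits_of)
  names(l) <- seq_along(l)
  l
}

test_that("seed-target percentages are track counts over seed totals", {
  # 10 tracks through STN, 3 of them also touching SNr
  tracks <- c(rep(list(c(1, 0, 3)), 3), rep(list(c(1, 0)), 7))
  tab <- seed_target_table(do.call(seqs_from, tracks), ss)
  expect_equal(tab$total_tracks[["STN"]], 10)
  expect_equal(tab$percent["SNr", "STN"], 30)
  expect_equal(tab$count["SNr", "STN"], 3)
})

test_that("a track leaving a seed at two borders is counted once per pair", {
  # [STN, GPe, STN, SNr]: once for STN's total, once per (STN, target)
  tab <- seed_target_table(seqs_from(c(1, 0, 4, 0, 1, 0, 3)), ss)
  expect_equal(tab$total_tracks[["STN"]], 1)
  expect_equal(tab$count["GPe", "STN"], 1)
  expect_equal(tab$count["SNr", "STN"], 1)
})

test_that("multi-target tracks push seed column sums above 100 percent", {
  tracks <- rep(list(c(1, 0, 2, 0, 3, 0, 4)), 4)
  tab <- seed_target_table(do.call(seqs_from, tracks), ss)
  expect_gt(sum(tab$percent[, "STN"], na.rm = TRUE), 100)
  expect_true(all(tab$percent >= 0 & tab$percent <= 100, na.rm = TRUE))
})

test_that("composite targets use union semantics: SN counts a SNc+SNr track once", {
  tab <- seed_target_table(seqs_from(c(1, 0, 2, 0, 3), c(1, 0, 2)), ss)
  expect_equal(tab$count["SN", "STN"], 2)      # union, not 3
  expect_equal(tab$count["SNc", "STN"], 2)
  expect_equal(tab$count["SNr", "STN"], 1)
  expect_lte(tab$count["SN", "STN"],
             tab$count["SNc", "STN"] + tab$count["SNr", "STN"])
})

test_that("count never exceeds the seed total and unknown targets error", {
  ph <- small_phantom(n_tracks = 60, seed = 31L)
  sel <- select_seed_tracks(ph$tract, ph$volume, ph$structures)
  tab <- seed_target_table(sel$sequences, ph$structures)
  for (s in colnames(tab$count))
    expect_true(all(tab$count[, s] <= tab$total_tracks[[s]]))
  expect_error(seed_target_table(sel$sequences, ph$structures,
                                 targets = "cerebellum"), "unknown")
})

test_that("the inclusion threshold retains a target if any seed reaches it", {
  tracks <- c(rep(list(c(1, 0)), 999), list(c(1, 0, 9)))
  tab <- seed_target_table(do.call(seqs_from, tracks), ss)
  expect_equal(tab$percent["capsule", "STN"], 0.1)
  kept <- apply_inclusion_threshold(tab, 1)
  expect_false("capsule" %in% rownames(kept$percent))
  expect_true("capsule" %in% attr(kept, "dropped"))
  # retained when a single seed reaches the threshold
  kept2 <- apply_inclusion_threshold(tab, 0.1)
  expect_true("capsule" %in% rownames(kept2$percent))
  # threshold 0 is the identity
  expect_equal(apply_inclusion_threshold(tab, 0)$percent, tab$percent)
})

test_that("voxel maps give the per-voxel fraction of traversing tracks reaching the target", {
  # one voxel at (2,2,2), 4 tracks through it, 1 reaching STN at (5,2,2)
  vol <- tiny_volume(labels = list(c(2L, 2L, 2L, 2L), c(1L, 5L, 2L, 2L)))
  ssx <- structure_set(c(STN = 1, SNc = 2, SNr = 3, GPe = 4, GPi = 5),
                       seeds = c("STN", "SNc"))
  mk <- function(to) line_track(c(2, 2, 0.6), to, 0.2)
  to_stn <- densify(rbind(c(2, 2, 0.6), c(2, 2, 2), c(5, 2, 2.4)), 0.2)
  tract <- tractogram(list(to_stn,                      # reaches STN
                           mk(c(2, 2, 3.4)), mk(c(2, 2, 3.4)),
                           mk(c(2, 2, 3.4))))
  map <- voxel_projection_map(tract, vol, ssx, "SNc", "STN")
  expect_equal(map$values[3, 3, 3], 25)
  # a voxel of the structure traversed by no track is NaN, never 0
  vol2 <- tiny_volume(labels = list(c(2L, 2L, 2L, 2L), c(2L, 7L, 7L, 7L),
                                    c(1L, 5L, 2L, 2L)))
  map2 <- voxel_projection_map(tract, vol2, ssx, "SNc", "STN")
  expect_true(is.nan(map2$values[8, 8, 8]))
  expect_true(is.nan(map2$values[1, 1, 1]))  # outside the structure
})

test_that("a track traversing a voxel twice counts once in both terms", {
  vol <- tiny_volume(labels = list(c(2L, 2L, 2L, 2L), c(1L, 5L, 2L, 2L)))
  ssx <- structure_set(c(STN = 1, SNc = 2, SNr = 3, GPe = 4, GPi = 5),
                       seeds = c("STN", "SNc"))
  # out and back through the SNc voxel, then on to STN
  pts <- rbind(c(2, 2, 0.6), c(2, 2, 2.4), c(2, 2, 0.6), c(2, 2, 2),
               c(5, 2, 2.4))
  tract <- tractogram(list(densify(pts, 0.2)))
  map <- voxel_projection_map(tract, vol, ssx, "SNc", "STN")
  expect_equal(map$values[3, 3, 3], 100)
})

test_that("voxel maps written as NIfTI align with the label volume and keep NaN", {
  ph <- small_phantom(n_tracks = 40, seed = 37L)
  sel <- select_seed_tracks(ph$tract, ph$volume, ph$structures)
  map <- voxel_projection_map(ph$tract, ph$volume, ph$structures,
                              "SNc", "STN", ids = sel$selected)
  expect_true(all(map$values >= 0 & map$values <= 100, na.rm = TRUE))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_voxel_map(map, f)
  img <- RNifti::readNifti(f)
  expect_equal(dim(img), dim(ph$volume$grid))
  expect_equal(sum(is.nan(img)), sum(is.nan(map$values)))
  expect_equal(unclass(RNifti::xform(img)), ph$volume$affine,
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("splitting a symmetric box yields equal halves and conserves voxels", {
  grid <- array(0L, c(12, 12, 12))
  grid[3:8, 3:10, 4:9] <- 7L
  vol <- label_volume(grid, voxel_size = c(1, 1, 1))
  out <- split_structure(vol, 7L)
  subs <- attr(out, "sublabels")
  n1 <- sum(out$grid == subs["anteromedial"])
  n2 <- sum(out$grid == subs["posterolateral"])
  expect_equal(n1 + n2, sum(grid == 7L))
  expect_lte(abs(n1 - n2), 1)
  expect_equal(sum(out$grid == 7L), 0)
  # longest extent is y, so the plane normal points anteriorly: the
  # anteromedial half is the high-y half
  amy <- which(out$grid == subs["anteromedial"], arr.ind = TRUE)
  ply <- which(out$grid == subs["posterolateral"], arr.ind = TRUE)
  expect_gt(mean(amy[, 2]), mean(ply[, 2]))
})

test_that("axis-aligned split rule and degenerate structures behave as documented", {
  grid <- array(0L, c(6, 6, 6))
  grid[2:5, 2:5, 2:5] <- 3L
  vol <- label_volume(grid)
  out <- split_structure(vol, 3L, plane_rule = "z",
                         sublabels = c(10L, 11L))
  expect_equal(sum(out$grid == 10L), sum(out$grid == 11L))
  expect_error(split_structure(vol, 99L), "fewer than 3")
})

test_that("per-track union of structure halves equals the whole-structure intersection", {
  ph <- small_phantom(n_tracks = 60, seed = 41L)
  split <- split_structure(ph$volume, 4L)  # GPe
  subs <- attr(split, "sublabels")
  for (pts in ph$tract$streamlines[seq(1, 60, by = 5)]) {
    whole <- any(labels_at(pts, ph$volume) == 4L)
    halves <- labels_at(pts, split)
    expect_equal(whole, any(halves %in% subs))
  }
})

test_that("structure volumes are voxel count times voxel volume", {
  grid <- array(0L, c(10, 10, 10))
  grid[1:4, 1:5, 1:5] <- 2L  # 100 voxels
  vol <- label_volume(grid, voxel_size = c(0.3, 0.3, 0.3))
  expect_equal(structure_volume(vol, 2L), 2.7)
  expect_warning(v0 <- structure_volume(vol, 9L), "not present")
  expect_equal(v0, 0)
})
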