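test_that("generation is deterministic for a fixed seed", {
  cfg <- small_synth(seed = 9L)
  n1 <- generate_network(cfg)
  n2 <- generate_network(cfg)
  expect_identical(n1$stack$voxels, n2$stack$voxels)
  expect_identical(n1$truth$segments, n2$truth$segments)
  n3 <- generate_network(small_synth(seed = 10L))
  expect_false(identical(n1$stack$voxels, n3$stack$voxels))
})

test_that("rarefaction removes a subset of signal, mainly the small classes", {
  dense <- generate_network(small_synth(seed = 12L))
  rare <- generate_network(small_synth(seed = 12L, rarefaction = 0.5))
  # same tree, fewer kept branches: strict voxel containment
  expect_true(all(dense$stack$voxels[rare$stack$voxels]))
  expect_lt(sum(rare$stack$voxels), sum(dense$stack$voxels))
  lad <- caliber_ladder(voxel_area = 1)
  h_d <- class_histogram(classify_vessels(dense$stack, lad))
  h_r <- class_histogram(classify_vessels(rare$stack, lad))
  small <- c("class_4", "class_5", "class_6", "sub_offset")
  large <- c("class_1", "class_2")
  ratio_small <- sum(h_r[small]) / sum(h_d[small])
  ratio_large <- sum(h_r[large]) / sum(h_d[large])
  expect_lt(ratio_small, 0.85)
  expect_gt(ratio_large, ratio_small + 0.05)
})

test_that("an axis-aligned cylinder classifies by its rasterized disk area", {
  # straight segment along x, radius 3 voxels at 1 um spacing
  r_um <- 3
  d <- c(16L, 16L, 30L)
  seg <- data.frame(z0 = 8, y0 = 8, x0 = 2, z1 = 8, y1 = 8, x1 = 28)
  ras <- microangio:::cpp_rasterize_capsules(
    as.matrix(seg[, c("z0", "y0", "x0")]), as.matrix(seg[, c("z1", "y1", "x1")]),
    r_um, d, 1.0)
  b <- binary_stack(ras$voxels, 1)
  # oracle: rasterized disk area = count of unit-grid centers within radius
  centers <- expand.grid(z = (1:16) - 0.5, y = (1:16) - 0.5)
  disk <- sum((centers$z - 8)^2 + (centers$y - 8)^2 <= r_um^2)
  m <- min_cross_section_map(b)
  mid <- m[8, 8, 15]
  expect_equal(mid, disk)
  # interior voxels of the shaft share that minimal cross-section
  expect_true(all(m[b$voxels & rep(seq_len(d[3]) %in% 10:20,
                                   each = d[1] * d[2])] <= disk))
})

test_that("rasterization commutes with axis permutation of the geometry", {
  d <- c(20L, 20L, 20L)
  seg_zyx <- matrix(c(4, 5, 2, 16, 9, 18), nrow = 1)  # (z0,y0,x0,z1,y1,x1)
  ras1 <- microangio:::cpp_rasterize_capsules(
    seg_zyx[, 1:3, drop = FALSE], seg_zyx[, 4:6, drop = FALSE], 2.2, d, 1.0)
  # permute axes (z,y,x) -> (x,z,y) in both geometry and grid
  perm <- c(3, 1, 2)
  ras2 <- microangio:::cpp_rasterize_capsules(
    seg_zyx[, 1:3, drop = FALSE][, perm, drop = FALSE],
    seg_zyx[, 4:6, drop = FALSE][, perm, drop = FALSE], 2.2, d, 1.0)
  expect_identical(aperm(ras1$voxels, perm), ras2$voxels)
})

test_that("oblique segments never show a smaller section than the perpendicular disk", {
  d <- c(24L, 24L, 24L)
  p0 <- matrix(c(4, 4, 4), nrow = 1)
  p1 <- matrix(c(20, 18, 16), nrow = 1)
  r_um <- 2.5
  ras <- microangio:::cpp_rasterize_capsules(p0, p1, r_um, d, 1.0)
  b <- binary_stack(ras$voxels, 1)
  m <- min_cross_section_map(b)
  # conservative lower bound: the inscribed disk of radius r - half-diagonal
  lower <- sum(outer((1:24) - 0.5 - 12, (1:24) - 0.5 - 12,
                     function(a, b) a^2 + b^2) <= (r_um - sqrt(2) / 2)^2)
  interior <- m > 0
  # restrict to voxels away from the capsule caps
  core <- array(FALSE, d)
  core[8:16, 8:16, 8:16] <- TRUE
  vals <- m[interior & core]
  expect_true(all(vals >= lower))
})

test_that("cohorts have the prescribed design and derived seeds", {
  cfg <- small_synth(seed = 5L)
  coh <- make_cohort(cfg, cfg, n_units = 4, stacks_per_unit = 3,
                     master_seed = 77, group_names = c("wt", "twi"))
  expect_length(coh$stacks, 24)
  expect_equal(nrow(coh$manifest), 24)
  expect_equal(sort(unique(coh$manifest$group)), c("twi", "wt"))
  expect_equal(length(unique(coh$manifest$unit_id)), 8)
  expect_equal(anyDuplicated(coh$manifest$seed), 0L)
  coh2 <- make_cohort(cfg, cfg, n_units = 4, stacks_per_unit = 3,
                      master_seed = 77, group_names = c("wt", "twi"))
  expect_identical(coh$stacks[["wt_u2_s3"]]$voxels,
                   coh2$stacks[["wt_u2_s3"]]$voxels)
  expect_error(synth_config(rarefaction = 1.0), "rarefaction")
  expect_error(synth_config(grid_shape = c(4, 4, 4), root_radius_um = 10),
               "too small")
})
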