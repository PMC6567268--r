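test_that("threshold ladder follows round(offset * ratio^k) and rejects bad input", {
  lad <- caliber_ladder(4, 1.8, 6, 0.41)
  expect_identical(lad$thresholds_voxels, c(4L, 7L, 13L, 23L, 42L, 76L, 136L))
  expect_equal(lad$thresholds_um2, c(4, 7, 13, 23, 42, 76, 136) * 0.41)
  expect_identical(caliber_ladder(1, 2.0, 2, 1.0)$thresholds_voxels,
                   c(1L, 2L, 4L))
  expect_error(caliber_ladder(4, 1.0, 6, 0.41), "> 1")
  expect_error(caliber_ladder(0, 1.8, 6, 0.41))
  expect_error(caliber_ladder(4, 1.05, 6, 0.41), "ascending")
})

test_that("min_cross_section matches hand-countable fixtures", {
  v <- array(FALSE, c(9, 9, 9))
  v[5, 5, 5] <- TRUE
  expect_equal(min_cross_section(binary_stack(v, 1), c(5, 5, 5)), 1L)
  expect_error(min_cross_section(binary_stack(v, 1), c(1, 1, 1)), "background")

  # solid 3x3x10 bar: plane areas 9, 30, 30 -> min 9
  bar <- array(FALSE, c(7, 7, 14))
  bar[3:5, 3:5, 3:12] <- TRUE
  expect_equal(min_cross_section(binary_stack(bar, 1), c(4, 4, 7)), 9L)

  # diagonal contact counts as one component under 8-connectivity: two
  # 1-voxel bars along z touch only diagonally in every z-plane, so the
  # minimal plane section has size 2 (it would be 1 under 4-connectivity)
  dg <- array(FALSE, c(6, 5, 5))
  dg[1:6, 2, 2] <- TRUE
  dg[1:6, 3, 3] <- TRUE
  expect_equal(min_cross_section(binary_stack(dg, 1), c(3, 2, 2)), 2L)
})

test_that("optimized cross-section map equals per-voxel brute force on random stacks", {
  set.seed(31)
  for (i in 1:4) {
    d <- sample(5:12, 3, replace = TRUE)
    v <- random_stack(d, runif(1, 0.2, 0.6))
    m <- min_cross_section_map(binary_stack(v, 1))
    idx <- which(v, arr.ind = TRUE)
    take <- idx[sample.int(nrow(idx), min(40, nrow(idx))), , drop = FALSE]
    for (r in seq_len(nrow(take))) {
      expect_equal(m[take[r, 1], take[r, 2], take[r, 3]],
                   naive_min_xsec(v, take[r, 1], take[r, 2], take[r, 3]))
    }
    expect_true(all(m[!v] == 0L))
  }
})

test_that("classification follows the upper-inclusive interval convention", {
  lad <- caliber_ladder(4, 1.8, 6, 1.0)
  # a side x side x len solid bar (len > side) has minimal cross-section
  # side^2 at every interior voxel
  bar_class <- function(side, len = side + 8L) {
    v <- array(FALSE, c(side + 2L, side + 2L, len + 2L))
    v[2:(side + 1), 2:(side + 1), 2:(len + 1)] <- TRUE
    cm <- classify_vessels(binary_stack(v, 1), lad)
    cm$labels[2 + side %/% 2, 2 + side %/% 2, 2 + len %/% 2]
  }
  expect_equal(bar_class(2L), 7L)    # a = 4 <= T0: sub-offset class
  expect_equal(bar_class(3L), 5L)    # a = 9, 7 < 9 <= 13 -> class 5
  expect_equal(bar_class(10L), 1L)   # a = 100, 76 < 100 <= 136 -> class 1
  expect_equal(bar_class(12L), 8L)   # a = 144 > 136 -> over-range sentinel
})

test_that("labels partition the foreground and are axis-permutation invariant", {
  set.seed(33)
  v <- random_stack(c(10, 12, 14), 0.35)
  b <- binary_stack(v, 1)
  lad <- caliber_ladder(4, 1.8, 6, 1.0)
  cm <- classify_vessels(b, lad)
  h <- class_histogram(cm)
  expect_equal(sum(h), sum(v))
  expect_true(all(cm$labels[!v] == 0L))
  expect_true(all(cm$labels[v] > 0L))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    cmp <- classify_vessels(binary_stack(aperm(v, perm), 1), lad)
    expect_equal(unname(class_histogram(cmp)), unname(h))
  }
})

test_that("equivalent diameters convert area to circle diameter", {
  expect_equal(equivalent_diameter(pi), 2)
  expect_equal(equivalent_diameter(c(1.64, 55.76)), c(1.445030, 8.425903),
               tolerance = 1e-6)
})
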