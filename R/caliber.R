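#' Geometric ladder of cross-section thresholds
#'
#' Caliber classes are delimited by cross-section thresholds that grow
#' geometrically from an initial offset: threshold k is
#' `round(offset_voxels * ratio^k)` voxels, k = 0..n_classes, converted to
#' square micrometers through the voxel area. Rounding to integer voxel
#' counts is part of the definition: cross-sections are themselves integer
#' voxel counts. With the defaults (offset 4 voxels at 0.64 um spacing,
#' ratio 1.8, six classes) the ladder is 4/7/13/23/42/76/136 voxels, i.e.
#' approximately 1.6/2.9/5.3/9.4/17/31/56 square micrometers.
#'
#' @param offset_voxels smallest analyzed cross-section, in voxels (>= 1).
#' @param ratio dimensionless multiplier between adjacent thresholds (> 1).
#' @param n_classes number of analyzed caliber classes (>= 1).
#' @param voxel_area in-plane voxel area in square micrometers.
#' @return An object of class `caliber_ladder` with fields `offset_voxels`,
#'   `ratio`, `n_classes`, `voxel_area`, `thresholds_voxels` (T0..Tn,
#'   ascending integers) and `thresholds_um2`.
#' @examples
#' caliber_ladder(4, 1.8, 6, 0.41)
#' @export
caliber_ladder <- function(offset_voxels = 4L, ratio = 1.8, n_classes = 6L,
                           voxel_area = 0.64^2) {
  offset_voxels <- as.integer(offset_voxels)
  n_classes <- as.integer(n_classes)
  if (is.na(offset_voxels) || offset_voxels < 1L)
    stop("`offset_voxels` must be a positive integer")
  if (!is.finite(ratio) || ratio <= 1)
    stop("`ratio` must be > 1 (thresholds must ascend)")
  if (is.na(n_classes) || n_classes < 1L)
    stop("`n_classes` must be >= 1")
  if (!is.finite(voxel_area) || voxel_area <= 0)
    stop("`voxel_area` must be positive")
  tv <- as.integer(round(offset_voxels * ratio^(0:n_classes)))
  if (any(diff(tv) <= 0L))
    stop("thresholds are not strictly ascending; increase `ratio` or `offset_voxels`")
  structure(
    list(offset_voxels = offset_voxels, ratio = ratio, n_classes = n_classes,
         voxel_area = voxel_area, thresholds_voxels = tv,
         thresholds_um2 = tv * voxel_area),
    class = "caliber_ladder"
  )
}

#' @export
print.caliber_ladder <- function(x, ...) {
  cat(sprintf("caliber_ladder: offset %d voxels, ratio %.3g, %d classes (voxel area %.4g um^2)\n",
              x$offset_voxels, x$ratio, x$n_classes, x$voxel_area))
  cat("  thresholds [voxels]:", paste(x$thresholds_voxels, collapse = ", "), "\n")
  cat("  thresholds [um^2]:  ",
      paste(sprintf("%.4g", x$thresholds_um2), collapse = ", "), "\n")
  cat(sprintf("  equivalent diameters: %.2g to %.2g um\n",
              equivalent_diameter(x$thresholds_um2[1]),
              equivalent_diameter(x$thresholds_um2[length(x$thresholds_um2)])))
  invisible(x)
}

#' Circle-equivalent diameter of a cross-sectional area
#'
#' @param area_um2 cross-sectional area in square micrometers.
#' @return Diameter (micrometers) of the circle with that area.
#' @export
equivalent_diameter <- function(area_um2) 2 * sqrt(area_um2 / pi)

#' Per-voxel minimal cross-section map
#'
#' For every foreground voxel, the area (in voxels) of the 8-connected
#' in-plane foreground component containing it is computed in each of the
#' three axis-aligned planes through the voxel; the map records the minimum
#' of the three. This is the caliber proxy: a tube's smallest plane section
#' tracks its true cross-section regardless of orientation.
#'
#' @param b a [binary_stack()].
#' @return Integer array, same dim as the stack; 0 on background.
#' @export
min_cross_section_map <- function(b) {
  if (!inherits(b, "binary_stack")) stop("`b` must be a binary_stack")
  cpp_min_xsec(b$voxels, dim(b$voxels))
}

#' Minimal cross-section through a single voxel
#'
#' @param b a [binary_stack()].
#' @param voxel integer (z, y, x) coordinates, 1-based; must be foreground.
#' @return Integer voxel count of the minimal in-plane component.
#' @export
min_cross_section <- function(b, voxel) {
  if (!inherits(b, "binary_stack")) stop("`b` must be a binary_stack")
  voxel <- as.integer(voxel)
  if (length(voxel) != 3L || anyNA(voxel)) stop("`voxel` must be (z, y, x)")
  d <- dim(b$voxels)
  if (any(voxel < 1L) || any(voxel > d)) stop("`voxel` outside the stack")
  if (!b$voxels[voxel[1], voxel[2], voxel[3]])
    stop("queried voxel is background")
  m <- cpp_min_xsec(b$voxels, d)
  m[voxel[1], voxel[2], voxel[3]]
}

#' Classify foreground voxels into caliber classes
#'
#' Each foreground voxel is assigned by its minimal cross-section `a`
#' (see [min_cross_section_map()]) against the ladder thresholds T0..Tn:
#' label `n_classes + 1` (the sub-offset normalizing class) when `a <= T0`;
#' label `k` (k = 1 largest ... n_classes smallest) when
#' `T[n-k] < a <= T[n-k+1]` (intervals upper-inclusive); and the over-range
#' sentinel `n_classes + 2` when `a > Tn` - such voxels are excluded from
#' every architecture and from normalization.
#'
#' @param b a [binary_stack()] (typically the filled solid-vessel map).
#' @param ladder a [caliber_ladder()] whose `voxel_area` matches the stack.
#' @return An object of class `class_map` with fields `labels` (integer
#'   array), `ladder`, `sub_offset_label`, `over_range_label`.
#' @export
classify_vessels <- function(b, ladder = caliber_ladder(voxel_area = b$voxel_area)) {
  if (!inherits(b, "binary_stack")) stop("`b` must be a binary_stack")
  if (!inherits(ladder, "caliber_ladder")) stop("`ladder` must be a caliber_ladder")
  if (abs(ladder$voxel_area - b$voxel_area) > 1e-6 * b$voxel_area)
    stop("ladder voxel_area does not match the stack's voxel area")
  a <- cpp_min_xsec(b$voxels, dim(b$voxels))
  n <- ladder$n_classes
  # j = number of thresholds strictly below a (a, thresholds both integer)
  j <- findInterval(as.numeric(a) - 0.5, ladder$thresholds_voxels)
  labels <- integer(length(a))
  fg <- a > 0L
  labels[fg & j == 0L] <- n + 1L            # sub-offset, normalizing only
  labels[fg & j > n] <- n + 2L              # over-range, excluded
  mid <- fg & j >= 1L & j <= n
  labels[mid] <- n + 1L - j[mid]            # class 1 = largest analyzed
  labels <- array(labels, dim = dim(b$voxels))
  structure(
    list(labels = labels, ladder = ladder,
         sub_offset_label = n + 1L, over_range_label = n + 2L,
         spacing_iso = b$spacing_iso),
    class = "class_map"
  )
}

#' @export
print.class_map <- function(x, ...) {
  h <- class_histogram(x)
  cat(sprintf("class_map: %s voxels, %d caliber classes\n",
              paste(dim(x$labels), collapse = " x "), x$ladder$n_classes))
  print(h)
  invisible(x)
}

#' Voxel counts per caliber class
#'
#' @param cm a [class_map][classify_vessels()].
#' @return Named integer vector: classes `1..n_classes`, `sub_offset`,
#'   `over_range`.
#' @export
class_histogram <- function(cm) {
  if (!inherits(cm, "class_map")) stop("`cm` must be a class_map")
  n <- cm$ladder$n_classes
  counts <- tabulate(cm$labels[cm$labels > 0L], nbins = n + 2L)
  names(counts) <- c(paste0("class_", seq_len(n)), "sub_offset", "over_range")
  counts
}
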