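#' Parameters for lumen recovery
#'
#' @param close_cycles number of 26-neighborhood dilation steps, followed by
#'   the same number of erosion steps (morphological closing).
#' @param max_fill_voxels cap on the size of any single cavity that may be
#'   filled; components of this size or larger are left open so that
#'   intervascular space is never swallowed.
#' @return An object of class `fill_params`.
#' @export
fill_params <- function(close_cycles = 2L, max_fill_voxels = 1200L) {
  close_cycles <- as.integer(close_cycles)
  max_fill_voxels <- as.integer(max_fill_voxels)
  if (is.na(close_cycles) || close_cycles < 0L)
    stop("`close_cycles` must be a non-negative integer")
  if (is.na(max_fill_voxels) || max_fill_voxels < 1L)
    stop("`max_fill_voxels` must be >= 1")
  structure(list(close_cycles = close_cycles,
                 max_fill_voxels = max_fill_voxels),
            class = "fill_params")
}

#' Recover vessel lumina by size-capped 3D close-and-fill
#'
#' Immunostained vessel walls image as hollow or broken tubes. This step
#' (1) applies a morphological closing (`close_cycles` dilations with the
#' 26-neighborhood, then as many erosions), (2) fills every 6-connected
#' background cavity of the closed image that does not touch a stack face
#' and is smaller than `max_fill_voxels`, and (3) unions the result with the
#' input, so no original foreground voxel is ever lost. The size cap keeps
#' genuine intervascular space open.
#'
#' @param b a [binary_stack()].
#' @param p a [fill_params()] object.
#' @return A [binary_stack()] whose foreground is a superset of `b`'s.
#' @export
close_and_fill <- function(b, p = fill_params()) {
  if (!inherits(b, "binary_stack")) stop("`b` must be a binary_stack")
  if (!inherits(p, "fill_params")) stop("`p` must be a fill_params object")
  d <- dim(b$voxels)
  closed <- b$voxels
  if (p$close_cycles > 0L) {
    for (i in seq_len(p$close_cycles)) closed <- cpp_dilate(closed, d, 26L)
    for (i in seq_len(p$close_cycles)) closed <- cpp_erode(closed, d, 26L)
  }
  bg <- cpp_label(!closed, d, 6L)
  fillable <- which(!bg$touches_face & bg$sizes < p$max_fill_voxels)
  out <- closed | b$voxels
  if (length(fillable) > 0L)
    out <- out | array(bg$labels %in% fillable, dim = d)
  binary_stack(out, b$spacing_iso)
}

#' Restrict classified signal to originally observed voxels
#'
#' Caliber classification runs on the filled solid-vessel map, but only the
#' signal actually acquired should be analyzed: voxels added by
#' [close_and_fill()] are removed again while surviving voxels keep their
#' class.
#'
#' @param classified a [binary_stack()] or [class_map][classify_vessels()]
#'   on the filled map.
#' @param original the [binary_stack()] of original (pre-fill) signal, same
#'   grid shape.
#' @return Same type as `classified`, intersected with `original`.
#' @export
restrict_to_original <- function(classified, original) {
  if (!inherits(original, "binary_stack"))
    stop("`original` must be a binary_stack")
  if (inherits(classified, "binary_stack")) {
    stopifnot_same_shape(classified$voxels, original$voxels)
    return(binary_stack(classified$voxels & original$voxels,
                        classified$spacing_iso))
  }
  if (inherits(classified, "class_map")) {
    stopifnot_same_shape(classified$labels, original$voxels)
    labels <- classified$labels
    labels[!original$voxels] <- 0L
    classified$labels <- labels
    return(classified)
  }
  stop("`classified` must be a binary_stack or class_map")
}
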