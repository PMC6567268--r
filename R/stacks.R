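#' Greyscale image stack with anisotropic voxel spacing
#'
#' Container for a confocal-style z-stack of non-negative intensities.
#' Arrays are stored with `dim = c(nz, ny, nx)` so that `voxels[z, y, x]`
#' addresses optical section `z`.
#'
#' @param voxels 3D numeric array of non-negative intensities, dim (z, y, x).
#' @param spacing numeric length-3 vector of physical voxel size in
#'   micrometers, ordered (z, y, x).
#' @return An object of class `grey_stack` with elements `voxels`, `spacing`.
#' @seealso [read_stack()], [make_isotropic()], [binarize()]
#' @export
grey_stack <- function(voxels, spacing) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("all stack dimensions must be >= 1")
  if (any(voxels < 0)) stop("intensities must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (z, y, x) in micrometers")
  structure(list(voxels = voxels, spacing = spacing), class = "grey_stack")
}

#' Binary isotropic image stack
#'
#' The universal currency of the pipeline: a boolean voxel grid with a single
#' isotropic voxel side. Derived quantities `voxel_area` (square micrometers)
#' and `voxel_volume` (cubic micrometers) are stored for convenience.
#'
#' @param voxels 3D logical array, dim (z, y, x).
#' @param spacing_iso isotropic voxel side in micrometers.
#' @return An object of class `binary_stack`.
#' @export
binary_stack <- function(voxels, spacing_iso) {
  if (is.numeric(voxels)) {
    storage.mode(voxels) <- "logical"
  }
  if (!is.array(voxels) || length(dim(voxels)) != 3L || !is.logical(voxels))
    stop("`voxels` must be a 3D logical array")
  if (anyNA(voxels)) stop("`voxels` must not contain NA")
  spacing_iso <- as.numeric(spacing_iso)
  if (length(spacing_iso) != 1L || !is.finite(spacing_iso) || spacing_iso <= 0)
    stop("`spacing_iso` must be a single positive number")
  structure(
    list(voxels = voxels, spacing_iso = spacing_iso,
         voxel_area = spacing_iso^2, voxel_volume = spacing_iso^3),
    class = "binary_stack"
  )
}

#' @export
print.grey_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("grey_stack: %d x %d x %d voxels (z,y,x), spacing %.3g/%.3g/%.3g um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.binary_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("binary_stack: %d x %d x %d voxels (z,y,x) at %.3g um isotropic\n",
              d[1], d[2], d[3], x$spacing_iso))
  cat(sprintf("  foreground %d voxels (%.3f%% of volume)\n",
              sum(x$voxels), percent_volume(x)))
  invisible(x)
}

#' Read a multi-page TIFF into a greyscale stack
#'
#' Pages become optical sections along z; intensities are preserved bit-exact
#' for 8- and 16-bit integer TIFFs.
#'
#' @param path path to a readable greyscale multi-page TIFF.
#' @param spacing physical voxel size in micrometers, (z, y, x).
#' @return A [grey_stack()].
#' @export
read_stack <- function(path, spacing) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("unreadable TIFF: ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF contains no pages")
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] != 1L) stop("multi-channel TIFF not supported")
      p <- p[, , 1L]
    }
    p
  })
  d1 <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1))))
    stop("inconsistent page dimensions in TIFF")
  vox <- array(0, dim = c(length(pages), d1[1], d1[2]))
  for (i in seq_along(pages)) vox[i, , ] <- pages[[i]]
  grey_stack(vox, spacing)
}

#' Write a stack as a multi-page TIFF
#'
#' Greyscale stacks are written at the requested bit depth; binary stacks are
#' written as 8-bit masks with values 0 and 255.
#'
#' @param x a [grey_stack()] or [binary_stack()].
#' @param path output file path.
#' @param bits bits per sample for greyscale data (8 or 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, bits = 8L) {
  if (inherits(x, "binary_stack")) {
    vox <- array(as.numeric(x$voxels), dim = dim(x$voxels))
    bits <- 8L
  } else if (inherits(x, "grey_stack")) {
    if (!bits %in% c(8L, 16L)) stop("`bits` must be 8 or 16")
    vox <- x$voxels / (2^bits - 1)
    if (max(x$voxels) > 2^bits - 1) stop("intensities exceed requested bit depth")
  } else stop("`x` must be a grey_stack or binary_stack")
  pages <- lapply(seq_len(dim(vox)[1]), function(z) vox[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Resample a stack to isotropic voxels
#'
#' The target spacing is the in-plane spacing; only the z-axis is resampled,
#' by linear interpolation between neighboring optical sections. The z extent
#' becomes `round(nz * spacing_z / spacing_xy)` sections; in-plane dimensions
#' are untouched. Already-isotropic stacks are returned unchanged.
#'
#' @param g a [grey_stack()].
#' @return A [grey_stack()] with equal spacing on all axes.
#' @export
make_isotropic <- function(g) {
  if (!inherits(g, "grey_stack")) stop("`g` must be a grey_stack")
  sp <- g$spacing
  if (abs(sp[2] - sp[3]) > 1e-9 * sp[2])
    stop("in-plane spacing must be equal in y and x")
  zf <- sp[1] / sp[2]
  if (abs(zf - 1) < 1e-12) return(g)
  nz <- dim(g$voxels)[1]
  nz2 <- max(1L, as.integer(round(nz * zf)))
  # output section j (0-based) samples input coordinate j / zf (section units)
  pos <- (seq_len(nz2) - 1) / zf
  pos <- pmin(pmax(pos, 0), nz - 1)
  k0 <- pmin(floor(pos), nz - 2)
  k0[nz < 2] <- 0
  w <- pos - k0
  out <- array(0, dim = c(nz2, dim(g$voxels)[2], dim(g$voxels)[3]))
  if (nz == 1L) {
    for (j in seq_len(nz2)) out[j, , ] <- g$voxels[1, , ]
  } else {
    for (j in seq_len(nz2)) {
      out[j, , ] <- (1 - w[j]) * g$voxels[k0[j] + 1, , ] +
        w[j] * g$voxels[k0[j] + 2, , ]
    }
  }
  grey_stack(out, rep(sp[2], 3))
}

#' Iterative-intermeans (IsoData-variant) threshold
#'
#' The classic automatic threshold: starting from mid-range, the threshold is
#' repeatedly replaced by the mean of the two class means until it stabilizes.
#' Integer-valued data with a range up to 65535 are binned at unit width;
#' other data use 256 equal-width bins over the intensity range.
#'
#' @param x numeric vector (or array) of intensities with >= 2 distinct values.
#' @return The scalar threshold; foreground is the set of values strictly
#'   above it.
#' @export
isodata_threshold <- function(x) {
  x <- as.numeric(x)
  r <- range(x)
  if (r[1] == r[2])
    stop("constant stack: no threshold exists")
  integerish <- all(x == round(x)) && diff(r) <= 65535
  if (integerish) {
    centers <- seq(r[1], r[2])
    counts <- tabulate(as.integer(x - r[1] + 1), nbins = length(centers))
  } else {
    h <- graphics::hist(x, breaks = seq(r[1], r[2], length.out = 257L),
                        plot = FALSE)
    centers <- h$mids
    counts <- h$counts
  }
  t_cur <- mean(r)
  for (it in 1:1000) {
    lo <- centers <= t_cur
    if (!any(lo) || all(lo)) break
    m1 <- sum(centers[lo] * counts[lo]) / sum(counts[lo])
    m2 <- sum(centers[!lo] * counts[!lo]) / sum(counts[!lo])
    t_new <- (m1 + m2) / 2
    if (is.na(t_new) || abs(t_new - t_cur) < 1e-9) break
    t_cur <- t_new
  }
  t_cur
}

#' Binarize a greyscale stack by automatic thresholding
#'
#' Applies the iterative-intermeans threshold to the whole-stack histogram;
#' voxels strictly above the threshold become foreground. The stack must be
#' isotropic (run [make_isotropic()] first). The threshold used is attached
#' as attribute `"threshold"` on the result.
#'
#' @param g a [grey_stack()] with equal spacing on all axes.
#' @return A [binary_stack()] with attribute `threshold`.
#' @export
binarize <- function(g) {
  if (!inherits(g, "grey_stack")) stop("`g` must be a grey_stack")
  if (max(abs(g$spacing - g$spacing[2])) > 1e-9 * g$spacing[2])
    stop("stack is not isotropic; run make_isotropic() first")
  thr <- isodata_threshold(g$voxels)
  b <- binary_stack(g$voxels > thr, g$spacing[2])
  attr(b, "threshold") <- thr
  b
}

stopifnot_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("grid shapes differ")
  invisible(TRUE)
}
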