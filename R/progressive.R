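#' Percent volume occupancy
#'
#' @param b a [binary_stack()], or a logical array.
#' @return 100 x foreground count / total voxel count.
#' @export
percent_volume <- function(b) {
  v <- if (inherits(b, "binary_stack")) b$voxels else b
  100 * sum(v) / length(v)
}

#' Assemble progressively reconstituted vascular trees
#'
#' Architecture k is the union of caliber classes 1..k (largest caliber
#' first), intersected with the originally observed signal; the sequence is
#' nested and culminates in the complete analyzed angioarchitecture at
#' k = n_classes. A further `normalizing_total` additionally includes the
#' sub-offset class and is used only to normalize dispersion for signal
#' amount. Over-range voxels are never included.
#'
#' @param cm a [class_map][classify_vessels()] from the filled map.
#' @param original the original (pre-fill) [binary_stack()], same shape.
#' @return An object of class `progressive_set`: `architectures` (list of
#'   [binary_stack()], length n_classes), `normalizing_total`
#'   ([binary_stack()]), `vol_pct` (per architecture), `vol_pct_total`.
#' @export
build_progressive <- function(cm, original) {
  if (!inherits(cm, "class_map")) stop("`cm` must be a class_map")
  if (!inherits(original, "binary_stack"))
    stop("`original` must be a binary_stack")
  cm <- restrict_to_original(cm, original)
  n <- cm$ladder$n_classes
  labels <- cm$labels
  d <- dim(labels)
  archs <- vector("list", n)
  for (k in seq_len(n)) {
    archs[[k]] <- binary_stack(array(labels >= 1L & labels <= k, dim = d),
                               original$spacing_iso)
  }
  total <- binary_stack(array(labels >= 1L & labels <= n + 1L, dim = d),
                        original$spacing_iso)
  structure(
    list(architectures = archs, normalizing_total = total,
         vol_pct = vapply(archs, percent_volume, numeric(1)),
         vol_pct_total = percent_volume(total)),
    class = "progressive_set"
  )
}

#' @export
print.progressive_set <- function(x, ...) {
  n <- length(x$architectures)
  cat(sprintf("progressive_set: %d nested architectures + normalizing total\n", n))
  cat("  Vol%:", paste(sprintf("%.3f", x$vol_pct), collapse = ", "),
      sprintf("(total %.3f)\n", x$vol_pct_total))
  invisible(x)
}
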