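#' Structuring-element sequences for iterated dilation
#'
#' The dispersion index counts dilation steps, so the element sequence is
#' part of the index definition and must be identical for all compared
#' samples. The `"rhombicuboctahedral"` scheme cycles through the
#' 6-, 18- and 26-neighborhoods; the Minkowski sum of one full cycle is a
#' rhombicuboctahedron-like solid that approximates Euclidean expansion much
#' better than any single cubic element.
#'
#' @param scheme scheme name; currently `"rhombicuboctahedral"`.
#' @return Integer vector of neighborhood sizes, one per step in the cycle.
#' @export
dilation_scheme <- function(scheme = "rhombicuboctahedral") {
  switch(scheme,
         rhombicuboctahedral = c(6L, 18L, 26L),
         stop("unknown dilation scheme: ", scheme))
}

#' One structured dilation step
#'
#' Applies the structuring element that position `step_index` of the
#' repeating scheme cycle prescribes. Dilation is clipped at the stack faces:
#' the acquired field is the reference volume.
#'
#' @param b a non-empty [binary_stack()].
#' @param step_index 1-based step number within the dilation sequence.
#' @param scheme scheme name, see [dilation_scheme()].
#' @return The dilated [binary_stack()] (a superset of the input).
#' @export
dilate_step <- function(b, step_index, scheme = "rhombicuboctahedral") {
  if (!inherits(b, "binary_stack")) stop("`b` must be a binary_stack")
  if (!any(b$voxels)) stop("cannot dilate an empty stack")
  step_index <- as.integer(step_index)
  if (is.na(step_index) || step_index < 1L) stop("`step_index` must be >= 1")
  cyc <- dilation_scheme(scheme)
  conn <- cyc[((step_index - 1L) %% length(cyc)) + 1L]
  binary_stack(cpp_dilate(b$voxels, dim(b$voxels), conn), b$spacing_iso)
}

interp_steps <- function(occupancy, target) {
  # fractional step count to reach `target` Vol% given the per-step
  # occupancy trace (occupancy[1] = before any dilation)
  if (occupancy[1] >= target) return(0)
  k <- which(occupancy >= target)[1]
  if (is.na(k)) stop("trace does not reach target occupancy ", target)
  (k - 2) + (target - occupancy[k - 1]) / (occupancy[k] - occupancy[k - 1])
}

#' Dilate a stack to target occupancies
#'
#' Iterates [dilate_step()] while recording percent occupancy, then converts
#' each target to a fractional step count: if the target falls between the
#' occupancies of steps k-1 and k, the count is `(k-1) + ` the linearly
#' interpolated fraction of the final step. A stack already at or above a
#' target scores 0 for it.
#'
#' @param b a non-empty [binary_stack()].
#' @param targets occupancy targets in percent, each in (0, 100].
#' @param scheme dilation scheme name.
#' @return A list with `trace` (object of class `dilation_trace`: `occupancy`
#'   vector, `scheme`) and `steps` (named numeric, fractional step counts per
#'   target).
#' @export
fill_to_target <- function(b, targets = c(90, 95, 99),
                           scheme = "rhombicuboctahedral") {
  if (!inherits(b, "binary_stack")) stop("`b` must be a binary_stack")
  if (!any(b$voxels)) stop("cannot dilate an empty stack")
  targets <- as.numeric(targets)
  if (any(!is.finite(targets)) || any(targets <= 0) || any(targets > 100))
    stop("`targets` must lie in (0, 100]")
  occ <- cpp_occupancy_trace(b$voxels, dim(b$voxels), max(targets),
                             dilation_scheme(scheme), 100000L)
  steps <- vapply(targets, function(p) interp_steps(occ, p), numeric(1))
  names(steps) <- paste0("hv", targets)
  list(trace = structure(list(occupancy = occ, scheme = scheme),
                         class = "dilation_trace"),
       steps = steps)
}

#' @export
print.dilation_trace <- function(x, ...) {
  cat(sprintf("dilation_trace (%s): %d steps, %.3f%% -> %.3f%% occupancy\n",
              x$scheme, length(x$occupancy) - 1L,
              x$occupancy[1], x$occupancy[length(x$occupancy)]))
  invisible(x)
}

#' Normalize dispersion indices for signal amount
#'
#' Raw Hv counts confound dispersion with signal amount: a sample with less
#' signal needs more dilation regardless of arrangement. The normalization
#' subtracts the fractional number of steps needed to expand the sample from
#' its own occupancy up to the occupancy of the normalizing image (the total
#' architecture with the maximal percent volume among compared samples),
#' using the same interpolation rule on the sample's own trace.
#'
#' @param hv named numeric of raw fractional step counts (from
#'   [fill_to_target()]), typically `hv90`, `hv95`, `hv99`.
#' @param trace the sample's `dilation_trace`.
#' @param norm_vol_pct percent volume of the normalizing image; must be at
#'   least the sample's initial occupancy.
#' @return An object of class `hv_result`: raw `hv*`, normalized `nhv*`, and
#'   `norm_offset`.
#' @export
normalize_hv <- function(hv, trace, norm_vol_pct) {
  if (!inherits(trace, "dilation_trace")) stop("`trace` must be a dilation_trace")
  v0 <- trace$occupancy[1]
  if (norm_vol_pct < v0 - 1e-9)
    stop(sprintf(
      "norm_vol_pct (%.4f) is below the sample's occupancy (%.4f); the normalizing image must have the maximal percent volume",
      norm_vol_pct, v0))
  offset <- interp_steps(trace$occupancy, min(norm_vol_pct, 100))
  nhv <- hv - offset
  names(nhv) <- sub("^hv", "nhv", names(hv))
  structure(c(as.list(hv), as.list(nhv), list(norm_offset = offset)),
            class = "hv_result")
}

#' @export
print.hv_result <- function(x, ...) {
  raw <- grep("^hv", names(x), value = TRUE)
  nrm <- grep("^nhv", names(x), value = TRUE)
  cat("hv_result (fractional dilation steps):\n")
  for (nm in raw) cat(sprintf("  %-6s %8.4f\n", nm, x[[nm]]))
  for (nm in nrm) cat(sprintf("  %-6s %8.4f\n", nm, x[[nm]]))
  cat(sprintf("  norm_offset %.4f\n", x$norm_offset))
  invisible(x)
}
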