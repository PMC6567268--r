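#' Pipeline run configuration
#'
#' Bundles every parameter of the analysis together with the inputs: either
#' in-memory binary stacks (e.g. from [make_cohort()]) or paths to greyscale
#' multi-page TIFFs with their voxel spacing, plus the grouping map
#' stack -> unit (animal) -> group.
#'
#' @param stacks named list of [binary_stack()]s (names = stack ids), or
#'   NULL when reading from `paths`.
#' @param paths named character vector of TIFF paths (names = stack ids),
#'   or NULL.
#' @param spacing (z, y, x) voxel spacing in micrometers for `paths` input.
#' @param grouping data.frame with columns `stack_id`, `unit_id`, `group`
#'   covering every input stack.
#' @param ladder a [caliber_ladder()]; built from the first stack's voxel
#'   area when NULL.
#' @param fill a [fill_params()].
#' @param targets dilation occupancy targets in percent; the analysis index
#'   is the normalized count at 95.
#' @param scheme dilation scheme name (see [dilation_scheme()]).
#' @param include_suboffset_point also emit the sub-offset-inclusive
#'   normalizing total as a 7th fingerprint point (default FALSE: the six
#'   analyzed architectures are the plotted points).
#' @param norm_scope `"all"` (default) picks the normalizing image across
#'   all samples being compared jointly; `"group"` normalizes per group.
#' @param alpha significance level for flagging group differences.
#' @return Object of class `run_config`.
#' @export
run_config <- function(stacks = NULL, paths = NULL, spacing = NULL,
                       grouping, ladder = NULL, fill = fill_params(),
                       targets = c(90, 95, 99),
                       scheme = "rhombicuboctahedral",
                       include_suboffset_point = FALSE,
                       norm_scope = c("all", "group"), alpha = 0.05) {
  norm_scope <- match.arg(norm_scope)
  cfg <- structure(
    list(stacks = stacks, paths = paths, spacing = spacing,
         grouping = grouping, ladder = ladder, fill = fill,
         targets = as.numeric(targets), scheme = scheme,
         include_suboffset_point = isTRUE(include_suboffset_point),
         norm_scope = norm_scope, alpha = alpha),
    class = "run_config")
  errs <- validate_config(cfg)
  if (length(errs) > 0L)
    stop("invalid run_config:\n  ", paste(errs, collapse = "\n  "))
  cfg
}

#' Validate a run configuration
#'
#' @param cfg a `run_config` (or plain list with the same fields).
#' @return Character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  has_stacks <- !is.null(cfg$stacks)
  has_paths <- !is.null(cfg$paths)
  chk(xor(has_stacks, has_paths),
      "exactly one of `stacks` or `paths` must be given")
  ids <- character(0)
  if (has_stacks) {
    chk(is.list(cfg$stacks) && length(cfg$stacks) > 0L &&
          !is.null(names(cfg$stacks)) && all(nzchar(names(cfg$stacks))),
        "`stacks` must be a non-empty named list")
    if (is.list(cfg$stacks))
      chk(all(vapply(cfg$stacks, inherits, logical(1), "binary_stack")),
          "every element of `stacks` must be a binary_stack")
    ids <- names(cfg$stacks)
  }
  if (has_paths) {
    chk(!is.null(names(cfg$paths)) && all(nzchar(names(cfg$paths))),
        "`paths` must be named by stack id")
    missing <- cfg$paths[!file.exists(cfg$paths)]
    chk(length(missing) == 0L,
        paste("missing input file(s):", paste(missing, collapse = ", ")))
    chk(is.numeric(cfg$spacing) && length(cfg$spacing) == 3L &&
          all(cfg$spacing > 0),
        "`spacing` must be 3 positive values (z, y, x) for path input")
    ids <- names(cfg$paths)
  }
  g <- cfg$grouping
  if (is.data.frame(g) &&
      all(c("stack_id", "unit_id", "group") %in% names(g))) {
    uncovered <- setdiff(ids, g$stack_id)
    chk(length(uncovered) == 0L,
        paste("grouping misses stack(s):", paste(uncovered, collapse = ", ")))
    chk(length(unique(g$group)) <= 2L,
        "at most two groups are supported for comparison")
  } else {
    errs <- c(errs, "`grouping` must be a data.frame with stack_id, unit_id, group")
  }
  if (!is.null(cfg$ladder))
    chk(inherits(cfg$ladder, "caliber_ladder"), "`ladder` must be a caliber_ladder")
  chk(inherits(cfg$fill, "fill_params"), "`fill` must be a fill_params")
  chk(is.numeric(cfg$targets) && all(cfg$targets > 0 & cfg$targets <= 100),
      "`targets` must lie in (0, 100]")
  chk(95 %in% cfg$targets, "`targets` must include 95 (the analysis index)")
  errs
}

#' Analyze a single binary stack up to its dilation traces
#'
#' Runs lumen recovery, caliber classification, restriction to original
#' signal, progressive-tree assembly and the occupancy traces for every
#' architecture. Normalization is deferred: it needs the maximal percent
#' volume across the whole comparison set.
#'
#' @param b original (pre-fill) [binary_stack()].
#' @param ladder a [caliber_ladder()].
#' @param fill a [fill_params()].
#' @param targets occupancy targets (percent).
#' @param scheme dilation scheme name.
#' @return List with `progressive` ([build_progressive()] result), `traces`
#'   and `steps` per architecture (NULL for empty architectures), and the
#'   class histogram.
#' @export
analyze_stack <- function(b, ladder = caliber_ladder(voxel_area = b$voxel_area),
                          fill = fill_params(), targets = c(90, 95, 99),
                          scheme = "rhombicuboctahedral") {
  filled <- close_and_fill(b, fill)
  cm <- classify_vessels(filled, ladder)
  ps <- build_progressive(cm, b)
  runs <- lapply(ps$architectures, function(a) {
    if (!any(a$voxels)) return(NULL)
    fill_to_target(a, targets, scheme)
  })
  total_run <- if (any(ps$normalizing_total$voxels))
    fill_to_target(ps$normalizing_total, targets, scheme) else NULL
  list(progressive = ps,
       traces = lapply(runs, function(r) r$trace),
       steps = lapply(runs, function(r) r$steps),
       total_trace = if (is.null(total_run)) NULL else total_run$trace,
       total_steps = if (is.null(total_run)) NULL else total_run$steps,
       histogram = class_histogram(restrict_to_original(cm, b)))
}

#' Run the full angioarchitecture pipeline on a comparison set
#'
#' For every stack: lumen recovery, caliber classification, restriction to
#' the original signal, progressive trees, percent volume and dilation
#' traces. The normalizing image is the total architecture of the sample
#' with the maximal percent volume (across all compared samples by
#' default); every architecture's raw dispersion is normalized against it.
#' Per-unit fingerprints are then fitted and, when two groups are present,
#' compared: slopes by the pooled F-test, amount parameters (a, d, e) by
#' t-tests, dispersion parameters (b, f, g) by Mann-Whitney.
#'
#' @param cfg a [run_config()].
#' @return Object of class `angio_result`: `points` (per stack x
#'   architecture: Vol%, raw and normalized dispersion), `stack_table`,
#'   `fingerprints` (per unit), `unit_params`, `slope_test`, `param_test`,
#'   `norm_vol_pct`, `ladder`, `config`.
#' @export
run_pipeline <- function(cfg) {
  errs <- validate_config(cfg)
  if (length(errs) > 0L)
    stop("invalid run_config:\n  ", paste(errs, collapse = "\n  "))
  stacks <- cfg$stacks
  if (is.null(stacks)) {
    stacks <- lapply(cfg$paths, function(p)
      binarize(make_isotropic(read_stack(p, cfg$spacing))))
    names(stacks) <- names(cfg$paths)
  }
  ladder <- cfg$ladder
  if (is.null(ladder))
    ladder <- caliber_ladder(voxel_area = stacks[[1L]]$voxel_area)
  grouping <- cfg$grouping
  groups <- unique(grouping$group)

  analyses <- list()
  for (sid in names(stacks)) {
    analyses[[sid]] <- tryCatch(
      analyze_stack(stacks[[sid]], ladder, cfg$fill, cfg$targets, cfg$scheme),
      error = function(e) stop("stack '", sid, "', stage analyze: ",
                               conditionMessage(e), call. = FALSE))
  }

  totals <- vapply(analyses, function(a) a$progressive$vol_pct_total, numeric(1))
  norm_for <- function(sid) {
    if (cfg$norm_scope == "all") return(max(totals))
    grp <- grouping$group[match(sid, grouping$stack_id)]
    in_grp <- grouping$stack_id[grouping$group == grp]
    max(totals[names(totals) %in% in_grp])
  }

  n <- ladder$n_classes
  rows <- list()
  for (sid in names(analyses)) {
    an <- analyses[[sid]]
    gi <- match(sid, grouping$stack_id)
    norm_pct <- norm_for(sid)
    ks <- seq_len(n)
    if (cfg$include_suboffset_point) ks <- c(ks, n + 1L)
    for (k in ks) {
      if (k <= n) {
        steps <- an$steps[[k]]; trace <- an$traces[[k]]
        vol <- an$progressive$vol_pct[k]
      } else {
        steps <- an$total_steps; trace <- an$total_trace
        vol <- an$progressive$vol_pct_total
      }
      if (is.null(steps)) next  # empty architecture: no point
      hv <- normalize_hv(steps, trace, norm_pct)
      rows[[length(rows) + 1L]] <- data.frame(
        stack_id = sid, unit_id = grouping$unit_id[gi],
        group = grouping$group[gi], k = k, vol_pct = vol,
        hv90 = hv$hv90, hv95 = hv$hv95, hv99 = hv$hv99,
        nhv90 = hv$nhv90, nhv95 = hv$nhv95, nhv99 = hv$nhv99,
        norm_offset = hv$norm_offset)
    }
  }
  points <- do.call(rbind, rows)

  stack_table <- data.frame(
    stack_id = names(analyses),
    unit_id = grouping$unit_id[match(names(analyses), grouping$stack_id)],
    group = grouping$group[match(names(analyses), grouping$stack_id)],
    vol_pct_total = unname(totals))

  fingerprints <- list()
  unit_params <- list()
  for (uid in unique(grouping$unit_id)) {
    up <- points[points$unit_id == uid & points$k <= n, , drop = FALSE]
    fp <- tryCatch(fit_fingerprint(up, n_classes = n), error = function(e) NULL)
    if (is.null(fp)) next
    fingerprints[[uid]] <- fp
    unit_params[[uid]] <- data.frame(
      unit_id = uid, group = grouping$group[match(uid, grouping$unit_id)],
      slope = fp$slope, r2 = fp$r2, a = fp$a, b = fp$b, d = fp$d,
      e = fp$e, f = fp$f, g = fp$g)
  }
  unit_params <- do.call(rbind, c(unit_params, list(make.row.names = FALSE)))

  slope_test <- NULL
  param_test <- NULL
  if (length(groups) == 2L && !is.null(unit_params)) {
    ptsA <- points[points$group == groups[1] & points$k <= n, ]
    ptsB <- points[points$group == groups[2] & points$k <= n, ]
    slope_test <- tryCatch(compare_slopes(ptsA, ptsB), error = function(e) NULL)
    pA <- unit_params[unit_params$group == groups[1], ]
    pB <- unit_params[unit_params$group == groups[2], ]
    param_test <- tryCatch(compare_parameters(pA, pB, alpha = cfg$alpha),
                           error = function(e) NULL)
  }

  structure(
    list(points = points, stack_table = stack_table,
         fingerprints = fingerprints, unit_params = unit_params,
         slope_test = slope_test, param_test = param_test,
         norm_vol_pct = if (cfg$norm_scope == "all") max(totals) else
           vapply(unique(grouping$group), function(g)
             max(totals[names(totals) %in%
                          grouping$stack_id[grouping$group == g]]),
             numeric(1)),
         groups = groups, ladder = ladder, config = cfg),
    class = "angio_result")
}

#' @export
print.angio_result <- function(x, ...) {
  cat(sprintf("angio_result: %d stacks, %d units, group(s): %s\n",
              nrow(x$stack_table), length(x$fingerprints),
              paste(x$groups, collapse = ", ")))
  cat(sprintf("  normalizing Vol%%: %s\n",
              paste(sprintf("%.3f", x$norm_vol_pct), collapse = ", ")))
  if (!is.null(x$unit_params)) {
    cat("  per-unit fingerprints:\n")
    up <- x$unit_params
    up[-(1:2)] <- lapply(up[-(1:2)], signif, 4)
    print(up, row.names = FALSE)
  }
  if (!is.null(x$slope_test)) print(x$slope_test)
  if (!is.null(x$param_test)) print(x$param_test)
  invisible(x)
}
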