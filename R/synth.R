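#' Configuration for the synthetic vascular-network generator
#'
#' Random branching tubular trees are grown from seed vessels, tapered at
#' bifurcations, pruned below a radius floor, optionally rarefied (deletion
#' of thin terminal segments, the synthetic analogue of small-capillary
#' loss), and rasterized as capsules onto an isotropic voxel grid. Defaults
#' are scaled for desk-size grids while spanning the full analyzed caliber
#' range (vessel diameters roughly 1.4 to 8.4 micrometers).
#'
#' @param grid_shape integer (z, y, x) grid extent in voxels.
#' @param spacing_iso isotropic voxel side, micrometers.
#' @param n_roots number of seed vessels.
#' @param root_radius_um seed vessel radius, micrometers.
#' @param taper child/parent radius ratio applied at each bifurcation,
#'   in (0, 1].
#' @param branch_prob probability that a segment ends in a bifurcation
#'   (otherwise the branch continues at unchanged radius).
#' @param segment_len_um mean segment length, micrometers.
#' @param min_radius_um pruning floor: children thinner than this are not
#'   grown.
#' @param rarefaction fraction of thin vessel branches deleted, in [0, 1).
#' @param rarefy_radius_um caliber cutoff for rarefaction: maximal subtrees
#'   whose segments all have radius at or below this are the deletable units
#'   (thin-capillary loss). The default 1.75 corresponds to cross-sections
#'   in the three smallest analyzed caliber classes at 0.64 um spacing.
#' @param turn_sd_deg bounded turning: maximal deviation (degrees) of a
#'   continuing segment's direction from its parent's.
#' @param branch_angle_deg maximal half-angle (degrees) between a parent and
#'   each child at a bifurcation.
#' @param max_segments safety cap on tree size.
#' @param seed RNG seed; the generator is fully deterministic given the seed.
#' @return Validated list of class `synth_config`.
#' @export
synth_config <- function(grid_shape = c(96L, 192L, 192L),
                         spacing_iso = 0.64,
                         n_roots = 6L,
                         root_radius_um = 3.2,
                         taper = 0.75,
                         branch_prob = 0.65,
                         segment_len_um = 18,
                         min_radius_um = 0.7,
                         rarefaction = 0,
                         rarefy_radius_um = 1.75,
                         turn_sd_deg = 30,
                         branch_angle_deg = 45,
                         max_segments = 4000L,
                         seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape), spacing_iso = spacing_iso,
              n_roots = as.integer(n_roots), root_radius_um = root_radius_um,
              taper = taper, branch_prob = branch_prob,
              segment_len_um = segment_len_um, min_radius_um = min_radius_um,
              rarefaction = rarefaction, rarefy_radius_um = rarefy_radius_um,
              turn_sd_deg = turn_sd_deg, branch_angle_deg = branch_angle_deg,
              max_segments = as.integer(max_segments), seed = as.integer(seed))
  errs <- validate_synth_config(cfg)
  if (length(errs) > 0L) stop(paste(errs, collapse = "; "))
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(length(cfg$grid_shape) == 3L && all(cfg$grid_shape >= 1L),
      "grid_shape must be 3 positive integers (z, y, x)")
  chk(is.numeric(cfg$spacing_iso) && cfg$spacing_iso > 0,
      "spacing_iso must be positive")
  chk(cfg$n_roots >= 1L, "n_roots must be >= 1")
  chk(cfg$root_radius_um > 0, "root_radius_um must be positive")
  chk(cfg$taper > 0 && cfg$taper <= 1, "taper must be in (0, 1]")
  chk(cfg$branch_prob >= 0 && cfg$branch_prob <= 1,
      "branch_prob must be in [0, 1]")
  chk(cfg$segment_len_um > 0, "segment_len_um must be positive")
  chk(cfg$min_radius_um > 0, "min_radius_um must be positive")
  chk(cfg$rarefaction >= 0 && cfg$rarefaction < 1,
      "rarefaction must be in [0, 1)")
  chk(cfg$rarefy_radius_um > 0, "rarefy_radius_um must be positive")
  chk(cfg$max_segments >= 1L, "max_segments must be >= 1")
  if (length(cfg$grid_shape) == 3L && is.numeric(cfg$spacing_iso) &&
      cfg$spacing_iso > 0 && is.numeric(cfg$root_radius_um)) {
    ext <- cfg$grid_shape * cfg$spacing_iso
    chk(all(ext / 2 >= cfg$root_radius_um),
        "grid too small to hold a root radius")
  }
  errs
}

# unit vector uniformly distributed within a cone of half-angle `ang_deg`
# around unit vector `dir`
perturb_direction <- function(dir, ang_deg) {
  theta <- acos(1 - stats::runif(1) * (1 - cos(ang_deg * pi / 180)))
  phi <- stats::runif(1, 0, 2 * pi)
  # orthonormal basis around dir
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * dir) * dir
  u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  out <- cos(theta) * dir + sin(theta) * (cos(phi) * u + sin(phi) * v)
  out / sqrt(sum(out^2))
}

random_unit_vector <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  c(z, r * cos(phi), r * sin(phi))
}

#' Generate a synthetic vascular network
#'
#' Grows `n_roots` random branching trees inside the grid (bounded turning
#' angles, reflection at the field boundary, taper at bifurcations, pruning
#' below the radius floor), deletes a `rarefaction` fraction of the thin
#' vessel branches (maximal subtrees below the radius cutoff, removed
#' whole), and rasterizes all surviving segments as capsules: a voxel is
#' foreground when its center lies within a segment's radius.
#'
#' @param cfg a [synth_config()].
#' @return A list with `stack` (a [binary_stack()]) and `truth` (the ground
#'   truth: `segments` data.frame with start/end coordinates in micrometers,
#'   `radius_um`, `terminal` and `kept` flags, and `radius_map`, the
#'   per-voxel generating radius).
#' @export
generate_network <- function(cfg = synth_config()) {
  if (!inherits(cfg, "synth_config")) stop("`cfg` must be a synth_config")
  set.seed(cfg$seed)
  ext <- cfg$grid_shape * cfg$spacing_iso  # (z, y, x) extent in um
  segs <- list()
  n_children <- integer(0)
  # active tips: position, direction, radius, parent segment index
  tips <- vector("list", cfg$n_roots)
  for (i in seq_len(cfg$n_roots)) {
    pos <- stats::runif(3) * ext
    tips[[i]] <- list(pos = pos, dir = random_unit_vector(),
                      radius = cfg$root_radius_um, parent = 0L)
  }
  head <- 1L
  while (head <= length(tips) && length(segs) < cfg$max_segments) {
    tip <- tips[[head]]
    head <- head + 1L
    len <- stats::rnorm(1, cfg$segment_len_um, 0.25 * cfg$segment_len_um)
    len <- max(len, 0.25 * cfg$segment_len_um)
    p1 <- tip$pos + len * tip$dir
    dir <- tip$dir
    # reflect at the field boundary: growth stays inside the acquired volume
    for (i in 1:3) {
      while (p1[i] < 0 || p1[i] > ext[i]) {
        if (p1[i] < 0) p1[i] <- -p1[i] else p1[i] <- 2 * ext[i] - p1[i]
        dir[i] <- -dir[i]
      }
    }
    si <- length(segs) + 1L
    segs[[si]] <- c(tip$pos, p1, tip$radius, tip$parent)
    n_children[si] <- 0L
    if (tip$parent > 0L) n_children[tip$parent] <- n_children[tip$parent] + 1L
    if (stats::runif(1) < cfg$branch_prob) {
      r_child <- tip$radius * cfg$taper
      if (r_child >= cfg$min_radius_um) {
        for (j in 1:2) {
          tips[[length(tips) + 1L]] <- list(
            pos = p1, dir = perturb_direction(dir, cfg$branch_angle_deg),
            radius = r_child, parent = si)
        }
      }
    } else {
      tips[[length(tips) + 1L]] <- list(
        pos = p1, dir = perturb_direction(dir, cfg$turn_sd_deg),
        radius = tip$radius, parent = si)
    }
  }
  m <- do.call(rbind, segs)
  segments <- data.frame(
    z0 = m[, 1], y0 = m[, 2], x0 = m[, 3],
    z1 = m[, 4], y1 = m[, 5], x1 = m[, 6],
    radius_um = m[, 7], parent = as.integer(m[, 8]),
    terminal = n_children[seq_len(nrow(m))] == 0L
  )
  segments$kept <- TRUE
  # rarefaction removes whole thin branches (vessel regression): eligible
  # units are the maximal subtrees made of segments at or below the radius
  # cutoff; a deleted entry segment takes all its descendants with it
  thin <- segments$radius_um <= cfg$rarefy_radius_um
  entry <- thin & (segments$parent == 0L | !thin[pmax(segments$parent, 1L)])
  eligible <- which(entry)
  if (cfg$rarefaction > 0 && length(eligible) > 0L) {
    n_del <- round(cfg$rarefaction * length(eligible))
    if (n_del > 0L) {
      removed <- logical(nrow(segments))
      removed[eligible[sample.int(length(eligible), n_del)]] <- TRUE
      # parents precede children, so one forward pass propagates removal
      for (i in seq_len(nrow(segments))) {
        p <- segments$parent[i]
        if (p > 0L && removed[p]) removed[i] <- TRUE
      }
      segments$kept <- !removed
    }
  }
  keep <- segments$kept
  ras <- cpp_rasterize_capsules(
    as.matrix(segments[keep, c("z0", "y0", "x0")]),
    as.matrix(segments[keep, c("z1", "y1", "x1")]),
    segments$radius_um[keep], cfg$grid_shape, cfg$spacing_iso)
  list(stack = binary_stack(ras$voxels, cfg$spacing_iso),
       truth = list(segments = segments, radius_map = ras$radius_map))
}

#' Generate a labeled two-group cohort of synthetic stacks
#'
#' Emulates the design of a two-condition animal study: `n_units` animals
#' per group, several z-stacks per animal, one condition typically rarefied
#' relative to the other. Per-stack seeds are derived from `master_seed` by
#' fixed arithmetic so the cohort is reproducible piecewise.
#'
#' @param cfg_a,cfg_b [synth_config()]s for the two groups (e.g. control
#'   vs rarefied); their `seed` fields are overridden per stack.
#' @param n_units animals per group.
#' @param stacks_per_unit z-stacks per animal.
#' @param master_seed master RNG seed.
#' @param group_names labels for the two groups.
#' @return A list with `stacks` (named list of [binary_stack()]) and
#'   `manifest` (data.frame: `stack_id`, `unit_id`, `group`, `seed`).
#' @export
make_cohort <- function(cfg_a, cfg_b, n_units = 4L, stacks_per_unit = 3L,
                        master_seed = 1L, group_names = c("A", "B")) {
  if (!inherits(cfg_a, "synth_config") || !inherits(cfg_b, "synth_config"))
    stop("`cfg_a` and `cfg_b` must be synth_config objects")
  n_units <- as.integer(n_units)
  stacks_per_unit <- as.integer(stacks_per_unit)
  if (n_units < 1L || stacks_per_unit < 1L)
    stop("`n_units` and `stacks_per_unit` must be >= 1")
  stacks <- list()
  manifest <- list()
  for (gi in 1:2) {
    cfg <- if (gi == 1L) cfg_a else cfg_b
    for (u in seq_len(n_units)) {
      for (s in seq_len(stacks_per_unit)) {
        seed <- (as.integer(master_seed) + 499979L * (gi - 1L) +
                 7919L * (u - 1L) + 104729L * (s - 1L)) %% .Machine$integer.max
        cfg_s <- cfg
        cfg_s$seed <- as.integer(seed)
        sid <- sprintf("%s_u%d_s%d", group_names[gi], u, s)
        stacks[[sid]] <- generate_network(cfg_s)$stack
        manifest[[sid]] <- data.frame(
          stack_id = sid, unit_id = sprintf("%s_u%d", group_names[gi], u),
          group = group_names[gi], seed = seed)
      }
    }
  }
  list(stacks = stacks, manifest = do.call(rbind, c(manifest, list(make.row.names = FALSE))))
}
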