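# Naive reference implementations used as independent oracles on small
# fixtures. These deliberately share no code with the package internals.

# offsets of the 6/18/26 neighborhoods
neigh_offsets <- function(conn) {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  m <- abs(g$dz) + abs(g$dy) + abs(g$dx)
  keep <- m > 0 & m <= switch(as.character(conn), "6" = 1, "18" = 2, "26" = 3)
  g[keep, , drop = FALSE]
}

# one binary dilation by explicit neighbor scan
naive_dilate <- function(v, conn) {
  d <- dim(v)
  out <- v
  off <- neigh_offsets(conn)
  idx <- which(v, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out)
  for (r in seq_len(nrow(off))) {
    sh <- idx
    sh[, 1] <- sh[, 1] + off$dz[r]
    sh[, 2] <- sh[, 2] + off$dy[r]
    sh[, 3] <- sh[, 3] + off$dx[r]
    ok <- sh[, 1] >= 1 & sh[, 1] <= d[1] & sh[, 2] >= 1 & sh[, 2] <= d[2] &
      sh[, 3] >= 1 & sh[, 3] <= d[3]
    out[sh[ok, , drop = FALSE]] <- TRUE
  }
  out
}

# flood-fill labeling of a logical array (3D, conn in {6, 18, 26})
naive_label3d <- function(v, conn) {
  d <- dim(v)
  lab <- array(0L, d)
  off <- as.matrix(neigh_offsets(conn))
  nxt <- 0L
  for (i in which(v)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue) > 0) {
      j <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(j, d)
      for (r in seq_len(nrow(off))) {
        zz <- co[1] + off[r, 1]; yy <- co[2] + off[r, 2]; xx <- co[3] + off[r, 3]
        if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3]) next
        k <- zz + d[1] * ((yy - 1) + d[2] * (xx - 1))
        if (v[k] && lab[k] == 0L) {
          lab[k] <- nxt
          queue <- c(queue, k)
        }
      }
    }
  }
  lab
}

# 8-connected component area of a 2D slice at a given position
naive_area2d <- function(m, u, v) {
  d <- dim(m)
  seen <- matrix(FALSE, d[1], d[2])
  queue <- list(c(u, v))
  seen[u, v] <- TRUE
  area <- 0L
  while (length(queue) > 0) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    area <- area + 1L
    for (du in -1:1) for (dv in -1:1) {
      if (du == 0 && dv == 0) next
      uu <- p[1] + du; vv <- p[2] + dv
      if (uu < 1 || uu > d[1] || vv < 1 || vv > d[2]) next
      if (m[uu, vv] && !seen[uu, vv]) {
        seen[uu, vv] <- TRUE
        queue[[length(queue) + 1]] <- c(uu, vv)
      }
    }
  }
  area
}

# per-voxel minimal cross-section by brute force over the three planes
naive_min_xsec <- function(v, z, y, x) {
  min(naive_area2d(v[z, , ], y, x),
      naive_area2d(v[, y, ], z, x),
      naive_area2d(v[, , x], z, y))
}

# hollow axis-aligned box with 1-voxel walls inside an `outer`-sized grid
hollow_box <- function(outer, margin = 2L) {
  v <- array(FALSE, rep(outer + 2L * margin, 3L))
  lo <- margin + 1L
  hi <- margin + outer
  v[lo:hi, lo:hi, lo:hi] <- TRUE
  v[(lo + 1L):(hi - 1L), (lo + 1L):(hi - 1L), (lo + 1L):(hi - 1L)] <- FALSE
  v
}

random_stack <- function(dim, p = 0.2) {
  array(stats::runif(prod(dim)) < p, dim = dim)
}

# small synth config for fast end-to-end tests (voxel units, spacing 1 um)
small_synth <- function(...) {
  synth_config(grid_shape = c(28L, 56L, 56L), spacing_iso = 1.0, n_roots = 2L,
               root_radius_um = 5.0, taper = 0.74, min_radius_um = 1.15,
               segment_len_um = 14, rarefy_radius_um = 2.71,
               max_segments = 800L, ...)
}
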