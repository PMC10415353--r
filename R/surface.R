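# Surface construction: lofting placed contours into watertight tubes,
# signed-distance union of the two branches, plaque component solids, and the
# mapping-back quality check / refinement loop.

#' Attach a contour to a placement
#' @param ct A [contour()].
#' @param pl A placement from [place_frames()].
#' @return A `bifuse_placed_contour` with the ring mapped into 3D.
#' @export
placed_contour <- function(ct, pl) {
  structure(list(contour = ct, placement = pl,
                 points3d = place_points3d(ct$points, pl)),
            class = "bifuse_placed_contour")
}

# Stitch an ordered list of corresponding 3D rings (equal length, consistent
# winding and start) into a capped, watertight tube.
loft_rings3d <- function(rings, label = "surface", cap = TRUE) {
  nr <- length(rings)
  n <- nrow(rings[[1]])
  V <- do.call(rbind, rings)
  tri <- vector("list", nr - 1L)
  for (k in seq_len(nr - 1L)) {
    b0 <- (k - 1L) * n
    j <- seq_len(n)
    jn <- c(seq(2L, n), 1L)
    tri[[k]] <- rbind(cbind(b0 + j, b0 + jn, b0 + n + jn),
                      cbind(b0 + j, b0 + n + jn, b0 + n + j))
  }
  F <- do.call(rbind, tri)
  if (cap) {
    c1 <- colMeans(rings[[1]])
    c2 <- colMeans(rings[[nr]])
    i1 <- nrow(V) + 1L
    i2 <- nrow(V) + 2L
    V <- rbind(V, c1, c2)
    j <- seq_len(n)
    jn <- c(seq(2L, n), 1L)
    F <- rbind(F,
               cbind(rep(i1, n), jn, j),                       # start cap
               cbind(rep(i2, n), (nr - 1L) * n + j, (nr - 1L) * n + jn)) # end cap
  }
  mesh_orient_outward(surface_mesh(V, F, label))
}

#' Loft placed contours into a watertight surface
#'
#' Each ring is resampled to `n_theta` points at equal angles about the frame
#' origin starting along the frame's u axis; corresponding points are
#' stitched into triangles and planar end caps close the tube.
#'
#' @param contours List of [placed_contour()] objects with a common label,
#'   ordered by arc length.
#' @param n_theta Number of circumferential samples (>= 8).
#' @return A watertight [surface_mesh()].
#' @export
loft_surface <- function(contours, n_theta = 256L) {
  if (length(contours) < 2L) stop("lofting needs >= 2 contours")
  if (n_theta < 8L) stop("n_theta must be >= 8")
  labels <- vapply(contours, function(pc) pc$contour$label, character(1))
  if (length(unique(labels)) != 1L) stop("lofted contours must share one label")
  s <- vapply(contours, function(pc) pc$placement$s, numeric(1))
  if (any(diff(s) <= 0)) stop("contour planes cross (arc lengths not strictly increasing)")
  rings <- lapply(contours, function(pc) {
    q <- ensure_ccw(placement_plane_coords(pc$contour$points, pc$placement))
    ring2 <- tryCatch(
      resample_ring_by_angle(q, n_theta, center = c(0, 0)),
      error = function(e) {
        # non-star ring (e.g. merged slice near the ostium): fall back to
        # arc-length resampling, started at the vertex nearest angle 0
        r <- densify_ring(q, n_theta)
        a0 <- atan2(r[, 2], r[, 1])
        st <- which.min(abs(a0))
        r[((seq_len(n_theta) - 1L + st - 1L) %% n_theta) + 1L, , drop = FALSE]
      })
    pl <- pc$placement
    t(pl$origin + outer(pl$u, ring2[, 1]) + outer(pl$v, ring2[, 2]))
  })
  loft_rings3d(rings, label = labels[1])
}

#' Union of the two branch surfaces on a signed-distance grid
#'
#' Both meshes are sampled as signed distance fields on a common grid at
#' voxel `pitch`; the pointwise minimum is isosurfaced with marching
#' tetrahedra, yielding a single watertight surface whose accuracy is
#' controlled by the pitch.
#'
#' @param mv,sb Watertight [surface_mesh()] objects that overlap near the
#'   carina.
#' @param pitch Grid pitch in mm (default 0.1).
#' @return A watertight [surface_mesh()].
#' @export
merge_branches <- function(mv, sb, pitch = 0.1) {
  for (m in list(mv, sb)) {
    if (!mesh_is_watertight(m)) stop("merge_branches requires watertight inputs")
  }
  # the 0.37 offset de-aligns the grid from flat mesh faces (axis-aligned
  # caps sitting exactly on grid planes would create zero-value nodes)
  lo <- pmin(apply(mv$vertices, 2, min), apply(sb$vertices, 2, min)) - 4.37 * pitch
  hi <- pmax(apply(mv$vertices, 2, max), apply(sb$vertices, 2, max)) + 4 * pitch
  dims <- as.integer(ceiling((hi - lo) / pitch)) + 1L
  band <- 3 * pitch
  fa <- cpp_signed_distance_grid(mv$vertices, mv$triangles, lo, dims, pitch, band)
  fb <- cpp_signed_distance_grid(sb$vertices, sb$triangles, lo, dims, pitch, band)
  if (!any(fa < 0 & fb < 0)) stop("branches do not intersect")
  res <- cpp_marching_tets(pmin(fa, fb), lo, dims, pitch)
  mesh_orient_outward(surface_mesh(res$vertices, res$triangles, mv$label))
}

#' Loft plaque components into solids
#'
#' Same-label components on consecutive frames are linked into chains when
#' their frame-plane overlap (shared area over the smaller area) reaches
#' `tau`; each chain is lofted with arc-length ring correspondence (plaque
#' crescents are rarely star-shaped) and capped at its first and last
#' appearance. A component seen on a single frame becomes a thin capped disc
#' of thickness `disc_thickness`.
#'
#' @param contours List of [placed_contour()] objects of one plaque label
#'   (possibly several components per frame), ordered by frame.
#' @param label The plaque label (used when `contours` is empty).
#' @param tau Overlap threshold in (0, 1).
#' @param n_theta Ring resampling resolution.
#' @param disc_thickness Thickness for single-frame components (mm); default
#'   the median inter-frame spacing.
#' @return List of watertight [surface_mesh()] objects (possibly empty).
#' @export
loft_plaque_components <- function(contours, label = NULL, tau = 0.3,
                                   n_theta = 64L, disc_thickness = NULL) {
  if (!length(contours)) return(list())
  label <- contours[[1]]$contour$label
  s <- vapply(contours, function(pc) pc$placement$s, numeric(1))
  frames <- vapply(contours, function(pc) pc$contour$frame_index, integer(1))
  ord <- order(s, vapply(contours, function(pc) pc$contour$component_id, integer(1)))
  contours <- contours[ord]; s <- s[ord]; frames <- frames[ord]
  ulev <- sort(unique(frames))
  if (is.null(disc_thickness)) {
    us <- sort(unique(s))
    disc_thickness <- if (length(us) > 1L) median(diff(us)) else 0.5
  }
  by_frame <- lapply(ulev, function(f) which(frames == f))
  plane_coords <- lapply(contours, function(pc) {
    placement_plane_coords(pc$contour$points, pc$placement)
  })

  # chain building: greedy best-overlap link between consecutive frames
  chain_id <- integer(length(contours))
  next_chain <- 0L
  for (fi in seq_along(ulev)) {
    cur <- by_frame[[fi]]
    if (fi == 1L) {
      for (i in cur) { next_chain <- next_chain + 1L; chain_id[i] <- next_chain }
      next
    }
    prev <- by_frame[[fi - 1L]]
    taken <- logical(length(prev))
    for (i in cur) {
      ovl <- vapply(seq_along(prev), function(pj) {
        if (taken[pj]) return(-1)
        polygon_overlap_fraction(plane_coords[[i]], plane_coords[[prev[pj]]])
      }, numeric(1))
      best <- which.max(ovl)
      if (length(best) && ovl[best] >= tau) {
        chain_id[i] <- chain_id[prev[best]]
        taken[best] <- TRUE
      } else {
        next_chain <- next_chain + 1L
        chain_id[i] <- next_chain
      }
    }
  }

  out <- list()
  for (cid in unique(chain_id)) {
    members <- which(chain_id == cid)
    members <- members[order(s[members])]
    rings2 <- lapply(members, function(i) densify_ring(ensure_ccw(plane_coords[[i]]), n_theta))
    rings3 <- lapply(seq_along(members), function(k) {
      pl <- contours[[members[k]]]$placement
      r <- rings2[[k]]
      t(pl$origin + outer(pl$u, r[, 1]) + outer(pl$v, r[, 2]))
    })
    if (length(members) == 1L) {
      pl <- contours[[members[1]]]$placement
      h <- disc_thickness / 2
      r3 <- rings3[[1]]
      mesh <- loft_rings3d(list(sweep(r3, 2, h * pl$t, `-`),
                                sweep(r3, 2, h * pl$t, `+`)),
                           label = label)
    } else {
      # align ring starts by cyclic shift to avoid spiral stitching
      for (k in seq_along(rings3)[-1]) {
        rings3[[k]] <- align_ring_start(rings3[[k - 1]], rings3[[k]])
      }
      mesh <- loft_rings3d(rings3, label = label)
    }
    out[[length(out) + 1L]] <- mesh
  }
  out
}

align_ring_start <- function(ref, ring) {
  n <- nrow(ring)
  costs <- vapply(seq_len(n) - 1L, function(sh) {
    idx <- ((seq_len(n) - 1L + sh) %% n) + 1L
    sum((ref - ring[idx, , drop = FALSE])^2)
  }, numeric(1))
  sh <- which.min(costs) - 1L
  idx <- ((seq_len(n) - 1L + sh) %% n) + 1L
  ring[idx, , drop = FALSE]
}

#' Map segmented frames back onto a reconstructed surface
#'
#' Slices the mesh with each frame plane, picks the slice loop whose centroid
#' is nearest the frame origin, and reports the mean and maximum distance
#' between corresponding points of the contour and the slice loop (both
#' densified by arc length, starts aligned by the best cyclic shift). The
#' correspondence distance upper-bounds the point-to-curve distance and, in
#' contrast to it, reads a rigid in-plane shift of the surface as exactly
#' that shift.
#'
#' @param mesh A watertight [surface_mesh()].
#' @param contours List of [placed_contour()] objects.
#' @return Data frame: `frame_index`, `s`, `mean_dev`, `max_dev`, `n_loops`.
#' @export
map_back_check <- function(mesh, contours) {
  rows <- lapply(contours, function(pc) {
    pl <- pc$placement
    loops <- list()
    # end-frame planes coincide with the tube's end rings; nudge slightly
    for (eps in c(0, 1e-6, -1e-6, 1e-3, -1e-3)) {
      loops <- slice_mesh_plane(mesh, pl$origin + eps * pl$t, pl$t)
      if (length(loops)) break
    }
    if (!length(loops)) {
      stop(sprintf("frame %d: plane misses the mesh", pc$contour$frame_index))
    }
    loops2 <- lapply(loops, loop_to_2d, origin = pl$origin, u = pl$u, v = pl$v)
    cendist <- vapply(loops2, function(lp) sqrt(sum(polygon_centroid(lp)^2)), numeric(1))
    loop <- ensure_ccw(loops2[[which.min(cendist)]])
    q <- densify_ring(ensure_ccw(placement_plane_coords(pc$contour$points, pl)), 256L)
    lp <- densify_ring(loop, 256L)
    lp <- align_ring_start(cbind(q, 0), cbind(lp, 0))[, 1:2, drop = FALSE]
    d <- sqrt(rowSums((q - lp)^2))
    data.frame(frame_index = pc$contour$frame_index, s = pl$s,
               mean_dev = mean(d), max_dev = max(d), n_loops = length(loops))
  })
  do.call(rbind, rows)
}

#' Pull a lofted surface onto its segmented contours
#'
#' Iteratively moves vertices near each frame plane toward the closest point
#' of that frame's contour ring until the mean mapping-back deviation drops
#' to `tol` or `max_iter` is reached. The deviation never increases: if an
#' iteration would, the previous mesh is returned with a warning.
#'
#' @param mesh A lofted [surface_mesh()].
#' @param contours The [placed_contour()] list the mesh should conform to.
#' @param tol Target mean deviation in mm.
#' @param max_iter Maximum number of sweeps.
#' @return The refined mesh with attribute `mapback` (final report).
#' @export
refine_to_contours <- function(mesh, contours, tol = 0.05, max_iter = 10L) {
  rep0 <- map_back_check(mesh, contours)
  best <- mesh
  best_dev <- mean(rep0$mean_dev)
  s_all <- vapply(contours, function(pc) pc$placement$s, numeric(1))
  spacing <- if (length(s_all) > 1L) min(diff(sort(s_all))) else 1
  rings3 <- lapply(contours, function(pc) {
    densify3d <- densify_ring(placement_plane_coords(pc$contour$points, pc$placement), 512L)
    pl <- pc$placement
    t(pl$origin + outer(pl$u, densify3d[, 1]) + outer(pl$v, densify3d[, 2]))
  })
  mean_radius <- mean(vapply(seq_along(contours), function(i) {
    q <- placement_plane_coords(contours[[i]]$contour$points, contours[[i]]$placement)
    sqrt(polygon_area(q) / pi)
  }, numeric(1)))

  # signed distance of every vertex to every frame plane (vectorized)
  Tm <- t(vapply(contours, function(pc) pc$placement$t, numeric(3)))
  Om <- t(vapply(contours, function(pc) pc$placement$origin, numeric(3)))
  off <- rowSums(Tm * Om)

  for (it in seq_len(max_iter)) {
    if (best_dev <= tol) break
    V <- best$vertices
    D <- abs(sweep(V %*% t(Tm), 2, off))
    j_near <- max.col(-D, ties.method = "first")
    d_near <- D[cbind(seq_len(nrow(V)), j_near)]
    w <- pmax(0, 1 - d_near / (0.5 * spacing))
    for (j in unique(j_near[w > 0])) {
      vi <- which(j_near == j & w > 0)
      ring <- rings3[[j]]
      # nv x nring squared distances
      d2 <- outer(rowSums(V[vi, , drop = FALSE]^2), rowSums(ring^2), `+`) -
        2 * V[vi, , drop = FALSE] %*% t(ring)
      kmin <- max.col(-d2, ties.method = "first")
      dmin <- sqrt(pmax(0, d2[cbind(seq_along(vi), kmin)]))
      pull <- dmin <= 0.5 * mean_radius # leave interior vertices (cap apices) alone
      if (!any(pull)) next
      vi <- vi[pull]
      tgt <- ring[kmin[pull], , drop = FALSE]
      V[vi, ] <- V[vi, , drop = FALSE] +
        w[vi] * (tgt - V[vi, , drop = FALSE])
    }
    cand <- best
    cand$vertices <- V
    dev <- mean(map_back_check(cand, contours)$mean_dev)
    if (dev >= best_dev - 1e-12) {
      if (best_dev > tol) warning(sprintf(
        "refine_to_contours stalled at mean deviation %.4f mm (tol %.4f)", best_dev, tol))
      break
    }
    best <- cand
    best_dev <- dev
  }
  if (best_dev > tol) {
    warning(sprintf("refine_to_contours: final mean deviation %.4f mm exceeds tol %.4f",
                    best_dev, tol))
  }
  attr(best, "mapback") <- map_back_check(best, contours)
  best
}
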