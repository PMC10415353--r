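# Placement of gated IVUS frames along the 3D centerline: rotation minimizing
# frames, lumen-centroid registration, catheter twist correction, carina
# reference alignment and virtual catheter path repair.

#' Keep only ECG-gated (end-diastolic) frames
#'
#' @param p A [pullback()].
#' @return The pullback restricted to gated frames, order preserved.
#' @export
select_gated_frames <- function(p) {
  gated <- vapply(p$frames, function(f) f$gated, logical(1))
  if (!any(gated)) stop("no gated frames in pullback")
  if (!is.na(p$carina_frame)) {
    idx <- vapply(p$frames, function(f) f$frame_index, integer(1))
    if (!p$carina_frame %in% idx[gated]) {
      stop(sprintf("carina frame %d is not gated", p$carina_frame))
    }
  }
  p$frames <- p$frames[gated]
  p
}

#' Distance between consecutive IVUS frames
#'
#' `speed / frame_rate`: 0.5 mm/s at 30 frames/s gives 0.017 mm, 1.0 mm/s
#' gives 0.033 mm.
#'
#' @param speed Pullback speed in mm/s (> 0).
#' @param frame_rate Frames per second (> 0).
#' @return Inter-frame distance in mm.
#' @export
frame_spacing <- function(speed, frame_rate) {
  if (!(speed > 0)) stop("speed must be > 0")
  if (!(frame_rate > 0)) stop("frame_rate must be > 0")
  speed / frame_rate
}

#' Rotation minimizing frames along a centerline (double reflection)
#'
#' Transports an initial normal along the curve with zero rotation about the
#' tangent (Wang et al. 2008 double-reflection scheme), avoiding the
#' torsion-driven spin of Frenet frames and remaining defined on straight
#' segments.
#'
#' @param cl A [centerline3d()].
#' @param u0 Optional initial normal (unit, perpendicular to the first
#'   tangent); a deterministic default is chosen otherwise.
#' @return List with matrices `t`, `u`, `v` (one row per centerline point).
#' @export
compute_rmf <- function(cl, u0 = NULL) {
  P <- cl$points
  n <- nrow(P)
  tg <- centerline_tangents(cl)
  if (is.null(u0)) {
    # reference axis least aligned with the first tangent
    ax <- diag(3)[, which.min(abs(tg[1, ]))]
    u0 <- ax - sum(ax * tg[1, ]) * tg[1, ]
    u0 <- u0 / sqrt(sum(u0^2))
  } else {
    u0 <- u0 - sum(u0 * tg[1, ]) * tg[1, ]
    nu <- sqrt(sum(u0^2))
    if (nu < 1e-12) stop("u0 is parallel to the initial tangent")
    u0 <- u0 / nu
  }
  U <- matrix(0, n, 3)
  U[1, ] <- u0
  for (i in seq_len(n - 1L)) {
    v1 <- P[i + 1L, ] - P[i, ]
    c1 <- sum(v1 * v1)
    if (c1 <= 0) stop("zero-length centerline segment")
    rL <- U[i, ] - (2 / c1) * sum(v1 * U[i, ]) * v1
    tL <- tg[i, ] - (2 / c1) * sum(v1 * tg[i, ]) * v1
    v2 <- tg[i + 1L, ] - tL
    c2 <- sum(v2 * v2)
    U[i + 1L, ] <- if (c2 < 1e-300) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    # re-orthogonalize against drift
    U[i + 1L, ] <- U[i + 1L, ] - sum(U[i + 1L, ] * tg[i + 1L, ]) * tg[i + 1L, ]
    U[i + 1L, ] <- U[i + 1L, ] / sqrt(sum(U[i + 1L, ]^2))
  }
  V <- cbind(tg[, 2] * U[, 3] - tg[, 3] * U[, 2],
             tg[, 3] * U[, 1] - tg[, 1] * U[, 3],
             tg[, 1] * U[, 2] - tg[, 2] * U[, 1])
  list(t = tg, u = U, v = V)
}

#' Place gated frames on the centerline
#'
#' Frame k sits at arc length `s0 + (frame_index_k - frame_index_1) *
#' frame_spacing`; its plane is perpendicular to the centerline (rotation
#' minimizing triad) and it is translated in-plane so the lumen centroid of
#' the (roll-corrected) contour lands on the centerline point — the frame
#' centroid registration of the reconstruction workflow. The catheter point
#' then generally sits off the centerline and traces the virtual catheter
#' path.
#'
#' @param p A gated [pullback()] (every frame must carry a lumen contour).
#' @param cl A [centerline3d()] (resampled reasonably finely).
#' @param s0 Arc length of the first frame (default 0, the distal end).
#' @param rolls Optional per-frame roll angles in degrees (from
#'   [correct_relative_twist()] / [register_carina()]); default all 0.
#' @return List of `bifuse_placement` objects (fields `frame_index`, `s`,
#'   `origin`, `t`, `u`, `v`, `roll`, `centroid`, `shift`).
#' @export
place_frames <- function(p, cl, s0 = 0, rolls = NULL) {
  n <- length(p$frames)
  if (n < 1L) stop("no frames to place")
  idx <- vapply(p$frames, function(f) f$frame_index, integer(1))
  sp <- frame_spacing(p$pullback_speed, p$frame_rate)
  s <- s0 + (idx - idx[1]) * sp
  L <- centerline_length(cl)
  if (s[n] > L + 1e-9) {
    stop(sprintf("pullback overhangs the centerline by %.3f mm", s[n] - L))
  }
  if (is.null(rolls)) rolls <- rep(0, n)
  rmf <- compute_rmf(cl)
  placements <- vector("list", n)
  for (k in seq_len(n)) {
    fr <- p$frames[[k]]
    lum <- frame_contour(fr, "lumen")
    if (is.null(lum)) stop(sprintf("frame %d has no lumen contour", fr$frame_index))
    node <- which.min(abs(cl$arclength - s[k]))
    tk <- tangent_at(cl, s[k])
    # carry the RMF normal of the nearest node onto the exact tangent
    uk <- rmf$u[node, ] - sum(rmf$u[node, ] * tk) * tk
    uk <- uk / sqrt(sum(uk^2))
    vk <- c(tk[2] * uk[3] - tk[3] * uk[2],
            tk[3] * uk[1] - tk[1] * uk[3],
            tk[1] * uk[2] - tk[2] * uk[1])
    placements[[k]] <- structure(
      list(frame_index = fr$frame_index, s = s[k],
           origin = as.numeric(centerline_point_at(cl, s[k])),
           t = tk, u = uk, v = vk, roll = rolls[k],
           centroid = polygon_centroid(lum$points),
           shift = c(0, 0)),
      class = "bifuse_placement")
  }
  placements
}

# In-plane 2D coordinates of contour points under a placement (roll about the
# catheter point, then centroid registration and any correction shift).
placement_plane_coords <- function(pts2d, pl) {
  q <- rotate2d(pts2d, pl$roll)
  cen <- as.numeric(rotate2d(rbind(pl$centroid), pl$roll))
  sweep(q, 2, cen - pl$shift)
}

#' Map contour points into 3D through a placement
#' @param pts2d n x 2 matrix in frame coordinates (catheter point at origin).
#' @param pl A placement from [place_frames()].
#' @return n x 3 matrix of world coordinates.
#' @export
place_points3d <- function(pts2d, pl) {
  q <- placement_plane_coords(pts2d, pl)
  t(pl$origin + outer(pl$u, q[, 1]) + outer(pl$v, q[, 2]))
}

#' Correct relative catheter twist between consecutive frames
#'
#' For each consecutive pair of gated frames the in-plane rotation about the
#' catheter point that best aligns the lumen radial profiles (mean squared
#' difference over `k` equiangular samples) is found on a coarse grid and
#' refined once; the negated rotations accumulate into per-frame roll angles.
#' Frames whose lumen is not star-shaped about the catheter point fall back
#' to a polygon-to-polygon mean distance objective. Ties prefer the smallest
#' magnitude, then negative angles.
#'
#' @param p A gated [pullback()]; every frame needs a lumen contour.
#' @param span_deg Half-width of the search grid in degrees.
#' @param grid_deg Coarse grid step in degrees.
#' @param refine_deg Refinement step in degrees.
#' @param k Number of radial profile samples.
#' @param max_profile_mismatch Quality gate: if the best-match RMS profile
#'   difference still exceeds this fraction of the mean lumen radius, the
#'   shapes are genuinely different (e.g. the lumen morphs across the
#'   bifurcation ostium) and rotation is unidentifiable — the increment is
#'   set to 0 instead of trusting a spurious angle.
#' @return Numeric vector of cumulative roll angles (degrees), first frame 0.
#' @export
correct_relative_twist <- function(p, span_deg = 45, grid_deg = 1,
                                   refine_deg = 0.1, k = 360L,
                                   max_profile_mismatch = 0.15) {
  frames <- p$frames
  n <- length(frames)
  lums <- lapply(frames, function(f) {
    ct <- frame_contour(f, "lumen")
    if (is.null(ct)) stop(sprintf("frame %d has no lumen contour", f$frame_index))
    ct$points
  })
  profs <- lapply(lums, radial_profile, k = k)
  ang <- 2 * pi * (seq_len(k) - 1L) / k
  cum <- numeric(n)
  if (n < 2L) return(cum)
  for (j in seq_len(n - 1L)) {
    r1 <- profs[[j]]; r2 <- profs[[j + 1L]]
    star <- isTRUE(attr(r1, "star")) && isTRUE(attr(r2, "star"))
    if (star) {
      obj_shift <- function(theta_deg) {
        # r2 evaluated at (phi - theta): rotating the ring by theta shifts its
        # profile forward by theta
        r2s <- ray_crossings(lums[[j + 1L]], ang - theta_deg * pi / 180)
        mean((r1 - r2s)^2)
      }
      # coarse grid: integer-degree shifts are circular shifts of the profile
      steps_per_deg <- k / 360
      cand <- seq(-span_deg, span_deg, by = grid_deg)
      objs <- vapply(cand, function(th) {
        sh <- round(th * steps_per_deg)
        idx <- ((seq_len(k) - 1L - sh) %% k) + 1L
        mean((r1 - r2[idx])^2)
      }, numeric(1))
    } else {
      obj_shift <- function(theta_deg) {
        q <- rotate2d(lums[[j + 1L]], theta_deg)
        mean(points_to_ring_distance(q[, 1], q[, 2], lums[[j]]))
      }
      cand <- seq(-span_deg, span_deg, by = grid_deg)
      objs <- vapply(cand, obj_shift, numeric(1))
    }
    best <- pick_tie_break(cand, objs)
    fine <- seq(best - grid_deg, best + grid_deg, by = refine_deg)
    fobjs <- vapply(fine, obj_shift, numeric(1))
    theta <- pick_tie_break(fine, fobjs)
    if (star) {
      quality <- sqrt(min(fobjs)) / mean(r1)
      if (quality > max_profile_mismatch) theta <- 0
    }
    cum[j + 1L] <- cum[j] + theta
  }
  cum
}

# smallest objective; ties resolved toward smallest |theta|, then negative
pick_tie_break <- function(cand, objs) {
  tol <- 1e-12 * max(1, max(objs))
  best <- min(objs)
  tied <- which(objs <= best + tol)
  tied <- tied[order(abs(cand[tied]), cand[tied])]
  cand[tied[1]]
}

#' Align both frame stacks to the carina reference
#'
#' Applies one global roll per stack so that, in the carina frame's plane,
#' the annotated carina direction points at the projection of the other
#' branch's take-off direction (the other centerline's tangent at its point
#' nearest the carina, oriented distally).
#'
#' @param mv_pl,sb_pl Placement lists from [place_frames()].
#' @param mv_p,sb_p The corresponding pullbacks (carina annotations).
#' @param mv_cl,sb_cl The branch centerlines.
#' @return List `mv`, `sb` (updated placements) and `residual_deg`.
#' @export
register_carina <- function(mv_pl, sb_pl, mv_p, sb_p, mv_cl, sb_cl) {
  do_one <- function(pl_list, p, other_cl) {
    if (is.na(p$carina_frame)) stop("pullback has no carina_frame annotation")
    kc <- which(vapply(pl_list, function(pl) pl$frame_index, integer(1)) == p$carina_frame)
    if (!length(kc)) stop("carina frame is not among the placed frames")
    pl <- pl_list[[kc]]
    w <- takeoff_direction(other_cl, pl$origin)
    wp <- c(sum(w * pl$u), sum(w * pl$v))
    nw <- sqrt(sum(wp^2))
    if (nw < 1e-6) stop("other-branch take-off is parallel to the frame normal")
    psi <- atan2(wp[2], wp[1]) * 180 / pi
    delta <- wrap_angle(psi - p$carina_direction - pl$roll)
    for (i in seq_along(pl_list)) pl_list[[i]]$roll <- pl_list[[i]]$roll + delta
    # residual: re-derive the mapped angle after applying the roll
    plc <- pl_list[[kc]]
    mapped <- wrap_angle(p$carina_direction + plc$roll - psi)
    list(pl = pl_list, residual = abs(mapped))
  }
  mv <- do_one(mv_pl, mv_p, sb_cl)
  sb <- do_one(sb_pl, sb_p, mv_cl)
  list(mv = mv$pl, sb = sb$pl,
       residual_deg = c(MV = mv$residual, SB = sb$residual))
}

# Unit direction of a branch at its point nearest `pt`, oriented toward the
# branch's distal end (decreasing arc length).
takeoff_direction <- function(cl, pt) {
  d2 <- rowSums(sweep(cl$points, 2, pt)^2)
  s_star <- cl$arclength[which.min(d2)]
  -as.numeric(tangent_at(cl, s_star))
}

wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  if (a <= -180) a + 360 else a
}

#' Virtual catheter path of a placed frame stack
#'
#' The 3D position of each frame's catheter (transducer) point under its
#' placement. Because frames are registered by lumen centroid, catheter
#' points trace a path off the centerline whose irregularities (typically at
#' the carina) flag placement errors.
#'
#' @param placements Placement list from [place_frames()].
#' @return A `bifuse_catheter_path`: `points` (n x 3), `s`, `outlier_mask`.
#' @export
catheter_path <- function(placements) {
  pts <- do.call(rbind, lapply(placements, function(pl) place_points3d(rbind(c(0, 0)), pl)))
  structure(list(points = pts,
                 s = vapply(placements, function(pl) pl$s, numeric(1)),
                 outlier_mask = rep(FALSE, length(placements)),
                 correction = matrix(0, length(placements), 3)),
            class = "bifuse_catheter_path")
}

#' Flag and repair deviating catheter points
#'
#' Each coordinate is smoothed against arc length with a cubic smoothing
#' spline (GCV); points whose residual norm exceeds `k` times the MAD are
#' replaced by a spline refit through the remaining points. The returned
#' `correction` vectors are meant to be applied to the frames of flagged
#' points (in-plane translation).
#'
#' @param path A [catheter_path()] (>= 5 points).
#' @param k MAD multiplier for the outlier rule.
#' @param break_at Optional frame position (1-based index into the path) at
#'   which the smooth path model is allowed a kink: an SB pullback's catheter
#'   path bends genuinely where the branch opens into the trunk (the carina
#'   frame), and fitting across that corner would smear the bend into
#'   spurious corrections elsewhere. Each side is fitted separately.
#' @return The path with corrected `points`, `outlier_mask` and `correction`.
#' @export
correct_catheter_path <- function(path, k = 3, break_at = NULL) {
  P <- path$points
  n <- nrow(P)
  if (n < 5L) stop("catheter path needs >= 5 points")
  s <- path$s
  seg_of <- rep(1L, n)
  if (!is.null(break_at) && break_at > 5L && break_at < n - 4L) {
    seg_of[seq(break_at, n)] <- 2L
  }
  spline_fit <- function(keep) {
    out <- matrix(NA_real_, n, 3)
    for (sg in unique(seg_of)) {
      idx <- which(seg_of == sg)
      use <- idx[keep[idx]]
      if (length(use) < 5L) use <- idx # too few left: fit on all of them
      for (j in 1:3) {
        fit <- smooth.spline(s[use], P[use, j], cv = FALSE)
        out[idx, j] <- predict(fit, s[idx])$y
      }
    }
    out
  }
  # iterated flag-and-refit: a long excursion (e.g. at the carina) can drag
  # the GCV spline with it on the first pass; refitting without flagged
  # points exposes the rest of the excursion until the flag set stabilizes
  flag <- rep(FALSE, n)
  fit <- spline_fit(!flag)
  for (it in 1:10) {
    res <- sqrt(rowSums((P - fit)^2))
    madv <- stats::mad(res[!flag])
    new_flag <- res > k * max(madv, 1e-9)
    if (sum(!new_flag) < 5L || identical(new_flag, flag)) break
    flag <- new_flag
    fit <- spline_fit(!flag)
  }
  corrected <- P
  if (any(flag)) corrected[flag, ] <- fit[flag, , drop = FALSE]
  path$points <- corrected
  path$outlier_mask <- flag
  path$correction <- corrected - P
  path
}

#' Apply catheter path corrections to frame placements
#'
#' Projects each flagged point's 3D correction vector into its frame plane
#' and adds it to the placement's in-plane shift, translating all contours of
#' that frame identically.
#'
#' @param placements Placement list.
#' @param path A corrected [catheter_path()].
#' @return Updated placement list.
#' @export
apply_path_correction <- function(placements, path) {
  for (i in seq_along(placements)) {
    if (path$outlier_mask[i]) {
      d <- path$correction[i, ]
      pl <- placements[[i]]
      placements[[i]]$shift <- pl$shift + c(sum(d * pl$u), sum(d * pl$v))
    }
  }
  placements
}
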