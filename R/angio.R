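# Biplane angiography: isocentric C-arm camera model, forward projection and
# epipolar triangulation of vessel centerlines. World frame: isocenter origin,
# patient axes; RAO/LAO rotates the imaging chain about the patient long axis
# (z), cranial/caudal about the patient lateral axis (x).

#' Acquisition geometry of one angiographic projection
#'
#' @param rao_lao_angle RAO/LAO gantry angle in degrees.
#' @param cran_caud_angle Cranial/caudal angulation in degrees.
#' @param source_isocenter_distance SID in mm (> 0).
#' @param source_detector_distance SDD in mm (>= SID).
#' @param detector_pixel_spacing Detector pixel pitch in mm/px (metadata only;
#'   curve coordinates are in detector mm).
#' @param principal_point 2D detector coordinate (mm) of the beam axis.
#' @return A `bifuse_projection` object with source position, detector axes
#'   and viewing axis precomputed.
#' @export
projection_geometry <- function(rao_lao_angle, cran_caud_angle,
                                source_isocenter_distance = 765,
                                source_detector_distance = 1100,
                                detector_pixel_spacing = 0.2,
                                principal_point = c(0, 0)) {
  if (!(source_isocenter_distance > 0)) stop("source_isocenter_distance must be > 0")
  if (source_detector_distance < source_isocenter_distance) {
    stop("source_detector_distance must be >= source_isocenter_distance")
  }
  a <- rao_lao_angle * pi / 180
  b <- cran_caud_angle * pi / 180
  rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(b), sin(b), 0, -sin(b), cos(b)), 3, 3)
  R <- rz %*% rx
  e1 <- R %*% c(1, 0, 0) # detector x axis
  e2 <- R %*% c(0, 0, 1) # detector y axis
  w <- R %*% c(0, 1, 0)  # viewing axis, source -> detector
  structure(
    list(rao_lao_angle = rao_lao_angle, cran_caud_angle = cran_caud_angle,
         sid = source_isocenter_distance, sdd = source_detector_distance,
         pixel_spacing = detector_pixel_spacing,
         principal_point = as.numeric(principal_point),
         e1 = as.numeric(e1), e2 = as.numeric(e2), w = as.numeric(w),
         source = as.numeric(-source_isocenter_distance * w)),
    class = "bifuse_projection")
}

#' A 2D centerline curve on the detector
#' @param points n x 2 matrix of detector coordinates in mm, ordered distal
#'   to proximal (same convention in both views).
#' @param branch Branch tag (`"MV"`/`"SB"` or other).
#' @return A `bifuse_curve2d` object.
#' @export
curve2d <- function(points, branch = "MV") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 2L) stop("curve needs >= 2 points")
  structure(list(points = points, branch = branch), class = "bifuse_curve2d")
}

#' A 3D centerline with arc-length parametrization
#' @param points n x 3 matrix (mm).
#' @param reprojection_rms RMS 2D reprojection residual in mm, when the
#'   centerline was triangulated.
#' @return A `bifuse_centerline` with cumulative `arclength`.
#' @export
centerline3d <- function(points, reprojection_rms = NA_real_) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 2L) stop("centerline needs >= 2 points")
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg <= 0)) stop("centerline has zero-length segments")
  structure(
    list(points = points, arclength = c(0, cumsum(seg)),
         reprojection_rms = reprojection_rms),
    class = "bifuse_centerline")
}

#' Total arc length of a centerline
#' @param cl A [centerline3d()].
#' @return Length in mm.
#' @export
centerline_length <- function(cl) cl$arclength[length(cl$arclength)]

#' Read a 2D curve + acquisition geometry from JSON
#'
#' Schema: `points_mm` (n x 2), `branch`, `rao_lao_deg`, `cran_caud_deg`,
#' `sid_mm`, `sdd_mm`, optional `pixel_spacing_mm`, `principal_point_mm`.
#'
#' @param path JSON file path.
#' @return List with `curve` ([curve2d()]) and `geom`
#'   ([projection_geometry()]).
#' @export
read_curve_json <- function(path) {
  raw <- jsonlite::fromJSON(path)
  list(curve = curve2d(raw$points_mm, branch = if (is.null(raw$branch)) "MV" else raw$branch),
       geom = projection_geometry(
         raw$rao_lao_deg, raw$cran_caud_deg, raw$sid_mm, raw$sdd_mm,
         detector_pixel_spacing = if (is.null(raw$pixel_spacing_mm)) 0.2 else raw$pixel_spacing_mm,
         principal_point = if (is.null(raw$principal_point_mm)) c(0, 0) else raw$principal_point_mm))
}

#' Write a 2D curve + geometry to JSON
#' @param curve A [curve2d()].
#' @param geom A [projection_geometry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_json <- function(curve, geom, path) {
  jsonlite::write_json(
    list(points_mm = unname(curve$points), branch = curve$branch,
         rao_lao_deg = geom$rao_lao_angle, cran_caud_deg = geom$cran_caud_angle,
         sid_mm = geom$sid, sdd_mm = geom$sdd,
         pixel_spacing_mm = geom$pixel_spacing,
         principal_point_mm = geom$principal_point),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a centerline as a 3-column CSV of xyz mm
#' @param cl A [centerline3d()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_centerline_csv <- function(cl, path) {
  df <- as.data.frame(cl$points)
  names(df) <- c("x_mm", "y_mm", "z_mm")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Perspective (cone-beam) projection of a 3D centerline
#'
#' @param cl A [centerline3d()] in isocenter mm.
#' @param geom A [projection_geometry()].
#' @return A [curve2d()] of detector coordinates in mm.
#' @export
project_centerline <- function(cl, geom) {
  p <- project_points(cl$points, geom)
  curve2d(p, branch = "projected")
}

project_points <- function(pts, geom) {
  rel <- sweep(as.matrix(pts), 2, geom$source)
  z <- as.numeric(rel %*% geom$w)
  if (any(z <= 0)) stop("point behind the X-ray source")
  x <- as.numeric(rel %*% geom$e1) * geom$sdd / z + geom$principal_point[1]
  y <- as.numeric(rel %*% geom$e2) * geom$sdd / z + geom$principal_point[2]
  cbind(x, y, deparse.level = 0)
}

# World-space ray through a detector point: origin at the source, unit
# direction toward the detector coordinate.
backproject_ray <- function(pt2d, geom) {
  d <- (pt2d[1] - geom$principal_point[1]) * geom$e1 +
       (pt2d[2] - geom$principal_point[2]) * geom$e2 +
       geom$sdd * geom$w
  list(origin = geom$source, dir = d / sqrt(sum(d^2)))
}

#' Angular separation between two viewing axes
#' @param geomA,geomB [projection_geometry()] objects.
#' @return Angle in degrees.
#' @export
view_separation <- function(geomA, geomB) {
  cosang <- sum(geomA$w * geomB$w)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Triangulate a 3D centerline from two projections
#'
#' For each point of `curveA`, its epipolar line in view B is intersected with
#' `curveB` under a monotone ordering constraint (matches cannot go backwards
#' along the curve); the 3D point is the midpoint of the common perpendicular
#' of the two back-projection rays.
#'
#' @param curveA,curveB [curve2d()] objects, ordered consistently.
#' @param geomA,geomB Their [projection_geometry()].
#' @return A [centerline3d()] with `reprojection_rms` recorded.
#' @export
triangulate_centerlines <- function(curveA, geomA, curveB, geomB) {
  sep <- view_separation(geomA, geomB)
  if (sep < 15) stop(sprintf("views only %.1f deg apart (< 15 deg): triangulation is ill-posed", sep))
  if (sep < 30) warning(sprintf("views %.1f deg apart (< 30 deg): accuracy degraded", sep))

  A <- curveA$points
  B <- curveB$points
  nB <- nrow(B)
  segB <- sqrt(rowSums(diff(B)^2))
  sB <- c(0, cumsum(segB))

  pts3 <- matrix(0, nrow(A), 3)
  resid2 <- numeric(0)
  last_s <- -Inf
  for (i in seq_len(nrow(A))) {
    rayA <- backproject_ray(A[i, ], geomA)
    # epipolar line in view B: projection of two points along ray A
    q1 <- project_points(rbind(rayA$origin + 10 * rayA$dir), geomB)
    q2 <- project_points(rbind(rayA$origin + geomA$sid * 2 * rayA$dir), geomB)
    l0 <- q1[1, ]; ldir <- q2[1, ] - q1[1, ]
    nrm <- c(-ldir[2], ldir[1]) # normal to the epipolar line
    f <- as.numeric((B - matrix(l0, nB, 2, byrow = TRUE)) %*% nrm)
    # crossings of the polyline with the line f == 0
    cand_s <- numeric(0)
    for (e in seq_len(nB - 1L)) {
      f1 <- f[e]; f2 <- f[e + 1L]
      if ((f1 <= 0 && f2 >= 0) || (f1 >= 0 && f2 <= 0)) {
        if (f1 == f2) next
        t <- f1 / (f1 - f2)
        cand_s <- c(cand_s, sB[e] + t * segB[e])
      }
    }
    # endpoint grazing: the line passes (numerically) through a vertex, or —
    # with noisy detector curves — just beyond an end of the curve
    if (!length(cand_s)) {
      eps <- 1e-9 * max(abs(f), 1)
      near0 <- which(abs(f) < eps)
      if (length(near0)) cand_s <- sB[near0]
    }
    if (!length(cand_s)) {
      d_end <- abs(c(f[1], f[nB])) / sqrt(sum(nrm^2))
      if (min(d_end) < 2) { # mm on the detector: treat as an endpoint graze
        cand_s <- if (d_end[1] <= d_end[2]) 0 else sB[nB]
      } else {
        stop(sprintf("epipolar line of point %d does not intersect the second curve", i))
      }
    }
    cand_s <- sort(cand_s)
    ok <- cand_s[cand_s >= last_s - 1e-9]
    s_match <- if (length(ok)) ok[1] else cand_s[length(cand_s)]
    last_s <- s_match
    bpt <- point_on_polyline_2d(B, sB, s_match)
    rayB <- backproject_ray(bpt, geomB)
    # midpoint of the common perpendicular
    w0 <- rayA$origin - rayB$origin
    a <- 1; bb <- sum(rayA$dir * rayB$dir); cc <- 1
    dd <- sum(rayA$dir * w0); ee <- sum(rayB$dir * w0)
    den <- a * cc - bb * bb
    if (abs(den) < 1e-12) stop("back-projection rays are parallel")
    tA <- (bb * ee - cc * dd) / den
    tB <- (a * ee - bb * dd) / den
    pA <- rayA$origin + tA * rayA$dir
    pB <- rayB$origin + tB * rayB$dir
    pts3[i, ] <- (pA + pB) / 2
    # consistency residual: the epipolar match reprojects exactly onto both
    # measured points by construction, so the informative residual is the
    # distance between the reprojected 3D point and the second curve's
    # sample under index correspondence (curves from the same acquisition
    # are sampled consistently); it is 0 for noiseless inputs and grows
    # with 2D noise
    pb2 <- project_points(rbind(pts3[i, ]), geomB)
    ref <- if (nrow(A) == nB) B[i, ] else point_on_polyline_2d(B, sB, s_match)
    resid2 <- c(resid2, sum((pb2 - ref)^2))
  }
  cl <- centerline3d(dedupe_points(pts3), reprojection_rms = sqrt(mean(resid2)))
  cl
}

point_on_polyline_2d <- function(P, s, target) {
  n <- nrow(P)
  if (target <= 0) return(P[1, ])
  if (target >= s[n]) return(P[n, ])
  e <- findInterval(target, s, rightmost.closed = TRUE)
  t <- (target - s[e]) / (s[e + 1] - s[e])
  P[e, ] + t * (P[e + 1, ] - P[e, ])
}

dedupe_points <- function(P, eps = 1e-9) {
  if (nrow(P) < 2L) return(P)
  keep <- c(TRUE, rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2) > eps^2)
  P[keep, , drop = FALSE]
}

#' Resample a centerline at equal arc-length steps
#'
#' The end point is preserved: if the total length is not a multiple of
#' `step`, the final point is appended.
#'
#' @param cl A [centerline3d()].
#' @param step Step in mm (> 0, <= total length).
#' @return A resampled [centerline3d()].
#' @export
resample_by_arclength <- function(cl, step) {
  if (!(step > 0)) stop("step must be > 0")
  L <- centerline_length(cl)
  if (step > L) stop(sprintf("step %.3g mm exceeds the total length %.3g mm", step, L))
  grid <- seq(0, L, by = step)
  if (L - grid[length(grid)] > 1e-9 * max(1, L)) grid <- c(grid, L)
  P <- sapply(1:3, function(k) approx(cl$arclength, cl$points[, k], xout = grid)$y)
  centerline3d(dedupe_points(P), reprojection_rms = cl$reprojection_rms)
}

#' Interpolated point on a centerline at arc length `s`
#' @param cl A [centerline3d()].
#' @param s Arc length in mm (vectorized).
#' @return Matrix of 3D points.
#' @export
centerline_point_at <- function(cl, s) {
  L <- centerline_length(cl)
  if (any(s < -1e-9 | s > L + 1e-9)) stop("arc length outside [0, total length]")
  s <- pmin(pmax(s, 0), L)
  out <- sapply(1:3, function(k) approx(cl$arclength, cl$points[, k], xout = s)$y)
  if (length(s) == 1L) matrix(out, 1, 3) else out
}

# Unit tangents at every centerline point: central differences inside,
# second-order one-sided differences at the ends (first order there would
# tilt the initial rotation-minimizing normal by O(h)).
centerline_tangents <- function(cl) {
  P <- cl$points
  n <- nrow(P)
  tg <- matrix(0, n, 3)
  if (n == 2L) {
    tg[1, ] <- tg[2, ] <- P[2, ] - P[1, ]
  } else {
    s <- cl$arclength
    # one-sided endpoint derivative from a local polynomial through the m
    # nearest points (cubic when available)
    end_tangent <- function(idx) {
      m <- min(4L, n)
      pts <- if (idx == 1L) seq_len(m) else seq(n - m + 1L, n)
      ds <- s[pts] - s[idx]
      V <- outer(ds, 0:(m - 1L), `^`)
      co <- solve(V, P[pts, , drop = FALSE])
      co[2L, ]
    }
    tg[1, ] <- end_tangent(1L)
    tg[n, ] <- end_tangent(n)
    tg[2:(n - 1), ] <- P[3:n, ] - P[1:(n - 2), ]
  }
  tg / sqrt(rowSums(tg^2))
}

#' Unit tangent at arc length `s`
#'
#' Central-difference tangents at the polyline nodes, linearly interpolated in
#' arc length, renormalized.
#'
#' @param cl A [centerline3d()].
#' @param s Arc length in mm (scalar or vector).
#' @return Unit 3D vector (or matrix, one row per `s`).
#' @export
tangent_at <- function(cl, s) {
  L <- centerline_length(cl)
  if (any(s < -1e-9 | s > L + 1e-9)) stop("arc length outside [0, total length]")
  s <- pmin(pmax(s, 0), L)
  tg <- centerline_tangents(cl)
  out <- sapply(1:3, function(k) approx(cl$arclength, tg[, k], xout = s)$y)
  out <- matrix(out, ncol = 3)
  out <- out / sqrt(rowSums(out^2))
  if (length(s) == 1L) as.numeric(out) else out
}
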