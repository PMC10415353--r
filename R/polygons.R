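# 2D polygon primitives used throughout: rings are n x 2 matrices of mm
# coordinates, closed implicitly (last vertex connects to the first).

#' Signed polygon area (shoelace)
#'
#' Positive for counter-clockwise winding.
#'
#' @param pts n x 2 matrix of ring vertices (not repeated at the end).
#' @return Signed area in mm^2.
#' @export
polygon_area_signed <- function(pts) {
  pts <- as_ring(pts)
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (absolute value of the shoelace sum)
#' @inheritParams polygon_area_signed
#' @return Area in mm^2.
#' @export
polygon_area <- function(pts) abs(polygon_area_signed(pts))

#' Area centroid of a simple polygon
#' @inheritParams polygon_area_signed
#' @return Length-2 numeric (x, y) in mm.
#' @export
polygon_centroid <- function(pts) {
  pts <- as_ring(pts)
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(pts))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

as_ring <- function(pts) {
  pts <- as.matrix(pts)
  if (ncol(pts) != 2L) stop("ring must be an n x 2 matrix")
  if (nrow(pts) >= 2L && all(abs(pts[1L, ] - pts[nrow(pts), ]) < 1e-12)) {
    pts <- pts[-nrow(pts), , drop = FALSE]
  }
  storage.mode(pts) <- "double"
  pts
}

#' Normalize ring winding to counter-clockwise
#' @inheritParams polygon_area_signed
#' @return The ring, reversed if it was clockwise.
#' @export
ensure_ccw <- function(pts) {
  pts <- as_ring(pts)
  if (polygon_area_signed(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  pts
}

# Segment-intersection test for simplicity checking. O(n^2); contours are small.
segments_properly_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Is a ring a simple (non-self-intersecting) polygon?
#' @inheritParams polygon_area_signed
#' @return Logical.
#' @export
is_simple_polygon <- function(pts) {
  pts <- as_ring(pts)
  n <- nrow(pts)
  if (n < 3L) return(FALSE)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      # skip adjacent edges (share a vertex)
      if (j == i || idx(j + 1L) == i || idx(i + 1L) == j) next
      if (segments_properly_intersect(pts[i, ], pts[idx(i + 1L), ],
                                      pts[j, ], pts[idx(j + 1L), ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Even-odd point-in-polygon test (vectorized over points)
#' @param px,py Point coordinates.
#' @inheritParams polygon_area_signed
#' @return Logical vector.
#' @export
points_in_polygon <- function(px, py, pts) {
  pts <- as_ring(pts)
  n <- nrow(pts)
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  inside <- rep(FALSE, length(px))
  for (e in seq_len(n)) {
    crosses <- ((y[e] > py) != (yn[e] > py))
    if (any(crosses)) {
      xint <- x[e] + (py[crosses] - y[e]) / (yn[e] - y[e]) * (xn[e] - x[e])
      hit <- px[crosses] < xint
      w <- which(crosses)[hit]
      inside[w] <- !inside[w]
    }
  }
  inside
}

# Radii at which rays from `center` at `angles` (radians) cross the ring
# boundary; returns the largest crossing per ray (NA if none).
ray_crossings <- function(pts, angles, center = c(0, 0)) {
  pts <- as_ring(pts)
  a <- sweep(pts, 2, center)
  b <- rbind(a[-1, , drop = FALSE], a[1, , drop = FALSE])
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  # tiny deterministic angular nudge so rays never pass exactly through a
  # vertex (which would otherwise be missed or double-counted)
  angles <- angles + 1.2345678e-9
  out <- rep(NA_real_, length(angles))
  counts <- integer(length(angles))
  for (qi in seq_along(angles)) {
    dx <- cos(angles[qi]); dy <- sin(angles[qi])
    # solve a + t*(b-a) = r*(dx,dy), t in [0,1), r >= 0
    den <- dx * ey - dy * ex
    ok <- abs(den) > 1e-14
    t <- (dx * (-a[, 2]) - dy * (-a[, 1])) / den
    r <- if (abs(dx) > abs(dy)) (a[, 1] + t * ex) / dx else (a[, 2] + t * ey) / dy
    hit <- ok & t >= 0 & t < 1 & r > 0
    if (any(hit)) {
      out[qi] <- max(r[hit])
      counts[qi] <- sum(hit)
    }
  }
  attr(out, "n_crossings") <- counts
  out
}

#' Radial boundary profile of a ring about a center point
#'
#' Samples the boundary radius along `k` equiangular rays. For star-shaped
#' rings each ray crosses once; otherwise the outermost crossing is returned
#' and the profile is flagged non-star.
#'
#' @inheritParams polygon_area_signed
#' @param k Number of equiangular samples.
#' @param center Ray origin (default the coordinate origin = catheter point).
#' @return Numeric vector of radii with attribute `star` (logical).
#' @export
radial_profile <- function(pts, k = 360L, center = c(0, 0)) {
  ang <- 2 * pi * (seq_len(k) - 1L) / k
  r <- ray_crossings(pts, ang, center)
  star <- !anyNA(r) && all(attr(r, "n_crossings") == 1L)
  if (anyNA(r)) {
    # fill rare misses by interpolation so downstream code stays total
    idx <- which(is.na(r))
    ok <- which(!is.na(r))
    if (length(ok) < 2L) stop("ring does not enclose the center point")
    r[idx] <- approx(ok, r[ok], xout = idx, rule = 2)$y
  }
  attr(r, "star") <- star
  r
}

#' Resample a ring to n points by arc length
#' @inheritParams polygon_area_signed
#' @param n Number of output vertices.
#' @return n x 2 matrix; starts at the original first vertex.
#' @export
densify_ring <- function(pts, n = 512L) {
  pts <- as_ring(pts)
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate ring")
  target <- total * (seq_len(n) - 1L) / n
  xi <- approx(s, closed[, 1], xout = target)$y
  yi <- approx(s, closed[, 2], xout = target)$y
  cbind(xi, yi, deparse.level = 0)
}

# Resample a star-shaped ring to n_theta points at equiangular directions from
# `center`, starting along +x. Used by the lofting correspondence.
resample_ring_by_angle <- function(pts, n_theta, center = c(0, 0)) {
  ang <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  r <- ray_crossings(pts, ang, center)
  if (anyNA(r)) stop("ring is not star-shaped about the resampling center")
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang), deparse.level = 0)
}

#' Rotate 2D points about the origin
#' @inheritParams polygon_area_signed
#' @param deg Rotation angle in degrees (counter-clockwise).
#' @return Rotated matrix.
#' @export
rotate2d <- function(pts, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  as.matrix(pts) %*% t(R)
}

# Fraction of the smaller polygon's area shared with the other, estimated on a
# sampling grid (exact polygon clipping is not needed at the 0.3 threshold
# used for plaque chaining).
polygon_overlap_fraction <- function(a, b, n_grid = 48L) {
  a <- as_ring(a); b <- as_ring(b)
  lo <- pmin(apply(a, 2, min), apply(b, 2, min))
  hi <- pmax(apply(a, 2, max), apply(b, 2, max))
  if (any(hi <= lo)) return(0)
  gx <- seq(lo[1], hi[1], length.out = n_grid)
  gy <- seq(lo[2], hi[2], length.out = n_grid)
  g <- expand.grid(x = gx, y = gy)
  ina <- points_in_polygon(g$x, g$y, a)
  inb <- points_in_polygon(g$x, g$y, b)
  denom <- min(sum(ina), sum(inb))
  if (denom == 0L) return(0)
  sum(ina & inb) / denom
}

# Mean distance from points to a ring boundary (polyline, closed).
points_to_ring_distance <- function(px, py, ring) {
  ring <- as_ring(ring)
  a <- ring
  b <- rbind(ring[-1, , drop = FALSE], ring[1, , drop = FALSE])
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  len2 <- pmax(ex^2 + ey^2, 1e-300)
  best <- rep(Inf, length(px))
  for (e in seq_len(nrow(a))) {
    t <- pmin(1, pmax(0, ((px - a[e, 1]) * ex[e] + (py - a[e, 2]) * ey[e]) / len2[e]))
    d <- sqrt((px - (a[e, 1] + t * ex[e]))^2 + (py - (a[e, 2] + t * ey[e]))^2)
    best <- pmin(best, d)
  }
  best
}
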