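# Synthetic coronary bifurcation phantoms with known ground truth, plus
# virtual IVUS pullbacks and virtual biplane centerline projections. Stands in
# for the silicone bench models: default dimensions are coronary scale
# (MV radius 1.5 mm, SB 1.2 mm, branch lengths 10-35 mm).

#' Specify a synthetic bifurcation phantom
#'
#' @param mv_control Control points (k x 3 mm) of the MV centerline, ordered
#'   distal to proximal; interpolated with natural cubic splines.
#' @param sb_takeoff_s Arc length on the MV where the side branch takes off.
#' @param bifurcation_angle Angle (degrees) between MV and SB directions at
#'   the take-off, in (15, 120).
#' @param mv_radius Distal MV lumen radius (mm).
#' @param sb_radius SB lumen radius (mm).
#' @param murray_exponent Exponent coupling the proximal trunk radius to the
#'   daughters (`r_prox^n = r_mv^n + r_sb^n`); 3 is Murray's law.
#' @param sb_length Length of the SB beyond the take-off (mm).
#' @param trunk_overlap How far the SB centerline continues into the proximal
#'   trunk (mm), mirroring an SB pullback that ends in the main vessel.
#' @param mv_taper,sb_taper Fractional radius change per mm toward the
#'   proximal end (coronary arteries taper distally; a nonzero taper also
#'   gives the diameter/length profile genuine variance, which the z-score
#'   regression validation needs).
#' @param ellipticity Cross-section minor/major axis ratio (1 = circular);
#'   sections keep area pi * r(s)^2.
#' @param stenosis Optional `list(center_s, depth, width)`: Gaussian radius
#'   reduction on the MV (`depth` in [0, 1)).
#' @param eem_wall EEM offset outside the lumen (mm), or `NULL` for none.
#' @param plaque_specs List of `list(label, s_range, ang_range, thickness)`
#'   crescents on the MV wall.
#' @param seed Integer seed (recorded; generation itself is deterministic).
#' @return A `bifuse_phantom_spec`.
#' @export
phantom_spec <- function(mv_control = NULL,
                         sb_takeoff_s = 18,
                         bifurcation_angle = 55,
                         mv_radius = 1.5,
                         sb_radius = 1.2,
                         murray_exponent = 3,
                         sb_length = 12,
                         trunk_overlap = 3,
                         mv_taper = 0.010,
                         sb_taper = 0.025,
                         ellipticity = 0.85,
                         stenosis = NULL,
                         eem_wall = 0.5,
                         plaque_specs = list(
                           list(label = "calcium", s_range = c(8, 12),
                                ang_range = c(20, 130), thickness = 0.4),
                           list(label = "fibrosis", s_range = c(13.5, 16.5),
                                ang_range = c(170, 300), thickness = 0.5)),
                         seed = 1L) {
  if (is.null(mv_control)) {
    mv_control <- rbind(c(0, 0, 0), c(8, 1.2, 1), c(16, 3.2, 2),
                        c(24, 6.5, 2.6), c(31, 10.5, 3.2))
  }
  stopifnot(mv_radius > 0, sb_radius > 0, ellipticity > 0, ellipticity <= 1)
  if (!(bifurcation_angle > 15 && bifurcation_angle < 120)) {
    stop("bifurcation_angle must be in (15, 120) degrees")
  }
  if (!is.null(stenosis) && !(stenosis$depth >= 0 && stenosis$depth < 1)) {
    stop("stenosis depth must be in [0, 1)")
  }
  structure(list(mv_control = mv_control, sb_takeoff_s = sb_takeoff_s,
                 bifurcation_angle = bifurcation_angle, mv_radius = mv_radius,
                 sb_radius = sb_radius, murray_exponent = murray_exponent,
                 sb_length = sb_length, trunk_overlap = trunk_overlap,
                 mv_taper = mv_taper, sb_taper = sb_taper,
                 ellipticity = ellipticity, stenosis = stenosis,
                 eem_wall = eem_wall, plaque_specs = plaque_specs,
                 seed = as.integer(seed)),
            class = "bifuse_phantom_spec")
}

spline_through <- function(control, step = 0.1) {
  d <- sqrt(rowSums(diff(control)^2))
  tpar <- c(0, cumsum(d))
  tt <- seq(0, tpar[length(tpar)], by = step / 2)
  P <- sapply(1:3, function(k) spline(tpar, control[, k], xout = tt, method = "natural")$y)
  centerline3d(dedupe_points(P))
}

#' Build the phantom geometry
#'
#' Sweeps elliptical cross-sections along both centerlines, lofts each branch
#' into a watertight tube, unions them on a signed-distance grid and locates
#' the carina (the apex of the flow-divider wedge on the seam between the
#' branch surfaces).
#'
#' @param spec A [phantom_spec()].
#' @param ring_spacing Spacing of the swept sections (mm).
#' @param n_theta Circumferential resolution of the ground-truth meshes.
#' @param pitch Union grid pitch (mm).
#' @return A `bifuse_phantom` with ground-truth meshes, centerlines, radius
#'   functions and the carina point.
#' @export
make_phantom <- function(spec, ring_spacing = 0.25, n_theta = 128L, pitch = 0.1) {
  mv_cl <- resample_by_arclength(spline_through(spec$mv_control), 0.1)
  L_mv <- centerline_length(mv_cl)
  if (spec$sb_takeoff_s <= 2 || spec$sb_takeoff_s >= L_mv - 2) {
    stop("sb_takeoff_s outside the usable MV span")
  }
  rmf_mv <- compute_rmf(mv_cl)
  s_bif <- spec$sb_takeoff_s
  takeoff <- as.numeric(centerline_point_at(mv_cl, s_bif))
  t_bif <- as.numeric(tangent_at(mv_cl, s_bif))
  node <- which.min(abs(mv_cl$arclength - s_bif))
  u_bif <- rmf_mv$u[node, ]
  u_bif <- u_bif - sum(u_bif * t_bif) * t_bif
  u_bif <- u_bif / sqrt(sum(u_bif^2))

  # SB take-off: rotate the (proximally pointing) MV tangent by the
  # bifurcation angle toward -u, then point it distally into the branch
  ang <- spec$bifurcation_angle * pi / 180
  dir_sb <- cos(ang) * (-t_bif) + sin(ang) * u_bif # distally, into the SB
  # SB control points: straight take-off with a gentle out-of-plane bend
  w_bif <- c(t_bif[2] * u_bif[3] - t_bif[3] * u_bif[2],
             t_bif[3] * u_bif[1] - t_bif[1] * u_bif[3],
             t_bif[1] * u_bif[2] - t_bif[2] * u_bif[1])
  # control points at size-independent distances from the take-off so the
  # junction turn radius does not tighten for short side branches (ring
  # planes of a lofted pullback must not cross inside the tube)
  LSB <- spec$sb_length
  d3 <- max(2.2, 0.33 * LSB)
  d2 <- min(max(4.4, 0.66 * LSB), 0.8 * LSB)
  sb_body <- rbind(
    takeoff + LSB * dir_sb + 0.15 * LSB * w_bif,
    takeoff + d2 * dir_sb + 0.10 * d2 * w_bif,
    takeoff + d3 * dir_sb + 0.04 * d3 * w_bif,
    takeoff)
  # continue into the proximal trunk along the MV centerline
  s_trunk <- seq(s_bif + 1.5, min(L_mv, s_bif + spec$trunk_overlap), by = 1)
  sb_control <- rbind(sb_body, centerline_point_at(mv_cl, s_trunk))
  sb_cl <- resample_by_arclength(spline_through(sb_control), 0.1)

  # radius profiles
  r_trunk <- (spec$mv_radius^spec$murray_exponent +
                spec$sb_radius^spec$murray_exponent)^(1 / spec$murray_exponent)
  blend <- function(s, s0, w) 0.5 * (1 + tanh((s - s0) / w))
  # mv_radius / sb_radius are the radii AT the bifurcation; branches taper
  # distally and the proximal trunk blends to the Murray-coupled radius
  mv_radius_at <- function(s) {
    base <- spec$mv_radius * (1 + spec$mv_taper * pmin(s - s_bif, 0))
    r <- base + (r_trunk - base) * blend(s, s_bif, 0.8)
    if (!is.null(spec$stenosis)) {
      st <- spec$stenosis
      r <- r * (1 - st$depth * exp(-(s - st$center_s)^2 / (2 * st$width^2)))
    }
    r
  }
  sb_bif_s <- centerline_length(sb_cl) - spec$trunk_overlap # take-off on SB arc length
  sb_radius_at <- function(s) {
    base <- spec$sb_radius * (1 + spec$sb_taper * pmin(s - sb_bif_s, 0))
    base + (r_trunk - base) * blend(s, sb_bif_s + 0.5, 0.6)
  }

  ellipse_ring <- function(r, ratio, n = 96L) {
    a <- r / sqrt(ratio); b <- r * sqrt(ratio)
    th <- 2 * pi * (seq_len(n) - 1L) / n
    cbind(a * cos(th), b * sin(th))
  }
  sweep_branch <- function(cl, radius_at, label) {
    rmf <- compute_rmf(cl)
    sgrid <- seq(0, centerline_length(cl), by = ring_spacing)
    if (centerline_length(cl) - sgrid[length(sgrid)] > 1e-6) {
      sgrid <- c(sgrid, centerline_length(cl))
    }
    rings <- lapply(sgrid, function(s) {
      o <- as.numeric(centerline_point_at(cl, s))
      node <- which.min(abs(cl$arclength - s))
      tk <- as.numeric(tangent_at(cl, s))
      uk <- rmf$u[node, ] - sum(rmf$u[node, ] * tk) * tk
      uk <- uk / sqrt(sum(uk^2))
      vk <- c(tk[2] * uk[3] - tk[3] * uk[2], tk[3] * uk[1] - tk[1] * uk[3],
              tk[1] * uk[2] - tk[2] * uk[1])
      ring2 <- resample_ring_by_angle(
        ellipse_ring(radius_at(s), spec$ellipticity), n_theta)
      t(o + outer(uk, ring2[, 1]) + outer(vk, ring2[, 2]))
    })
    loft_rings3d(rings, label = label)
  }
  mv_mesh <- sweep_branch(mv_cl, mv_radius_at, "lumen")
  sb_mesh <- sweep_branch(sb_cl, sb_radius_at, "lumen")
  lumen <- merge_branches(mv_mesh, sb_mesh, pitch = pitch)

  carina <- find_carina_point(lumen, mv_cl, sb_cl)

  eem <- NULL
  if (!is.null(spec$eem_wall)) {
    eem_mv <- sweep_branch(mv_cl, function(s) mv_radius_at(s) + spec$eem_wall, "eem")
    eem_sb <- sweep_branch(sb_cl, function(s) sb_radius_at(s) + spec$eem_wall, "eem")
    eem <- merge_branches(eem_mv, eem_sb, pitch = pitch)
  }

  structure(list(spec = spec, mv_centerline = mv_cl, sb_centerline = sb_cl,
                 mv_mesh = mv_mesh, sb_mesh = sb_mesh, lumen = lumen,
                 eem = eem, carina_point = carina,
                 s_bif = s_bif, sb_bif_s = sb_bif_s, trunk_radius = r_trunk,
                 mv_radius_at = mv_radius_at, sb_radius_at = sb_radius_at),
            class = "bifuse_phantom")
}

#' Locate the carina on a merged lumen surface
#'
#' The carina (flow-divider apex) is found by marching from the take-off
#' point along the bisector of the two distal branch directions until the ray
#' exits the lumen; the exit point lies on the ridge where the two branch
#' surfaces meet. The landmark is deterministic and identical in definition
#' for ground-truth and reconstructed models, which is what carina
#' co-registration requires.
#'
#' @param lumen Merged, watertight lumen [surface_mesh()].
#' @param mv_cl,sb_cl Branch centerlines.
#' @return 3D carina coordinate (mm), on the lumen surface.
#' @export
find_carina_point <- function(lumen, mv_cl, sb_cl) {
  # take-off: the most distal MV point where the SB centerline approaches
  # (the SB centerline may run inside the trunk for several mm, so the
  # closest point alone is ambiguous)
  dprof <- vapply(seq_len(nrow(mv_cl$points)), function(i) {
    min(sqrt(rowSums(sweep(sb_cl$points, 2, mv_cl$points[i, ])^2)))
  }, numeric(1))
  thr <- max(0.3, 1.5 * min(dprof))
  hit <- which(dprof < thr)
  if (!length(hit)) stop("centerlines never approach: no bifurcation found")
  takeoff_s <- mv_cl$arclength[hit[1]]
  takeoff <- as.numeric(centerline_point_at(mv_cl, takeoff_s))
  dir_mv <- -as.numeric(tangent_at(mv_cl, takeoff_s))   # distal MV
  dir_sb <- takeoff_direction(sb_cl, takeoff)           # distal SB

  ray_exit <- function(w) {
    ts <- seq(0, 10, by = 0.1)
    pts <- matrix(takeoff, length(ts), 3, byrow = TRUE) + outer(ts, w)
    inside <- cpp_points_inside(pts, lumen$vertices, lumen$triangles)
    if (!inside[1]) stop("take-off point is not inside the lumen")
    exit <- which(!inside)[1]
    if (is.na(exit)) return(Inf)
    lo <- ts[exit - 1L]; hi <- ts[exit]
    for (it in 1:28) {
      mid <- (lo + hi) / 2
      if (cpp_points_inside(rbind(takeoff + mid * w), lumen$vertices, lumen$triangles)[1]) {
        lo <- mid
      } else {
        hi <- mid
      }
    }
    (lo + hi) / 2
  }
  # the flow-divider apex is the notch of the union boundary in the wedge
  # between the two branch directions: scanning rays across the wedge, it is
  # the exit of minimum distance (a pure bisector ray overshoots, exiting on
  # the far wall of the wider branch)
  lam <- seq(0.15, 0.85, by = 0.05)
  dists <- vapply(lam, function(l) {
    w <- (1 - l) * dir_mv + l * dir_sb
    ray_exit(w / sqrt(sum(w^2)))
  }, numeric(1))
  l0 <- lam[which.min(dists)]
  fine <- seq(max(0.05, l0 - 0.05), min(0.95, l0 + 0.05), by = 0.01)
  dfine <- vapply(fine, function(l) {
    w <- (1 - l) * dir_mv + l * dir_sb
    ray_exit(w / sqrt(sum(w^2)))
  }, numeric(1))
  lbest <- fine[which.min(dfine)]
  wb <- (1 - lbest) * dir_mv + lbest * dir_sb
  wb <- wb / sqrt(sum(wb^2))
  takeoff + ray_exit(wb) * wb
}

#' Simulate an IVUS pullback through a phantom branch
#'
#' Samples true planar cross-sections of the ground-truth lumen along the
#' branch centerline at the acquisition frame spacing, then corrupts them the
#' way a real pullback would: cumulative catheter twist (random walk),
#' smooth in-plane catheter offset, and radial contour noise. EEM and plaque
#' contours are generated analytically on the MV. The carina frame and
#' in-plane carina direction are derived from the geometry and recorded.
#'
#' @param ph A [make_phantom()] result.
#' @param branch `"MV"` or `"SB"`.
#' @param speed Pullback speed mm/s.
#' @param frame_rate Frames per second.
#' @param gating_stride Every `gating_stride`-th frame is ECG-gated.
#' @param twist_sigma_deg SD of the per-gated-frame twist increment.
#' @param offset_sigma_mm SD of the smooth catheter offset field.
#' @param contour_noise_mm SD of radial vertex noise on the lumen contour.
#' @param seed Integer seed; the same seed reproduces the pullback bit for
#'   bit.
#' @param n_points Vertices per stored contour.
#' @param with_plaque Include EEM/plaque contours (MV only).
#' @param margin_mm Stand-off from both centerline ends (avoids slicing the
#'   ground-truth end caps).
#' @return List: `pullback` and `truth` (per-gated-frame `s`, twist series,
#'   offsets, carina annotation).
#' @export
simulate_pullback <- function(ph, branch = c("MV", "SB"), speed = 0.5,
                              frame_rate = 30, gating_stride = 15L,
                              twist_sigma_deg = 0, offset_sigma_mm = 0,
                              contour_noise_mm = 0, seed = 1L,
                              n_points = 96L, with_plaque = TRUE,
                              margin_mm = 0.5) {
  branch <- match.arg(branch)
  cl <- if (branch == "MV") ph$mv_centerline else ph$sb_centerline
  L <- centerline_length(cl)
  sp <- frame_spacing(speed, frame_rate)
  # keep clear of the end caps: frames start margin_mm from the distal end
  n_total <- floor((L - 2 * margin_mm) / sp) + 1L
  if (margin_mm + (n_total - 1L) * sp > L + 1e-9) stop("pullback exceeds the branch length")
  gated_idx <- seq(1L, n_total, by = gating_stride)
  ng <- length(gated_idx)

  set.seed(seed)
  twist <- cumsum(c(0, rnorm(ng - 1L, 0, twist_sigma_deg)))
  # smooth offset field: a few random low-frequency harmonics per axis
  sgat <- margin_mm + (gated_idx - 1L) * sp
  offs <- matrix(0, ng, 2)
  if (offset_sigma_mm > 0) {
    for (ax in 1:2) {
      ph_ang <- runif(3, 0, 2 * pi)
      amp <- rnorm(3, 0, offset_sigma_mm / sqrt(3) * sqrt(2))
      offs[, ax] <- rowSums(sapply(1:3, function(h) {
        amp[h] * sin(2 * pi * h * sgat / max(sgat) + ph_ang[h])
      }))
    }
  }

  rmf <- compute_rmf(cl)
  s_car <- { d2 <- rowSums(sweep(cl$points, 2, ph$carina_point)^2); cl$arclength[which.min(d2)] }
  car_g <- which.min(abs(sgat - s_car))
  other_cl <- if (branch == "MV") ph$sb_centerline else ph$mv_centerline

  triad_at <- function(s) {
    node <- which.min(abs(cl$arclength - s))
    tk <- as.numeric(tangent_at(cl, s))
    uk <- rmf$u[node, ] - sum(rmf$u[node, ] * tk) * tk
    uk <- uk / sqrt(sum(uk^2))
    vk <- c(tk[2] * uk[3] - tk[3] * uk[2], tk[3] * uk[1] - tk[1] * uk[3],
            tk[1] * uk[2] - tk[2] * uk[1])
    list(o = as.numeric(centerline_point_at(cl, s)), t = tk, u = uk, v = vk)
  }

  frames <- vector("list", n_total)
  truth_origin <- matrix(NA_real_, ng, 3)
  prev_centroid <- NULL # world centroid of the previously traced lumen loop
  for (k in seq_len(n_total)) {
    g <- match(k, gated_idx)
    if (is.na(g)) {
      frames[[k]] <- ivus_frame(k, list(), gated = FALSE)
      next
    }
    s <- margin_mm + (k - 1L) * sp
    tri <- triad_at(s)
    truth_origin[g, ] <- tri$o
    loops <- slice_mesh_plane(ph$lumen, tri$o, tri$t)
    if (!length(loops)) stop(sprintf("phantom slice empty at s = %.2f", s))
    loops2 <- lapply(loops, loop_to_2d, origin = tri$o, u = tri$u, v = tri$v)
    # trace the same lumen from frame to frame: near the ostium two loops
    # have comparable centroid offsets and a per-frame nearest-to-axis rule
    # would flip between them, which no human tracing a pullback would do
    cen2 <- lapply(loops2, polygon_centroid)
    ref2 <- if (is.null(prev_centroid)) {
      c(0, 0)
    } else {
      rel <- prev_centroid - tri$o
      c(sum(rel * tri$u), sum(rel * tri$v))
    }
    cdist <- vapply(cen2, function(cc) sqrt(sum((cc - ref2)^2)), numeric(1))
    pick <- which.min(cdist)
    prev_centroid <- tri$o + cen2[[pick]][1] * tri$u + cen2[[pick]][2] * tri$v
    sec <- densify_ring(ensure_ccw(loops2[[pick]]), n_points)
    if (contour_noise_mm > 0) {
      cen <- polygon_centroid(sec)
      rad <- sweep(sec, 2, cen)
      rn <- sqrt(rowSums(rad^2)); rn[rn == 0] <- 1
      # boundary-correlated noise (circular moving average of white noise):
      # segmentation errors are smooth along the contour, and uncorrelated
      # spikes could self-intersect narrow waists of merged slices
      eps <- rnorm(nrow(sec))
      hw <- 7L
      kern <- exp(-0.5 * ((-hw):hw / (hw / 2))^2)
      idx <- outer(seq_len(nrow(sec)), (-hw):hw, function(i, d) ((i - 1 + d) %% nrow(sec)) + 1)
      sm <- as.numeric(matrix(eps[idx], nrow(sec)) %*% kern) / sqrt(sum(kern^2))
      sec <- sec + rad / rn * (contour_noise_mm * sm)
    }
    cts <- list(make_stored_contour(k, "lumen", sec, offs[g, ], twist[g]))
    if (with_plaque && branch == "MV") {
      if (!is.null(ph$spec$eem_wall)) {
        eem2 <- ellipse_ring_at(ph, s, extra = ph$spec$eem_wall, n = n_points)
        cts <- c(cts, list(make_stored_contour(k, "eem", eem2, offs[g, ], twist[g])))
      }
      ci <- 1L
      for (pspec in ph$spec$plaque_specs) {
        if (s >= pspec$s_range[1] && s <= pspec$s_range[2]) {
          cres <- crescent_ring(ph$mv_radius_at(s), ph$spec$ellipticity,
                                pspec$ang_range, pspec$thickness)
          cts <- c(cts, list(make_stored_contour(k, pspec$label, cres,
                                                 offs[g, ], twist[g], ci)))
          ci <- ci + 1L
        }
      }
    }
    frames[[k]] <- ivus_frame(k, cts, gated = TRUE)
  }

  # carina annotation on the nearest gated frame
  tri_c <- triad_at(sgat[car_g])
  w <- takeoff_direction(other_cl, tri_c$o)
  psi <- atan2(sum(w * tri_c$v), sum(w * tri_c$u)) * 180 / pi
  carina_direction <- wrap_angle(psi + twist[car_g])

  pb <- pullback(branch, frames, speed, frame_rate,
                 carina_frame = gated_idx[car_g],
                 carina_direction = carina_direction)
  list(pullback = pb,
       truth = list(s = sgat, twist = twist, offsets = offs,
                    origins = truth_origin, carina_s = s_car,
                    carina_gated_index = car_g))
}

# store a contour in image coordinates: catheter at the origin, the frame
# rotated by the accumulated twist
make_stored_contour <- function(frame_index, label, pts2d, offset, twist_deg,
                                component_id = 1L) {
  q <- rotate2d(sweep(pts2d, 2, offset), twist_deg)
  contour(frame_index, label, q, component_id = component_id)
}

ellipse_ring_at <- function(ph, s, extra = 0, n = 96L) {
  r <- ph$mv_radius_at(s) + extra
  a <- r / sqrt(ph$spec$ellipticity); b <- r * sqrt(ph$spec$ellipticity)
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(a * cos(th), b * sin(th))
}

# annular crescent between the lumen ellipse and an outward offset of it
crescent_ring <- function(r, ratio, ang_range, thickness, n = 48L) {
  a <- r / sqrt(ratio); b <- r * sqrt(ratio)
  th <- seq(ang_range[1], ang_range[2], length.out = n) * pi / 180
  inner <- cbind(a * cos(th), b * sin(th))
  outer_r <- cbind((a + thickness) * cos(rev(th)), (b + thickness) * sin(rev(th)))
  rbind(inner, outer_r)
}

#' Simulate biplane angiographic centerline curves
#'
#' @param ph A [make_phantom()].
#' @param geomA,geomB [projection_geometry()] of the two views.
#' @param noise_mm SD of 2D Gaussian noise added to the detector curves.
#' @param seed Integer seed.
#' @return Nested list: `mv$A`, `mv$B`, `sb$A`, `sb$B` ([curve2d()] objects).
#' @export
simulate_biplane <- function(ph, geomA, geomB, noise_mm = 0, seed = 1L) {
  set.seed(seed)
  one <- function(cl, geom, branch) {
    cv <- project_centerline(cl, geom)
    if (noise_mm > 0) cv$points <- cv$points + rnorm(length(cv$points), 0, noise_mm)
    cv$branch <- branch
    cv
  }
  list(mv = list(A = one(ph$mv_centerline, geomA, "MV"),
                 B = one(ph$mv_centerline, geomB, "MV")),
       sb = list(A = one(ph$sb_centerline, geomA, "SB"),
                 B = one(ph$sb_centerline, geomB, "SB")))
}
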