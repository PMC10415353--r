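# gating, frame spacing, rotation minimizing frames, placement, twist and
# carina corrections, virtual catheter path

test_that("gating keeps every flagged frame in order and enforces the carina", {
  mk <- function(n, stride) {
    frames <- lapply(seq_len(n), function(k) {
      ivus_frame(k, list(contour(k, "lumen", circle_ring(1, 16))),
                 gated = (k - 1L) %% stride == 0L)
    })
    pullback("MV", frames, 0.5, 30, carina_frame = 1L, carina_direction = 0)
  }
  p <- mk(300L, 30L)
  g <- select_gated_frames(p)
  expect_length(g$frames, 10L)
  expect_identical(vapply(g$frames, function(f) f$frame_index, integer(1)),
                   seq(1L, 300L, by = 30L))

  all_gated <- mk(20L, 1L)
  expect_identical(select_gated_frames(all_gated)$frames, all_gated$frames)

  p_bad <- mk(300L, 30L)
  p_bad$carina_frame <- 2L # frame 2 is not gated
  expect_error(select_gated_frames(p_bad), "not gated")
  p_none <- mk(4L, 1L)
  for (i in 1:4) p_none$frames[[i]]$gated <- FALSE
  expect_error(select_gated_frames(p_none), "no gated")
})

test_that("frame spacing reproduces the printed pullback distances", {
  expect_equal(round(frame_spacing(0.5, 30), 3), 0.017)
  expect_equal(round(frame_spacing(1.0, 30), 3), 0.033)
  expect_error(frame_spacing(0, 30), "> 0")
  expect_error(frame_spacing(0.5, 0), "> 0")
})

test_that("RMF: straight line constant, planar semicircle twist-free", {
  line <- resample_by_arclength(centerline3d(rbind(c(0, 0, 0), c(0, 0, 20))), 0.5)
  rmf <- compute_rmf(line)
  expect_lt(max(abs(sweep(rmf$u, 2, rmf$u[1, ]))), 1e-12)

  tt <- seq(0, pi, length.out = 400)
  semi <- centerline3d(cbind(5 * cos(tt), 5 * sin(tt), 0))
  rmf2 <- compute_rmf(semi, u0 = c(0, 0, 1))
  # the out-of-plane normal stays out of plane: no in-plane twist
  expect_lt(max(abs(rmf2$u[, 1])), 1e-9)
  expect_lt(max(abs(rmf2$u[, 2])), 1e-9)
  expect_equal(abs(rmf2$u[, 3]), rep(1, 400), tolerance = 1e-9)
})

test_that("RMF on a helix agrees with a fine-step transport oracle", {
  tt <- seq(0, 4 * pi, length.out = 100)
  helix100 <- centerline3d(cbind(2 * cos(tt), 2 * sin(tt), 10 * tt / (2 * pi)))
  rmf <- compute_rmf(helix100)

  # oracle: parallel transport at 100x finer sampling, compared at shared knots
  tt_f <- seq(0, 4 * pi, length.out = 9901) # every 100th point matches tt
  helix_f <- centerline3d(cbind(2 * cos(tt_f), 2 * sin(tt_f), 10 * tt_f / (2 * pi)))
  tg_f <- bifuse:::centerline_tangents(helix_f)
  u <- compute_rmf(helix100)$u[1, ] # same start normal as the implementation
  U_or <- matrix(0, 100, 3)
  U_or[1, ] <- u
  ki <- 1L
  for (i in 1:(nrow(helix_f$points) - 1L)) {
    # rotate u by the angle between consecutive tangents about their cross product
    t1 <- tg_f[i, ]; t2 <- tg_f[i + 1L, ]
    ax <- c(t1[2] * t2[3] - t1[3] * t2[2], t1[3] * t2[1] - t1[1] * t2[3],
            t1[1] * t2[2] - t1[2] * t2[1])
    na <- sqrt(sum(ax^2))
    if (na > 1e-15) {
      ax <- ax / na
      ang <- asin(min(1, na))
      u <- u * cos(ang) + c(ax[2] * u[3] - ax[3] * u[2],
                            ax[3] * u[1] - ax[1] * u[3],
                            ax[1] * u[2] - ax[2] * u[1]) * sin(ang) +
        ax * sum(ax * u) * (1 - cos(ang))
    }
    u <- u - sum(u * t2) * t2
    u <- u / sqrt(sum(u^2))
    if (i %% 100 == 0L) {
      ki <- ki + 1L
      U_or[ki, ] <- u
    }
  }
  ang_dev <- acos(pmin(1, abs(rowSums(rmf$u * U_or)))) * 180 / pi
  expect_lt(max(ang_dev), 0.1)
})

test_that("triads are orthonormal and right-handed everywhere", {
  set.seed(2)
  tt <- seq(0, 3, length.out = 200)
  wiggly <- centerline3d(cbind(tt * 8, sin(3 * tt), cos(2 * tt)))
  rmf <- compute_rmf(wiggly)
  for (i in seq(1, 200, by = 17)) {
    R <- cbind(rmf$t[i, ], rmf$u[i, ], rmf$v[i, ])
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("placement: arc-length law, centroid registration, overhang error", {
  frames <- lapply(1:11, function(k) {
    ivus_frame(k, list(contour(k, "lumen", circle_ring(1, 64))))
  })
  p <- pullback("MV", frames, pullback_speed = 1, frame_rate = 1) # spacing 1 mm
  cl <- resample_by_arclength(centerline3d(rbind(c(0, 0, 0), c(0, 0, 10))), 0.5)
  pl <- place_frames(p, cl)
  expect_equal(vapply(pl, function(x) x$s, numeric(1)), 0:10, tolerance = 1e-12)
  # span == (n_gated - 1) * spacing exactly
  expect_equal(pl[[11]]$s - pl[[1]]$s, 10, tolerance = 1e-12)

  # centered unit circle: placed centroid on the centerline
  pts3 <- place_points3d(frames[[3]]$contours[[1]]$points, pl[[3]])
  expect_lt(max(abs(colMeans(pts3) - pl[[3]]$origin)), 1e-9)

  # off-center contour: lumen centroid still registered onto the centerline
  off <- circle_ring(1, 64, center = c(0.7, -0.3))
  p2 <- pullback("MV", lapply(1:11, function(k) {
    ivus_frame(k, list(contour(k, "lumen", off)))
  }), 1, 1)
  pl2 <- place_frames(p2, cl)
  pts3b <- place_points3d(off, pl2[[5]])
  expect_lt(max(abs(colMeans(pts3b) - pl2[[5]]$origin)), 1e-9)
  # ... and the catheter point is off the centerline by the centroid offset
  path <- catheter_path(pl2)
  expect_equal(sqrt(sum((path$points[5, ] - pl2[[5]]$origin)^2)),
               sqrt(0.7^2 + 0.3^2), tolerance = 1e-9)

  p12 <- pullback("MV", lapply(1:12, function(k) {
    ivus_frame(k, list(contour(k, "lumen", circle_ring(1, 32))))
  }), 1, 1)
  expect_error(place_frames(p12, cl), "overhang")
})

test_that("twist recovery: injected rotations, circles tie-break, brute-force oracle", {
  ell <- ellipse_ring(2, 1.2, 96)
  frames <- lapply(1:6, function(k) {
    ivus_frame(k, list(contour(k, "lumen", rotate2d(ell, 15 * (k - 1)))))
  })
  p <- pullback("MV", frames, 0.5, 30)
  rec <- correct_relative_twist(p)
  expect_equal(rec, -15 * (0:5), tolerance = 0.2)

  # rotation-invariant circles: all angles 0 by the smallest-|theta| tie rule
  pc <- pullback("MV", lapply(1:5, function(k) {
    ivus_frame(k, list(contour(k, "lumen", circle_ring(1.2, 90))))
  }), 0.5, 30)
  expect_equal(correct_relative_twist(pc), rep(0, 5), tolerance = 1e-9)

  # grid search equals exhaustive 0.1-degree brute force on random star shapes
  set.seed(9)
  for (rep in 1:10) {
    base <- random_star_polygon(40L, r_base = 1.5, wobble = 0.3)
    inj <- runif(1, -30, 30)
    p2 <- pullback("MV", list(
      ivus_frame(1, list(contour(1, "lumen", base))),
      ivus_frame(2, list(contour(2, "lumen", rotate2d(base, inj))))), 0.5, 30)
    rec2 <- correct_relative_twist(p2)[2]
    # brute force at 0.1 degree over the same span, same objective
    prof1 <- radial_profile(base, 360L)
    cand <- seq(-45, 45, by = 0.1)
    obj <- vapply(cand, function(thd) {
      ang <- 2 * pi * (0:359) / 360
      r2 <- bifuse:::ray_crossings(rotate2d(base, inj), ang - thd * pi / 180)
      mean((prof1 - r2)^2)
    }, numeric(1))
    brute <- cand[which.min(obj)]
    expect_lt(abs(rec2 - brute), 0.1 + 1e-9)
    expect_lt(abs(rec2 + inj), 0.2)
  }
})

test_that("twist random-walk recovery RMSE < 2 deg at the 1-degree grid", {
  ell <- ellipse_ring(1.9, 1.45, 96)
  for (seed in 1:5) {
    set.seed(seed)
    tw <- cumsum(c(0, rnorm(49, 0, 2)))
    p <- pullback("MV", lapply(1:50, function(k) {
      ivus_frame(k, list(contour(k, "lumen", rotate2d(ell, tw[k]))))
    }), 0.5, 30)
    rec <- correct_relative_twist(p)
    err <- rec + tw
    err <- err - mean(err)
    expect_lt(sqrt(mean(err^2)), 2)
  }
})

test_that("twist correction requires a lumen on every frame", {
  p <- pullback("MV", list(
    ivus_frame(1, list(contour(1, "lumen", circle_ring(1, 24)))),
    ivus_frame(2, list())), 0.5, 30)
  expect_error(correct_relative_twist(p), "no lumen")
})

test_that("carina registration aligns phantom bifurcations within 0.5 deg", {
  # synthetic Y bifurcation: MV along +z, SB taking off toward +y
  set.seed(4)
  for (ang_deg in seq(30, 90, length.out = 10)) {
    mv_cl <- resample_by_arclength(centerline3d(rbind(c(0, 0, 0), c(0, 0, 30))), 0.5)
    a <- ang_deg * pi / 180
    # SB distal -> proximal: ends at the take-off point (0, 0, 15)
    sb_pts <- cbind(0, sin(a) * seq(10, 0, length.out = 40),
                    15 - cos(a) * seq(10, 0, length.out = 40))
    sb_cl <- resample_by_arclength(centerline3d(sb_pts), 0.5)

    ell <- ellipse_ring(1.5, 1.1, 64)
    mk <- function(n, car_frame, car_dir) {
      pullback("MV", lapply(seq_len(n), function(k) {
        ivus_frame(k, list(contour(k, "lumen", ell)))
      }), 1, 1, carina_frame = car_frame, carina_direction = car_dir)
    }
    # MV: take-off direction of SB at the carina projects onto +y = 90 deg
    # in the MV frame (u = +x, v = +y for a +z line with default RMF)
    mv_p <- mk(31, 16L, 90)
    sb_p <- mk(11, 11L, 0) # annotation value irrelevant for the residual check
    mv_pl <- place_frames(mv_p, mv_cl)
    sb_pl <- place_frames(sb_p, sb_cl)
    reg <- register_carina(mv_pl, sb_pl, mv_p, sb_p, mv_cl, sb_cl)
    expect_lt(reg$residual_deg[["MV"]], 0.5)
    expect_lt(reg$residual_deg[["SB"]], 0.5)
    # MV carina_direction = 90 and SB take-off along +y (= v axis): roll 0
    expect_lt(abs(bifuse:::wrap_angle(reg$mv[[16]]$roll)), 0.5 + ang_deg * 0)
  }
})

test_that("carina registration errors: missing annotation, degenerate projection", {
  cl <- resample_by_arclength(centerline3d(rbind(c(0, 0, 0), c(0, 0, 10))), 0.5)
  p <- pullback("MV", lapply(1:11, function(k) {
    ivus_frame(k, list(contour(k, "lumen", circle_ring(1, 32))))
  }), 1, 1)
  pl <- place_frames(p, cl)
  expect_error(register_carina(pl, pl, p, p, cl, cl), "no carina_frame")

  # other branch parallel to the frame normal: projection undefined
  p2 <- p; p2$carina_frame <- 6L; p2$carina_direction <- 0
  other <- resample_by_arclength(centerline3d(rbind(c(3, 0, -5), c(3, 0, 15))), 0.5)
  expect_error(register_carina(pl, pl, p2, p2, other, other), "parallel")
})

test_that("catheter path correction flags and repairs a displaced point", {
  frames <- lapply(1:21, function(k) {
    center <- if (k == 11) c(1, 0) else c(0, 0) # one frame displaced 1 mm
    ivus_frame(k, list(contour(k, "lumen", circle_ring(1, 48, center = center))))
  })
  p <- pullback("MV", frames, 1, 1)
  cl <- resample_by_arclength(centerline3d(rbind(c(0, 0, 0), c(0, 0, 22))), 0.5)
  pl <- place_frames(p, cl)
  path <- catheter_path(pl)
  corr <- correct_catheter_path(path)
  expect_true(corr$outlier_mask[11])
  expect_identical(sum(corr$outlier_mask), 1L)
  # the corrected point returns to the straight catheter line (x = y = 0)
  expect_lt(sqrt(sum(corr$points[11, 1:2]^2)), 0.05)

  # collinear path: nothing flagged, nothing changed
  straight <- catheter_path(place_frames(pullback("MV", lapply(1:11, function(k) {
    ivus_frame(k, list(contour(k, "lumen", circle_ring(1, 48))))
  }), 1, 1), cl))
  c2 <- correct_catheter_path(straight)
  expect_false(any(c2$outlier_mask))
  expect_equal(c2$points, straight$points, tolerance = 1e-12)
  expect_error(correct_catheter_path(catheter_path(pl[1:4])), ">= 5")
})

test_that("spline repair reduces catheter path MSE under Gaussian noise", {
  wins <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    s <- seq(0, 20, by = 0.25)
    truth <- cbind(0.3 * sin(s / 4), 0.2 * cos(s / 5), s)
    noisy <- truth
    noisy[, 1:2] <- noisy[, 1:2] + rnorm(2 * length(s), 0, 0.1)
    path <- structure(list(points = noisy, s = s,
                           outlier_mask = rep(FALSE, length(s)),
                           correction = matrix(0, length(s), 3)),
                      class = "bifuse_catheter_path")
    corr <- correct_catheter_path(path, k = 1) # aggressive repair for smoothing
    # apply the spline value everywhere it was flagged; elsewhere points kept
    mse_raw <- mean(rowSums((noisy - truth)^2))
    mse_cor <- mean(rowSums((corr$points - truth)^2))
    if (mse_cor < mse_raw) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("path corrections translate frame contours in-plane", {
  frames <- lapply(1:21, function(k) {
    center <- if (k == 11) c(1, 0) else c(0, 0)
    ivus_frame(k, list(contour(k, "lumen", circle_ring(1, 48, center = center))))
  })
  p <- pullback("MV", frames, 1, 1)
  cl <- resample_by_arclength(centerline3d(rbind(c(0, 0, 0), c(0, 0, 22))), 0.5)
  pl <- place_frames(p, cl)
  corr <- correct_catheter_path(catheter_path(pl))
  pl2 <- apply_path_correction(pl, corr)
  # frame 11's contour moves by the same in-plane vector as its catheter point
  before <- place_points3d(frames[[11]]$contours[[1]]$points, pl[[11]])
  after <- place_points3d(frames[[11]]$contours[[1]]$points, pl2[[11]])
  shift <- colMeans(after - before)
  expect_equal(shift, corr$correction[11, ], tolerance = 1e-9)
})
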