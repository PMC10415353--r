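# biplane camera model, triangulation and arc-length utilities

test_that("projection maps the isocenter to the principal point and magnifies laterally", {
  g <- projection_geometry(25, 15, source_isocenter_distance = 700,
                           source_detector_distance = 1050,
                           principal_point = c(1.5, -2))
  p0 <- bifuse:::project_points(rbind(c(0, 0, 0)), g)
  expect_equal(as.numeric(p0), c(1.5, -2), tolerance = 1e-9)

  # 1 mm lateral offset at the isocenter magnified by SDD/SID = 1.5
  off <- bifuse:::project_points(rbind(g$e1), g) # e1 is unit lateral
  expect_equal(sqrt(sum((off - p0)^2)), 1.5, tolerance = 1e-9)
})

test_that("projection agrees with an independent 4x4 homogeneous-matrix oracle", {
  g <- projection_geometry(-30, 20, 720, 1100, principal_point = c(0.7, 0.3))
  # oracle: P = K [R | t] with rows built from the camera axes
  R <- rbind(g$e1, g$e2, g$w)
  tvec <- -as.numeric(R %*% g$source)
  K <- matrix(c(g$sdd, 0, g$principal_point[1],
                0, g$sdd, g$principal_point[2],
                0, 0, 1), 3, 3, byrow = TRUE)
  set.seed(3)
  X <- cbind(runif(50, -40, 40), runif(50, -40, 40), runif(50, -40, 40))
  ours <- bifuse:::project_points(X, g)
  hom <- t(K %*% (R %*% t(X) + tvec))
  oracle <- hom[, 1:2] / hom[, 3]
  expect_lt(max(abs(ours - oracle)), 1e-9)
})

test_that("points behind the source are rejected", {
  g <- projection_geometry(0, 0, 700, 1000)
  behind <- rbind(g$source - 10 * g$w)
  cl <- centerline3d(rbind(behind, behind + c(0, 0, 1)))
  expect_error(project_centerline(cl, g), "behind")
})

test_that("triangulation recovers a straight segment and a helix exactly", {
  gA <- projection_geometry(0, 0)
  gB <- projection_geometry(90, 0)
  seg <- centerline3d(rbind(c(-5, 2, -10), c(5, -1, 10)))
  segf <- resample_by_arclength(seg, 1)
  rec <- triangulate_centerlines(project_centerline(segf, gA), gA,
                                 project_centerline(segf, gB), gB)
  expect_lt(max(abs(rec$points[c(1, nrow(rec$points)), ] -
                    segf$points[c(1, nrow(segf$points)), ])), 1e-6)

  tt <- seq(0, 4 * pi, length.out = 200)
  helix <- centerline3d(cbind(2 * cos(tt), 2 * sin(tt), 10 * tt / (2 * pi)))
  rec2 <- triangulate_centerlines(project_centerline(helix, gA), gA,
                                  project_centerline(helix, gB), gB)
  expect_lt(max(abs(rec2$points - helix$points)), 1e-6)
  expect_lt(rec2$reprojection_rms, 1e-9)
})

test_that("view separation preconditions: error < 15 deg, warning < 30 deg", {
  g0 <- projection_geometry(0, 0)
  g5 <- projection_geometry(5, 0)
  g25 <- projection_geometry(25, 0)
  seg <- resample_by_arclength(centerline3d(rbind(c(0, 0, -5), c(0, 0, 5))), 1)
  expect_error(triangulate_centerlines(project_centerline(seg, g0), g0,
                                       project_centerline(seg, g5), g5),
               "ill-posed")
  expect_warning(triangulate_centerlines(project_centerline(seg, g0), g0,
                                         project_centerline(seg, g25), g25),
                 "accuracy degraded")
})

test_that("reprojection RMS is ~0 noiseless and grows monotonically with 2D noise", {
  gA <- projection_geometry(0, 0)
  gB <- projection_geometry(50, 10)
  # helix fixture: its projections keep the epipolar correspondence
  # well-posed (a full closed loop in projection would not)
  tt <- seq(0, 4 * pi, length.out = 80)
  cl <- centerline3d(cbind(2 * cos(tt), 2 * sin(tt), 10 * tt / (2 * pi)))
  cA <- project_centerline(cl, gA)
  cB <- project_centerline(cl, gB)
  rms_at <- function(sigma, seed) {
    set.seed(seed)
    a <- cA; b <- cB
    a$points <- a$points + rnorm(length(a$points), 0, sigma)
    b$points <- b$points + rnorm(length(b$points), 0, sigma)
    tryCatch(triangulate_centerlines(a, gA, b, gB)$reprojection_rms,
             error = function(e) NA_real_)
  }
  expect_lt(rms_at(0, 1), 1e-9)
  sig <- c(0.05, 0.1, 0.2)
  means <- sapply(sig, function(s) {
    mean(sapply(1:10, function(k) rms_at(s, k)), na.rm = TRUE)
  })
  expect_true(all(diff(means) > 0))
})

test_that("resample_by_arclength spacing, endpoints and arc-length limit", {
  line <- centerline3d(rbind(c(0, 0, 0), c(0, 0, 10)))
  r <- resample_by_arclength(line, 1)
  expect_identical(nrow(r$points), 11L)
  expect_equal(centerline_length(r), 10, tolerance = 1e-12)
  expect_equal(r$points[11, ], c(0, 0, 10), tolerance = 1e-12)

  # quarter circle r = 1: fine resampling converges to the analytic length
  tt <- seq(0, pi / 2, length.out = 20000)
  qc <- centerline3d(cbind(cos(tt), sin(tt), 0))
  rq <- resample_by_arclength(qc, 1e-3)
  expect_equal(centerline_length(rq), pi / 2, tolerance = 1e-5)

  expect_error(resample_by_arclength(line, 0), "> 0")
  expect_error(resample_by_arclength(line, 20), "exceeds")
})

test_that("tangent_at: straight line, circle perpendicularity, unit norm", {
  line <- resample_by_arclength(centerline3d(rbind(c(0, 0, 0), c(0, 0, 10))), 0.5)
  for (s in c(0, 3.3, 10)) {
    expect_equal(as.numeric(tangent_at(line, s)), c(0, 0, 1), tolerance = 1e-9)
  }
  tt <- seq(0, 2 * pi, length.out = 4000)
  circ <- centerline3d(cbind(cos(tt), sin(tt), 0))
  # central differences are second order away from the (one-sided) endpoints
  s_q <- centerline_length(circ) / 4
  tg0 <- as.numeric(tangent_at(circ, s_q))
  radial <- c(cos(pi / 2), sin(pi / 2), 0)
  expect_lt(abs(sum(tg0 * radial)), 1e-6) # perpendicular to the radius
  set.seed(1)
  ss <- runif(100, 0, centerline_length(circ))
  tg <- tangent_at(circ, ss)
  expect_equal(sqrt(rowSums(tg^2)), rep(1, 100), tolerance = 1e-12)
  expect_error(tangent_at(circ, -1), "outside")
})

test_that("curve JSON round-trips", {
  g <- projection_geometry(12, -8, 750, 1080)
  cv <- curve2d(cbind(1:5, sin(1:5)), branch = "SB")
  path <- withr::local_tempfile(fileext = ".json")
  write_curve_json(cv, g, path)
  back <- read_curve_json(path)
  expect_equal(back$curve$points, cv$points, tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(back$curve$branch, "SB")
  expect_equal(back$geom$w, g$w, tolerance = 1e-12)
})
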