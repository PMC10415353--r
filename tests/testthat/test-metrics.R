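# cross-section metrics, z-scores, regression, Bland-Altman, model comparison

test_that("max chord and width: circle, ellipse, brute-force oracle", {
  ch <- max_chord_and_width(circle_ring(1, 256))
  expect_equal(ch$dist_x, 2, tolerance = 2e-3)
  expect_equal(ch$dist_y, 2, tolerance = 2e-3)
  expect_equal(ch$shape_ratio, 1, tolerance = 1e-3)

  ce <- max_chord_and_width(ellipse_ring(2, 1, 512))
  expect_equal(ce$dist_x, 4, tolerance = 4e-3)
  expect_equal(ce$dist_y, 2, tolerance = 2e-3)
  expect_equal(ce$shape_ratio, 0.5, tolerance = 5e-4)

  # brute force: all vertex pairs for the chord, full projection for the width
  set.seed(17)
  for (i in 1:100) {
    # random convex polygon: hull of random points
    pts <- cbind(rnorm(40), rnorm(40))
    hull <- pts[grDevices::chull(pts), ]
    got <- max_chord_and_width(hull, densify = 256L)
    dense <- densify_ring(hull, 256L)
    d2 <- as.matrix(dist(dense))
    dist_x <- max(d2)
    ij <- which(d2 == dist_x, arr.ind = TRUE)[1, ]
    dir <- (dense[ij[2], ] - dense[ij[1], ]) / dist_x
    perp <- c(-dir[2], dir[1])
    proj <- dense %*% perp
    dist_y <- max(proj) - min(proj)
    expect_equal(got$dist_x, dist_x, tolerance = 1e-9)
    expect_equal(got$dist_y, dist_y, tolerance = 1e-9)
  }
  expect_error(max_chord_and_width(rbind(c(0, 0), c(1, 0), c(2, 0))), "degenerate")
})

test_that("shape ratio is invariant under rigid motion and scaling", {
  set.seed(23)
  base <- random_star_polygon(36L)
  ref <- max_chord_and_width(base)$shape_ratio
  for (i in 1:100) {
    ang <- runif(1, 0, 360)
    sc <- runif(1, 0.2, 5)
    shift <- rnorm(2, 0, 10)
    poly <- sweep(sc * rotate2d(base, ang), 2, shift, `+`)
    expect_equal(max_chord_and_width(poly)$shape_ratio, ref, tolerance = 1e-6)
  }
})

test_that("equivalent diameter: circle, ellipse, fan-triangulation oracle", {
  expect_equal(equivalent_diameter(circle_ring(1, 512)), 2, tolerance = 2e-3)
  expect_equal(equivalent_diameter(ellipse_ring(2, 1, 512)), 2 * sqrt(2),
               tolerance = 3e-3)
  set.seed(31)
  for (i in 1:20) {
    poly <- random_star_polygon(25L)
    # fan triangulation area oracle
    a_fan <- 0
    for (k in 2:(nrow(poly) - 1)) {
      v1 <- poly[k, ] - poly[1, ]; v2 <- poly[k + 1, ] - poly[1, ]
      a_fan <- a_fan + (v1[1] * v2[2] - v1[2] * v2[1]) / 2
    }
    expect_equal(equivalent_diameter(poly), 2 * sqrt(abs(a_fan) / pi),
                 tolerance = 1e-12)
  }
})

test_that("z-score normalization: [1,2,3], moments, affine invariance, errors", {
  expect_equal(zscore_normalize(c(1, 2, 3)), c(-1, 0, 1), tolerance = 1e-12)
  set.seed(5)
  x <- rnorm(200, 10, 3)
  z <- zscore_normalize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore_normalize(2.5 * x - 7), z, tolerance = 1e-9)
  expect_error(zscore_normalize(rep(4, 10)), "constant")
  expect_error(zscore_normalize(1), ">= 2")
})

test_that("linear regression: exact lines and closed-form oracle", {
  r1 <- linear_regression(1:10, 1:10)
  expect_equal(c(r1$slope, r1$intercept, r1$r_squared), c(1, 0, 1), tolerance = 1e-12)
  expect_lt(r1$p_value, 1e-12)
  r2 <- linear_regression(1:10, 2 * (1:10) + 1)
  expect_equal(c(r2$slope, r2$intercept, r2$r_squared), c(2, 1, 1), tolerance = 1e-12)

  set.seed(19)
  x <- rnorm(60); y <- 1.4 * x + rnorm(60, 0, 0.6)
  got <- linear_regression(x, y)
  # normal-equations oracle + lm cross-check for the p-value
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  expect_equal(got$slope, b, tolerance = 1e-9)
  expect_equal(got$intercept, a, tolerance = 1e-9)
  expect_equal(got$r_squared, cor(x, y)^2, tolerance = 1e-9)
  lmfit <- summary(lm(y ~ x))
  expect_equal(got$p_value, lmfit$coefficients[2, 4], tolerance = 1e-9)
  expect_error(linear_regression(rep(1, 5), 1:5), "zero variance")
  expect_error(linear_regression(1:2, 1:2), "n >= 3")
})

test_that("Bland-Altman: identity, sign convention, formula oracle", {
  ba0 <- bland_altman(1:5, 1:5)
  expect_equal(unlist(ba0), c(mean_difference = 0, loa_low = 0, loa_high = 0),
               tolerance = 1e-12)
  ba <- bland_altman(1:5, 1:5 - 0.5)
  expect_equal(ba$mean_difference, 0.5, tolerance = 1e-12)
  expect_equal(ba$loa_low, 0.5, tolerance = 1e-12) # constant offset: zero width

  set.seed(29)
  a <- rnorm(40); b <- rnorm(40)
  got <- bland_altman(a, b)
  d <- a - b
  expect_equal(got$mean_difference, mean(d), tolerance = 1e-12)
  expect_equal(got$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(got$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_error(bland_altman(1:3, 1:4), "mismatch")
})

test_that("cross-sections of a straight tube: count and area", {
  tube <- tube_mesh(circle_ring(1, 256), seq(-0.2, 2.2, by = 0.2))
  cl <- resample_by_arclength(centerline3d(rbind(c(0, 0, 0), c(0, 0, 2))), 0.1)
  secs <- sample_cross_sections(tube, cl, step = 0.1)
  expect_identical(nrow(secs), 21L) # floor(L / step) + 1
  expect_true(all(abs(secs$area / pi - 1) < 0.01))
  expect_true(all(abs(secs$shape_ratio - 1) < 0.01))
})

test_that("cross-sections near a bifurcation pick the loop on the branch axis", {
  ph <- .small_phantom()
  secs <- suppressWarnings(
    sample_cross_sections(ph$lumen, ph$mv_centerline, step = 0.5,
                          max_centroid_dist = 1.5))
  expect_gt(nrow(secs), 20L)
  # each chosen loop centroid is close to the centerline (not the SB loop)
  # re-derive centroid distances for a few sections distal to the carina
  for (s in c(2, 5, 7.5)) {
    o <- as.numeric(centerline_point_at(ph$mv_centerline, s))
    tg <- as.numeric(tangent_at(ph$mv_centerline, s))
    loops <- bifuse:::slice_mesh_plane(ph$lumen, o, tg)
    u <- bifuse:::pick_perp(tg)
    v <- c(tg[2] * u[3] - tg[3] * u[2], tg[3] * u[1] - tg[1] * u[3],
           tg[1] * u[2] - tg[2] * u[1])
    cen <- sapply(loops, function(lp) {
      sqrt(sum(polygon_centroid(bifuse:::loop_to_2d(lp, o, u, v))^2))
    })
    expect_lt(min(cen), 0.2)
  }
})

test_that("self-comparison and dilation invariance of compare_models", {
  ph <- .small_phantom()
  model <- bifurcation_model(ph$lumen, ph$mv_centerline, ph$sb_centerline, ph$carina_point)
  cmp <- suppressWarnings(compare_models(model, model, step = 0.25))
  for (br in c("MV", "SB")) {
    expect_equal(cmp[[br]]$regression$slope, 1, tolerance = 1e-9)
    expect_equal(cmp[[br]]$regression$intercept, 0, tolerance = 1e-9)
    expect_equal(cmp[[br]]$regression$r_squared, 1, tolerance = 1e-9)
    expect_equal(unlist(cmp[[br]]$bland_altman),
                 c(mean_difference = 0, loa_low = 0, loa_high = 0), tolerance = 1e-12)
    expect_true(cmp[[br]]$significant)
  }

  # diameters uniformly overestimated x1.2 (IVUS overestimating lumen size):
  # radial dilation about the local centerline keeps arc lengths, and the
  # z-score normalization removes the scale factor
  dilated <- model
  v <- model$lumen$vertices
  allcl <- rbind(model$mv_centerline$points, model$sb_centerline$points)
  for (i in seq_len(nrow(v))) {
    c0 <- allcl[which.min(rowSums(sweep(allcl, 2, v[i, ])^2)), ]
    v[i, ] <- c0 + 1.2 * (v[i, ] - c0)
  }
  dilated$lumen$vertices <- v
  cmp2 <- suppressWarnings(compare_models(dilated, model, step = 0.25))
  for (br in c("MV", "SB")) {
    expect_gt(cmp2[[br]]$regression$r_squared, 0.98)
    expect_lt(abs(cmp2[[br]]$regression$slope - 1), 0.05)
  }
})

test_that("compare_models r2 is symmetric and OLS slope relation holds", {
  ph <- .small_phantom()
  model <- bifurcation_model(ph$lumen, ph$mv_centerline, ph$sb_centerline, ph$carina_point)
  jig <- model
  set.seed(77)
  jig$lumen$vertices <- jig$lumen$vertices * (1 + rnorm(1, 0, 0.001))
  ab <- suppressWarnings(compare_models(model, jig, step = 0.25))
  ba <- suppressWarnings(compare_models(jig, model, step = 0.25))
  for (br in c("MV", "SB")) {
    expect_equal(ab[[br]]$regression$r_squared, ba[[br]]$regression$r_squared,
                 tolerance = 1e-9)
    prod_slopes <- ab[[br]]$regression$slope * ba[[br]]$regression$slope
    expect_equal(prod_slopes, ab[[br]]$regression$r_squared, tolerance = 1e-9)
  }
})

test_that("co-registration: self and rigid translation", {
  ph <- .small_phantom()
  model <- bifurcation_model(ph$lumen, ph$mv_centerline, ph$sb_centerline, ph$carina_point)
  org <- coregister_at_carina(model, model)
  expect_equal(org$A, org$B, tolerance = 1e-12)

  moved <- model
  shift <- c(5, -3, 2)
  moved$lumen$vertices <- sweep(model$lumen$vertices, 2, shift, `+`)
  moved$mv_centerline <- centerline3d(sweep(model$mv_centerline$points, 2, shift, `+`))
  moved$sb_centerline <- centerline3d(sweep(model$sb_centerline$points, 2, shift, `+`))
  moved$carina_point <- model$carina_point + shift
  cmp <- suppressWarnings(compare_models(model, moved, step = 0.25))
  for (br in c("MV", "SB")) {
    m <- cmp[[br]]$sections
    expect_lt(max(abs(m$diameter_A - m$diameter_B)), 1e-9)
  }
  nocarina <- model
  nocarina$carina_point <- c(NA_real_, NA_real_, NA_real_)
  expect_error(carina_arclength(nocarina), "carina")
})
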