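# lofting, branch union, plaque solids, mapping-back and refinement

test_that("lofted cylinder and frustum volumes match analytic values within 1%", {
  rings_cyl <- lapply(1:5, function(k) circle_ring(1, 128))
  pcs <- straight_placed_stack(rings_cyl, spacing = 0.25)
  cyl <- loft_surface(pcs, n_theta = 256L)
  expect_watertight(cyl)
  expect_lt(abs(mesh_volume(cyl) / (pi * 1^2 * 1) - 1), 0.01)

  # frustum r 1 -> 2 over L = 3: V = pi * L * (r1^2 + r1 r2 + r2^2) / 3 = 7 pi
  n <- 13L
  radii <- seq(1, 2, length.out = n)
  rings_fr <- lapply(radii, function(r) circle_ring(r, 128))
  pcs_fr <- straight_placed_stack(rings_fr, spacing = 3 / (n - 1))
  frustum <- loft_surface(pcs_fr, n_theta = 256L)
  expect_watertight(frustum)
  expect_lt(abs(mesh_volume(frustum) / (7 * pi) - 1), 0.01)
})

test_that("lofting is watertight and outward for random star-shaped stacks", {
  set.seed(12)
  for (rep in 1:20) {
    rings <- lapply(1:4, function(k) random_star_polygon(30L, r_base = 1.3, wobble = 0.25))
    mesh <- loft_surface(straight_placed_stack(rings, spacing = 0.5), n_theta = 64L)
    expect_watertight(mesh)
  }
})

test_that("loft preconditions: ring count, n_theta, crossing planes, mixed labels", {
  rings <- lapply(1:3, function(k) circle_ring(1, 32))
  pcs <- straight_placed_stack(rings, spacing = 0.5)
  expect_error(loft_surface(pcs[1], n_theta = 64L), ">= 2")
  expect_error(loft_surface(pcs, n_theta = 4L), "n_theta")
  rev_pcs <- rev(pcs)
  expect_error(loft_surface(rev_pcs, n_theta = 64L), "cross")
  mixed <- pcs
  mixed[[2]]$contour$label <- "eem"
  expect_error(loft_surface(mixed, n_theta = 64L), "label")
})

test_that("branch union: Steinmetz volume, containment, disjoint error, commutation", {
  circ <- circle_ring(1, 128)
  A <- tube_mesh(circ, seq(-3, 3, by = 0.25))
  B <- {
    rings <- lapply(seq(-3, 3, by = 0.25), function(x) cbind(x, circ))
    bifuse:::loft_rings3d(rings, "lumen")
  }
  U <- merge_branches(A, B, pitch = 0.05)
  expect_watertight(U)
  v_expected <- 2 * (pi * 1^2 * 6) - 16 / 3 # V1 + V2 - Steinmetz solid
  expect_lt(abs(mesh_volume(U) / v_expected - 1), 0.02)

  # union contains both inputs (within a grid pitch)
  set.seed(8)
  pts <- cbind(runif(1000, -1, 1), runif(1000, -1, 1), runif(1000, -3, 3))
  keepA <- bifuse:::cpp_points_inside(pts, A$vertices, A$triangles)
  interior <- pts[keepA, , drop = FALSE]
  # shrink towards the axis by one pitch to stay clear of the discretized skin
  interior[, 1:2] <- interior[, 1:2] * (1 - 0.06)
  inU <- bifuse:::cpp_points_inside(interior, U$vertices, U$triangles)
  expect_true(all(inU))

  U2 <- merge_branches(B, A, pitch = 0.05)
  expect_lt(abs(mesh_volume(U2) / mesh_volume(U) - 1), 0.001)

  Bfar <- B
  Bfar$vertices[, 2] <- Bfar$vertices[, 2] + 10
  expect_error(merge_branches(A, Bfar, pitch = 0.1), "do not intersect")
})

test_that("plaque components: chaining, gaps, angularly disjoint arcs", {
  arc <- function(a1, a2, r1 = 1, r2 = 1.4) {
    th <- seq(a1, a2, length.out = 24) * pi / 180
    rbind(cbind(r1 * cos(th), r1 * sin(th)),
          cbind(r2 * cos(rev(th)), r2 * sin(rev(th))))
  }
  lum <- circle_ring(1, 64)
  mkframe <- function(k, plaque_arcs) {
    cts <- list(contour(k, "lumen", lum))
    for (j in seq_along(plaque_arcs)) {
      cts <- c(cts, list(contour(k, "calcium", plaque_arcs[[j]], component_id = j)))
    }
    ivus_frame(k, cts)
  }
  # calcium on frames 10..20 only -> one solid spanning those s values
  frames <- lapply(1:30, function(k) {
    mkframe(k, if (k >= 10 && k <= 20) list(arc(20, 120)) else list())
  })
  p <- pullback("MV", frames, 1, 2) # spacing 0.5 mm
  cl <- resample_by_arclength(centerline3d(rbind(c(0, 0, 0), c(0, 0, 16))), 0.25)
  pl <- place_frames(p, cl)
  pcs <- list()
  for (i in seq_along(frames)) {
    for (ct in frames[[i]]$contours) {
      if (ct$label == "calcium") pcs[[length(pcs) + 1L]] <- placed_contour(ct, pl[[i]])
    }
  }
  solids <- loft_plaque_components(pcs)
  expect_length(solids, 1L)
  expect_watertight(solids[[1]])
  zr <- range(solids[[1]]$vertices[, 3])
  expect_equal(zr, c(pl[[10]]$s, pl[[20]]$s), tolerance = 0.05)

  # two angularly disjoint arcs per frame -> two solids
  frames2 <- lapply(1:10, function(k) mkframe(k, list(arc(0, 80), arc(180, 260))))
  p2 <- pullback("MV", frames2, 1, 2)
  pl2 <- place_frames(p2, cl)
  pcs2 <- list()
  for (i in seq_along(frames2)) {
    for (ct in frames2[[i]]$contours) {
      if (ct$label == "calcium") pcs2[[length(pcs2) + 1L]] <- placed_contour(ct, pl2[[i]])
    }
  }
  solids2 <- loft_plaque_components(pcs2)
  expect_length(solids2, 2L)
  for (s in solids2) expect_watertight(s)

  expect_identical(loft_plaque_components(list()), list())
})

test_that("single-frame plaque becomes a thin capped disc", {
  lum <- circle_ring(1, 64)
  arc <- rbind(cbind(cos(seq(0, 1.2, length.out = 16)), sin(seq(0, 1.2, length.out = 16))),
               1.3 * cbind(cos(seq(1.2, 0, length.out = 16)), sin(seq(1.2, 0, length.out = 16))))
  frames <- lapply(1:3, function(k) {
    cts <- list(contour(k, "lumen", lum))
    if (k == 2) cts <- c(cts, list(contour(k, "calcium", arc)))
    ivus_frame(k, cts)
  })
  p <- pullback("MV", frames, 1, 2)
  cl <- resample_by_arclength(centerline3d(rbind(c(0, 0, 0), c(0, 0, 3))), 0.25)
  pl <- place_frames(p, cl)
  pc <- placed_contour(frame_contour(frames[[2]], "calcium"), pl[[2]])
  solids <- loft_plaque_components(list(pc), disc_thickness = 0.5)
  expect_length(solids, 1L)
  expect_watertight(solids[[1]])
  expect_equal(diff(range(solids[[1]]$vertices[, 3])), 0.5, tolerance = 1e-9)
})

test_that("map-back: lofted mesh round-trips, translation is detected, misses error", {
  rings <- lapply(1:9, function(k) ellipse_ring(1.6, 1.2, 96))
  pcs <- straight_placed_stack(rings, spacing = 0.5)
  mesh <- loft_surface(pcs, n_theta = 256L)
  rep0 <- map_back_check(mesh, pcs)
  expect_lt(max(rep0$mean_dev), 0.01)

  shifted <- mesh
  shifted$vertices[, 1] <- shifted$vertices[, 1] + 1 # in-plane translation
  rep1 <- map_back_check(shifted, pcs)
  expect_true(all(abs(rep1$mean_dev - 1) < 0.02 * 1))

  far <- pcs[[1]]
  far$placement$origin <- far$placement$origin + c(0, 0, 100)
  expect_error(map_back_check(mesh, list(far)), "misses")
})

test_that("refinement pulls a perturbed surface back to the contours", {
  rings <- lapply(1:9, function(k) circle_ring(1.5, 96))
  pcs <- straight_placed_stack(rings, spacing = 0.5)
  mesh <- loft_surface(pcs, n_theta = 128L)

  # smooth radial bump, 0.3 mm amplitude
  bumped <- mesh
  v <- bumped$vertices
  r <- sqrt(v[, 1]^2 + v[, 2]^2)
  onwall <- r > 1e-6
  amp <- 0.3 * exp(-((v[, 3] - 2)^2) / 0.8) * sin(atan2(v[, 2], v[, 1]))
  scale <- 1 + amp / pmax(r, 1e-6)
  bumped$vertices[onwall, 1:2] <- v[onwall, 1:2] * scale[onwall]

  devs <- c(mean(map_back_check(bumped, pcs)$mean_dev))
  ref <- bumped
  for (it in 1:4) {
    if (devs[length(devs)] <= 0.05) break # converged
    ref <- suppressWarnings(refine_to_contours(ref, pcs, tol = 1e-6, max_iter = 1L))
    devs <- c(devs, mean(map_back_check(ref, pcs)$mean_dev))
  }
  expect_true(all(diff(devs) < 0))       # strictly decreasing until tolerance
  expect_lte(devs[length(devs)], 0.05)   # reaches the tolerance
  expect_watertight(ref)

  # already conforming mesh: unchanged within 1e-6
  same <- refine_to_contours(mesh, pcs, tol = 0.05, max_iter = 3L)
  expect_lt(max(abs(same$vertices - mesh$vertices)), 1e-6)
})
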