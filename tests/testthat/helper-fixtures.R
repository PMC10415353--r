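# Shared fixtures: rings, tubes, tiny phantoms. Everything is generated in
# code; no binary fixtures.

circle_ring <- function(r = 1, n = 256L, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

ellipse_ring <- function(a = 2, b = 1, n = 256L, rot_deg = 0) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  rotate2d(cbind(a * cos(th), b * sin(th)), rot_deg)
}

# random simple star-shaped polygon about the origin
random_star_polygon <- function(n = 24L, r_base = 1, wobble = 0.35) {
  th <- sort(runif(n, 0, 2 * pi))
  # enforce distinct angles
  th <- th + seq_len(n) * 1e-6
  r <- r_base * (1 + runif(n, -wobble, wobble))
  cbind(r * cos(th), r * sin(th))
}

# straight-centerline pullback of identical rings -> placed contours
straight_placed_stack <- function(rings, spacing = 1, speed = NULL, frame_rate = NULL) {
  n <- length(rings)
  if (is.null(speed)) { speed <- spacing; frame_rate <- 1 }
  frames <- lapply(seq_len(n), function(k) {
    ivus_frame(k, list(contour(k, "lumen", rings[[k]])))
  })
  p <- pullback("MV", frames, speed, frame_rate)
  cl <- centerline3d(cbind(0, 0, seq(0, (n - 1) * spacing + 2, by = 0.5)))
  pl <- place_frames(p, cl)
  lapply(seq_len(n), function(k) {
    placed_contour(frame_contour(p$frames[[k]], "lumen"), pl[[k]])
  })
}

# lofted cylinder/tube mesh from a ring sweep along z
tube_mesh <- function(ring2d, zs, label = "lumen") {
  rings <- lapply(zs, function(z) cbind(ring2d, z))
  bifuse:::loft_rings3d(rings, label)
}

# small, fast phantom used by several test files (built once per run)
.small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(
        mv_control = rbind(c(0, 0, 0), c(6, 0.8, 0.6), c(12, 2.2, 1.4), c(18, 4.4, 2.0)),
        sb_takeoff_s = 10, sb_length = 7, trunk_overlap = 2.5,
        plaque_specs = list(list(label = "calcium", s_range = c(4, 6),
                                 ang_range = c(30, 120), thickness = 0.35)))
      cache <<- make_phantom(spec, ring_spacing = 0.4, n_theta = 96L, pitch = 0.12)
    }
    cache
  }
})

expect_watertight <- function(mesh) {
  expect_true(mesh_is_watertight(mesh))
  expect_gt(mesh_volume(mesh), 0)
}
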