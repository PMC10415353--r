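# Geometric validation: serial cross-sections, diameter and shape metrics,
# z-score normalization, linear regression and Bland-Altman agreement.

#' Bundle a reconstructed bifurcation
#'
#' @param lumen Merged lumen [surface_mesh()].
#' @param mv_centerline,sb_centerline Branch [centerline3d()] objects.
#' @param carina_point 3D carina coordinate (mm).
#' @param eem Optional EEM mesh.
#' @param plaques Named list of plaque meshes (or list of lists per label).
#' @return A `bifuse_model` object.
#' @export
bifurcation_model <- function(lumen, mv_centerline, sb_centerline, carina_point,
                              eem = NULL, plaques = list()) {
  structure(list(lumen = lumen, eem = eem, plaques = plaques,
                 mv_centerline = mv_centerline, sb_centerline = sb_centerline,
                 carina_point = as.numeric(carina_point)),
            class = "bifuse_model")
}

#' @export
print.bifuse_model <- function(x, ...) {
  cat(sprintf("<bifuse_model> lumen %d tris; MV %.1f mm, SB %.1f mm; carina (%.2f, %.2f, %.2f)\n",
              nrow(x$lumen$triangles), centerline_length(x$mv_centerline),
              centerline_length(x$sb_centerline),
              x$carina_point[1], x$carina_point[2], x$carina_point[3]))
  invisible(x)
}

#' Arc length of the carina on each branch centerline
#'
#' Used to co-register two models: s = 0 at the carina, positive toward the
#' proximal end (frames and centerlines run distal to proximal).
#'
#' @param model A [bifurcation_model()].
#' @return Named numeric: `MV`, `SB` carina arc lengths.
#' @export
carina_arclength <- function(model) {
  if (is.null(model$carina_point) || anyNA(model$carina_point)) {
    stop("model has no carina annotation")
  }
  one <- function(cl) {
    d2 <- rowSums(sweep(cl$points, 2, model$carina_point)^2)
    cl$arclength[which.min(d2)]
  }
  c(MV = one(model$mv_centerline), SB = one(model$sb_centerline))
}

#' Co-register two models at the carina
#' @param modelA,modelB [bifurcation_model()] objects.
#' @return List of per-model, per-branch carina arc-length origins.
#' @export
coregister_at_carina <- function(modelA, modelB) {
  list(A = carina_arclength(modelA), B = carina_arclength(modelB))
}

#' Maximum chord, perpendicular width and shape ratio of a polygon
#'
#' `dist_x` is the maximum distance between two boundary points (rotating
#' calipers over the convex hull of the densified ring); `dist_y` is the
#' polygon's extent along the direction perpendicular to that chord. Their
#' ratio `dist_y / dist_x` is 1 for a circle and < 1 for ovals.
#'
#' @param pts Ring matrix (n x 2, mm).
#' @param densify Number of boundary samples before the chord search.
#' @return List `dist_x`, `dist_y`, `shape_ratio`.
#' @export
max_chord_and_width <- function(pts, densify = 512L) {
  pts <- as_ring(pts)
  if (polygon_area(pts) <= 1e-12) stop("degenerate (zero-area) polygon")
  dense <- densify_ring(pts, densify)
  hull <- dense[rev(grDevices::chull(dense)), , drop = FALSE]
  h <- nrow(hull)
  # all-pairs over hull vertices (h is small after hulling)
  d2 <- outer(rowSums(hull^2), rowSums(hull^2), `+`) - 2 * hull %*% t(hull)
  best <- which(d2 == max(d2), arr.ind = TRUE)
  best <- best[order(pmin(best[, 1], best[, 2]), pmax(best[, 1], best[, 2])), , drop = FALSE]
  i <- best[1, 1]; j <- best[1, 2]
  dist_x <- sqrt(max(d2[i, j], 0))
  dir <- (hull[j, ] - hull[i, ]) / dist_x
  perp <- c(-dir[2], dir[1])
  proj <- as.numeric(dense %*% perp)
  dist_y <- max(proj) - min(proj)
  list(dist_x = dist_x, dist_y = dist_y, shape_ratio = dist_y / dist_x)
}

#' Area-equivalent diameter of a polygon
#' @param pts Ring matrix (n x 2, mm).
#' @return `2 * sqrt(area / pi)` in mm.
#' @export
equivalent_diameter <- function(pts) {
  a <- polygon_area(pts)
  if (a <= 0) stop("zero-area polygon")
  2 * sqrt(a / pi)
}

#' Z-score normalize a series
#'
#' `(x - mean) / sd` with the sample standard deviation (n - 1 denominator),
#' removing a modality's systematic size offset before regression.
#'
#' @param x Numeric vector (>= 2 values, non-constant).
#' @return Normalized vector with mean 0 and SD 1.
#' @export
zscore_normalize <- function(x) {
  if (length(x) < 2L) stop("need >= 2 values")
  s <- sd(x)
  if (!(s > 0)) stop("constant series cannot be z-scored")
  (x - mean(x)) / s
}

#' Ordinary least squares of y on x
#' @param x,y Numeric vectors, length >= 3.
#' @return List `slope`, `intercept`, `r_squared`, `p_value` (two-sided t
#'   test on the slope, n - 2 df).
#' @export
linear_regression <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need equal-length x, y with n >= 3")
  sxx <- sum((x - mean(x))^2)
  if (!(sxx > 0)) stop("x has zero variance")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  sse <- sum(res^2)
  syy <- sum((y - mean(y))^2)
  r2 <- if (syy > 0) 1 - sse / syy else 1
  se <- sqrt(sse / (n - 2) / sxx)
  pv <- if (se > 0) 2 * pt(abs(slope / se), df = n - 2, lower.tail = FALSE) else 0
  list(slope = slope, intercept = intercept, r_squared = r2, p_value = pv)
}

#' Bland-Altman agreement of paired measurements
#'
#' Differences are `a - b`; limits of agreement are the mean difference plus
#' and minus 1.96 sample standard deviations.
#'
#' @param a,b Equal-length numeric vectors (n >= 2).
#' @return List `mean_difference`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2L) stop("need >= 2 pairs")
  d <- a - b
  m <- mean(d)
  s <- sd(d)
  list(mean_difference = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

#' Serial cross-sections of a lumen mesh along a centerline
#'
#' Slices the mesh perpendicular to the centerline tangent every `step` mm,
#' keeps the slice loop whose centroid is nearest the centerline point, and
#' measures area, area-equivalent diameter, maximum chord, perpendicular
#' width and shape ratio. Sections whose nearest loop centroid is farther
#' than `max_centroid_dist` (loops of the other branch) are skipped, as are
#' empty slices; skips are recorded in the `skipped` attribute.
#'
#' @param mesh Watertight lumen [surface_mesh()].
#' @param cl Branch [centerline3d()] inside the mesh.
#' @param step Sampling step in mm (0.1 mm in the validation protocol).
#' @param s_range Optional `c(min, max)` arc-length window.
#' @param max_centroid_dist Reject threshold for loop centroid distance (mm).
#' @return Data frame with `s`, `area`, `diameter`, `dist_x`, `dist_y`,
#'   `shape_ratio`.
#' @export
sample_cross_sections <- function(mesh, cl, step = 0.1, s_range = NULL,
                                  max_centroid_dist = Inf) {
  L <- centerline_length(cl)
  grid <- seq(0, L, by = step)
  if (!is.null(s_range)) grid <- grid[grid >= s_range[1] & grid <= s_range[2]]
  rows <- vector("list", length(grid))
  skipped <- numeric(0)
  for (gi in seq_along(grid)) {
    s <- grid[gi]
    o <- as.numeric(centerline_point_at(cl, s))
    tg <- as.numeric(tangent_at(cl, s))
    loops <- slice_mesh_plane(mesh, o, tg)
    if (!length(loops)) { skipped <- c(skipped, s); next }
    u <- pick_perp(tg)
    v <- c(tg[2] * u[3] - tg[3] * u[2], tg[3] * u[1] - tg[1] * u[3], tg[1] * u[2] - tg[2] * u[1])
    loops2 <- lapply(loops, loop_to_2d, origin = o, u = u, v = v)
    cendist <- vapply(loops2, function(lp) sqrt(sum(polygon_centroid(lp)^2)), numeric(1))
    jl <- which.min(cendist)
    if (cendist[jl] > max_centroid_dist) { skipped <- c(skipped, s); next }
    poly <- loops2[[jl]]
    if (polygon_area(poly) <= 1e-9) { skipped <- c(skipped, s); next }
    ch <- max_chord_and_width(poly)
    rows[[gi]] <- data.frame(
      s = s, area = polygon_area(poly), diameter = equivalent_diameter(poly),
      dist_x = ch$dist_x, dist_y = ch$dist_y, shape_ratio = ch$shape_ratio)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(s = numeric(0), area = numeric(0),
                                      diameter = numeric(0), dist_x = numeric(0),
                                      dist_y = numeric(0), shape_ratio = numeric(0))
  if (length(skipped)) {
    warning(sprintf("%d cross-sections skipped (empty or off-branch slice)", length(skipped)))
  }
  attr(out, "skipped") <- skipped
  out
}

pick_perp <- function(t) {
  ax <- diag(3)[, which.min(abs(t))]
  u <- ax - sum(ax * t) * t
  u / sqrt(sum(u^2))
}

#' Compare two bifurcation models section by section
#'
#' Both models are co-registered at the carina (s = 0), sampled at matched
#' arc lengths every `step` mm per branch, and compared with z-score
#' normalized diameter regression (A on B) and Bland-Altman analysis of the
#' shape ratios. p < 0.01 is the reporting significance level.
#'
#' @param modelA,modelB [bifurcation_model()] objects.
#' @param step Section spacing in mm.
#' @param min_sections Minimum matched sections per branch.
#' @return A `bifuse_comparison` list with one entry per branch: the paired
#'   section table, regression, Bland-Altman, shape medians and IQRs, and the
#'   number of unmatched sections dropped.
#' @export
compare_models <- function(modelA, modelB, step = 0.1, min_sections = 10L) {
  org <- coregister_at_carina(modelA, modelB)
  out <- list()
  for (br in c("MV", "SB")) {
    clA <- if (br == "MV") modelA$mv_centerline else modelA$sb_centerline
    clB <- if (br == "MV") modelB$mv_centerline else modelB$sb_centerline
    # matched carina-relative grid
    loA <- -org$A[[br]]; hiA <- centerline_length(clA) - org$A[[br]]
    loB <- -org$B[[br]]; hiB <- centerline_length(clB) - org$B[[br]]
    lo <- max(loA, loB); hi <- min(hiA, hiB)
    # at and beyond the carina an SB-normal plane cuts through the main
    # vessel (the other branch's domain): those sections are excluded. The
    # carina apex lies on the MV surface, so planes within about one SB
    # radius distal of it still graze the ostium; the margin is derived from
    # the local SB radius, not tuned.
    if (br == "SB") {
      probe <- suppressWarnings(
        sample_cross_sections(modelB$lumen, clB, step = step,
                              s_range = org$B[[br]] + c(-4, -2),
                              max_centroid_dist = 1.5))
      r_loc <- if (nrow(probe)) median(probe$diameter) / 2 else 1.5
      hi <- min(hi, -r_loc)
    }
    rel <- seq(ceiling(lo / step) * step, floor(hi / step) * step, by = step)
    n_dropped <- length(seq(ceiling(min(loA, loB) / step) * step,
                            floor(max(hiA, hiB) / step) * step, by = step)) - length(rel)
    radius_guard <- 1.5 # mm: reject slice loops from the other branch
    secA <- sample_cross_sections(modelA$lumen, clA, step = step,
                                  s_range = org$A[[br]] + range(rel),
                                  max_centroid_dist = radius_guard)
    secB <- sample_cross_sections(modelB$lumen, clB, step = step,
                                  s_range = org$B[[br]] + range(rel),
                                  max_centroid_dist = radius_guard)
    secA$rel <- round((secA$s - org$A[[br]]) / step)
    secB$rel <- round((secB$s - org$B[[br]]) / step)
    m <- merge(secA, secB, by = "rel", suffixes = c("_A", "_B"))
    m$rel_mm <- m$rel * step
    if (nrow(m) < min_sections) {
      stop(sprintf("branch %s: only %d matched sections (need >= %d)",
                   br, nrow(m), min_sections))
    }
    zA <- zscore_normalize(m$diameter_A)
    zB <- zscore_normalize(m$diameter_B)
    reg <- linear_regression(zB, zA)
    ba <- bland_altman(m$shape_ratio_A, m$shape_ratio_B)
    out[[br]] <- list(
      sections = m,
      n_matched = nrow(m),
      n_dropped = n_dropped,
      regression = reg,
      significant = reg$p_value < 0.01,
      bland_altman = ba,
      shape_A = c(median = median(m$shape_ratio_A),
                  q25 = unname(quantile(m$shape_ratio_A, 0.25)),
                  q75 = unname(quantile(m$shape_ratio_A, 0.75))),
      shape_B = c(median = median(m$shape_ratio_B),
                  q25 = unname(quantile(m$shape_ratio_B, 0.25)),
                  q75 = unname(quantile(m$shape_ratio_B, 0.75))))
  }
  structure(out, class = "bifuse_comparison")
}

#' @export
print.bifuse_comparison <- function(x, ...) {
  for (br in names(x)) {
    b <- x[[br]]
    cat(sprintf("%s: n=%d  r^2=%.3f  y=%.2fx%+.2f  p=%.2g%s  BA mean diff %+.4f [%+.4f, %+.4f]\n",
                br, b$n_matched, b$regression$r_squared, b$regression$slope,
                b$regression$intercept, b$regression$p_value,
                if (b$significant) " (p<0.01)" else "",
                b$bland_altman$mean_difference, b$bland_altman$loa_low,
                b$bland_altman$loa_high))
  }
  invisible(x)
}

#' Write a comparison report to CSV
#'
#' One row per matched cross-section followed by a summary block (slope,
#' intercept, r-squared, Bland-Altman statistics) per branch.
#'
#' @param report A `bifuse_comparison` from [compare_models()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("branch,s_rel_mm,diameter_A,diameter_B,shape_ratio_A,shape_ratio_B", con)
  total <- 0L
  for (br in names(report)) {
    b <- report[[br]]
    m <- b$sections
    total <- total + nrow(m)
    if (nrow(m)) {
      writeLines(sprintf("%s,%.6g,%.6g,%.6g,%.6g,%.6g", br, m$rel_mm,
                         m$diameter_A, m$diameter_B, m$shape_ratio_A, m$shape_ratio_B), con)
    }
  }
  writeLines("", con)
  writeLines("branch,slope,intercept,r_squared,p_value,ba_mean_diff,ba_loa_low,ba_loa_high", con)
  for (br in names(report)) {
    b <- report[[br]]
    writeLines(sprintf("%s,%.10g,%.10g,%.10g,%.3g,%.10g,%.10g,%.10g", br,
                       b$regression$slope, b$regression$intercept,
                       b$regression$r_squared, b$regression$p_value,
                       b$bland_altman$mean_difference, b$bland_altman$loa_low,
                       b$bland_altman$loa_high), con)
  }
  if (total == 0L) warning("comparison report has no matched sections")
  invisible(path)
}
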