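# Data model for segmented IVUS pullbacks. Contour coordinates are 2D mm in
# the frame plane with the origin at the catheter (transducer) point; frames
# are ordered distal -> proximal (the pullback direction).

CONTOUR_LABELS <- c("lumen", "eem", "calcium", "fibrosis", "fibrolipid")

#' Create a segmented contour
#'
#' @param frame_index Integer frame index the contour belongs to.
#' @param label One of `lumen`, `eem`, `calcium`, `fibrosis`, `fibrolipid`.
#' @param points n x 2 matrix of ring vertices (mm, catheter point at origin).
#'   Clockwise rings are re-wound counter-clockwise; area is unchanged.
#' @param component_id Integer distinguishing multiple same-label components
#'   in one frame.
#' @return A `bifuse_contour` object.
#' @export
contour <- function(frame_index, label, points, component_id = 1L) {
  label <- match.arg(label, CONTOUR_LABELS)
  points <- as_ring(points)
  if (nrow(points) < 3L) {
    stop(sprintf("contour (frame %d, %s): needs >= 3 points", frame_index, label))
  }
  if (!all(is.finite(points))) {
    stop(sprintf("contour (frame %d, %s): non-finite coordinates", frame_index, label))
  }
  if (!is_simple_polygon(points)) {
    stop(sprintf("contour (frame %d, %s): polygon is self-intersecting", frame_index, label))
  }
  points <- ensure_ccw(points)
  structure(
    list(frame_index = as.integer(frame_index), label = label,
         points = points, component_id = as.integer(component_id)),
    class = "bifuse_contour")
}

#' Create an IVUS frame
#'
#' @param frame_index Integer index (pullback order, distal to proximal).
#' @param contours List of [contour()] objects.
#' @param catheter_point Transducer center in image mm (usually `c(0, 0)`).
#' @param gated Logical: end-diastolic (ECG-gated) frame.
#' @return A `bifuse_frame` object.
#' @export
ivus_frame <- function(frame_index, contours = list(), catheter_point = c(0, 0),
                       gated = TRUE) {
  labels <- vapply(contours, function(ct) ct$label, character(1))
  if (sum(labels == "lumen") > 1L) {
    stop(sprintf("frame %d: more than one lumen contour", frame_index))
  }
  structure(
    list(frame_index = as.integer(frame_index),
         catheter_point = as.numeric(catheter_point),
         contours = contours, gated = isTRUE(gated)),
    class = "bifuse_frame")
}

#' Extract the first contour with a given label from a frame
#' @param frame An [ivus_frame()].
#' @param label Contour label.
#' @return A [contour()] or `NULL`.
#' @export
frame_contour <- function(frame, label) {
  for (ct in frame$contours) if (ct$label == label) return(ct)
  NULL
}

#' Create a pullback
#'
#' @param branch `"MV"` or `"SB"`.
#' @param frames List of [ivus_frame()] objects with strictly increasing
#'   indices, ordered distal to proximal.
#' @param pullback_speed Pullback speed in mm/s (> 0).
#' @param frame_rate Acquisition frame rate in frames/s (> 0).
#' @param carina_frame Frame index carrying the carina annotation.
#' @param carina_direction In-plane angle (degrees, from the frame x axis,
#'   counter-clockwise) pointing toward the other branch at the carina frame.
#' @return A `bifuse_pullback` object.
#' @export
pullback <- function(branch, frames, pullback_speed, frame_rate,
                     carina_frame = NA_integer_, carina_direction = NA_real_) {
  branch <- match.arg(branch, c("MV", "SB"))
  if (!(pullback_speed > 0)) stop("pullback_speed must be > 0")
  if (!(frame_rate > 0)) stop("frame_rate must be > 0")
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  if (length(idx) && any(diff(idx) <= 0L)) {
    stop("frame indices must be strictly increasing")
  }
  if (!is.na(carina_frame) && !(carina_frame %in% idx)) {
    stop(sprintf("carina_frame %d is not among the pullback frames", carina_frame))
  }
  structure(
    list(branch = branch, frames = frames,
         pullback_speed = as.numeric(pullback_speed),
         frame_rate = as.numeric(frame_rate),
         carina_frame = as.integer(carina_frame),
         carina_direction = as.numeric(carina_direction)),
    class = "bifuse_pullback")
}

#' @export
print.bifuse_pullback <- function(x, ...) {
  n <- length(x$frames)
  ng <- sum(vapply(x$frames, function(f) f$gated, logical(1)))
  cat(sprintf("<bifuse_pullback> %s: %d frames (%d gated), %.3g mm/s @ %.3g fps, carina frame %s\n",
              x$branch, n, ng, x$pullback_speed, x$frame_rate,
              ifelse(is.na(x$carina_frame), "-", x$carina_frame)))
  invisible(x)
}

#' Read a contour-stack JSON file into a pullback
#'
#' Schema (top level): `branch`, `pullback_speed_mm_s`, `frame_rate_fps`,
#' `carina_frame`, `carina_direction_deg`, `frames` — each frame has
#' `frame_index`, `gated`, `catheter_point_mm` and a list of `contours` with
#' `label`, `component_id`, `points_mm`.
#'
#' @param path Path to the JSON file.
#' @return A [pullback()] with all contour invariants enforced.
#' @export
read_contour_stack <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  need <- c("branch", "pullback_speed_mm_s", "frame_rate_fps", "frames")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("contour stack parse error: missing field(s) ", paste(miss, collapse = ", "))
  frames <- lapply(raw$frames, function(fr) {
    fmiss <- setdiff(c("frame_index", "catheter_point_mm"), names(fr))
    if (length(fmiss)) stop("contour stack parse error: frame missing field(s) ",
                            paste(fmiss, collapse = ", "))
    cts <- lapply(fr$contours, function(ct) {
      cmiss <- setdiff(c("label", "points_mm"), names(ct))
      if (length(cmiss)) stop("contour stack parse error: contour missing field(s) ",
                              paste(cmiss, collapse = ", "))
      pts <- ct$points_mm
      if (is.list(pts)) pts <- do.call(rbind, pts)
      contour(fr$frame_index, ct$label, pts,
              component_id = if (is.null(ct$component_id)) 1L else ct$component_id)
    })
    ivus_frame(fr$frame_index, cts, catheter_point = fr$catheter_point_mm,
               gated = if (is.null(fr$gated)) TRUE else fr$gated)
  })
  pullback(raw$branch, frames, raw$pullback_speed_mm_s, raw$frame_rate_fps,
           carina_frame = if (is.null(raw$carina_frame)) NA_integer_ else raw$carina_frame,
           carina_direction = if (is.null(raw$carina_direction_deg)) NA_real_ else raw$carina_direction_deg)
}

#' Write a pullback to contour-stack JSON
#' @param p A [pullback()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contour_stack <- function(p, path) {
  stopifnot(inherits(p, "bifuse_pullback"))
  obj <- list(
    branch = p$branch,
    pullback_speed_mm_s = p$pullback_speed,
    frame_rate_fps = p$frame_rate,
    carina_frame = p$carina_frame,
    carina_direction_deg = p$carina_direction,
    frames = lapply(p$frames, function(fr) {
      list(frame_index = fr$frame_index,
           gated = fr$gated,
           catheter_point_mm = fr$catheter_point,
           contours = lapply(fr$contours, function(ct) {
             list(label = ct$label, component_id = ct$component_id,
                  points_mm = unname(ct$points))
           }))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
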