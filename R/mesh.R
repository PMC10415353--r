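# Triangle surface meshes: vertices (n x 3 mm), triangles (m x 3, 1-based,
# counter-clockwise seen from outside).

#' Create a triangle surface mesh
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param label Semantic tag (e.g. `"lumen"`, `"eem"`, `"calcium"`).
#' @return A `bifuse_mesh` object.
#' @export
surface_mesh <- function(vertices, triangles, label = "surface") {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(vertices) <- "double"
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  if (ncol(triangles) != 3L) stop("triangles must be m x 3")
  if (nrow(triangles) && (min(triangles) < 1L || max(triangles) > nrow(vertices))) {
    stop("triangle indices out of range")
  }
  structure(list(vertices = vertices, triangles = triangles, label = label),
            class = "bifuse_mesh")
}

#' @export
print.bifuse_mesh <- function(x, ...) {
  cat(sprintf("<bifuse_mesh> %s: %d vertices, %d triangles, volume %.3f mm^3\n",
              x$label, nrow(x$vertices), nrow(x$triangles), mesh_volume(x)))
  invisible(x)
}

#' Is a mesh watertight and consistently oriented?
#'
#' Every directed edge must appear exactly once and its reverse exactly once.
#'
#' @param mesh A [surface_mesh()].
#' @return Logical.
#' @export
mesh_is_watertight <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0L) return(FALSE)
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  if (any(e[, 1] == e[, 2])) return(FALSE) # degenerate edge
  key <- paste(e[, 1], e[, 2])
  rkey <- paste(e[, 2], e[, 1])
  if (anyDuplicated(key)) return(FALSE)
  all(rkey %in% key)
}

#' Signed enclosed volume of a closed mesh (divergence theorem)
#' @param mesh A [surface_mesh()].
#' @return Volume in mm^3 (positive when outward-oriented).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  if (nrow(tr) == 0L) return(0)
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  cc <- v[tr[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Flip orientation if the signed volume is negative
#' @param mesh A [surface_mesh()].
#' @return Mesh with outward-pointing normals.
#' @export
mesh_orient_outward <- function(mesh) {
  if (mesh_volume(mesh) < 0) mesh$triangles <- mesh$triangles[, c(1, 3, 2)]
  mesh
}

#' Write a mesh to STL (binary) or PLY (ASCII)
#'
#' Non-watertight meshes are written with a warning.
#'
#' @param mesh A [surface_mesh()].
#' @param path Output file path.
#' @param format `"stl"` or `"ply"`; default from the file extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("stl", "ply")) stop("cannot infer mesh format from extension: ", path)
  }
  if (nrow(mesh$triangles) == 0L) stop("refusing to write an empty mesh")
  if (!mesh_is_watertight(mesh)) warning("mesh '", mesh$label, "' is not watertight; writing anyway")
  v <- mesh$vertices; tr <- mesh$triangles
  if (format == "stl") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", paste("bifuse", mesh$label)))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(tr)), con, size = 4, endian = "little")
    a <- v[tr[, 1], , drop = FALSE]; b <- v[tr[, 2], , drop = FALSE]; cc <- v[tr[, 3], , drop = FALSE]
    e1 <- b - a; e2 <- cc - a
    n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    nn <- sqrt(rowSums(n^2)); nn[nn == 0] <- 1
    n <- n / nn
    block <- t(cbind(n, a, b, cc)) # 12 floats per facet
    for (i in seq_len(nrow(tr))) {
      writeBin(as.numeric(block[, i]), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("comment bifuse", mesh$label),
                 paste("element vertex", nrow(v)),
                 "property double x", "property double y", "property double z",
                 paste("element face", nrow(tr)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L), con)
  }
  invisible(path)
}

#' Read an STL (binary) or ASCII PLY mesh
#' @param path File path.
#' @param label Label to attach to the mesh.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path, label = "surface") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    verts <- matrix(0, 3 * nf, 3)
    for (i in seq_len(nf)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      verts[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
    # merge duplicate vertices
    key <- apply(round(verts, 9), 1, paste, collapse = ",")
    uid <- match(key, unique(key))
    v <- verts[!duplicated(key), , drop = FALSE]
    tr <- matrix(uid, ncol = 3, byrow = TRUE)
    surface_mesh(v, tr, label)
  } else if (ext == "ply") {
    lines <- readLines(path)
    endh <- which(lines == "end_header")[1]
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
    body <- lines[(endh + 1):length(lines)]
    v <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                               function(x) as.numeric(x[1:3])))
    f <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                               function(x) as.integer(x[2:4]) + 1L))
    surface_mesh(v, f, label)
  } else {
    stop("unsupported mesh format: ", path)
  }
}

# --- plane slicing ---------------------------------------------------------

# Intersect a mesh with the plane through `origin` with unit normal `normal`.
# Returns a list of closed 3D loops (k x 3 matrices), chained through shared
# triangle edges so the result is exact for watertight meshes. Thin wrapper
# over the compiled kernel; the R implementation below is kept as a reference
# oracle for tests.
slice_mesh_plane <- function(mesh, origin, normal) {
  out <- cpp_slice_mesh(mesh$vertices, mesh$triangles,
                        as.numeric(origin), as.numeric(normal))
  Filter(function(lp) nrow(lp) >= 3L, out)
}

slice_mesh_plane_r <- function(mesh, origin, normal) {
  v <- mesh$vertices; tr <- mesh$triangles
  d <- as.numeric((v - matrix(origin, nrow(v), 3, byrow = TRUE)) %*% normal)
  # perturb exact-zero vertices deterministically to avoid degenerate crossings
  z <- abs(d) < 1e-12
  if (any(z)) d[z] <- 1e-12
  s1 <- d[tr[, 1]]; s2 <- d[tr[, 2]]; s3 <- d[tr[, 3]]
  cross_tri <- !((s1 > 0 & s2 > 0 & s3 > 0) | (s1 < 0 & s2 < 0 & s3 < 0))
  idx <- which(cross_tri)
  if (!length(idx)) return(list())

  edge_key <- function(a, b) ifelse(a < b, paste(a, b), paste(b, a))
  segs_from <- character(0); segs_to <- character(0)
  pts_env <- new.env(parent = emptyenv())
  seg_a <- c(); seg_b <- c()
  get_pt <- function(a, b) {
    k <- edge_key(a, b)
    if (is.null(pts_env[[k]])) {
      t <- d[a] / (d[a] - d[b])
      pts_env[[k]] <- v[a, ] + t * (v[b, ] - v[a, ])
    }
    k
  }
  for (f in idx) {
    vv <- tr[f, ]
    ss <- d[vv]
    pos <- vv[ss > 0]; neg <- vv[ss < 0]
    if (length(pos) == 0L || length(neg) == 0L) next
    if (length(pos) == 1L) {
      a <- pos[1]
      k1 <- get_pt(a, neg[1]); k2 <- get_pt(a, neg[2])
    } else {
      a <- neg[1]
      k1 <- get_pt(a, pos[1]); k2 <- get_pt(a, pos[2])
    }
    seg_a <- c(seg_a, k1); seg_b <- c(seg_b, k2)
  }
  if (!length(seg_a)) return(list())

  # chain segments into loops via shared edge keys
  used <- rep(FALSE, length(seg_a))
  loops <- list()
  lookup <- new.env(parent = emptyenv())
  addl <- function(k, i) lookup[[k]] <- c(lookup[[k]], i)
  for (i in seq_along(seg_a)) { addl(seg_a[i], i); addl(seg_b[i], i) }
  for (start in seq_along(seg_a)) {
    if (used[start]) next
    used[start] <- TRUE
    chain <- c(seg_a[start], seg_b[start])
    repeat {
      tailk <- chain[length(chain)]
      nxt <- NULL
      for (i in lookup[[tailk]]) {
        if (!used[i]) { nxt <- i; break }
      }
      if (is.null(nxt)) break
      used[nxt] <- TRUE
      nk <- if (seg_a[nxt] == tailk) seg_b[nxt] else seg_a[nxt]
      if (nk == chain[1]) break
      chain <- c(chain, nk)
    }
    if (length(chain) >= 3L) {
      loop <- do.call(rbind, lapply(chain, function(k) pts_env[[k]]))
      loops[[length(loops) + 1L]] <- loop
    }
  }
  loops
}

# Express 3D planar loop points in the 2D basis (u, v) about `origin`.
loop_to_2d <- function(loop, origin, u, v) {
  rel <- sweep(loop, 2, origin)
  cbind(as.numeric(rel %*% u), as.numeric(rel %*% v))
}

#' Mean symmetric surface distance between two meshes
#'
#' Samples points on each mesh's triangles (area-weighted barycenters of a
#' subdivision) and averages point-to-surface distances in both directions.
#'
#' @param a,b [surface_mesh()] objects.
#' @param n_samples Approximate number of samples per direction.
#' @param clip_planes Optional list of `list(origin, normal)` half-spaces;
#'   samples with `(p - origin) . normal < 0` are ignored on both meshes
#'   (used to restrict the comparison to a common coverage window, e.g.
#'   excluding pullback end caps).
#' @return Mean symmetric distance in mm.
#' @export
mean_surface_distance <- function(a, b, n_samples = 4000L, clip_planes = NULL) {
  sample_surface <- function(mesh, n) {
    v <- mesh$vertices; tr <- mesh$triangles
    p1 <- v[tr[, 1], , drop = FALSE]; p2 <- v[tr[, 2], , drop = FALSE]; p3 <- v[tr[, 3], , drop = FALSE]
    cen <- (p1 + p2 + p3) / 3
    e1 <- p2 - p1; e2 <- p3 - p1
    n3 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    w <- sqrt(rowSums(n3^2)) / 2
    if (nrow(cen) > n) {
      keep <- seq(1L, nrow(cen), length.out = n)
      cen <- cen[keep, , drop = FALSE]; w <- w[keep]
    }
    list(p = cen, w = w)
  }
  clip <- function(s) {
    if (is.null(clip_planes)) return(s)
    keep <- rep(TRUE, nrow(s$p))
    for (pl in clip_planes) {
      keep <- keep & (sweep(s$p, 2, pl$origin) %*% pl$normal >= 0)
    }
    list(p = s$p[keep, , drop = FALSE], w = s$w[keep])
  }
  sa <- clip(sample_surface(a, n_samples))
  sb <- clip(sample_surface(b, n_samples))
  da <- cpp_point_mesh_distance(sa$p, b$vertices, b$triangles)
  db <- cpp_point_mesh_distance(sb$p, a$vertices, a$triangles)
  (sum(da * sa$w) / sum(sa$w) + sum(db * sb$w) / sum(sb$w)) / 2
}
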