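#' Triangulated rectum surface mesh
#'
#' @param vertices N x 3 numeric matrix, mm.
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param vertex_dose optional length-N numeric, Gy.
#' @param vertex_slice optional length-N integer slice index.
#' @param n_ring optional points-per-slice ring count for slice-structured
#'   tube meshes (set by [contours_to_mesh]).
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, vertex_dose = NULL,
                         vertex_slice = NULL, n_ring = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) stopf("vertices must be N x 3")
  if (ncol(faces) != 3) stopf("faces must be M x 3")
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices))) {
    stopf("faces reference invalid vertex indices")
  }
  if (!is.null(vertex_dose)) {
    vertex_dose <- as.numeric(vertex_dose)
    if (length(vertex_dose) != nrow(vertices)) {
      stopf("vertex_dose length %d != %d vertices",
            length(vertex_dose), nrow(vertices))
    }
  }
  if (!is.null(vertex_slice)) {
    vertex_slice <- as.integer(vertex_slice)
    if (length(vertex_slice) != nrow(vertices)) {
      stopf("vertex_slice length mismatch")
    }
  }
  structure(list(vertices = vertices, faces = faces,
                 vertex_dose = vertex_dose, vertex_slice = vertex_slice,
                 n_ring = n_ring),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$vertex_dose)) ", with per-vertex dose" else ""))
  invisible(x)
}

#' Build a tube mesh from stacked slice contours
#'
#' Adjacent contours are stitched by corresponding-point laddering: ring `i`
#' vertex `j` is joined to ring `i+1` vertex `j`, each quad split into two
#' triangles. With `n_points = NULL` (default) the raw contour vertices are
#' used when every slice has the same vertex count; otherwise (or when counts
#' differ) each contour is resampled by arc length to `n_points` points
#' starting at the posterior cut. The result is an open tube with two
#' boundary loops; per-vertex slice indices are recorded.
#'
#' @param stack a [contour_stack] with at least 2 slices.
#' @param n_points optional fixed ring vertex count (arc-length resampling).
#' @return a [surface_mesh].
#' @export
contours_to_mesh <- function(stack, n_points = NULL) {
  stopifnot(inherits(stack, "contour_stack"))
  ns <- length(stack$slices)
  if (ns < 2) stopf("contours_to_mesh needs at least 2 slices")
  counts <- vapply(stack$slices, function(s) nrow(s$xy), integer(1))
  for (i in seq_len(ns)) {
    if (abs(polygon_signed_area(stack$slices[[i]]$xy)) < 1e-9) {
      stopf("slice %d: degenerate polygon (zero area)", i)
    }
  }
  if (is.null(n_points)) {
    if (length(unique(counts)) == 1) {
      rings <- lapply(stack$slices, function(s) s$xy)
      n <- counts[1]
    } else {
      n <- 128L
      rings <- lapply(stack$slices, function(s) resample_polygon(s$xy, n))
    }
  } else {
    n <- as.integer(n_points)
    if (n < 3) stopf("n_points must be >= 3")
    rings <- lapply(stack$slices, function(s) resample_polygon(s$xy, n))
  }
  z <- contour_z(stack)
  vertices <- do.call(rbind, lapply(seq_len(ns), function(i) {
    cbind(rings[[i]], z[i])
  }))
  vertex_slice <- rep(seq_len(ns), each = n)
  faces <- matrix(0L, 2L * n * (ns - 1L), 3L)
  r <- 0L
  for (i in seq_len(ns - 1L)) {
    base0 <- (i - 1L) * n
    base1 <- i * n
    j <- seq_len(n)
    jn <- c(2:n, 1L)
    # quad (j, jn) x (ring i, ring i+1), consistent outward winding
    faces[r + j, ] <- cbind(base0 + j, base0 + jn, base1 + j)
    faces[r + n + j, ] <- cbind(base0 + jn, base1 + jn, base1 + j)
    r <- r + 2L * n
  }
  surface_mesh(vertices, faces, vertex_slice = vertex_slice, n_ring = n)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices
  a <- v[mesh$faces[, 1], , drop = FALSE]
  b <- v[mesh$faces[, 2], , drop = FALSE]
  c3 <- v[mesh$faces[, 3], , drop = FALSE]
  u <- b - a
  w <- c3 - a
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx ^ 2 + cy ^ 2 + cz ^ 2)
}

#' Total mesh surface area in mm^2
#' @param mesh a [surface_mesh].
#' @export
surface_area <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  sum(triangle_areas(mesh))
}

#' Per-vertex area weights in mm^2
#'
#' Each triangle contributes one third of its area to each of its vertices,
#' so the weights partition the surface: `sum(vertex_areas(m)) ==
#' surface_area(m)`.
#'
#' @param mesh a [surface_mesh].
#' @export
vertex_areas <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ta <- triangle_areas(mesh) / 3
  va <- numeric(nrow(mesh$vertices))
  for (k in 1:3) {
    acc <- tapply(ta, mesh$faces[, k], sum)
    idx <- as.integer(names(acc))
    va[idx] <- va[idx] + as.numeric(acc)
  }
  va
}

#' 3D dose grid in Gy
#'
#' Voxel centres are at `origin + (index - 1) * spacing` per axis.
#'
#' @param values 3D numeric array, Gy, all values `>= 0`.
#' @param origin length-3 numeric, mm (centre of voxel `[1,1,1]`).
#' @param spacing length-3 positive numeric, mm per axis.
#' @param is_eqd2 whether values are already EQD2-converted.
#' @export
dose_grid <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                      is_eqd2 = FALSE) {
  values <- as.array(values)
  if (length(dim(values)) != 3) stopf("dose grid values must be a 3D array")
  if (any(values < 0)) stopf("dose values must be >= 0")
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stopf("grid spacing must be > 0")
  structure(list(values = values, origin = rep_len(as.numeric(origin), 3),
                 spacing = spacing, is_eqd2 = isTRUE(is_eqd2)),
            class = "dose_grid")
}

#' Sample a dose grid at mesh vertices by trilinear interpolation
#'
#' Vertices outside the grid bounds are clamped to the boundary with a
#' warning.
#'
#' @param mesh a [surface_mesh].
#' @param grid a [dose_grid].
#' @return per-vertex dose in Gy.
#' @export
sample_dose <- function(mesh, grid) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(grid, "dose_grid"))
  dims <- dim(grid$values)
  # fractional 1-based voxel coordinates
  fc <- sweep(sweep(mesh$vertices, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
  oob <- FALSE
  for (k in 1:3) {
    lo <- fc[, k] < 1; hi <- fc[, k] > dims[k]
    if (any(lo | hi)) oob <- TRUE
    fc[lo, k] <- 1
    fc[hi, k] <- dims[k]
  }
  if (oob) warnf("sample_dose: vertices outside grid bounds were clamped")
  dimm <- matrix(dims, nrow(fc), 3, byrow = TRUE)  # avoid column recycling
  i0 <- pmin(pmax(floor(fc), 1), pmax(dimm - 1, 1))
  tfr <- fc - i0
  tfr[, dims == 1] <- 0
  i1 <- pmin(i0 + 1, dimm)
  v <- grid$values
  g <- function(a, b, c3) v[cbind(a, b, c3)]
  tx <- tfr[, 1]; ty <- tfr[, 2]; tz <- tfr[, 3]
  c000 <- g(i0[, 1], i0[, 2], i0[, 3]); c100 <- g(i1[, 1], i0[, 2], i0[, 3])
  c010 <- g(i0[, 1], i1[, 2], i0[, 3]); c110 <- g(i1[, 1], i1[, 2], i0[, 3])
  c001 <- g(i0[, 1], i0[, 2], i1[, 3]); c101 <- g(i1[, 1], i0[, 2], i1[, 3])
  c011 <- g(i0[, 1], i1[, 2], i1[, 3]); c111 <- g(i1[, 1], i1[, 2], i1[, 3])
  c00 <- c000 * (1 - tx) + c100 * tx
  c10 <- c010 * (1 - tx) + c110 * tx
  c01 <- c001 * (1 - tx) + c101 * tx
  c11 <- c011 * (1 - tx) + c111 * tx
  c0 <- c00 * (1 - ty) + c10 * ty
  c1 <- c01 * (1 - ty) + c11 * ty
  c0 * (1 - tz) + c1 * tz
}

#' Write a mesh as ASCII PLY (per-vertex dose as scalar property `dose`)
#' @param mesh a [surface_mesh].
#' @param path output path.
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  has_dose <- !is.null(mesh$vertex_dose)
  hdr <- c("ply", "format ascii 1.0", sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z")
  if (has_dose) hdr <- c(hdr, "property double dose")
  hdr <- c(hdr, sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  vm <- mesh$vertices
  if (has_dose) vm <- cbind(vm, mesh$vertex_dose)
  writeLines(apply(vm, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
  if (nf > 0) {
    writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  }
  invisible(path)
}

#' Read an ASCII PLY mesh written by [write_ply]
#' @param path input path.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stopf("'%s' is not a PLY file", path)
  end <- match("end_header", lines)
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  props <- sub("^property (double|float) ", "", grep("^property (double|float) ", hdr, value = TRUE))
  body <- lines[(end + 1L):length(lines)]
  vdat <- do.call(rbind, lapply(body[seq_len(nv)], function(ln) {
    as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]])
  }))
  vertices <- vdat[, 1:3, drop = FALSE]
  dose <- if ("dose" %in% props) vdat[, match("dose", props)] else NULL
  faces <- NULL
  if (nf > 0) {
    fdat <- do.call(rbind, lapply(body[nv + seq_len(nf)], function(ln) {
      as.integer(strsplit(trimws(ln), "[[:space:]]+")[[1]])
    }))
    faces <- fdat[, 2:4, drop = FALSE] + 1L
  } else {
    faces <- matrix(integer(0), 0, 3)
  }
  surface_mesh(vertices, faces, vertex_dose = dose)
}

#' Write a mesh as ASCII Wavefront OBJ (geometry only)
#' @param mesh a [surface_mesh].
#' @param path output path.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}
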