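#' Ordered closed slice contours of a rectum segmentation
#'
#' A `contour_stack` holds one closed planar polygon per axial CT slice, in
#' millimetres, ordered inferior to superior. On construction every polygon is
#' normalised to counter-clockwise orientation as seen from superior (+z) and
#' rotated so that its first vertex is the posterior-most point (minimum y,
#' ties broken by minimum x). This gives a deterministic cut line for meshing
#' and flattening.
#'
#' @param slices list of `list(z = <mm>, xy = <n x 2 matrix, mm>)`, z strictly
#'   increasing, each polygon with at least 3 vertices.
#' @param slice_spacing nominal slice spacing in mm; defaults to the median
#'   z-difference.
#' @param validate if `TRUE` (default) check polygon simplicity
#'   (non-self-intersection).
#' @return an object of class `contour_stack`.
#' @export
contour_stack <- function(slices, slice_spacing = NULL, validate = TRUE) {
  if (length(slices) < 1) stopf("contour_stack needs at least one slice")
  z <- vapply(slices, function(s) as.numeric(s$z), numeric(1))
  if (any(!is.finite(z))) stopf("non-finite slice z-position")
  if (length(z) > 1 && any(diff(z) <= 0)) {
    bad <- which(diff(z) <= 0)[1] + 1L
    stopf("slice z-positions must be strictly increasing (slice %d, z = %g)",
          bad, z[bad])
  }
  slices <- lapply(seq_along(slices), function(i) {
    xy <- slices[[i]]$xy
    xy <- as.matrix(xy)
    storage.mode(xy) <- "double"
    if (nrow(xy) < 3) {
      stopf("slice %d: polygon has %d point(s), need >= 3", i, nrow(xy))
    }
    if (ncol(xy) != 2 || any(!is.finite(xy))) {
      stopf("slice %d: polygon must be a finite n x 2 matrix", i)
    }
    # drop an explicitly repeated closing vertex
    if (all(abs(xy[1, ] - xy[nrow(xy), ]) < 1e-12) && nrow(xy) > 3) {
      xy <- xy[-nrow(xy), , drop = FALSE]
    }
    if (validate && !polygon_is_simple(xy)) {
      stopf("slice %d: polygon is self-intersecting", i)
    }
    xy <- normalize_polygon(xy)
    list(z = z[i], xy = xy)
  })
  if (is.null(slice_spacing)) {
    slice_spacing <- if (length(z) > 1) stats::median(diff(z)) else 2.5
  }
  obj <- structure(list(slices = slices, slice_spacing = slice_spacing),
                   class = "contour_stack")
  len <- contour_length(obj)
  if (length(z) > 1 && (len < 60 || len > 90)) {
    warnf("contour stack length %.1f mm outside the typical 60-90 mm range",
          len)
  }
  obj
}

#' @export
print.contour_stack <- function(x, ...) {
  cat(sprintf("<contour_stack> %d slices, z in [%.2f, %.2f] mm, spacing %.2f mm\n",
              length(x$slices), x$slices[[1]]$z,
              x$slices[[length(x$slices)]]$z, x$slice_spacing))
  invisible(x)
}

#' @export
`==.contour_stack` <- function(e1, e2) {
  isTRUE(all.equal(unclass(e1), unclass(e2), tolerance = 1e-9))
}

#' Superior-inferior extent of a contour stack in mm
#' @param stack a `contour_stack`
#' @export
contour_length <- function(stack) {
  z <- contour_z(stack)
  max(z) - min(z)
}

contour_z <- function(stack) {
  vapply(stack$slices, function(s) s$z, numeric(1))
}

# Shoelace signed area; > 0 means counter-clockwise viewed from +z.
polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_perimeter <- function(xy) {
  j <- c(seq_len(nrow(xy))[-1], 1L)
  sum(sqrt(rowSums((xy[j, , drop = FALSE] - xy) ^ 2)))
}

# Orient CCW (viewed from superior) and rotate start to posterior-most vertex.
normalize_polygon <- function(xy) {
  if (polygon_signed_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  start <- order(xy[, 2], xy[, 1])[1]
  if (start > 1) {
    idx <- c(start:nrow(xy), seq_len(start - 1L))
    xy <- xy[idx, , drop = FALSE]
  }
  xy
}

# Simplicity test: no two non-adjacent edges intersect. O(n^2), n is small.
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 4) return(TRUE)
  a <- xy
  b <- xy[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1) n - 1L else n
    js <- seq.int(i + 2L, jmax)
    if (length(js) == 0) next
    if (any(segments_intersect(a[i, ], b[i, ], a[js, , drop = FALSE],
                               b[js, , drop = FALSE]))) {
      return(FALSE)
    }
  }
  TRUE
}

# Proper intersection test of segment (p1,p2) against rows of (q1,q2).
segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- (q2[, 1] - q1[, 1]) * (p1[2] - q1[, 2]) -
        (q2[, 2] - q1[, 2]) * (p1[1] - q1[, 1])
  d2 <- (q2[, 1] - q1[, 1]) * (p2[2] - q1[, 2]) -
        (q2[, 2] - q1[, 2]) * (p2[1] - q1[, 1])
  d3 <- (p2[1] - p1[1]) * (q1[, 2] - p1[2]) -
        (p2[2] - p1[2]) * (q1[, 1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (q2[, 2] - p1[2]) -
        (p2[2] - p1[2]) * (q2[, 1] - p1[1])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Read slice contours from the plain-text contour format
#'
#' The format is one block per slice: a line `z <mm>` followed by one `x y`
#' pair per vertex; blocks separated by blank lines; `#` starts a comment.
#' An optional `spacing <mm>` header line fixes the nominal slice spacing.
#'
#' @param path file path.
#' @return a [contour_stack].
#' @export
read_contours <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[!startsWith(lines, "#")]
  spacing <- NULL
  slices <- list()
  cur_z <- NULL
  cur_pts <- NULL
  flush <- function() {
    if (!is.null(cur_z)) {
      if (is.null(cur_pts) || nrow(cur_pts) < 3) {
        stopf("contour file '%s': slice at z = %g has fewer than 3 points",
              path, cur_z)
      }
      slices[[length(slices) + 1L]] <<- list(z = cur_z, xy = cur_pts)
    }
    cur_z <<- NULL; cur_pts <<- NULL
  }
  for (ln in lines) {
    if (ln == "") { flush(); next }
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tok[1] == "spacing") {
      spacing <- as.numeric(tok[2])
    } else if (tok[1] == "z") {
      flush()
      cur_z <- as.numeric(tok[2])
      if (!is.finite(cur_z)) stopf("contour file '%s': bad z line '%s'", path, ln)
      cur_pts <- matrix(numeric(0), 0, 2)
    } else {
      v <- suppressWarnings(as.numeric(tok))
      if (length(v) != 2 || any(!is.finite(v))) {
        stopf("contour file '%s': bad point line '%s'", path, ln)
      }
      if (is.null(cur_z)) stopf("contour file '%s': point before any z line", path)
      cur_pts <- rbind(cur_pts, v)
    }
  }
  flush()
  if (length(slices) == 0) stopf("contour file '%s' contains no slices", path)
  contour_stack(slices, slice_spacing = spacing)
}

#' Write slice contours to the plain-text contour format
#'
#' @param stack a [contour_stack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(stack, path) {
  stopifnot(inherits(stack, "contour_stack"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("spacing %.9g", stack$slice_spacing), con)
  for (s in stack$slices) {
    writeLines(sprintf("z %.9g", s$z), con)
    writeLines(sprintf("%.9g %.9g", s$xy[, 1], s$xy[, 2]), con)
    writeLines("", con)
  }
  invisible(path)
}

# Resample a closed polygon to n points equally spaced in arc length,
# starting at the (already normalised) first vertex, preserving orientation.
resample_polygon <- function(xy, n) {
  m <- nrow(xy)
  closed <- rbind(xy, xy[1, ])
  seg <- sqrt(rowSums(diff(closed) ^ 2))
  cum <- c(0, cumsum(seg))
  total <- cum[m + 1]
  if (total <= 0) stopf("degenerate polygon: zero perimeter")
  s <- seq(0, total, length.out = n + 1)[seq_len(n)]
  x <- stats::approx(cum, closed[, 1], xout = s, ties = "ordered")$y
  y <- stats::approx(cum, closed[, 2], xout = s, ties = "ordered")$y
  cbind(x, y)
}
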