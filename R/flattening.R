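#' Construct a rectum surface dose map object
#'
#' Low-level constructor used by [flatten] and by tests building toy maps.
#' `row_height` gives the physical height each row's pixels represent; it
#' defaults to a constant `row_spacing` (maps produced by [flatten] use
#' half-height boundary rows so that [rsdm_area] matches the mesh's
#' trapezoidal lateral area).
#'
#' @param dose numeric matrix, Gy (row 1 = inferior).
#' @param mask logical validity matrix, same shape.
#' @param row_spacing,col_spacing pixel spacings, mm.
#' @param row_circumference per-row physical circumference, mm; defaults to
#'   the per-row valid arc length.
#' @param row_height per-row pixel heights, mm.
#' @param patient_id optional identifier.
#' @export
rsdm <- function(dose, mask = NULL, row_spacing = 1, col_spacing = 1,
                 row_circumference = NULL, row_height = NULL,
                 patient_id = NULL) {
  dose <- as.matrix(dose)
  if (is.null(mask)) mask <- !is.na(dose)
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(dose))) stopf("dose / mask shape mismatch")
  if (any(!is.finite(dose[mask]))) stopf("dose must be finite where mask is TRUE")
  if (is.null(row_circumference)) {
    row_circumference <- rowSums(mask) * col_spacing
  }
  if (is.null(row_height)) row_height <- rep(row_spacing, nrow(dose))
  structure(list(dose = dose, mask = mask, row_spacing = row_spacing,
                 col_spacing = col_spacing,
                 row_circumference = row_circumference,
                 row_height = rep_len(row_height, nrow(dose)),
                 patient_id = patient_id),
            class = "rsdm")
}

#' Flatten cumulative surface dose into a 2D rectum surface dose map
#'
#' Each slice ring is cut at its posterior-most point and unrolled
#' counter-clockwise (viewed from superior) by arc length into one row of the
#' map. Physical length is preserved in both directions: row spacing is the
#' slice spacing, column spacing is `col_spacing` mm along the circumference.
#' Rows are left-aligned at the cut; columns beyond a row's circumference are
#' masked out, so map width is patient-specific (the maximum circumference).
#' Dose is linearly interpolated along each ring.
#'
#' @param cum a `cumulative_surface_dose` on a slice-structured tube mesh
#'   (as built by [contours_to_mesh]).
#' @param contours optional [contour_stack] used to cross-check slice
#'   z-positions.
#' @param col_spacing circumferential pixel size in mm (default 1).
#' @param patient_id optional identifier carried on the map.
#' @return an object of class `rsdm` with fields `dose`, `mask`,
#'   `row_spacing`, `col_spacing`, `row_circumference`, `patient_id`. Row 1
#'   is the inferior-most slice.
#' @export
flatten <- function(cum, contours = NULL, col_spacing = 1, patient_id = NULL) {
  stopifnot(inherits(cum, "cumulative_surface_dose"))
  mesh <- cum$mesh
  if (is.null(mesh$n_ring) || is.null(mesh$vertex_slice)) {
    stopf("flatten requires a slice-structured tube mesh")
  }
  n <- mesh$n_ring
  ns <- nrow(mesh$vertices) / n
  if (ns != round(ns)) stopf("inconsistent ring structure")
  ns <- as.integer(ns)
  zs <- mesh$vertices[seq(1, nrow(mesh$vertices), by = n), 3]
  if (!is.null(contours)) {
    zc <- contour_z(contours)
    if (length(zc) != ns || max(abs(zc - zs)) > 1e-6) {
      stopf("contours do not match the mesh slice structure")
    }
  }
  row_spacing <- if (ns > 1) stats::median(diff(zs)) else 2.5
  circ <- numeric(ns)
  ring_s <- vector("list", ns)
  for (i in seq_len(ns)) {
    idx <- ((i - 1L) * n + 1L):(i * n)
    ring <- mesh$vertices[idx, 1:2, drop = FALSE]
    seg <- sqrt(rowSums((ring[c(2:n, 1), , drop = FALSE] - ring) ^ 2))
    circ[i] <- sum(seg)
    ring_s[[i]] <- c(0, cumsum(seg))   # arc position of vertex j, plus wrap
  }
  ncol_map <- max(1L, ceiling(max(circ) / col_spacing))
  dose <- matrix(NA_real_, ns, ncol_map)
  mask <- matrix(FALSE, ns, ncol_map)
  s_cols <- (seq_len(ncol_map) - 1L) * col_spacing
  for (i in seq_len(ns)) {
    idx <- ((i - 1L) * n + 1L):(i * n)
    dvec <- cum$dose[idx]
    if (any(!is.finite(dvec))) stopf("slice %d: missing dose", i)
    svec <- ring_s[[i]]
    valid <- s_cols < circ[i] - 1e-9
    nvalid <- max(1L, sum(valid))
    # wrap: repeat first vertex at s = circumference for interpolation
    dose[i, seq_len(nvalid)] <- stats::approx(svec, c(dvec, dvec[1]),
                                              xout = s_cols[seq_len(nvalid)],
                                              ties = "ordered")$y
    mask[i, seq_len(nvalid)] <- TRUE
  }
  # boundary slices carry half-height pixels so the map area integrates to
  # the trapezoidal lateral area of the tube
  heights <- rep(row_spacing, ns)
  if (ns > 1) heights[c(1L, ns)] <- row_spacing / 2
  rsdm(dose, mask, row_spacing = row_spacing, col_spacing = col_spacing,
       row_circumference = circ, row_height = heights,
       patient_id = patient_id)
}

#' @export
print.rsdm <- function(x, ...) {
  cat(sprintf("<rsdm> %d x %d (%.2f x %.2f mm px), %d valid px, dose [%.1f, %.1f] Gy\n",
              nrow(x$dose), ncol(x$dose), x$row_spacing, x$col_spacing,
              sum(x$mask), min(x$dose[x$mask]), max(x$dose[x$mask])))
  invisible(x)
}

#' Physical area of the valid region of an RSDM in mm^2
#'
#' Valid pixel counts per row weighted by the per-row pixel heights; for
#' maps with constant row heights this is `count(valid) * row_spacing *
#' col_spacing`.
#'
#' @param map an `rsdm`.
#' @export
rsdm_area <- function(map) {
  stopifnot(inherits(map, "rsdm"))
  sum(rowSums(map$mask) * map$row_height) * map$col_spacing
}

#' Write / read an RSDM as paired CSV (dose, mask) plus JSON header
#'
#' `path` is a stem: `<stem>_dose.csv`, `<stem>_mask.csv`, `<stem>.json`.
#' @param map an `rsdm`.
#' @param path file stem.
#' @export
write_rsdm <- function(map, path) {
  stopifnot(inherits(map, "rsdm"))
  utils::write.table(map$dose, paste0(path, "_dose.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(map$mask * 1L, paste0(path, "_mask.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(row_spacing = map$row_spacing,
                            col_spacing = map$col_spacing,
                            row_circumference = map$row_circumference,
                            row_height = map$row_height,
                            patient_id = map$patient_id),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rsdm
#' @export
read_rsdm <- function(path) {
  dose <- as.matrix(utils::read.table(paste0(path, "_dose.csv"), sep = ","))
  mask <- as.matrix(utils::read.table(paste0(path, "_mask.csv"), sep = ",")) == 1
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dimnames(dose) <- NULL
  dimnames(mask) <- NULL
  rsdm(dose, mask, row_spacing = hdr$row_spacing,
       col_spacing = hdr$col_spacing,
       row_circumference = hdr$row_circumference,
       row_height = hdr$row_height, patient_id = hdr$patient_id)
}
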