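#' Linear-quadratic EQD2 parameters
#'
#' @param alpha_beta tissue alpha/beta ratio in Gy (rectum default 3 Gy).
#' @export
eqd2_params <- function(alpha_beta = 3) {
  if (!is.numeric(alpha_beta) || alpha_beta <= 0) {
    stopf("alpha_beta must be > 0")
  }
  structure(list(alpha_beta = alpha_beta, reference_fraction_size = 2),
            class = "eqd2_params")
}

#' Equieffective dose in 2 Gy fractions (linear-quadratic model)
#'
#' `EQD2 = D * (d + alpha/beta) / (2 + alpha/beta)` with total physical dose
#' `D` delivered in fractions of size `d`. `D` and `d` may be vectors
#' (recycled); `d = 2` Gy is the fixed point.
#'
#' @param D total physical dose, Gy (`>= 0`).
#' @param d dose per fraction, Gy (`> 0`).
#' @param params an [eqd2_params].
#' @return EQD2 dose in Gy.
#' @export
eqd2 <- function(D, d, params = eqd2_params()) {
  stopifnot(inherits(params, "eqd2_params"))
  if (any(d <= 0)) stopf("dose per fraction d must be > 0")
  if (any(D < 0)) stopf("physical dose D must be >= 0")
  ab <- params$alpha_beta
  D * (d + ab) / (2 + ab)
}

#' Treatment fraction record
#'
#' @param phase `"BT"` or `"EBRT"`.
#' @param fraction_index 1-based index within the phase.
#' @param geometry a [contour_stack] for this fraction.
#' @param mesh the [surface_mesh] built from `geometry`.
#' @param dose per-vertex physical dose for this single fraction, Gy
#'   (required for BT fractions), or a [dose_grid].
#' @param d prescribed dose per fraction, Gy.
#' @param n_fractions number of fractions in the phase.
#' @export
fraction_record <- function(phase = c("BT", "EBRT"), fraction_index,
                            geometry = NULL, mesh = NULL, dose = NULL,
                            d, n_fractions) {
  phase <- match.arg(phase)
  if (d <= 0) stopf("dose per fraction must be > 0")
  if (phase == "BT" && is.null(dose)) {
    stopf("BT fraction %d: dose is required", fraction_index)
  }
  if (!is.null(mesh) && inherits(dose, "dose_grid")) {
    dose <- sample_dose(mesh, dose)
  }
  structure(list(phase = phase, fraction_index = as.integer(fraction_index),
                 geometry = geometry, mesh = mesh, dose = dose, d = d,
                 n_fractions = as.integer(n_fractions)),
            class = "fraction_record")
}

new_cumulative_dose <- function(mesh, dose, provenance) {
  structure(list(mesh = mesh, dose = as.numeric(dose),
                 provenance = provenance),
            class = "cumulative_surface_dose")
}

#' @export
print.cumulative_surface_dose <- function(x, ...) {
  cat(sprintf("<cumulative_surface_dose> %d vertices, EQD2 range [%.2f, %.2f] Gy, %d fraction(s)\n",
              length(x$dose), min(x$dose), max(x$dose), length(x$provenance)))
  invisible(x)
}

# Per-fraction EQD2 of a single delivered fraction: D = d = the vertex's own
# fractional dose (the LQ conversion uses the locally received fraction size).
fraction_eqd2 <- function(dose, params) {
  out <- numeric(length(dose))
  pos <- dose > 0
  out[pos] <- eqd2(dose[pos], dose[pos], params)
  out
}

#' Deformably accumulate fractional BT surface dose in EQD2
#'
#' The first BT fraction is the reference; every other fraction's surface is
#' mapped onto the reference by its deformation vector field (DVF, defined on
#' the moving fraction's vertices and pointing toward the reference). Each
#' fraction's per-vertex physical dose is converted to EQD2 using the vertex's
#' own fractional dose as the fraction size, then pulled onto reference
#' vertices via nearest warped vertex and summed.
#'
#' @param reference the reference [fraction_record] (first BT fraction).
#' @param others list of remaining BT [fraction_record]s.
#' @param dvfs list of [dvf] objects, one per entry of `others`, each defined
#'   on that fraction's vertices and mapping toward the reference.
#' @param params an [eqd2_params].
#' @return a `cumulative_surface_dose` on the reference mesh.
#' @export
accumulate_bt <- function(reference, others = list(), dvfs = list(),
                          params = eqd2_params()) {
  stopifnot(inherits(reference, "fraction_record"))
  if (length(others) != length(dvfs)) {
    stopf("need one DVF per non-reference fraction (%d fractions, %d DVFs)",
          length(others), length(dvfs))
  }
  ref_mesh <- reference$mesh
  if (is.null(ref_mesh)) stopf("reference fraction has no mesh")
  if (is.null(reference$dose)) stopf("reference fraction has no dose")
  cum <- fraction_eqd2(reference$dose, params)
  prov <- list(list(phase = "BT", fraction_index = reference$fraction_index,
                    deformed = FALSE))
  for (k in seq_along(others)) {
    fr <- others[[k]]
    if (is.null(fr$dose)) stopf("BT fraction %d: missing dose", fr$fraction_index)
    if (is.null(dvfs[[k]])) stopf("BT fraction %d: missing DVF", fr$fraction_index)
    warped <- apply_dvf(fr$mesh, dvfs[[k]])
    fx_eqd2 <- fraction_eqd2(fr$dose, params)
    # pull dose onto each reference vertex from its nearest warped vertex
    nn <- nearest_neighbour(ref_mesh$vertices, warped$vertices)
    cum <- cum + fx_eqd2[nn]
    prov[[length(prov) + 1L]] <- list(phase = "BT",
                                      fraction_index = fr$fraction_index,
                                      deformed = TRUE)
  }
  new_cumulative_dose(ref_mesh, cum, prov)
}

# Index of nearest row of `b` for each row of `a`; chunked to bound memory.
nearest_neighbour <- function(a, b, chunk = 2048L) {
  n <- nrow(a)
  out <- integer(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- cross_dist2(a[s:e, , drop = FALSE], b)
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Add the homogeneous EBRT phase to an accumulated BT dose
#'
#' The EBRT phase is assumed homogeneous over the pelvis, so its EQD2 is a
#' single scalar added to every vertex without deformation.
#'
#' @param cum a `cumulative_surface_dose`.
#' @param ebrt_total total EBRT physical dose, Gy (default 45).
#' @param ebrt_d EBRT dose per fraction, Gy (default 1.8).
#' @param params an [eqd2_params].
#' @export
add_ebrt <- function(cum, ebrt_total = 45, ebrt_d = 1.8,
                     params = eqd2_params()) {
  stopifnot(inherits(cum, "cumulative_surface_dose"))
  add <- if (ebrt_total > 0) eqd2(ebrt_total, ebrt_d, params) else 0
  cum$dose <- cum$dose + add
  cum$provenance[[length(cum$provenance) + 1L]] <-
    list(phase = "EBRT", total = ebrt_total, d = ebrt_d, deformed = FALSE)
  cum
}

#' Static-hotspot-assumption accumulation (no deformation)
#'
#' Per-fraction EQD2 doses are summed vertex-index-wise, assuming hotspots are
#' spatially stationary across fractions. All fractions must share the
#' reference vertex count. This is the baseline behind the conventional
#' SA-D0.1/1/2cc parameters.
#'
#' @param fractions list of BT [fraction_record]s; the first is the reference.
#' @param params an [eqd2_params].
#' @export
static_accumulate <- function(fractions, params = eqd2_params()) {
  if (length(fractions) < 1) stopf("no fractions to accumulate")
  ref <- fractions[[1]]
  nv <- length(ref$dose)
  cum <- numeric(nv)
  prov <- list()
  for (fr in fractions) {
    if (is.null(fr$dose)) stopf("BT fraction %d: missing dose", fr$fraction_index)
    if (length(fr$dose) != nv) {
      stopf("BT fraction %d: vertex count %d != reference %d",
            fr$fraction_index, length(fr$dose), nv)
    }
    cum <- cum + fraction_eqd2(fr$dose, params)
    prov[[length(prov) + 1L]] <- list(phase = "BT",
                                      fraction_index = fr$fraction_index,
                                      deformed = FALSE)
  }
  new_cumulative_dose(ref$mesh, cum, prov)
}
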