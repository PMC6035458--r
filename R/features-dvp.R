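#' Dose-volume parameters Dx-cc from 3D surface dose
#'
#' `Dx` is the minimum dose in the most exposed `x` cm^3 of rectal wall, for
#' `x` in 0.1 and 0.5 to 10 cm^3 in 0.5 cm^3 steps (21 values). The surface
#' is converted to a volume by multiplying per-vertex area by a nominal wall
#' thickness: vertices are sorted by dose descending and `Dx` is the dose at
#' which the cumulative volume first reaches `x`. If the total wall volume is
#' below `x` the minimum dose is returned and the value is flagged in the
#' `"truncated"` attribute.
#'
#' @param vertex_dose per-vertex dose, Gy.
#' @param vertex_areas per-vertex area weights, mm^2 (see [vertex_areas]).
#' @param wall_thickness_mm nominal rectal wall thickness (default 3 mm).
#' @return named numeric vector of 21 values (`D0.1cc` ... `D10cc`).
#' @export
compute_dvps <- function(vertex_dose, vertex_areas, wall_thickness_mm = 3) {
  if (length(vertex_dose) == 0) stopf("compute_dvps: empty mesh")
  if (length(vertex_dose) != length(vertex_areas)) {
    stopf("dose and area vectors differ in length")
  }
  if (wall_thickness_mm <= 0) stopf("wall thickness must be > 0")
  xs <- dvp_volumes()
  ord <- order(vertex_dose, decreasing = TRUE)
  dose <- vertex_dose[ord]
  vol_cc <- cumsum(vertex_areas[ord] * wall_thickness_mm) / 1000
  total <- vol_cc[length(vol_cc)]
  out <- numeric(length(xs))
  trunc <- logical(length(xs))
  for (i in seq_along(xs)) {
    k <- which(vol_cc >= xs[i])[1]
    if (is.na(k)) {
      out[i] <- dose[length(dose)]
      trunc[i] <- TRUE
    } else {
      out[i] <- dose[k]
    }
  }
  if (any(trunc)) {
    warnf("compute_dvps: total wall volume %.2f cc below largest requested x",
          total)
  }
  names(out) <- dvp_names()
  attr(out, "truncated") <- trunc
  out
}

dvp_volumes <- function() c(0.1, seq(0.5, 10, by = 0.5))

dvp_names <- function() {
  xs <- dvp_volumes()
  paste0("D", ifelse(xs %% 1 == 0, sprintf("%d", as.integer(xs)),
                     sprintf("%.1f", xs)), "cc")
}
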