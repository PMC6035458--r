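#' Specification of a synthetic EBRT+BT cohort
#'
#' The generator emulates the structure the pipeline assumes: tubular rectum
#' surfaces 6-9 cm long, smooth inter-fraction non-rigid deformation, steep
#' anterior-wall brachytherapy hotspots at the 6-7 Gy-per-fraction scale, a
#' homogeneous 45 Gy / 25 x 1.8 Gy EBRT phase, and a minority toxicity class
#' whose labels are driven by a planted dose-geometry effect (by default the
#' relative RSDM area above a high EQD2 dose level).
#'
#' @param n_patients cohort size.
#' @param toxicity_prevalence expected positive fraction (default 12/42).
#' @param deformation_amplitude maximum inter-fraction point displacement, mm.
#' @param shape_amplitude amplitude of per-patient shape irregularity
#'   (centerline wobble + radial harmonics), mm; 0 gives perfect elliptical
#'   cylinders.
#' @param source_standoff mean distance of the BT source anterior of the
#'   anterior rectal wall (emulating applicator-to-wall separation), mm.
#' @param source_jitter half-range of the per-patient uniform jitter of the
#'   standoff, mm (per-fraction jitter is a fixed +/- 1.5 mm in every axis).
#' @param hotspot_r0 reference distance at which the BT field equals the
#'   prescription fraction dose, mm.
#' @param falloff_exponent inverse-power falloff exponent of the BT field.
#' @param effect_family feature family carrying the planted effect
#'   (`"area"` = relative RSDM area above `effect_level`; `"null"` disables
#'   the effect for type-I-error checks).
#' @param effect_level EQD2 dose level (Gy) defining the causal feature.
#' @param effect_slope logistic slope per percentage point of the causal
#'   feature (0 under `effect_family = "null"`).
#' @param slice_spacing CT slice spacing, mm.
#' @param n_contour_points contour vertices per slice.
#' @param seed master seed; fully determines the cohort.
#' @export
cohort_spec <- function(n_patients = 42, toxicity_prevalence = 12 / 42,
                        deformation_amplitude = 4, shape_amplitude = 3,
                        source_standoff = 9, source_jitter = 4,
                        hotspot_r0 = 10, falloff_exponent = 2,
                        effect_family = c("area", "null"), effect_level = 65,
                        effect_slope = 1.0, slice_spacing = 2.5,
                        n_contour_points = 48L, seed = 1L) {
  effect_family <- match.arg(effect_family)
  if (toxicity_prevalence <= 0 || toxicity_prevalence >= 1) {
    stopf("toxicity_prevalence must be in (0, 1)")
  }
  if (effect_family == "null") effect_slope <- 0
  structure(list(n_patients = as.integer(n_patients),
                 toxicity_prevalence = toxicity_prevalence,
                 deformation_amplitude = deformation_amplitude,
                 shape_amplitude = shape_amplitude,
                 source_standoff = source_standoff,
                 source_jitter = source_jitter,
                 hotspot_r0 = hotspot_r0, falloff_exponent = falloff_exponent,
                 effect_family = effect_family, effect_level = effect_level,
                 effect_slope = effect_slope, slice_spacing = slice_spacing,
                 n_contour_points = as.integer(n_contour_points),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw one synthetic rectum geometry
#'
#' A tube of elliptical cross-sections with smooth low-order-harmonic radial
#' perturbation and a smooth centerline wobble; length uniform in 60-90 mm.
#' With `spec$shape_amplitude = 0` the result is a perfect elliptical
#' cylinder.
#'
#' @param spec a [cohort_spec].
#' @param patient_seed integer seed for this patient.
#' @return a [contour_stack].
#' @export
make_rectum <- function(spec, patient_seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(patient_seed, {
    len <- runif(1, 60, 90)
    nz <- max(3L, floor(len / spec$slice_spacing) + 1L)
    zz <- (seq_len(nz) - 1L) * spec$slice_spacing
    a <- runif(1, 11, 16)   # lateral semi-axis, mm
    b <- runif(1, 8, 13)    # anterior-posterior semi-axis, mm
    amp <- spec$shape_amplitude
    # centerline wobble: one-period sinusoids with random phase
    cph <- runif(2, 0, 2 * pi)
    camp <- if (amp > 0) runif(2, 0, amp) else c(0, 0)
    # radial harmonics k = 2, 3 (relative amplitude scaled by shape_amplitude)
    eps <- if (amp > 0) runif(2, 0, 0.03 * amp) else c(0, 0)
    hph <- runif(2, 0, 2 * pi)
    theta <- seq(0, 2 * pi, length.out = spec$n_contour_points + 1L)[-(spec$n_contour_points + 1L)]
    slices <- lapply(seq_len(nz), function(i) {
      u <- zz[i] / max(zz)
      cx <- camp[1] * sin(2 * pi * u + cph[1])
      cy <- camp[2] * sin(2 * pi * u + cph[2])
      rmod <- 1 + eps[1] * cos(2 * theta + hph[1] + u) +
                  eps[2] * cos(3 * theta + hph[2] - u)
      x <- cx + a * rmod * cos(theta)
      y <- cy + b * rmod * sin(theta)
      list(z = zz[i], xy = cbind(x, y))
    })
    contour_stack(slices, slice_spacing = spec$slice_spacing, validate = FALSE)
  })
}

#' Deform a contour stack with a smooth random displacement field
#'
#' The field is a sum of six 3D Gaussian bumps with in-plane (x, y)
#' displacement vectors, rescaled so the maximum point displacement equals
#' `amplitude`; point correspondence (vertex ordering) is retained. If any
#' deformed polygon self-intersects the draw is retried with damped
#' amplitude.
#'
#' @param stack a [contour_stack].
#' @param amplitude maximum displacement, mm.
#' @param fraction_seed integer seed.
#' @return a [contour_stack] with the same vertex counts and correspondence.
#' @export
deform_fraction <- function(stack, amplitude, fraction_seed) {
  stopifnot(inherits(stack, "contour_stack"))
  if (amplitude < 0) stopf("amplitude must be >= 0")
  if (amplitude == 0) return(stack)
  amp <- amplitude
  for (attempt in 1:6) {
    res <- with_seed(derive_seed(fraction_seed, attempt), {
      pts <- do.call(rbind, lapply(stack$slices, function(s) {
        cbind(s$xy, s$z)
      }))
      bb_lo <- apply(pts, 2, min) - 10
      bb_hi <- apply(pts, 2, max) + 10
      K <- 6L
      centers <- cbind(runif(K, bb_lo[1], bb_hi[1]),
                       runif(K, bb_lo[2], bb_hi[2]),
                       runif(K, bb_lo[3], bb_hi[3]))
      sig <- runif(K, 15, 30)
      dir <- matrix(rnorm(2 * K), K, 2)
      dir <- dir / sqrt(rowSums(dir ^ 2))
      disp <- matrix(0, nrow(pts), 2)
      for (k in seq_len(K)) {
        wgt <- exp(-rowSums(sweep(pts, 2, centers[k, ]) ^ 2) / (2 * sig[k] ^ 2))
        disp <- disp + outer(wgt, dir[k, ])
      }
      mx <- max(sqrt(rowSums(disp ^ 2)))
      if (mx > 0) disp <- disp * (amp / mx)
      cnt <- 0L
      new_slices <- lapply(seq_along(stack$slices), function(i) {
        s <- stack$slices[[i]]
        ni <- nrow(s$xy)
        idx <- (cnt + 1L):(cnt + ni)
        cnt <<- cnt + ni
        list(z = s$z, xy = s$xy + disp[idx, , drop = FALSE])
      })
      ok <- all(vapply(new_slices, function(s) polygon_is_simple(s$xy),
                       logical(1)))
      list(ok = ok, slices = new_slices)
    })
    if (res$ok) {
      out <- stack
      # keep correspondence: do NOT renormalise vertex order
      out$slices <- lapply(seq_along(res$slices), function(i) {
        list(z = res$slices[[i]]$z, xy = res$slices[[i]]$xy)
      })
      return(out)
    }
    warnf("deform_fraction: self-intersecting result, damping amplitude")
    amp <- amp * 0.7
  }
  stopf("deform_fraction: could not generate a simple deformation")
}

#' Analytic brachytherapy point-source dose field
#'
#' `d(p) = strength * (r0 / ||p - source||)^exponent`, capped at
#' `3 * strength`. Returns a function evaluating the field at an N x 3 matrix
#' of points.
#'
#' @param source_position length-3 position of the source, mm.
#' @param strength dose at the reference distance `r0`, Gy (> 0).
#' @param exponent falloff exponent.
#' @param r0 reference distance, mm.
#' @export
bt_dose_field <- function(source_position, strength, exponent = 2, r0 = 12) {
  if (strength <= 0) stopf("strength must be > 0")
  source_position <- as.numeric(source_position)
  force(exponent); force(r0)
  function(points) {
    points <- as.matrix(points)
    r <- sqrt(rowSums(sweep(points, 2, source_position) ^ 2))
    if (any(r < 1e-6)) {
      warnf("bt_dose_field: point at the source position; cap applies")
      r <- pmax(r, 1e-6)
    }
    pmin(strength * (r0 / r) ^ exponent, 3 * strength)
  }
}

#' Generate a synthetic patient cohort
#'
#' For each patient a reference rectum and per-fraction deformed geometries
#' are drawn, the BT field is evaluated per fraction, the ground-truth
#' cumulative EQD2 surface dose (via true correspondences) plus homogeneous
#' EBRT is computed, the causal feature (relative RSDM area above
#' `spec$effect_level` Gy) is measured on the ground truth, and labels are
#' drawn from `logistic(alpha + slope * feature)` with `alpha` calibrated so
#' the expected prevalence matches the spec. BT schemes alternate 4 x 7 Gy
#' and 5 x 6 Gy by patient parity; EBRT is 45 Gy in 25 x 1.8 Gy.
#'
#' @param spec a [cohort_spec].
#' @return list of `synthetic_patient` objects, each with `fractions` (BT
#'   [fraction_record]s), `true_dvfs` (moving-to-reference, per non-reference
#'   fraction), `scheme`, `label`, and `ground_truth` (`cum_eqd2`,
#'   `causal_value`, `rsdm`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  pat_seeds <- with_seed(spec$seed,
                         sample.int(2147483L, spec$n_patients) * 997L)
  params <- eqd2_params(3)
  patients <- vector("list", spec$n_patients)
  for (p in seq_len(spec$n_patients)) {
    sd_p <- pat_seeds[p]
    base <- make_rectum(spec, derive_seed(sd_p, 1))
    n_fx <- if (p %% 2L == 1L) 4L else 5L
    d_fx <- if (n_fx == 4L) 7 else 6
    ref_mesh <- contours_to_mesh(base)
    ctr <- colMeans(ref_mesh$vertices)
    off_p <- with_seed(derive_seed(sd_p, 2),
                       runif(1, -spec$source_jitter, spec$source_jitter))
    fractions <- vector("list", n_fx)
    true_dvfs <- vector("list", n_fx)
    gt_dose <- numeric(nrow(ref_mesh$vertices))
    for (k in seq_len(n_fx)) {
      geom <- if (k == 1L) base else {
        deform_fraction(base, spec$deformation_amplitude,
                        derive_seed(sd_p, 10 + k))
      }
      mesh <- contours_to_mesh(geom)
      jit <- with_seed(derive_seed(sd_p, 20 + k), runif(3, -1.5, 1.5))
      # source sits `standoff` mm anterior of the anterior wall near mid-tube
      mid <- abs(mesh$vertices[, 3] - ctr[3]) < 10
      wall_y <- max(mesh$vertices[mid, 2])
      src <- c(ctr[1] + jit[1],
               wall_y + pmax(2, spec$source_standoff + off_p + jit[2]),
               ctr[3] + jit[3])
      field <- bt_dose_field(src, strength = d_fx,
                             exponent = spec$falloff_exponent,
                             r0 = spec$hotspot_r0)
      fx_dose <- field(mesh$vertices)
      fractions[[k]] <- fraction_record("BT", k, geometry = geom, mesh = mesh,
                                        dose = fx_dose, d = d_fx,
                                        n_fractions = n_fx)
      if (k > 1L) {
        true_dvfs[[k]] <- dvf(ref_mesh$vertices - mesh$vertices,
                              target = "reference")
      }
      # ground truth via true correspondence: fraction vertex i is reference
      # vertex i displaced, so its dose maps straight back
      gt_dose <- gt_dose + fraction_eqd2(fx_dose, params)
    }
    gt_dose_total <- gt_dose + eqd2(45, 1.8, params)
    gt_cum <- new_cumulative_dose(ref_mesh, gt_dose_total, list())
    gt_rsdm <- flatten(gt_cum, patient_id = p)
    causal <- causal_feature(gt_rsdm, spec$effect_level)
    patients[[p]] <- structure(
      list(id = p, fractions = fractions, true_dvfs = true_dvfs,
           scheme = list(bt_n = n_fx, bt_d = d_fx,
                         ebrt_total = 45, ebrt_d = 1.8),
           ground_truth = list(cum_eqd2 = gt_dose_total, causal_value = causal,
                               rsdm = gt_rsdm),
           seed = sd_p),
      class = "synthetic_patient")
  }
  x <- vapply(patients, function(p) p$ground_truth$causal_value, numeric(1))
  beta <- spec$effect_slope
  alpha <- calibrate_intercept(x, beta, spec$toxicity_prevalence)
  labels <- with_seed(derive_seed(spec$seed, 999),
                      rbinom(spec$n_patients, 1, plogis(alpha + beta * x)))
  for (p in seq_len(spec$n_patients)) patients[[p]]$label <- labels[p]
  attr(patients, "spec") <- spec
  attr(patients, "alpha") <- alpha
  patients
}

# Relative RSDM area (%) with dose >= level: the planted causal feature
# (identical definition to the DGP relative area).
causal_feature <- function(map, level) {
  region <- map$mask & !is.na(map$dose) & map$dose >= level
  100 * sum(rowSums(region) * map$row_height) / sum(rowSums(map$mask) * map$row_height)
}

# Solve mean(plogis(alpha + beta * x)) = prevalence for alpha.
calibrate_intercept <- function(x, beta, prevalence) {
  f <- function(a) mean(plogis(a + beta * x)) - prevalence
  stats::uniroot(f, c(-200, 200), tol = 1e-10)$root
}

#' Write a synthetic cohort to a directory
#'
#' Emits per-patient per-fraction contour files, PLY meshes with per-vertex
#' dose, `labels.csv`, and `ground_truth.json`.
#'
#' @param patients output of [generate_cohort].
#' @param dir output directory (created if absent).
#' @export
write_cohort <- function(patients, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- data.frame(patient = vapply(patients, `[[`, integer(1), "id"),
                       label = vapply(patients, `[[`, integer(1), "label"))
  utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  gt <- lapply(patients, function(p) {
    list(patient = p$id, causal_value = p$ground_truth$causal_value,
         scheme = p$scheme)
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  for (p in patients) {
    pd <- file.path(dir, sprintf("patient_%03d", p$id))
    dir.create(pd, showWarnings = FALSE)
    for (k in seq_along(p$fractions)) {
      fr <- p$fractions[[k]]
      write_contours(fr$geometry, file.path(pd, sprintf("fraction_%d.txt", k)))
      m <- fr$mesh
      m$vertex_dose <- fr$dose
      write_ply(m, file.path(pd, sprintf("fraction_%d.ply", k)))
    }
  }
  invisible(dir)
}
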