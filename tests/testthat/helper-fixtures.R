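# Fixtures built in code. Heavier shared fixtures are generated lazily once
# per test session and cached.

square_stack <- function(nz = 3, dz = 1, side = 1) {
  s <- side / 2
  sq <- rbind(c(-s, -s), c(s, -s), c(s, s), c(-s, s))
  suppressWarnings(contour_stack(lapply(seq_len(nz), function(i) {
    list(z = (i - 1) * dz, xy = sq)
  }), slice_spacing = dz))
}

circle_stack <- function(r = 10, n = 64, nz = 11, dz = 2, z0 = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  suppressWarnings(contour_stack(lapply(seq_len(nz), function(i) {
    list(z = z0 + (i - 1) * dz, xy = cbind(r * cos(th), r * sin(th)))
  }), slice_spacing = dz))
}

# Random small masked RSDM for texture / DGP oracle tests.
random_rsdm <- function(seed, nr = 12, nc = 12, dose_range = c(40, 100),
                        mask_frac = 0.85) {
  withr::with_seed(seed, {
    dose <- matrix(runif(nr * nc, dose_range[1], dose_range[2]), nr, nc)
    mask <- matrix(runif(nr * nc) < mask_frac, nr, nc)
    # keep at least an L-shaped valid core so every extractor has data
    mask[1:3, 1:3] <- TRUE
    dose[!mask] <- NA
    rsdm(dose, mask, row_spacing = 1, col_spacing = 1)
  })
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small synthetic patient shared across accumulation / flattening tests.
small_patient <- function() {
  cached("small_patient", {
    spec <- cohort_spec(n_patients = 1, seed = 303)
    generate_cohort(spec)[[1]]
  })
}

# A modest planted-effect cohort plus features, shared by screening /
# prediction sanity tests (scaled below acceptance size for speed).
small_cohort_features <- function() {
  cached("small_cohort_features", {
    spec <- cohort_spec(n_patients = 16, toxicity_prevalence = 0.3,
                        seed = 404)
    coh <- generate_cohort(spec)
    list(cohort = coh, table = cohort_features(coh, dvf_method = "true"))
  })
}
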