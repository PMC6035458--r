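test_that("make_rectum is deterministic and draws lengths in 60-90 mm", {
  spec <- cohort_spec(seed = 1)
  a <- make_rectum(spec, 12)
  b <- make_rectum(spec, 12)
  expect_identical(a, b)
  expect_false(identical(a, make_rectum(spec, 13)))

  # zero shape amplitude: perfect elliptical cylinder (all slices congruent)
  flat <- cohort_spec(shape_amplitude = 0, seed = 1)
  cyl <- make_rectum(flat, 5)
  ref <- cyl$slices[[1]]$xy
  for (s in cyl$slices) expect_lt(max(abs(s$xy - ref)), 1e-9)

  # length distribution: uniform on [60, 90]
  lens <- vapply(1:400, function(i) {
    contour_length(make_rectum(spec, 1000 + i))
  }, numeric(1))
  expect_true(all(lens >= 60 - 2.5 & lens <= 90))
  expect_equal(mean(lens), 75, tolerance = 0.03)
})

test_that("deform_fraction bounds displacement and keeps correspondence", {
  spec <- cohort_spec(seed = 2)
  st <- make_rectum(spec, 21)
  expect_identical(deform_fraction(st, 0, 5), st)
  for (amp in c(2, 4, 8)) {
    d <- deform_fraction(st, amp, 99)
    disp <- vapply(seq_along(st$slices), function(i) {
      max(sqrt(rowSums((d$slices[[i]]$xy - st$slices[[i]]$xy) ^ 2)))
    }, numeric(1))
    expect_lte(max(disp), amp + 1e-9)
    expect_equal(max(disp), amp, tolerance = 1e-6)  # rescaled to amplitude
    # z positions and vertex counts unchanged
    expect_equal(rsdmtox:::contour_z(d), rsdmtox:::contour_z(st))
  }
})

test_that("bt_dose_field follows the capped inverse power law", {
  f <- bt_dose_field(c(0, 0, 0), strength = 7, exponent = 2, r0 = 10)
  expect_equal(f(rbind(c(10, 0, 0))), 7)
  expect_equal(f(rbind(c(20, 0, 0))), 7 / 4)
  expect_equal(f(rbind(c(0.1, 0, 0))), 21)  # cap at 3x strength
  expect_warning(f(rbind(c(0, 0, 0))), "source")
  # max dose on a mesh is at the vertex nearest the source (exhaustive scan)
  m <- contours_to_mesh(circle_stack(r = 9, n = 24, nz = 5, dz = 2))
  src <- c(0, 14, 4)
  g <- bt_dose_field(src, 7, 2, 10)
  dose <- g(m$vertices)
  d2 <- rowSums(sweep(m$vertices, 2, src) ^ 2)
  # nearest vertex attains the maximum (ties possible under the cap)
  expect_equal(dose[which.min(d2)], max(dose))
})

test_that("generate_cohort is seed-deterministic with calibrated prevalence", {
  spec <- cohort_spec(n_patients = 6, seed = 31)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(cohort_spec(n_patients = 6,
                                                        seed = 32))))
  # schemes alternate 4 x 7 Gy and 5 x 6 Gy
  expect_equal(vapply(a, function(p) p$scheme$bt_n, integer(1)),
               c(4L, 5L, 4L, 5L, 4L, 5L))
  expect_equal(vapply(a, function(p) p$scheme$bt_d, numeric(1)),
               c(7, 6, 7, 6, 7, 6))
})

test_that("null cohorts hit the specified prevalence (binomial oracle)", {
  # beta = 0: labels are iid Bernoulli(prevalence); check over many draws
  # (cohort geometry is not needed, so patient count is modest but the
  # label draw is over 2000 patients via repeated small cohorts)
  hits <- 0; n_tot <- 0
  for (s in 1:25) {
    spec <- cohort_spec(n_patients = 8, toxicity_prevalence = 12 / 42,
                        effect_family = "null", seed = 5000 + s)
    coh <- generate_cohort(spec)
    hits <- hits + sum(vapply(coh, `[[`, integer(1), "label"))
    n_tot <- n_tot + length(coh)
  }
  phat <- hits / n_tot
  se <- sqrt((12 / 42) * (30 / 42) / n_tot)
  expect_lt(abs(phat - 12 / 42), 3 * se)
})

test_that("a strong planted effect separates classes on ground truth", {
  spec <- cohort_spec(n_patients = 60, toxicity_prevalence = 0.3,
                      effect_slope = 5, seed = 77)
  coh <- generate_cohort(spec)
  x <- vapply(coh, function(p) p$ground_truth$causal_value, numeric(1))
  y <- vapply(coh, `[[`, integer(1), "label")
  rpb <- stats::cor(x, y)
  expect_gt(rpb, 0.5)
})

test_that("accumulating with true DVFs reproduces the generator ground truth", {
  p <- small_patient()
  cum <- accumulate_bt(p$fractions[[1]], p$fractions[-1], p$true_dvfs[-1])
  cum <- add_ebrt(cum, p$scheme$ebrt_total, p$scheme$ebrt_d)
  expect_lt(max(abs(cum$dose - p$ground_truth$cum_eqd2)), 1e-6)
})

test_that("write_cohort emits contours, dosed meshes, labels and ground truth", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(cohort_spec(n_patients = 2, seed = 8))
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  f1 <- file.path(dir, "patient_001", "fraction_1.ply")
  expect_true(file.exists(f1))
  m <- read_ply(f1)
  expect_equal(m$vertex_dose, coh[[1]]$fractions[[1]]$dose, tolerance = 1e-8)
})
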