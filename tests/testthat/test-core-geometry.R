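test_that("contour files round-trip losslessly and reject malformed input", {
  stack <- make_rectum(cohort_spec(seed = 1), 77)
  path <- withr::local_tempfile(fileext = ".txt")
  write_contours(stack, path)
  back <- read_contours(path)
  expect_equal(length(back$slices), length(stack$slices))
  for (i in seq_along(stack$slices)) {
    expect_equal(back$slices[[i]]$z, stack$slices[[i]]$z, tolerance = 1e-6)
    expect_lt(max(abs(back$slices[[i]]$xy - stack$slices[[i]]$xy)), 1e-6)
  }
  expect_equal(back$slice_spacing, stack$slice_spacing, tolerance = 1e-9)

  # three-slice square tube parses
  sq <- square_stack(3)
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_contours(sq, p2)
  expect_equal(length(suppressWarnings(read_contours(p2))$slices), 3L)

  # malformed inputs name the offending slice
  expect_error(contour_stack(list(list(z = 0, xy = rbind(c(0, 0), c(1, 0))))),
               "3")
  expect_error(contour_stack(list(list(z = 0, xy = square_stack(1)$slices[[1]]$xy),
                                  list(z = 0, xy = square_stack(1)$slices[[1]]$xy))),
               "strictly increasing")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(contour_stack(list(list(z = 0, xy = bowtie))),
               "self-intersecting")
})

test_that("contours are normalised CCW with a posterior starting point", {
  cw <- rbind(c(0, 1), c(1, 1), c(1, 0), c(0, 0))  # clockwise square
  st <- contour_stack(list(list(z = 0, xy = cw)))
  xy <- st$slices[[1]]$xy
  expect_gt(rsdmtox:::polygon_signed_area(xy), 0)
  expect_equal(unname(xy[1, ]), c(0, 0))  # min y, then min x
})

test_that("contours_to_mesh stitches tubes with correct areas", {
  # two unit squares, dz = 1: 8 vertices, 8 triangles, lateral area 4
  sq <- square_stack(2)
  m <- contours_to_mesh(sq)
  expect_equal(nrow(m$vertices), 8L)
  expect_equal(nrow(m$faces), 8L)
  expect_equal(surface_area(m), 4, tolerance = 1e-12)
  expect_equal(m$vertex_slice, rep(1:2, each = 4))

  # cylinder radius 10, height 20 at 64 points/contour: within 2% of 2*pi*r*h
  cyl <- contours_to_mesh(circle_stack(r = 10, n = 64, nz = 11, dz = 2))
  expect_equal(surface_area(cyl), 2 * pi * 10 * 20, tolerance = 0.02)

  expect_error(contours_to_mesh(square_stack(1)), "2 slices")
  degenerate <- list(list(z = 0, xy = rbind(c(0, 0), c(1, 0), c(2, 0))),
                     list(z = 1, xy = rbind(c(0, 0), c(1, 0), c(2, 0))))
  expect_error(contours_to_mesh(suppressWarnings(contour_stack(degenerate, validate = FALSE))),
               "degenerate")
})

test_that("mesh area error decreases as contour sampling is refined", {
  errs <- vapply(c(16, 64, 256), function(n) {
    m <- contours_to_mesh(circle_stack(r = 10, n = n, nz = 5, dz = 2))
    abs(surface_area(m) - 2 * pi * 10 * 8)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("vertex areas partition the surface", {
  for (seed in c(5, 6)) {
    m <- contours_to_mesh(make_rectum(cohort_spec(seed = 1), seed))
    va <- vertex_areas(m)
    expect_equal(sum(va), surface_area(m), tolerance = 1e-9)
    expect_true(all(va > 0))
  }
})

test_that("sample_dose reproduces constant, linear and random fields", {
  m <- contours_to_mesh(circle_stack(r = 8, n = 32, nz = 5, dz = 2))
  # constant field
  g <- dose_grid(array(7, c(4, 4, 4)), origin = c(-12, -12, -2),
                 spacing = c(8, 8, 4))
  expect_equal(sample_dose(m, g), rep(7, nrow(m$vertices)))
  # linear ramp in z: trilinear reproduces linear fields exactly
  zs <- array(rep(seq(-2, 10, by = 4), each = 16), c(4, 4, 4))
  gz <- dose_grid(zs + 2, origin = c(-12, -12, -2), spacing = c(8, 8, 4))
  expect_equal(sample_dose(m, gz), m$vertices[, 3] + 2, tolerance = 1e-12)
  # random grid vs scalar oracle
  vals <- withr::with_seed(9, array(runif(5 * 6 * 7, 0, 10), c(5, 6, 7)))
  gr <- dose_grid(vals, origin = c(-10, -10, -1), spacing = c(5, 4, 2))
  got <- sample_dose(m, gr)
  want <- vapply(seq_len(nrow(m$vertices)), function(i) {
    oracle_trilinear(m$vertices[i, ], vals, c(-10, -10, -1), c(5, 4, 2))
  }, numeric(1))
  expect_lt(max(abs(got - want)), 1e-9)
  # out-of-bounds vertices clamp with a warning
  tiny <- dose_grid(array(1, c(2, 2, 2)), origin = c(0, 0, 0))
  expect_warning(sample_dose(m, tiny), "clamped")
})

test_that("PLY round-trips vertices, faces and dose", {
  m <- contours_to_mesh(square_stack(3))
  m$vertex_dose <- seq_len(nrow(m$vertices)) / 3
  path <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, path)
  back <- read_ply(path)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-9)
  expect_equal(back$faces, m$faces)
  expect_equal(back$vertex_dose, m$vertex_dose, tolerance = 1e-9)
})

test_that("atypical superior-inferior extent warns but does not error", {
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  short <- lapply(0:2, function(z) {
    list(z = z * 2, xy = cbind(10 * cos(th), 10 * sin(th)))
  })
  expect_warning(contour_stack(short), "60-90")
  long <- lapply(0:40, function(z) {
    list(z = z * 2.5, xy = cbind(10 * cos(th), 10 * sin(th)))
  })
  expect_warning(contour_stack(long), "60-90")
})
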