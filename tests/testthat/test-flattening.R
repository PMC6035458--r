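uniform_cum <- function(stack, value = 50) {
  m <- contours_to_mesh(stack)
  rsdmtox:::new_cumulative_dose(m, rep(value, nrow(m$vertices)), list())
}

test_that("a uniform tube flattens to a uniform, area-conserving map", {
  st <- circle_stack(r = 10, n = 64, nz = 9, dz = 2.5)
  cum <- uniform_cum(st, 50)
  map <- flatten(cum)
  expect_true(all(abs(map$dose[map$mask] - 50) < 1e-9))
  expect_equal(rsdm_area(map), surface_area(cum$mesh), tolerance = 0.02)
  # each row circumference matches the analytic circle perimeter of a 64-gon
  perim <- rsdmtox:::polygon_perimeter(st$slices[[1]]$xy)
  expect_true(all(abs(map$row_circumference - perim) < 1e-9))
  expect_equal(max(abs(map$row_circumference - 2 * pi * 10)), 0,
               tolerance = map$col_spacing)
  # valid pixels per row match circumference within one pixel
  expect_true(all(abs(rowSums(map$mask) * map$col_spacing -
                        map$row_circumference) <= map$col_spacing))
})

test_that("azimuthal dose unrolls into a per-row ramp wrapping at the cut", {
  st <- circle_stack(r = 10, n = 64, nz = 3, dz = 2.5)
  m <- contours_to_mesh(st)
  # dose = azimuth angle measured CCW from the posterior cut (first vertex)
  ring_pos <- (seq_len(nrow(m$vertices)) - 1) %% m$n_ring
  cum <- rsdmtox:::new_cumulative_dose(m, ring_pos * (360 / m$n_ring), list())
  map <- flatten(cum)
  row <- map$dose[2, map$mask[2, ]]
  s <- (seq_along(row) - 1) * map$col_spacing
  want <- 360 * s / map$row_circumference[2]
  # linear ramp except inside the final wrap segment back to 0
  keep <- s <= map$row_circumference[2] * (1 - 1 / m$n_ring)
  expect_equal(row[keep], want[keep], tolerance = 1e-6)
  expect_true(all(diff(row[keep]) > 0))
})

test_that("rsdm_area integrates per-row pixel heights", {
  map <- rsdm(matrix(50, 10, 10), matrix(TRUE, 10, 10))
  expect_equal(rsdm_area(map), 100)
  half <- matrix(TRUE, 10, 10)
  half[, 6:10] <- FALSE
  expect_equal(rsdm_area(rsdm(matrix(50, 10, 10), half)), 50)
})

test_that("flattening conserves the area-weighted dose distribution", {
  p <- small_patient()
  cum <- add_ebrt(accumulate_bt(p$fractions[[1]], p$fractions[-1],
                                p$true_dvfs[-1]))
  map <- flatten(cum)
  # earth-mover distance between area-weighted dose histograms
  br <- seq(floor(min(cum$dose)) - 1, ceiling(max(cum$dose)) + 1, by = 0.25)
  wa <- vertex_areas(cum$mesh)
  h_mesh <- vapply(seq_len(length(br) - 1), function(i) {
    sum(wa[cum$dose >= br[i] & cum$dose < br[i + 1]])
  }, numeric(1))
  px_h <- matrix(map$row_height, nrow(map$dose), ncol(map$dose))
  h_map <- vapply(seq_len(length(br) - 1), function(i) {
    sel <- map$mask & map$dose >= br[i] & map$dose < br[i + 1]
    sum(px_h[sel]) * map$col_spacing
  }, numeric(1))
  emd <- sum(abs(cumsum(h_mesh / sum(h_mesh)) - cumsum(h_map / sum(h_map)))) *
    0.25
  expect_lt(emd, 0.5)
})

test_that("RSDM CSV/JSON round-trip preserves the map", {
  p <- small_patient()
  cum <- add_ebrt(accumulate_bt(p$fractions[[1]], p$fractions[-1],
                                p$true_dvfs[-1]))
  map <- flatten(cum, patient_id = 1)
  stem <- file.path(withr::local_tempdir(), "map")
  write_rsdm(map, stem)
  back <- read_rsdm(stem)
  expect_equal(back$mask, map$mask)
  expect_equal(back$dose[back$mask], map$dose[map$mask], tolerance = 1e-9)
  expect_equal(back$row_circumference, map$row_circumference,
               tolerance = 1e-9)
  expect_equal(back$row_height, map$row_height, tolerance = 1e-9)
})

test_that("flatten rejects meshes without slice structure", {
  m <- contours_to_mesh(square_stack(3))
  m$n_ring <- NULL
  cum <- rsdmtox:::new_cumulative_dose(m, rep(1, nrow(m$vertices)), list())
  expect_error(flatten(cum), "slice-structured")
})
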