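test_that("EQD2 closed form matches the linear-quadratic conversion", {
  expect_equal(eqd2(20, 2), 20, tolerance = 1e-15)
  expect_equal(eqd2(45, 1.8), 43.2, tolerance = 1e-12)
  expect_equal(eqd2(28, 7), 56, tolerance = 1e-12)
  # linearity in D and monotonicity in d
  expect_equal(eqd2(3 * 12.5, 4.2), 3 * eqd2(12.5, 4.2), tolerance = 1e-12)
  ds <- seq(0.5, 9, by = 0.5)
  expect_true(all(diff(eqd2(30, ds)) > 0))
  expect_error(eqd2(10, 0), "> 0")
  expect_error(eqd2(-1, 2), ">= 0")
  # alpha/beta enters the conversion
  expect_equal(eqd2(28, 7, eqd2_params(10)), 28 * 17 / 12, tolerance = 1e-12)
})

test_that("accumulate_bt sums per-fraction EQD2 on the reference surface", {
  m <- contours_to_mesh(square_stack(3))
  nv <- nrow(m$vertices)
  mk <- function(idx) fraction_record("BT", idx, mesh = m,
                                      dose = rep(7, nv), d = 7,
                                      n_fractions = 4)
  frs <- lapply(1:4, mk)
  ident <- lapply(1:3, function(i) dvf(matrix(0, nv, 3)))
  cum <- accumulate_bt(frs[[1]], frs[-1], ident)
  # 4 x 7 Gy at alpha/beta 3: 4 * 7 * (7 + 3) / 5 = 56
  expect_equal(cum$dose, rep(56, nv), tolerance = 1e-12)
  expect_length(cum$provenance, 4L)

  # a single reference fraction equals its own EQD2
  solo <- accumulate_bt(frs[[1]], list(), list())
  expect_equal(solo$dose, rep(eqd2(7, 7), nv), tolerance = 1e-12)

  # order of the other fractions does not matter
  frs2 <- lapply(1:4, function(i) {
    fraction_record("BT", i, mesh = m,
                    dose = withr::with_seed(i, runif(nv, 1, 9)),
                    d = 7, n_fractions = 4)
  })
  c12 <- accumulate_bt(frs2[[1]], frs2[c(2, 3, 4)], ident)
  c21 <- accumulate_bt(frs2[[1]], frs2[c(4, 3, 2)], ident)
  expect_equal(c12$dose, c21$dose, tolerance = 1e-12)

  expect_error(accumulate_bt(frs[[1]], frs[-1], ident[1:2]), "DVF")
  expect_error(fraction_record("BT", 2, mesh = m, dose = NULL, d = 7,
                               n_fractions = 4), "dose")
})

test_that("add_ebrt shifts every vertex by the scalar EQD2", {
  m <- contours_to_mesh(square_stack(2))
  nv <- nrow(m$vertices)
  zero <- rsdmtox:::new_cumulative_dose(m, rep(0, nv), list())
  out <- add_ebrt(zero, 45, 1.8)
  expect_equal(out$dose, rep(43.2, nv), tolerance = 1e-12)
  expect_equal(add_ebrt(zero, 0, 1.8)$dose, zero$dose)
  ran <- rsdmtox:::new_cumulative_dose(m, withr::with_seed(4, runif(nv, 10, 60)),
                                       list())
  expect_equal(min(add_ebrt(ran, 45, 1.8)$dose), min(ran$dose) + 43.2,
               tolerance = 1e-12)
})

test_that("static accumulation is index-wise and misaligns moving hotspots", {
  m <- contours_to_mesh(circle_stack(r = 10, n = 16, nz = 3, dz = 2))
  nv <- nrow(m$vertices)
  # identical geometry: static equals deformable with identity DVFs
  fr <- lapply(1:2, function(i) {
    fraction_record("BT", i, mesh = m,
                    dose = withr::with_seed(10 + i, runif(nv, 1, 8)),
                    d = 7, n_fractions = 2)
  })
  stat <- static_accumulate(fr)
  defo <- accumulate_bt(fr[[1]], fr[-1], list(dvf(matrix(0, nv, 3))))
  expect_equal(stat$dose, defo$dose, tolerance = 1e-12)

  # single fraction: equals its own EQD2
  expect_equal(static_accumulate(fr[1])$dose, rep(0, nv) + eqd2(fr[[1]]$dose,
               fr[[1]]$dose), tolerance = 1e-12)

  # hotspot rotated half a turn between fractions: SA max < deformable max
  ring <- m$n_ring
  pos <- (seq_len(nv) - 1) %% ring          # circumferential position
  slice0 <- (seq_len(nv) - 1) %/% ring      # 0-based slice
  hot_a <- ifelse(pos < 3, 10, 1)
  hot_b <- ifelse(pos >= ring / 2 & pos < ring / 2 + 3, 10, 1)
  fa <- fraction_record("BT", 1, mesh = m, dose = hot_a, d = 7,
                        n_fractions = 2)
  fb <- fraction_record("BT", 2, mesh = m, dose = hot_b, d = 7,
                        n_fractions = 2)
  sa <- static_accumulate(list(fa, fb))
  # true alignment: rotate fraction b's vertices back by half a ring
  target <- slice0 * ring + ((pos - ring / 2) %% ring) + 1
  disp <- m$vertices[target, ] - m$vertices
  defo2 <- accumulate_bt(fa, list(fb), list(dvf(disp)))
  expect_lt(max(sa$dose), max(defo2$dose))

  short <- fraction_record("BT", 2, mesh = m, dose = rep(1, nv - 1), d = 7,
                           n_fractions = 2)
  expect_error(static_accumulate(list(fa, short)), "vertex count")
})
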