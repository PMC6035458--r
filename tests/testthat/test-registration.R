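test_that("registering a mesh to itself gives a near-zero DVF", {
  m <- contours_to_mesh(make_rectum(cohort_spec(seed = 3), 11))
  f <- register(m, m)
  warped <- apply_dvf(m, f)
  expect_lt(rsdmtox:::mean_nn_dist(warped$vertices, m$vertices), 1e-3)
})

test_that("a pure translation is recovered", {
  m <- contours_to_mesh(make_rectum(cohort_spec(seed = 3), 14))
  t <- c(-3, 2, 1)
  fixed <- m
  fixed$vertices <- sweep(fixed$vertices, 2, t, "+")
  f <- register(m, fixed)
  err <- sweep(f$displacements, 2, t)
  expect_lt(mean(sqrt(rowSums(err ^ 2))), 0.05 * sqrt(sum(t ^ 2)))
})

test_that("generator deformations are recovered (median VVD halved)", {
  spec <- cohort_spec(seed = 6)
  for (s in c(41, 42)) {
    ref <- make_rectum(spec, s)
    mov_stack <- deform_fraction(ref, 4, s * 7)
    fixed <- contours_to_mesh(ref)
    moving <- contours_to_mesh(mov_stack)
    pre <- compute_metrics(moving, fixed)
    f <- register(moving, fixed)
    post <- compute_metrics(apply_dvf(moving, f), fixed)
    expect_lt(post$VVD, 0.5 * pre$VVD)
    expect_gt(post$DC, pre$DC)
    # smoothness: the displacement field has bounded discrete Laplacian
    lap <- rsdmtox:::laplacian_smooth_field(moving, f$displacements, 1, 1) -
      f$displacements
    expect_lt(max(sqrt(rowSums(lap ^ 2))), 1)
  }
})

test_that("apply_dvf shifts vertices and is invertible", {
  m <- contours_to_mesh(square_stack(3))
  z <- dvf(matrix(0, nrow(m$vertices), 3))
  expect_equal(apply_dvf(m, z)$vertices, m$vertices)
  cst <- dvf(matrix(rep(c(1, 0, 0), each = nrow(m$vertices)),
                    nrow(m$vertices), 3))
  shifted <- apply_dvf(m, cst)
  expect_equal(colMeans(shifted$vertices) - colMeans(m$vertices), c(1, 0, 0))
  neg <- cst
  neg$displacements <- -neg$displacements
  expect_equal(apply_dvf(shifted, neg)$vertices, m$vertices)
  expect_error(apply_dvf(m, dvf(matrix(0, 2, 3))), "vertices")
})

test_that("similarity metrics: identity, analytic overlap, voxel oracle", {
  m <- contours_to_mesh(circle_stack(r = 8, n = 32, nz = 5, dz = 2))
  same <- compute_metrics(m, m)
  expect_equal(same$DC, 1)
  expect_equal(same$PE, 0)
  expect_equal(same$VVD, 0)
  expect_equal(same$HD, 0)

  # two 10 mm cubes overlapping half their volume: DC = 0.5
  cube <- function(x0) {
    suppressWarnings(contour_stack(lapply(0:10, function(z) {
      list(z = z, xy = rbind(c(x0, 0), c(x0 + 10, 0),
                             c(x0 + 10, 10), c(x0, 10)))
    })))
  }
  a <- contours_to_mesh(cube(0))
  b <- contours_to_mesh(cube(5))
  met <- compute_metrics(a, b, voxel_mm = 1)
  expect_equal(met$DC, 0.5, tolerance = 0.06)
  # PE = |A u B - A ^ B| / |B| = (150 - 50) / 100 = 1
  expect_equal(met$PE, 1, tolerance = 0.12)

  # DC equals an independent voxel-count oracle
  p <- small_patient()
  ma <- p$fractions[[2]]$mesh
  mb <- p$fractions[[1]]$mesh
  bb <- rbind(apply(rbind(ma$vertices, mb$vertices), 2, min) - 2,
              apply(rbind(ma$vertices, mb$vertices), 2, max) + 2)
  va <- oracle_voxelize(ma, 2, bb)
  vb <- oracle_voxelize(mb, 2, bb)
  dc_oracle <- 2 * sum(va & vb) / (sum(va) + sum(vb))
  got <- compute_metrics(ma, mb, voxel_mm = 2)
  expect_equal(got$DC, dc_oracle, tolerance = 1e-12)
})

test_that("DC and HD are symmetric; VVD direction is moving-to-fixed", {
  p <- small_patient()
  a <- p$fractions[[2]]$mesh
  b <- p$fractions[[1]]$mesh
  ab <- compute_metrics(a, b)
  ba <- compute_metrics(b, a)
  expect_equal(ab$DC, ba$DC, tolerance = 1e-12)
  expect_equal(ab$HD, ba$HD, tolerance = 1e-12)
  expect_equal(ab$VVD, rsdmtox:::mean_nn_dist(a$vertices, b$vertices))
})
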