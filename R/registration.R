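#' Deformation vector field on a moving surface
#'
#' @param displacements N x 3 matrix of per-vertex displacements in mm,
#'   defined on the moving surface and pointing toward the fixed surface.
#' @param target optional identifier of the fixed (reference) surface.
#' @param converged logical convergence flag.
#' @param sigma2 final GMM variance (normalised units), for diagnostics.
#' @export
dvf <- function(displacements, target = NULL, converged = TRUE, sigma2 = NA) {
  displacements <- as.matrix(displacements)
  storage.mode(displacements) <- "double"
  if (ncol(displacements) != 3 || any(!is.finite(displacements))) {
    stopf("DVF displacements must be a finite N x 3 matrix")
  }
  structure(list(displacements = displacements, target = target,
                 converged = converged, sigma2 = sigma2),
            class = "dvf")
}

#' Registration parameters
#'
#' @param beta Gaussian kernel width of the motion-coherence prior, in units
#'   of the normalised point-cloud scale (default 2).
#' @param lambda regularization weight trading data fit against smoothness
#'   (default 2).
#' @param max_iter maximum EM iterations (default 40).
#' @param tol relative change in the GMM variance declaring convergence.
#' @param outlier_w uniform-outlier mixture weight in `[0, 1)`.
#' @param max_control maximum number of control points; larger clouds are
#'   subsampled and the displacement field interpolated back through the same
#'   Gaussian kernel.
#' @param topology_iters iterations of neighbourhood Laplacian smoothing of
#'   the displacement field (local-topology penalty; default 2).
#' @param topology_tau smoothing step size in `[0, 1]`.
#' @export
register_params <- function(beta = 2, lambda = 2, max_iter = 50, tol = 1e-4,
                            outlier_w = 0.1, max_control = 700L,
                            topology_iters = 2L, topology_tau = 0.5) {
  structure(list(beta = beta, lambda = lambda, max_iter = max_iter, tol = tol,
                 outlier_w = outlier_w, max_control = as.integer(max_control),
                 topology_iters = as.integer(topology_iters),
                 topology_tau = topology_tau),
            class = "register_params")
}

#' Non-rigid surface registration (coherent Gaussian-mixture point matching)
#'
#' Registers the moving surface onto the fixed one and returns the per-vertex
#' deformation vector field. The default implementation is coherent-point
#' matching: moving points are GMM centroids fitted to the fixed points by EM,
#' with displacements constrained to a smooth (motion-coherent) Gaussian
#' reproducing-kernel field; a final Laplacian smoothing pass over the mesh
#' neighbourhood graph acts as a local-topology preservation penalty. Any
#' algorithm with this signature can be substituted.
#'
#' @param moving,fixed [surface_mesh] objects.
#' @param params a [register_params].
#' @return a [dvf] on the moving mesh's vertices. If the post-registration
#'   mean vertex-to-vertex distance fails to improve on the identity the best
#'   iterate is returned with `converged = FALSE` and a warning.
#' @export
register <- function(moving, fixed, params = register_params()) {
  stopifnot(inherits(moving, "surface_mesh"), inherits(fixed, "surface_mesh"))
  Y0 <- moving$vertices
  X0 <- fixed$vertices
  # rigid pre-alignment: match centroids, then fit the non-rigid residual
  t0 <- colMeans(X0) - colMeans(Y0)
  Y0a <- sweep(Y0, 2, t0, "+")
  # normalise both clouds jointly (translation + isotropic scale)
  mu <- colMeans(rbind(Y0a, X0))
  sc <- sqrt(mean(rowSums(sweep(rbind(Y0a, X0), 2, mu) ^ 2)))
  if (sc <= 0) sc <- 1
  Y <- sweep(Y0a, 2, mu) / sc
  X <- sweep(X0, 2, mu) / sc
  # control-point subsampling of both clouds for large meshes (the same
  # regular pattern on each, keeping the GMM balanced)
  sub_idx <- function(n) {
    if (n > params$max_control) {
      unique(round(seq(1, n, length.out = params$max_control)))
    } else {
      seq_len(n)
    }
  }
  ctrl <- sub_idx(nrow(Y))
  Yc <- Y[ctrl, , drop = FALSE]
  X <- X[sub_idx(nrow(X)), , drop = FALSE]
  M <- nrow(Yc); N <- nrow(X); D <- 3
  G <- exp(-cross_dist2(Yc, Yc) / (2 * params$beta ^ 2))
  W <- matrix(0, M, D)
  sigma2 <- sum(cross_dist2(Yc, X)) / (D * M * N)
  w <- params$outlier_w
  converged <- FALSE
  for (it in seq_len(params$max_iter)) {
    T_ <- Yc + G %*% W
    d2 <- cross_dist2(T_, X)
    P <- exp(-d2 / (2 * sigma2))
    cden <- (2 * pi * sigma2) ^ (D / 2) * w / (1 - w) * M / N
    den <- colSums(P) + cden
    P <- sweep(P, 2, den, "/")
    P1 <- rowSums(P)
    Np <- sum(P1)
    PX <- P %*% X
    # (d(P1) G + lambda sigma2 I) W = PX - d(P1) Yc
    A <- G * P1 + diag(params$lambda * sigma2, M)
    W_new <- solve(A, PX - Yc * P1)
    W <- W_new
    T_ <- Yc + G %*% W
    xPx <- sum(colSums(P) * rowSums(X ^ 2))
    yPy <- sum(P1 * rowSums(T_ ^ 2))
    trPXT <- sum(T_ * PX)
    sigma2_new <- max((xPx - 2 * trPXT + yPy) / (Np * D), 1e-10)
    if (abs(sigma2 - sigma2_new) / sigma2 < params$tol) {
      sigma2 <- sigma2_new
      converged <- TRUE
      break
    }
    sigma2 <- sigma2_new
  }
  # interpolate control displacements to all moving vertices via the kernel
  disp_c <- G %*% W
  if (length(ctrl) < nrow(Y)) {
    Gfull <- exp(-cross_dist2(Y, Yc) / (2 * params$beta ^ 2))
    coeff <- solve(G + diag(1e-8, M), disp_c)
    disp <- Gfull %*% coeff
  } else {
    disp <- disp_c
  }
  disp <- sweep(disp * sc, 2, t0, "+")  # back to mm, rigid part restored
  # local-topology penalty: Laplacian smoothing on the mesh adjacency
  if (params$topology_iters > 0 && nrow(moving$faces) > 0) {
    disp <- laplacian_smooth_field(moving, disp, params$topology_iters,
                                   params$topology_tau)
  }
  pre <- mean_nn_dist(Y0, X0)
  post <- mean_nn_dist(Y0 + disp, X0)
  if (post > pre && pre > 1e-9) {
    warnf("register: did not improve mean vertex distance (%.3f -> %.3f mm)",
          pre, post)
    converged <- FALSE
  }
  if (!converged && post <= pre) {
    # ran out of iterations but still improved; flag without failing
    warnf("register: reached max_iter before convergence")
  }
  dvf(disp, target = attr(fixed, "id"), converged = converged, sigma2 = sigma2)
}

mesh_adjacency <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  edges <- unique(edges)
  split(edges[, 2], edges[, 1])
}

laplacian_smooth_field <- function(mesh, disp, iters, tau) {
  adj <- mesh_adjacency(mesh)
  ord <- as.integer(names(adj))
  for (k in seq_len(iters)) {
    nb_mean <- disp
    for (c3 in 1:3) {
      col <- disp[, c3]
      nb_mean[ord, c3] <- vapply(adj, function(nb) mean(col[nb]), numeric(1))
    }
    disp <- (1 - tau) * disp + tau * nb_mean
  }
  disp
}

nn_dists <- function(a, b) {
  n <- nrow(a)
  out <- numeric(n)
  for (s in seq(1, n, by = 2048L)) {
    e <- min(s + 2047L, n)
    blk <- a[s:e, , drop = FALSE]
    d2 <- cross_dist2(blk, b)
    j <- max.col(-d2, ties.method = "first")
    # recompute the winning distance directly: the expanded-square formula
    # suffers cancellation (identical points must give exactly 0)
    out[s:e] <- sqrt(rowSums((blk - b[j, , drop = FALSE]) ^ 2))
  }
  out
}

mean_nn_dist <- function(a, b) mean(nn_dists(a, b))
max_nn_dist <- function(a, b) max(nn_dists(a, b))

#' Apply a deformation vector field to a mesh
#'
#' Vertices are displaced; faces, per-vertex dose and slice structure are
#' carried unchanged.
#'
#' @param mesh a [surface_mesh].
#' @param field a [dvf] defined on `mesh`'s vertices.
#' @export
apply_dvf <- function(mesh, field) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(field, "dvf"))
  if (nrow(field$displacements) != nrow(mesh$vertices)) {
    stopf("DVF has %d displacements but mesh has %d vertices",
          nrow(field$displacements), nrow(mesh$vertices))
  }
  mesh$vertices <- mesh$vertices + field$displacements
  mesh
}

#' Registration similarity metrics: DC, PE, VVD, HD
#'
#' Dice coefficient and percent error are computed on voxelised enclosed
#' volumes at `voxel_mm` isotropic resolution (`DC = 2|A^B| / (|A|+|B|)`,
#' `PE = |A u B  -  A^B| / |B|`, symmetric difference over the reference
#' volume). VVD is the mean distance from each vertex of `a` to its nearest
#' vertex of `b` (asymmetric; pass the moving/deformed surface first); HD is
#' the larger of the two directed maximum nearest-vertex distances
#' (symmetric). Both meshes must be slice-structured tubes (the slab-wise
#' voxelisation caps them implicitly).
#'
#' @param a moving/deformed [surface_mesh].
#' @param b fixed/reference [surface_mesh].
#' @param voxel_mm voxel edge for DC/PE (default 1 mm).
#' @return list with elements `DC`, `PE`, `VVD`, `HD`.
#' @export
compute_metrics <- function(a, b, voxel_mm = 1) {
  stopifnot(inherits(a, "surface_mesh"), inherits(b, "surface_mesh"))
  bb <- rbind(apply(rbind(a$vertices, b$vertices), 2, min) - 2 * voxel_mm,
              apply(rbind(a$vertices, b$vertices), 2, max) + 2 * voxel_mm)
  va <- voxelize_tube(a, voxel_mm, bb)
  vb <- voxelize_tube(b, voxel_mm, bb)
  inter <- sum(va & vb)
  na <- sum(va); nb <- sum(vb)
  dc <- if (na + nb > 0) 2 * inter / (na + nb) else 1
  pe <- if (nb > 0) (sum(va | vb) - inter) / nb else 0
  vvd <- mean_nn_dist(a$vertices, b$vertices)
  hd <- max(max_nn_dist(a$vertices, b$vertices),
            max_nn_dist(b$vertices, a$vertices))
  list(DC = dc, PE = pe, VVD = vvd, HD = hd)
}

#' Voxelise the volume enclosed by a slice-structured tube mesh
#'
#' For each voxel-centre z-plane within the tube's extent the bracketing
#' slice rings are linearly interpolated (corresponding points) into a
#' polygon and voxel centres are classified by even-odd ray crossing.
#'
#' @param mesh a slice-structured [surface_mesh].
#' @param voxel_mm isotropic voxel edge.
#' @param bbox optional 2 x 3 matrix (min row, max row) defining the grid.
#' @return logical 3D array of inside voxels.
#' @export
voxelize_tube <- function(mesh, voxel_mm = 1, bbox = NULL) {
  if (is.null(mesh$n_ring) || is.null(mesh$vertex_slice)) {
    stopf("voxelize_tube requires a slice-structured tube mesh (cannot cap)")
  }
  n <- mesh$n_ring
  ns <- nrow(mesh$vertices) / n
  if (is.null(bbox)) {
    bbox <- rbind(apply(mesh$vertices, 2, min) - 2 * voxel_mm,
                  apply(mesh$vertices, 2, max) + 2 * voxel_mm)
  }
  xs <- seq(bbox[1, 1] + voxel_mm / 2, bbox[2, 1], by = voxel_mm)
  ys <- seq(bbox[1, 2] + voxel_mm / 2, bbox[2, 2], by = voxel_mm)
  zs <- seq(bbox[1, 3] + voxel_mm / 2, bbox[2, 3], by = voxel_mm)
  zsl <- mesh$vertices[seq(1, nrow(mesh$vertices), by = n), 3]
  out <- array(FALSE, c(length(xs), length(ys), length(zs)))
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  for (k in seq_along(zs)) {
    z <- zs[k]
    if (z < min(zsl) || z > max(zsl)) next
    i <- findInterval(z, zsl, rightmost.closed = TRUE)
    i <- min(max(i, 1L), ns - 1L)
    t <- (z - zsl[i]) / (zsl[i + 1] - zsl[i])
    r0 <- mesh$vertices[((i - 1L) * n + 1L):(i * n), 1:2, drop = FALSE]
    r1 <- mesh$vertices[(i * n + 1L):((i + 1L) * n), 1:2, drop = FALSE]
    poly <- (1 - t) * r0 + t * r1
    inside <- points_in_polygon(gx, gy, poly)
    out[, , k] <- matrix(inside, length(xs), length(ys))
  }
  out
}

# Even-odd crossing-number point-in-polygon test, vectorised over points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    xi <- poly[k, 1]; yi <- poly[k, 2]
    xj <- poly[j[k], 1]; yj <- poly[j[k], 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}
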