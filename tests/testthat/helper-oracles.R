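# Independent brute-force oracles. These deliberately re-derive quantities
# with the plainest possible code (scalar loops, explicit enumeration) and
# stay independent of the package's vectorised implementations.

# Trilinear interpolation of one point in a dose grid, scalar arithmetic.
oracle_trilinear <- function(p, values, origin, spacing) {
  dims <- dim(values)
  fc <- (p - origin) / spacing + 1
  fc <- pmin(pmax(fc, 1), dims)
  i0 <- pmin(pmax(floor(fc), 1), pmax(dims - 1, 1))
  t <- fc - i0
  t[dims == 1] <- 0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) t[1] else 1 - t[1]) *
         (if (dy) t[2] else 1 - t[2]) *
         (if (dz) t[3] else 1 - t[3])
    acc <- acc + w * values[min(i0[1] + dx, dims[1]),
                            min(i0[2] + dy, dims[2]),
                            min(i0[3] + dz, dims[3])]
  }
  acc
}

# O(n^2) pairwise AUC: fraction of (positive, negative) pairs correctly
# ordered, ties half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney p-value by full enumeration of group
# assignments (wilcox.test's two-sided convention: 2 * min tail, capped).
oracle_mwu_exact <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(x), n1)
  ustat <- function(sel) {
    g1 <- x[sel]; g0 <- x[-sel]
    s <- 0
    for (u in g1) for (v in g0) s <- s + (u > v) + 0.5 * (u == v)
    s
  }
  u_obs <- ustat(seq_len(n1))
  us <- apply(idx, 2, ustat)
  pl <- mean(us <= u_obs)
  pu <- mean(us >= u_obs)
  min(1, 2 * min(pl, pu))
}

# Voxel-count Dice using a per-voxel winding-number point-in-polygon test
# (different algorithm from the package's even-odd crossing test).
oracle_winding_inside <- function(px, py, poly) {
  n <- nrow(poly)
  ang <- 0
  for (k in seq_len(n)) {
    j <- if (k == n) 1L else k + 1L
    v1 <- poly[k, ] - c(px, py)
    v2 <- poly[j, ] - c(px, py)
    ang <- ang + atan2(v1[1] * v2[2] - v1[2] * v2[1], sum(v1 * v2))
  }
  abs(ang) > pi
}

oracle_voxelize <- function(mesh, voxel, bbox) {
  n <- mesh$n_ring
  ns <- nrow(mesh$vertices) / n
  zsl <- mesh$vertices[seq(1, nrow(mesh$vertices), by = n), 3]
  xs <- seq(bbox[1, 1] + voxel / 2, bbox[2, 1], by = voxel)
  ys <- seq(bbox[1, 2] + voxel / 2, bbox[2, 2], by = voxel)
  zs <- seq(bbox[1, 3] + voxel / 2, bbox[2, 3], by = voxel)
  out <- array(FALSE, c(length(xs), length(ys), length(zs)))
  for (k in seq_along(zs)) {
    z <- zs[k]
    if (z < min(zsl) || z > max(zsl)) next
    i <- min(max(findInterval(z, zsl, rightmost.closed = TRUE), 1L), ns - 1L)
    t <- (z - zsl[i]) / (zsl[i + 1] - zsl[i])
    r0 <- mesh$vertices[((i - 1) * n + 1):(i * n), 1:2]
    r1 <- mesh$vertices[(i * n + 1):((i + 1) * n), 1:2]
    poly <- (1 - t) * r0 + t * r1
    for (a in seq_along(xs)) for (b in seq_along(ys)) {
      out[a, b, k] <- oracle_winding_inside(xs[a], ys[b], poly)
    }
  }
  out
}

# ---- texture oracles: matrices by explicit per-pixel enumeration ----

oracle_glcm <- function(lev, n_levels) {
  dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  mats <- list()
  for (d in dirs) {
    P <- matrix(0, n_levels, n_levels)
    for (r in seq_len(nrow(lev))) for (c3 in seq_len(ncol(lev))) {
      r2 <- r + d[1]; c2 <- c3 + d[2]
      if (r2 < 1 || r2 > nrow(lev) || c2 < 1 || c2 > ncol(lev)) next
      a <- lev[r, c3]; b <- lev[r2, c2]
      if (is.na(a) || is.na(b)) next
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
    if (sum(P) > 0) P <- P / sum(P)
    mats[[length(mats) + 1]] <- P
  }
  Reduce(`+`, mats) / length(mats)
}

oracle_glcm_features <- function(lev, n_levels) {
  P <- oracle_glcm(lev, n_levels)
  ng <- n_levels
  energy <- 0; contrast <- 0; hom <- 0; ent <- 0; dis <- 0; autoc <- 0
  sumavg <- 0
  px <- rowSums(P)
  mu <- 0
  for (i in 1:ng) mu <- mu + i * px[i]
  sig2 <- 0
  for (i in 1:ng) sig2 <- sig2 + (i - mu)^2 * px[i]
  varr <- 0; corr_num <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    energy <- energy + p^2
    contrast <- contrast + (i - j)^2 * p
    hom <- hom + p / (1 + abs(i - j))
    if (p > 0) ent <- ent - p * log2(p)
    dis <- dis + abs(i - j) * p
    autoc <- autoc + i * j * p
    sumavg <- sumavg + (i + j) * p
    varr <- varr + (i - mu)^2 * p
    corr_num <- corr_num + (i - mu) * (j - mu) * p
  }
  corr <- if (sig2 < 1e-24) 0 else corr_num / sig2
  c(glcm_energy = energy, glcm_contrast = contrast, glcm_correlation = corr,
    glcm_homogeneity = hom, glcm_entropy = ent, glcm_variance = varr,
    glcm_sum_average = sumavg, glcm_dissimilarity = dis,
    glcm_autocorrelation = autoc)
}

# Runs found by per-pixel scanning: a pixel starts a run if its predecessor
# along the direction is absent/invalid/different.
oracle_glrlm_matrix <- function(lev, n_levels, max_len) {
  dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  R <- matrix(0, n_levels, max_len)
  inb <- function(r, c3) r >= 1 && r <= nrow(lev) && c3 >= 1 && c3 <= ncol(lev)
  val <- function(r, c3) if (inb(r, c3)) lev[r, c3] else NA
  for (d in dirs) {
    for (r in seq_len(nrow(lev))) for (c3 in seq_len(ncol(lev))) {
      v <- lev[r, c3]
      if (is.na(v)) next
      pv <- val(r - d[1], c3 - d[2])
      if (!is.na(pv) && pv == v) next  # not a run start
      len <- 1
      rr <- r + d[1]; cc <- c3 + d[2]
      while (!is.na(val(rr, cc)) && val(rr, cc) == v) {
        len <- len + 1
        rr <- rr + d[1]; cc <- cc + d[2]
      }
      R[v, len] <- R[v, len] + 1
    }
  }
  R
}

# Zones by per-pixel label propagation (iterative relabelling, no queue).
oracle_glszm_matrix <- function(lev, n_levels) {
  nr <- nrow(lev); nc <- ncol(lev)
  lab <- matrix(seq_len(nr * nc), nr, nc)
  lab[is.na(lev)] <- NA
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c3 in seq_len(nc)) {
      if (is.na(lev[r, c3])) next
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c3 + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (is.na(lev[rr, cc]) || lev[rr, cc] != lev[r, c3]) next
        if (lab[rr, cc] < lab[r, c3]) {
          lab[r, c3] <- lab[rr, cc]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  ids <- unique(lab[!is.na(lab)])
  sizes <- integer(0); lvs <- integer(0)
  for (id in ids) {
    sizes <- c(sizes, sum(lab == id, na.rm = TRUE))
    lvs <- c(lvs, lev[which(lab == id)[1]])
  }
  Z <- matrix(0, n_levels, max(sizes, 1))
  for (q in seq_along(sizes)) Z[lvs[q], sizes[q]] <- Z[lvs[q], sizes[q]] + 1
  Z
}

oracle_rl_features <- function(R, n_valid, prefix, cn) {
  Nr <- sum(R)
  vals <- numeric(13)
  mu_i <- 0; mu_l <- 0
  for (i in seq_len(nrow(R))) for (l in seq_len(ncol(R))) {
    mu_i <- mu_i + i * R[i, l] / Nr
    mu_l <- mu_l + l * R[i, l] / Nr
  }
  for (i in seq_len(nrow(R))) for (l in seq_len(ncol(R))) {
    rr <- R[i, l]
    vals[1] <- vals[1] + rr / l^2
    vals[2] <- vals[2] + rr * l^2
    vals[6] <- vals[6] + rr / i^2
    vals[7] <- vals[7] + rr * i^2
    vals[8] <- vals[8] + rr / (i^2 * l^2)
    vals[9] <- vals[9] + rr * i^2 / l^2
    vals[10] <- vals[10] + rr * l^2 / i^2
    vals[11] <- vals[11] + rr * i^2 * l^2
    vals[12] <- vals[12] + rr / Nr * (i - mu_i)^2
    vals[13] <- vals[13] + rr / Nr * (l - mu_l)^2
  }
  vals[c(1, 2, 6, 7, 8, 9, 10, 11)] <- vals[c(1, 2, 6, 7, 8, 9, 10, 11)] / Nr
  vals[3] <- sum(rowSums(R)^2) / Nr
  vals[4] <- sum(colSums(R)^2) / Nr
  vals[5] <- Nr / n_valid
  names(vals) <- paste0(prefix, cn)
  vals
}

oracle_ngtdm_features <- function(lev, n_levels) {
  nr <- nrow(lev); nc <- ncol(lev)
  s_i <- numeric(n_levels); n_i <- numeric(n_levels)
  for (r in seq_len(nr)) for (c3 in seq_len(nc)) {
    v <- lev[r, c3]
    if (is.na(v)) next
    nbsum <- 0; nbcnt <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c3 + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (is.na(lev[rr, cc])) next
      nbsum <- nbsum + lev[rr, cc]; nbcnt <- nbcnt + 1
    }
    if (nbcnt == 0) next
    n_i[v] <- n_i[v] + 1
    s_i[v] <- s_i[v] + abs(v - nbsum / nbcnt)
  }
  N <- sum(n_i)
  p_i <- n_i / N
  act <- which(p_i > 0)
  eps <- 1e-12
  coars <- 1 / (eps + sum(p_i * s_i))
  contr <- 0; busy_den <- 0; compl <- 0; stren <- 0
  if (length(act) > 1) {
    for (i in act) for (j in act) {
      contr <- contr + p_i[i] * p_i[j] * (i - j)^2
      busy_den <- busy_den + abs(i * p_i[i] - j * p_i[j])
      compl <- compl + abs(i - j) * (p_i[i] * s_i[i] + p_i[j] * s_i[j]) /
        (p_i[i] + p_i[j])
      stren <- stren + (p_i[i] + p_i[j]) * (i - j)^2
    }
    contr <- contr / (length(act) * (length(act) - 1)) * sum(s_i) / N
    compl <- compl / N
    stren <- stren / (eps + sum(s_i))
  }
  busy <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
  c(ngtdm_coarseness = coars, ngtdm_contrast = contr, ngtdm_busyness = busy,
    ngtdm_complexity = compl, ngtdm_strength = stren)
}

oracle_first_order <- function(v) {
  m <- sum(v) / length(v)
  m2 <- sum((v - m)^2) / length(v)
  sk <- if (m2 < 1e-24) 0 else (sum((v - m)^3) / length(v)) / m2^1.5
  c(fo_mean = m, fo_sd = sqrt(sum((v - m)^2) / (length(v) - 1)),
    fo_skewness = sk)
}

# All 43 texture features via the oracles above.
oracle_texture_features <- function(map, n_levels = 32) {
  lev <- quantize(map, n_levels)
  nl <- max(lev, na.rm = TRUE)
  n_valid <- sum(!is.na(lev))
  R <- oracle_glrlm_matrix(lev, nl, max(dim(lev)))
  Z <- oracle_glszm_matrix(lev, nl)
  c(oracle_first_order(map$dose[map$mask]),
    oracle_glcm_features(lev, nl),
    oracle_rl_features(R, n_valid * 4, "glrlm_",
                       c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                         "srlge", "srhge", "lrlge", "lrhge", "glv", "rlv")),
    oracle_rl_features(Z, n_valid, "glszm_",
                       c("sae", "lae", "gln", "szn", "zp", "lgze", "hgze",
                         "szlge", "szhge", "lzlge", "lzhge", "glv", "zsv")),
    oracle_ngtdm_features(lev, nl))
}
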