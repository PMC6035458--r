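# Gray-level texture features on the RSDM. All matrices honour the validity
# mask: masked pixels never enter a co-occurrence pair, run, zone or
# neighbourhood. Quantization is range-relative, so every matrix-based
# feature is invariant to adding a constant dose offset.

#' Quantize an RSDM into integer gray levels
#'
#' Equal-width bins over the `[min, max]` dose range of valid pixels. A
#' constant map maps to a single level 1.
#'
#' @param map an `rsdm`.
#' @param n_levels number of gray levels (default 32).
#' @return integer matrix of levels in `1..n_levels`, `NA` outside the mask.
#' @export
quantize <- function(map, n_levels = 32) {
  stopifnot(inherits(map, "rsdm"))
  if (n_levels < 2) stopf("n_levels must be >= 2")
  v <- map$dose
  v[!map$mask] <- NA_real_
  mn <- min(v, na.rm = TRUE); mx <- max(v, na.rm = TRUE)
  if (mx - mn < 1e-12) {
    lev <- ifelse(map$mask, 1L, NA_integer_)
    dim(lev) <- dim(v)
    return(lev)
  }
  lev <- floor((v - mn) / (mx - mn) * n_levels) + 1L
  lev[lev > n_levels] <- as.integer(n_levels)
  storage.mode(lev) <- "integer"
  lev
}

#' First-order dose statistics over the valid map region
#'
#' @param map an `rsdm`.
#' @return named vector: `fo_mean`, `fo_sd` (sample), `fo_skewness`
#'   (population moment ratio `m3 / m2^1.5`, 0 for a constant map).
#' @export
first_order <- function(map) {
  stopifnot(inherits(map, "rsdm"))
  v <- map$dose[map$mask]
  if (length(v) < 2) stopf("fewer than 2 valid pixels")
  m2 <- mean((v - mean(v)) ^ 2)
  sk <- if (m2 < 1e-24) 0 else mean((v - mean(v)) ^ 3) / m2 ^ 1.5
  c(fo_mean = mean(v), fo_sd = stats::sd(v), fo_skewness = sk)
}

# The four distance-1 direction offsets (row, col): 0, 45, 90, 135 degrees.
texture_directions <- function() {
  list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
}

#' Gray-level co-occurrence matrix for one direction
#'
#' Symmetric (both orderings counted), distance 1; pairs touching a masked
#' pixel are excluded. Returned matrix is normalised to sum 1.
#'
#' @param levels quantized level matrix (`NA` = invalid).
#' @param direction integer `(row, col)` offset.
#' @param n_levels number of levels (default `max(levels)`).
#' @export
glcm_matrix <- function(levels, direction, n_levels = max(levels, na.rm = TRUE)) {
  nr <- nrow(levels); nc <- ncol(levels)
  dr <- direction[1]; dc <- direction[2]
  r0 <- seq_len(nr); c0 <- seq_len(nc)
  rs <- r0[r0 + dr >= 1 & r0 + dr <= nr]
  cs <- c0[c0 + dc >= 1 & c0 + dc <= nc]
  P <- matrix(0, n_levels, n_levels)
  if (length(rs) && length(cs)) {
    a <- levels[rs, cs, drop = FALSE]
    b <- levels[rs + dr, cs + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      tab <- table(factor(a[ok], levels = seq_len(n_levels)),
                   factor(b[ok], levels = seq_len(n_levels)))
      P <- P + tab + t(tab)
    }
  }
  if (sum(P) > 0) P <- P / sum(P)
  unname(P)
}

#' Nine GLCM texture features
#'
#' The normalised symmetric GLCMs of the four distance-1 directions are
#' averaged and nine features computed: energy, contrast, correlation,
#' homogeneity, entropy (log2), variance, sum-average, dissimilarity,
#' autocorrelation. Correlation of a single-level map is defined as 0.
#'
#' @param levels quantized level matrix (`NA` = invalid).
#' @param directions list of `(row, col)` offsets (default the four standard
#'   directions).
#' @param n_levels number of levels.
#' @export
glcm_features <- function(levels, directions = texture_directions(),
                          n_levels = max(levels, na.rm = TRUE)) {
  if (sum(!is.na(levels)) < 2) stopf("fewer than 2 valid pixels")
  mats <- lapply(directions, glcm_matrix, levels = levels, n_levels = n_levels)
  P <- Reduce(`+`, mats) / length(mats)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(seq_len(n_levels) * px)
  sig2 <- sum((seq_len(n_levels) - mu) ^ 2 * px)
  corr <- if (sig2 < 1e-24) 0 else sum((i - mu) * (j - mu) * P) / sig2
  pnz <- P[P > 0]
  c(glcm_energy = sum(P ^ 2),
    glcm_contrast = sum((i - j) ^ 2 * P),
    glcm_correlation = corr,
    glcm_homogeneity = sum(P / (1 + abs(i - j))),
    glcm_entropy = -sum(pnz * log2(pnz)),
    glcm_variance = sum((i - mu) ^ 2 * P),
    glcm_sum_average = sum((i + j) * P),
    glcm_dissimilarity = sum(abs(i - j) * P),
    glcm_autocorrelation = sum(i * j * P))
}

# Extract the maximal lines of a matrix along a direction as value vectors;
# NA (masked) entries break runs naturally.
direction_lines <- function(levels, direction) {
  nr <- nrow(levels); nc <- ncol(levels)
  dr <- direction[1]; dc <- direction[2]
  if (dr == 0L) {
    lapply(seq_len(nr), function(r) levels[r, ])
  } else if (dc == 0L) {
    lapply(seq_len(nc), function(c3) levels[, c3])
  } else {
    # diagonals: group cells by col - dc/dr * row equivalence
    key <- if (dr * dc > 0) col(levels) - row(levels) else col(levels) + row(levels)
    ord <- order(key, row(levels) * sign(dr))
    ks <- key[ord]
    vals <- levels[ord]
    split(vals, ks)
  }
}

run_length_matrix <- function(levels, n_levels, max_len) {
  R <- matrix(0, n_levels, max_len)
  for (dir in texture_directions()) {
    for (ln in direction_lines(levels, dir)) {
      r <- rle(as.vector(ln))
      keep <- !is.na(r$values)
      if (!any(keep)) next
      lv <- r$values[keep]; le <- r$lengths[keep]
      for (q in seq_along(lv)) {
        R[lv[q], le[q]] <- R[lv[q], le[q]] + 1
      }
    }
  }
  R
}

# Shared formulas for run-length and size-zone style matrices: rows = gray
# level, cols = run length / zone size, entries = counts.
rl_style_features <- function(R, n_valid, prefix, col_names) {
  Nr <- sum(R)
  if (Nr == 0) stopf("empty texture matrix")
  i <- row(R); l <- col(R)
  p <- R / Nr
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  vals <- c(sum(R / l ^ 2) / Nr,                 # short emphasis
            sum(R * l ^ 2) / Nr,                 # long emphasis
            sum(rowSums(R) ^ 2) / Nr,            # gray-level non-uniformity
            sum(colSums(R) ^ 2) / Nr,            # length non-uniformity
            Nr / n_valid,                        # run/zone percentage
            sum(R / i ^ 2) / Nr,                 # low gray-level emphasis
            sum(R * i ^ 2) / Nr,                 # high gray-level emphasis
            sum(R / (i ^ 2 * l ^ 2)) / Nr,       # short low gray-level
            sum(R * i ^ 2 / l ^ 2) / Nr,         # short high gray-level
            sum(R * l ^ 2 / i ^ 2) / Nr,         # long low gray-level
            sum(R * i ^ 2 * l ^ 2) / Nr,         # long high gray-level
            sum(p * (i - mu_i) ^ 2),             # gray-level variance
            sum(p * (l - mu_l) ^ 2))             # length/size variance
  names(vals) <- paste0(prefix, col_names)
  vals
}

#' Thirteen GLRLM texture features
#'
#' Runs of equal gray level along the four standard directions, broken by
#' masked pixels and the map border; counts from all directions are pooled
#' into a single run-length matrix. The run percentage denominator is the
#' number of valid pixels times the number of directions.
#'
#' @inheritParams glcm_features
#' @export
glrlm_features <- function(levels, n_levels = max(levels, na.rm = TRUE)) {
  n_valid <- sum(!is.na(levels))
  if (n_valid < 2) stopf("fewer than 2 valid pixels")
  R <- run_length_matrix(levels, n_levels, max_len = max(dim(levels)))
  rl_style_features(R, n_valid * length(texture_directions()), "glrlm_",
                    c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                      "srlge", "srhge", "lrlge", "lrhge", "glv", "rlv"))
}

# 8-connected components of equal gray level within the mask.
size_zone_matrix <- function(levels, n_levels) {
  nr <- nrow(levels); nc <- ncol(levels)
  lab <- matrix(0L, nr, nc)
  sizes <- integer(0)
  zlev <- integer(0)
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  nxt <- 0L
  for (start in which(!is.na(levels))) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    lv <- levels[start]
    queue <- start
    lab[start] <- nxt
    sz <- 0L
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      sz <- sz + 1L
      r <- (cur - 1L) %% nr + 1L
      c3 <- (cur - 1L) %/% nr + 1L
      rr <- r + nb$dr; cc <- c3 + nb$dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      cand <- (cc[ok] - 1L) * nr + rr[ok]
      cand <- cand[!is.na(levels[cand]) & levels[cand] == lv & lab[cand] == 0L]
      if (length(cand)) {
        lab[cand] <- nxt
        queue <- c(queue, cand)
      }
    }
    sizes <- c(sizes, sz)
    zlev <- c(zlev, lv)
  }
  max_sz <- max(sizes, 1L)
  Z <- matrix(0, n_levels, max_sz)
  for (q in seq_along(sizes)) {
    Z[zlev[q], sizes[q]] <- Z[zlev[q], sizes[q]] + 1
  }
  Z
}

#' Thirteen GLSZM texture features
#'
#' Zones are 8-connected components of equal gray level within the mask; the
#' same thirteen emphasis/non-uniformity/variance formulas as the GLRLM are
#' applied to the zone-size matrix. The zone percentage denominator is the
#' number of valid pixels.
#'
#' @inheritParams glcm_features
#' @export
glszm_features <- function(levels, n_levels = max(levels, na.rm = TRUE)) {
  n_valid <- sum(!is.na(levels))
  if (n_valid < 2) stopf("fewer than 2 valid pixels")
  Z <- size_zone_matrix(levels, n_levels)
  rl_style_features(Z, n_valid, "glszm_",
                    c("sae", "lae", "gln", "szn", "zp", "lgze", "hgze",
                      "szlge", "szhge", "lzlge", "lzhge", "glv", "zsv"))
}

#' Five NGTDM texture features
#'
#' Neighbourhood gray-tone difference matrix over the 8-neighbourhood,
#' masked pixels excluded from both the centre set and the neighbourhood
#' averages: coarseness, contrast, busyness, complexity, strength
#' (Amadasun-King conventions; single-level maps give contrast = busyness =
#' complexity = strength = 0 and a large finite coarseness).
#'
#' @inheritParams glcm_features
#' @export
ngtdm_features <- function(levels, n_levels = max(levels, na.rm = TRUE)) {
  nr <- nrow(levels); nc <- ncol(levels)
  if (sum(!is.na(levels)) < 2) stopf("fewer than 2 valid pixels")
  pad <- matrix(NA_integer_, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- levels
  nb_sum <- matrix(0, nr, nc)
  nb_cnt <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE]
    hit <- !is.na(sh)
    nb_sum[hit] <- nb_sum[hit] + sh[hit]
    nb_cnt <- nb_cnt + hit
  }
  use <- !is.na(levels) & nb_cnt > 0
  A <- nb_sum[use] / nb_cnt[use]
  lv <- levels[use]
  N <- length(lv)
  n_i <- tabulate(lv, nbins = n_levels)
  s_i <- numeric(n_levels)
  dev <- abs(lv - A)
  acc <- tapply(dev, lv, sum)
  s_i[as.integer(names(acc))] <- as.numeric(acc)
  p_i <- n_i / N
  act <- which(p_i > 0)
  Ngp <- length(act)
  eps <- 1e-12
  coarseness <- 1 / (eps + sum(p_i * s_i))
  if (Ngp > 1) {
    ii <- rep(act, each = Ngp); jj <- rep(act, times = Ngp)
    pij2 <- p_i[ii] * p_i[jj] * (ii - jj) ^ 2
    contrast <- sum(pij2) / (Ngp * (Ngp - 1)) * sum(s_i) / N
    busy_den <- sum(abs(ii * p_i[ii] - jj * p_i[jj]))
    busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
    complexity <- sum(abs(ii - jj) * (p_i[ii] * s_i[ii] + p_i[jj] * s_i[jj]) /
                        (p_i[ii] + p_i[jj])) / N
    strength <- sum((p_i[ii] + p_i[jj]) * (ii - jj) ^ 2) / (eps + sum(s_i))
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}

#' All 43 texture features of an RSDM
#'
#' 3 first-order + 9 GLCM + 13 GLRLM + 13 GLSZM + 5 NGTDM. First-order
#' statistics use the raw dose; matrix features use the range-relative
#' quantization of [quantize].
#'
#' @param map an `rsdm`.
#' @param n_levels quantization depth (default 32).
#' @return named numeric vector of length 43.
#' @export
texture_features <- function(map, n_levels = 32) {
  lev <- quantize(map, n_levels)
  nl <- max(lev, na.rm = TRUE)
  c(first_order(map),
    glcm_features(lev, n_levels = nl),
    glrlm_features(lev, n_levels = nl),
    glszm_features(lev, n_levels = nl),
    ngtdm_features(lev, n_levels = nl))
}
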