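#' PCA representative features (F_PCA)
#'
#' Features are z-scored (constant features dropped with a warning), PCA is
#' applied, and the scores of the smallest number of leading components whose
#' cumulative explained variance exceeds `variance_threshold` are returned.
#'
#' @param table a [feature_table].
#' @param variance_threshold cumulative explained-variance cut (default
#'   0.99).
#' @return matrix of component scores (patients x n); attributes
#'   `n_components`, `explained_variance`, `dropped` (constant features).
#' @export
pca_features <- function(table, variance_threshold = 0.99) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$features
  if (nrow(X) < 2) stopf("PCA needs at least 2 patients")
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds < 1e-12]
  if (length(dropped)) {
    warnf("pca_features: dropping %d constant feature(s)", length(dropped))
    X <- X[, sds >= 1e-12, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev ^ 2 / sum(pc$sdev ^ 2)
  cum <- cumsum(ev)
  n <- which(cum > variance_threshold)[1]
  if (is.na(n)) n <- length(ev)
  n <- max(n, 1L)
  scores <- pc$x[, seq_len(n), drop = FALSE]
  attr(scores, "n_components") <- n
  attr(scores, "explained_variance") <- ev
  attr(scores, "dropped") <- dropped
  scores
}

#' Mann-Whitney U screening of significant features (F_sta)
#'
#' Per feature, a two-sided Mann-Whitney U (Wilcoxon rank-sum) test between
#' the toxicity and non-toxicity groups. The exact distribution is used when
#' both groups have at most `exact_max` patients and the feature is tie-free;
#' otherwise the normal approximation with tie and continuity correction.
#' Raw (unadjusted) p-values are reported and features with `p < alpha` are
#' selected; an optional `adjust` applies Bonferroni or BH before selection.
#'
#' @param table a [feature_table].
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default, matching the exploratory raw-p design),
#'   `"bonferroni"` or `"BH"`.
#' @param exact_max exact-test group-size cutoff (default 10).
#' @return a `screen_result` data.frame: `feature`, `family`, `p`,
#'   `p_adjusted`, `selected`.
#' @export
mwu_screen <- function(table, alpha = 0.05,
                       adjust = c("none", "bonferroni", "BH"),
                       exact_max = 10) {
  stopifnot(inherits(table, "feature_table"))
  adjust <- match.arg(adjust)
  y <- table$labels
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stopf("each class needs at least 2 patients")
  }
  X <- table$features
  g1 <- X[y == 1, , drop = FALSE]
  g0 <- X[y == 0, , drop = FALSE]
  p <- vapply(seq_len(ncol(X)), function(j) {
    a <- g1[, j]; b <- g0[, j]
    if (max(c(a, b)) - min(c(a, b)) < 1e-15) return(1)
    exact <- length(a) <= exact_max && length(b) <= exact_max &&
      !anyDuplicated(c(a, b))
    suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                        correct = TRUE)$p.value)
  }, numeric(1))
  p_adj <- switch(adjust,
                  none = p,
                  bonferroni = pmin(1, p * length(p)),
                  BH = stats::p.adjust(p, "BH"))
  res <- data.frame(feature = colnames(X),
                    family = feature_family(colnames(X)),
                    p = p, p_adjusted = p_adj,
                    selected = p_adj < alpha,
                    stringsAsFactors = FALSE)
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Subset a feature table to the screened features
#' @param table a [feature_table].
#' @param screen a `screen_result` from [mwu_screen].
#' @export
screened_table <- function(table, screen) {
  keep <- screen$feature[screen$selected]
  if (length(keep) == 0) stopf("no features passed screening")
  feature_table(table$features[, keep, drop = FALSE], table$labels,
                table$patient_ids)
}
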