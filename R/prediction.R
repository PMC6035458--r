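#' Synthetic minority over-sampling (SMOTE)
#'
#' Each synthetic sample is `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)` and
#' `x_nn` one of the `k` nearest minority-class neighbours of `x`. Base
#' samples are cycled deterministically; the neighbour and `u` draws are
#' seeded.
#'
#' @param minority matrix of minority-class samples (n x p, n >= 2).
#' @param k number of nearest neighbours (capped at n - 1).
#' @param n_synthetic number of synthetic samples to generate.
#' @param seed RNG seed.
#' @return matrix of `n_synthetic` synthetic samples.
#' @export
smote <- function(minority, k = 5, n_synthetic, seed = NULL) {
  minority <- as.matrix(minority)
  n <- nrow(minority)
  if (n < 2) stopf("SMOTE needs at least 2 minority samples")
  if (n_synthetic <= 0) return(minority[0, , drop = FALSE])
  k <- min(k, n - 1L)
  d2 <- cross_dist2(minority, minority)
  diag(d2) <- Inf
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) nn[i, ] <- order(d2[i, ])[seq_len(k)]
  with_seed(seed, {
    base <- ((seq_len(n_synthetic) - 1L) %% n) + 1L
    pick <- nn[cbind(base, sample.int(k, n_synthetic, replace = TRUE))]
    u <- runif(n_synthetic)
    minority[base, , drop = FALSE] +
      u * (minority[pick, , drop = FALSE] - minority[base, , drop = FALSE])
  })
}

# Balance a training set by SMOTE-augmenting the minority class to parity.
smote_balance <- function(X, y, k = 5, seed = NULL) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == n0) return(list(X = X, y = y))
  min_lab <- if (n1 < n0) 1L else 0L
  need <- abs(n0 - n1)
  syn <- smote(X[y == min_lab, , drop = FALSE], k = k, n_synthetic = need,
               seed = seed)
  list(X = rbind(X, syn), y = c(y, rep(min_lab, need)))
}

#' Cross-validation / model configuration
#'
#' @param k_folds outer folds (default 5).
#' @param repeats repetitions of the k-fold split (default 100).
#' @param smote_k SMOTE neighbour count (default 5).
#' @param C,gamma SVM hyperparameters ([svm_fit] defaults when `NULL`).
#' @param sfs_tol minimum criterion improvement to accept a feature.
#' @param sfs_max maximum number of selected features (`NULL` = no cap).
#' @param inner_folds folds of the selection criterion CV (default 5).
#' @param seed master seed.
#' @export
cv_config <- function(k_folds = 5, repeats = 100, smote_k = 5, C = 1,
                      gamma = NULL, sfs_tol = 1e-4, sfs_max = 10L,
                      inner_folds = 5, seed = 1L) {
  if (k_folds < 2) stopf("k_folds must be >= 2")
  if (repeats < 1) stopf("repeats must be >= 1")
  structure(list(k_folds = as.integer(k_folds), repeats = as.integer(repeats),
                 smote_k = smote_k, C = C, gamma = gamma, sfs_tol = sfs_tol,
                 sfs_max = if (is.null(sfs_max)) NULL else as.integer(sfs_max),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "cv_config")
}

# Deterministic stratified k-fold assignment (requires seeded RNG state).
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  # re-draw degenerate splits where a fold lacks a class in the training part
  fold
}

# Inner-CV AUC of an SVM on the given feature subset.
inner_cv_auc <- function(X, y, cols, config, seed) {
  folds <- with_seed(seed, stratified_folds(y, config$inner_folds))
  scores <- numeric(length(y))
  for (f in seq_len(config$inner_folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || !any(!tr)) return(NA_real_)
    m <- svm_fit(X[tr, cols, drop = FALSE], y[tr], C = config$C,
                 gamma = config$gamma)
    scores[!tr] <- svm_decision(m, X[!tr, cols, drop = FALSE])
  }
  auc(scores, y)
}

#' Sequential forward feature selection wrapped around the SVM
#'
#' Greedy forward selection: starting from the empty set, at each step the
#' feature whose addition maximises the inner k-fold cross-validated AUC of
#' the SVM is added; selection stops when the best improvement is below
#' `config$sfs_tol`, when `config$sfs_max` features are selected, or when all
#' features are in. Ties break to the lower feature index. The training data
#' are expected to be SMOTE-balanced already when used inside [repeated_cv].
#'
#' @param X training matrix.
#' @param y binary labels.
#' @param config a [cv_config].
#' @param seed RNG seed for the inner folds.
#' @return list with `selected` (column indices, in selection order),
#'   `criterion` (inner AUC sequence) and `model` (final fit on the selected
#'   subset).
#' @export
svm_sfs <- function(X, y, config = cv_config(), seed = config$seed) {
  X <- as.matrix(X)
  if (ncol(X) < 1) stopf("no features to select from")
  if (length(unique(y)) < 2) stopf("both classes must be present")
  selected <- integer(0)
  crit <- -Inf
  crit_seq <- numeric(0)
  remaining <- seq_len(ncol(X))
  max_k <- config$sfs_max %||% ncol(X)
  while (length(remaining) > 0 && length(selected) < max_k) {
    gains <- vapply(remaining, function(j) {
      inner_cv_auc(X, y, c(selected, j), config, seed = derive_seed(seed, j))
    }, numeric(1))
    if (all(is.na(gains))) break
    best <- remaining[which.max(gains)]  # ties: first (lowest index)
    best_crit <- max(gains, na.rm = TRUE)
    if (length(selected) > 0 && best_crit <= crit + config$sfs_tol) break
    selected <- c(selected, best)
    crit <- best_crit
    crit_seq <- c(crit_seq, best_crit)
    remaining <- setdiff(remaining, best)
  }
  if (length(selected) == 0) selected <- 1L
  model <- svm_fit(X[, selected, drop = FALSE], y, C = config$C,
                   gamma = config$gamma)
  list(selected = selected, criterion = crit_seq, model = model)
}

#' Confusion-matrix metrics
#'
#' `ACC = (TP + TN) / (TP + FP + FN + TN)`, `SEN = TP / (TP + FN)`,
#' `SPE = TN / (TN + FP)`. A zero denominator yields `NA` with a warning.
#'
#' @param TP,TN,FP,FN non-negative counts.
#' @return named vector `ACC`, `SEN`, `SPE`.
#' @export
confusion_metrics <- function(TP, TN, FP, FN) {
  if (any(c(TP, TN, FP, FN) < 0)) stopf("counts must be non-negative")
  tot <- TP + TN + FP + FN
  acc <- if (tot > 0) (TP + TN) / tot else NA_real_
  sen <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spe <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  if (any(is.na(c(acc, sen, spe)))) warnf("confusion_metrics: zero denominator")
  c(ACC = acc, SEN = sen, SPE = spe)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC; tied scores count one half. Equals the
#' trapezoidal area under [roc_curve] to numerical precision.
#'
#' @param scores numeric decision scores (larger = more positive).
#' @param labels binary labels.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("AUC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param scores numeric decision scores.
#' @param labels binary labels.
#' @return data.frame with `threshold`, `fpr`, `tpr`, ordered from (0, 0) to
#'   (1, 1).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("ROC needs both classes")
  ths <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(ths, function(t) sum(scores >= t & labels == 1) / n1,
                numeric(1))
  fpr <- vapply(ths, function(t) sum(scores >= t & labels == 0) / n0,
                numeric(1))
  data.frame(threshold = c(Inf, ths), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Repeated stratified k-fold cross-validation of the SMOTE + SVM-SFS scheme
#'
#' For every repeat a stratified split is drawn; in each fold SMOTE balances
#' the training portion only (validation instances are never synthesised or
#' oversampled), feature selection and model fitting run on the balanced
#' training data, and the untouched validation fold is scored. ACC/SEN/SPE
#' use the decision threshold 0; AUC is computed per repeat from the pooled
#' validation scores of its folds. Feature selection frequencies are
#' accumulated over all repeats x folds.
#'
#' @param table a [feature_table] (or a plain matrix plus `labels`).
#' @param labels optional labels when `table` is a matrix.
#' @param config a [cv_config].
#' @return a `prediction_result`: per-repeat metric data.frame, means, AUC
#'   95% CI (percentiles over repeats), pooled scores, and a
#'   `feature_ranking` data.frame of selection frequencies.
#' @export
repeated_cv <- function(table, labels = NULL, config = cv_config()) {
  if (inherits(table, "feature_table")) {
    X <- table$features
    y <- table$labels
  } else {
    X <- as.matrix(table)
    y <- as.integer(labels)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  k <- config$k_folds
  sel_count <- setNames(numeric(ncol(X)), colnames(X))
  per_repeat <- data.frame(repeat_index = seq_len(config$repeats),
                           ACC = NA_real_, SEN = NA_real_, SPE = NA_real_,
                           AUC = NA_real_)
  pooled <- vector("list", config$repeats)
  for (r in seq_len(config$repeats)) {
    rseed <- derive_seed(config$seed, r)
    folds <- NULL
    for (try in 1:20) {  # re-draw until every training part has both classes
      folds <- with_seed(derive_seed(rseed, try), stratified_folds(y, k))
      ok <- all(vapply(seq_len(k), function(f) {
        length(unique(y[folds != f])) == 2 && any(folds == f)
      }, logical(1)))
      if (ok) break
      if (try == 20) stopf("could not draw a valid stratified split")
    }
    scores <- numeric(length(y))
    for (f in seq_len(k)) {
      tr <- folds != f
      bal <- smote_balance(X[tr, , drop = FALSE], y[tr], k = config$smote_k,
                           seed = derive_seed(rseed, 100 + f))
      fit <- svm_sfs(bal$X, bal$y, config, seed = derive_seed(rseed, 200 + f))
      sel_names <- colnames(X)[fit$selected]
      sel_count[sel_names] <- sel_count[sel_names] + 1
      scores[!tr] <- svm_decision(fit$model, X[!tr, fit$selected, drop = FALSE])
    }
    pred <- as.integer(scores > 0)
    cm <- confusion_metrics(TP = sum(pred == 1 & y == 1),
                            TN = sum(pred == 0 & y == 0),
                            FP = sum(pred == 1 & y == 0),
                            FN = sum(pred == 0 & y == 1))
    per_repeat[r, c("ACC", "SEN", "SPE")] <- cm
    per_repeat$AUC[r] <- auc(scores, y)
    pooled[[r]] <- list(scores = scores, labels = y)
  }
  freq <- sel_count / (config$repeats * k)
  ranking <- data.frame(feature = names(freq),
                        family = feature_family(names(freq)),
                        frequency = as.numeric(freq),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$frequency, ranking$feature), ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  structure(list(per_repeat = per_repeat,
                 means = colMeans(per_repeat[, c("ACC", "SEN", "SPE", "AUC")],
                                  na.rm = TRUE),
                 auc_ci = stats::quantile(per_repeat$AUC, c(0.025, 0.975),
                                          names = FALSE),
                 pooled = pooled,
                 ranking = ranking,
                 config = config),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  m <- x$means
  cat(sprintf("<prediction_result> %d x %d-fold CV: ACC %.3f, SEN %.3f, SPE %.3f, AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$config$repeats, x$config$k_folds, m["ACC"], m["SEN"],
              m["SPE"], m["AUC"], x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' Paired comparison of two ROC curves (DeLong Z-test)
#'
#' Both score vectors must be computed on the same instances (paired). The
#' AUC difference is tested with the DeLong placement-based covariance
#' estimate; `z = (AUC_a - AUC_b) / se` and a two-sided normal p-value.
#'
#' @param scores_a,scores_b paired decision scores.
#' @param labels shared binary labels.
#' @return list with `auc_a`, `auc_b`, `z`, `p`.
#' @export
compare_rocs <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels)) {
    stopf("compare_rocs requires paired scores on the same instances")
  }
  pos <- which(labels == 1); neg <- which(labels == 0)
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stopf("both classes required")
  placements <- function(s) {
    # V10[i]: fraction of negatives ranked below positive i (ties half)
    V10 <- vapply(pos, function(i) {
      (sum(s[i] > s[neg]) + 0.5 * sum(s[i] == s[neg])) / n
    }, numeric(1))
    V01 <- vapply(neg, function(j) {
      (sum(s[pos] > s[j]) + 0.5 * sum(s[pos] == s[j])) / m
    }, numeric(1))
    list(V10 = V10, V01 = V01, auc = mean(V10))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$V10, pb$V10))
  s01 <- stats::cov(cbind(pa$V01, pb$V01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (var_diff <= 0) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = p)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`; `m` defaults to the number of p-values.
#'
#' @param pvals numeric p-values.
#' @param m number of comparisons.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  pmin(1, m * pvals)
}
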