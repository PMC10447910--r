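# Classifier selection and evaluation: rank-based AUC with DeLong
# confidence intervals, Youden-optimal operating points, a leave-one-out
# LDA sweep over principal-component counts, and a ten-algorithm bank under
# stratified 10-fold cross-validation. All cross-validated AUCs are computed
# on pooled out-of-fold scores (one score per sample), never averaged over
# per-fold AUCs, so LOOCV and k-fold are treated identically.

check_binary <- function(labels) {
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must be TRUE/FALSE without NA")
  if (!any(labels) || all(labels))
    stop("both classes must be present")
  labels
}

#' Area under the ROC curve
#'
#' The Mann-Whitney pair-counting estimator: the proportion of
#' (positive, negative) pairs in which the positive scores higher, ties
#' counted one half. Computed via midranks.
#'
#' @param scores numeric risk scores (higher = more positive).
#' @param labels logical (or coercible) outcome vector.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_binary(labels)
  stopifnot(length(scores) == length(labels))
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values and variance of the AUC estimator
delong_var <- function(scores, labels) {
  labels <- check_binary(labels)
  x <- scores[labels]; y <- scores[!labels]
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  auc <- mean(psi)
  var <- stats::var(v10) / m + stats::var(v01) / n
  list(auc = auc, var = var)
}

#' DeLong confidence interval for the AUC
#'
#' Normal-approximation interval using the DeLong variance of the
#' Mann-Whitney AUC, truncated to `[0, 1]`. For degenerate data (AUC exactly
#' 0 or 1, zero variance) a point interval is returned with a warning.
#'
#' @inheritParams roc_auc
#' @param level confidence level.
#' @return Named vector `c(low, high)`.
#' @export
auc_ci <- function(scores, labels, level = 0.95) {
  stopifnot(level > 0, level < 1)
  d <- delong_var(scores, labels)
  if (d$var <= 0) {
    warning("degenerate AUC variance; returning a point interval")
    return(c(low = d$auc, high = d$auc))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  hw <- z * sqrt(d$var)
  c(low = max(0, d$auc - hw), high = min(1, d$auc + hw))
}

#' Youden-optimal threshold
#'
#' Maximises sensitivity + specificity - 1 over the observed scores as
#' candidate thresholds (prediction positive when `score >= threshold`).
#' Ties are broken toward higher sensitivity, then toward the lower
#' threshold.
#'
#' @inheritParams roc_auc
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- check_binary(labels)
  thr <- sort(unique(scores))
  pos <- scores[labels]; neg <- scores[!labels]
  sens <- vapply(thr, function(t) mean(pos >= t), 0)
  spec <- vapply(thr, function(t) mean(neg < t), 0)
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-9)   # tolerance so float noise cannot split ties
  best <- best[order(-sens[best], thr[best])][1L]
  list(threshold = thr[best], sensitivity = sens[best],
       specificity = spec[best], youden = J[best])
}

#' Stratified bootstrap CI for sensitivity and specificity
#'
#' Percentile intervals from `n_boot` resamples drawn within each outcome
#' class, evaluated at a fixed threshold.
#'
#' @inheritParams roc_auc
#' @param threshold operating threshold (predict positive at `>=`).
#' @param level confidence level.
#' @param n_boot resamples.
#' @param seed RNG seed for the resampling.
#' @return List with `sensitivity_ci` and `specificity_ci` (low/high).
#' @export
sens_spec_ci <- function(scores, labels, threshold, level = 0.95,
                         n_boot = 2000L, seed = 1L) {
  labels <- check_binary(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  se <- sp <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    se[b] <- mean(sample(pos, replace = TRUE) >= threshold)
    sp[b] <- mean(sample(neg, replace = TRUE) < threshold)
  }
  a <- (1 - level) / 2
  list(sensitivity_ci = stats::quantile(se, c(a, 1 - a), names = FALSE),
       specificity_ci = stats::quantile(sp, c(a, 1 - a), names = FALSE))
}

# LDA with pooled covariance, matching MASS::lda posteriors (priors =
# training class proportions, pooled covariance with divisor n - 2).
# Returns the positive-class posterior for the query rows.
lda_posterior <- function(x_train, y_train, x_new) {
  x_train <- as.matrix(x_train); x_new <- as.matrix(x_new)
  y <- as.logical(y_train)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 < 2L || n0 < 2L) stop("LDA needs at least 2 samples per class")
  mu1 <- colMeans(x_train[y, , drop = FALSE])
  mu0 <- colMeans(x_train[!y, , drop = FALSE])
  S1 <- crossprod(sweep(x_train[y, , drop = FALSE], 2L, mu1))
  S0 <- crossprod(sweep(x_train[!y, , drop = FALSE], 2L, mu0))
  W <- (S1 + S0) / (n1 + n0 - 2L)
  Winv <- solve(W)
  beta <- Winv %*% (mu1 - mu0)
  c0 <- -0.5 * sum((mu1 + mu0) * beta) + log(n1 / n0)
  stats::plogis(drop(x_new %*% beta) + c0)
}

#' Leave-one-out cross-validated LDA scores
#'
#' For each sample, LDA is fitted on all other samples using the first
#' `n_pcs` feature columns and the held-out posterior probability of the
#' positive class is collected. Class means and scatters are downdated per
#' held-out sample rather than refitted, which is exact and fast.
#'
#' @param features n x m numeric matrix (e.g. PC scores).
#' @param labels logical outcome vector.
#' @param n_pcs number of leading columns to use.
#' @return Numeric vector of n pooled out-of-sample scores.
#' @export
loocv_lda_scores <- function(features, labels, n_pcs) {
  labels <- check_binary(labels)
  X <- as.matrix(features)[, seq_len(n_pcs), drop = FALSE]
  n <- nrow(X)
  y <- labels
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 < 2L || n0 < 2L)
    stop("need at least 2 samples per class for LOOCV LDA")
  mu1 <- colMeans(X[y, , drop = FALSE])
  mu0 <- colMeans(X[!y, , drop = FALSE])
  S1 <- crossprod(sweep(X[y, , drop = FALSE], 2L, mu1))
  S0 <- crossprod(sweep(X[!y, , drop = FALSE], 2L, mu0))
  out <- numeric(n)
  for (i in seq_len(n)) {
    xi <- X[i, ]
    if (y[i]) {
      m1 <- (n1 * mu1 - xi) / (n1 - 1L)
      s1 <- S1 - (n1 / (n1 - 1L)) * tcrossprod(xi - mu1)
      m0 <- mu0; s0 <- S0
      k1 <- n1 - 1L; k0 <- n0
    } else {
      m0 <- (n0 * mu0 - xi) / (n0 - 1L)
      s0 <- S0 - (n0 / (n0 - 1L)) * tcrossprod(xi - mu0)
      m1 <- mu1; s1 <- S1
      k1 <- n1; k0 <- n0 - 1L
    }
    W <- (s1 + s0) / (k1 + k0 - 2L)
    beta <- solve(W, m1 - m0)
    c0 <- -0.5 * sum((m1 + m0) * beta) + log(k1 / k0)
    out[i] <- stats::plogis(sum(xi * beta) + c0)
  }
  out
}

#' LOOCV-LDA sweep over principal-component counts
#'
#' For each candidate PC count, computes the pooled leave-one-out LDA
#' scores and a single AUC on them; the selected count is the AUC argmax
#' (smallest count on ties). Counts with `n_pcs >= n - 1` (or exceeding the
#' available columns) are skipped with a warning.
#'
#' @param features n x m matrix of PC scores ([score_table()] columns or
#'   `shape_space$scores`).
#' @param labels logical outcome vector.
#' @param pc_range integer vector of PC counts, by default `1:50`.
#' @return A `sweep_curve` tibble with columns `n_pcs`, `auc`, and
#'   attribute `best_n_pcs`.
#' @export
loocv_sweep <- function(features, labels, pc_range = 1:50) {
  labels <- check_binary(labels)
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 samples")
  keep <- pc_range < n - 1L & pc_range <= ncol(X) & pc_range >= 1L
  if (!all(keep))
    warning("skipping ", sum(!keep), " PC counts not supported by the data")
  pcs <- pc_range[keep]
  auc <- vapply(pcs, function(p)
    roc_auc(loocv_lda_scores(X, labels, p), labels), 0)
  out <- tibble::tibble(n_pcs = as.integer(pcs), auc = auc)
  best <- out$n_pcs[which.max(out$auc)]   # which.max takes the first max
  attr(out, "best_n_pcs") <- best
  class(out) <- c("sweep_curve", class(out))
  out
}

#' Selected PC count of a sweep
#' @param curve a `sweep_curve`.
#' @return Integer.
#' @export
best_n_pcs <- function(curve) attr(curve, "best_n_pcs")

#' Supported classifier names
#' @return Character vector of the ten algorithm identifiers.
#' @export
classifier_names <- function() {
  c("naive_bayes", "lda", "qda", "logistic", "svm", "random_forest",
    "extra_trees", "neural_net", "adaboost", "xgboost")
}

# ---- classifier bank -------------------------------------------------------
# Each entry fits on (x, y) and returns a numeric risk score for newdata.
# Hyperparameters are plain defaults (RBF SVM at unit cost, 500-tree
# forests, one hidden layer of 5 units, 100 boosting rounds); no tuning.

fit_score <- function(algorithm, x, y, x_new, seed) {
  x <- as.matrix(x); x_new <- as.matrix(x_new)
  yf <- factor(y, levels = c(FALSE, TRUE))
  df <- data.frame(x); colnames(df) <- paste0("f", seq_len(ncol(x)))
  dfn <- data.frame(x_new); colnames(dfn) <- colnames(df)
  set.seed(seed)
  switch(algorithm,
    naive_bayes = {
      fit <- e1071::naiveBayes(x, yf)
      stats::predict(fit, x_new, type = "raw")[, "TRUE"]
    },
    lda = lda_posterior(x, y, x_new),
    qda = {
      fit <- MASS::qda(x, grouping = yf)
      stats::predict(fit, x_new)$posterior[, "TRUE"]
    },
    logistic = {
      fit <- suppressWarnings(stats::glm.fit(cbind(1, x), as.numeric(y),
                                             family = stats::binomial()))
      stats::plogis(drop(cbind(1, x_new) %*% fit$coefficients))
    },
    svm = {
      fit <- e1071::svm(x, yf, kernel = "radial", cost = 1,
                        probability = TRUE)
      pr <- stats::predict(fit, x_new, probability = TRUE)
      attr(pr, "probabilities")[, "TRUE"]
    },
    random_forest = {
      fit <- randomForest::randomForest(x, yf, ntree = 500L)
      stats::predict(fit, x_new, type = "prob")[, "TRUE"]
    },
    extra_trees = {
      fit <- ranger::ranger(y = yf, x = df, num.trees = 500L,
                            splitrule = "extratrees", probability = TRUE,
                            num.threads = 1L, seed = seed)
      stats::predict(fit, dfn, num.threads = 1L)$predictions[, "TRUE"]
    },
    neural_net = {
      fit <- nnet::nnet(x, as.numeric(y), size = 5L, decay = 0.01,
                        maxit = 200L, trace = FALSE)
      drop(stats::predict(fit, x_new))
    },
    adaboost = adaboost_score(df, y, dfn),
    xgboost = {
      dtr <- xgboost::xgb.DMatrix(x, label = as.numeric(y))
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3L,
                      eta = 0.3, nthread = 1L),
        data = dtr, nrounds = 100L, verbose = 0)
      stats::predict(fit, xgboost::xgb.DMatrix(x_new))
    },
    stop("unknown algorithm '", algorithm, "'; supported: ",
         paste(classifier_names(), collapse = ", "))
  )
}

# discrete AdaBoost over depth-1 rpart stumps; score mapped through the
# logistic link so it is comparable to the probability outputs
adaboost_score <- function(df, y, dfn, n_rounds = 100L) {
  n <- nrow(df)
  w <- rep(1 / n, n)
  yy <- ifelse(y, 1, -1)
  Fs <- numeric(nrow(dfn))
  d <- df; d$.y <- factor(yy, levels = c(-1, 1))
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = d, weights = w,
                        control = rpart::rpart.control(maxdepth = 1L,
                                                       cp = -1,
                                                       minsplit = 2L,
                                                       xval = 0L))
    h <- ifelse(stats::predict(fit, d, type = "class") == "1", 1, -1)
    err <- sum(w * (h != yy))
    if (err <= 1e-12) { alpha <- 10 }
    else if (err >= 0.5) break
    else alpha <- 0.5 * log((1 - err) / err)
    hn <- ifelse(stats::predict(fit, dfn, type = "class") == "1", 1, -1)
    Fs <- Fs + alpha * hn
    w <- w * exp(-alpha * yy * h)
    w <- w / sum(w)
    if (err <= 1e-12) break
  }
  stats::plogis(2 * Fs)
}

#' Stratified fold assignment
#'
#' Shuffles each class separately (seeded) and deals samples into `k` folds
#' cyclically, so every fold's positive count differs from `n_pos / k` by
#' less than one.
#'
#' @param labels logical outcome vector.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return Integer fold id per sample.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  labels <- check_binary(labels)
  if (length(labels) < k) stop("fewer samples than folds")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in c(TRUE, FALSE)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated classifier bank
#'
#' Runs each requested algorithm under stratified k-fold cross-validation
#' with a fixed seed, pools the out-of-fold scores into one vector per
#' algorithm, and reports AUC with DeLong 95% CI, the Youden-optimal
#' threshold, and sensitivity/specificity with stratified-bootstrap CIs at
#' that threshold.
#'
#' @param features n x m numeric matrix (e.g. leading PC scores).
#' @param labels logical outcome vector.
#' @param algorithms character vector of [classifier_names()] entries, or
#'   `"all"`.
#' @param k folds.
#' @param seed seed controlling fold assignment, stochastic learners, and
#'   bootstrap CIs.
#' @param level confidence level.
#' @param n_boot bootstrap resamples for sensitivity/specificity CIs.
#' @return A `cv_bank` tibble, one row per algorithm, with the pooled
#'   out-of-fold scores in the attribute `scores` (a named list).
#' @export
crossval_bank <- function(features, labels, algorithms = "all", k = 10L,
                          seed = 1L, level = 0.95, n_boot = 2000L) {
  labels <- check_binary(labels)
  X <- as.matrix(features)
  stopifnot(nrow(X) == length(labels), nrow(X) >= k)
  if (identical(algorithms, "all")) algorithms <- classifier_names()
  bad <- setdiff(algorithms, classifier_names())
  if (length(bad))
    stop("unknown algorithm(s) ", paste(bad, collapse = ", "),
         "; supported: ", paste(classifier_names(), collapse = ", "))
  fold <- stratified_folds(labels, k, seed)
  for (f in seq_len(k))
    if (!any(labels[fold != f]) || all(labels[fold != f]))
      stop("a training fold lost a class; reduce k")

  score_list <- list()
  rows <- vector("list", length(algorithms))
  for (a in seq_along(algorithms)) {
    alg <- algorithms[[a]]
    oof <- numeric(length(labels))
    for (f in seq_len(k)) {
      tr <- fold != f
      oof[!tr] <- fit_score(alg, X[tr, , drop = FALSE], labels[tr],
                            X[!tr, , drop = FALSE],
                            seed = seed * 1000L + a * 37L + f)
    }
    auc <- roc_auc(oof, labels)
    ci <- suppressWarnings(auc_ci(oof, labels, level))
    yt <- youden_threshold(oof, labels)
    bs <- sens_spec_ci(oof, labels, yt$threshold, level, n_boot,
                       seed = seed * 1000L + a)
    score_list[[alg]] <- oof
    rows[[a]] <- tibble::tibble(
      algorithm = alg, n_features = ncol(X), folds = as.integer(k),
      auc = auc, auc_ci_low = ci[["low"]], auc_ci_high = ci[["high"]],
      sensitivity = yt$sensitivity,
      sens_ci_low = bs$sensitivity_ci[1L], sens_ci_high = bs$sensitivity_ci[2L],
      specificity = yt$specificity,
      spec_ci_low = bs$specificity_ci[1L], spec_ci_high = bs$specificity_ci[2L],
      threshold = yt$threshold, youden = yt$youden, seed = as.integer(seed))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "scores") <- score_list
  class(out) <- c("cv_bank", class(out))
  out
}

#' Evaluate a fixed risk score against outcomes
#'
#' Computes the same report row as [crossval_bank()] for an externally
#' defined score (e.g. the DIFFMASK clinical score), without any model
#' fitting.
#'
#' @param scores numeric risk scores.
#' @param labels logical outcome vector.
#' @param name label for the report row.
#' @param level confidence level.
#' @param n_boot bootstrap resamples.
#' @param seed seed for the bootstrap.
#' @return A one-row `cv_bank`-style tibble.
#' @export
score_report <- function(scores, labels, name = "score", level = 0.95,
                         n_boot = 2000L, seed = 1L) {
  labels <- check_binary(labels)
  auc <- roc_auc(scores, labels)
  ci <- suppressWarnings(auc_ci(scores, labels, level))
  yt <- youden_threshold(scores, labels)
  bs <- sens_spec_ci(scores, labels, yt$threshold, level, n_boot, seed)
  tibble::tibble(
    algorithm = name, n_features = NA_integer_, folds = NA_integer_,
    auc = auc, auc_ci_low = ci[["low"]], auc_ci_high = ci[["high"]],
    sensitivity = yt$sensitivity,
    sens_ci_low = bs$sensitivity_ci[1L], sens_ci_high = bs$sensitivity_ci[2L],
    specificity = yt$specificity,
    spec_ci_low = bs$specificity_ci[1L], spec_ci_high = bs$specificity_ci[2L],
    threshold = yt$threshold, youden = yt$youden, seed = as.integer(seed))
}
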