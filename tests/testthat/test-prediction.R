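test_that("roc_auc matches the pair-counting definition", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.3, 8), rep(c(FALSE, TRUE), 4)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")

  set.seed(100)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(stats::rnorm(n), 1)      # force ties sometimes
    expect_equal(roc_auc(scores, labels), auc_enum(scores, labels))
    # complement identity
    expect_equal(roc_auc(scores, labels) + roc_auc(-scores, labels), 1)
  }
})

test_that("roc_auc agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- stats::rnorm(60)
  labels <- stats::runif(60) < stats::plogis(scores)
  if (!any(labels) || all(labels)) labels[1:2] <- c(TRUE, FALSE)
  p <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(roc_auc(scores, labels), as.numeric(pROC::auc(p)),
               tolerance = 1e-12)
  ci <- pROC::ci.auc(p, method = "delong")
  expect_equal(unname(auc_ci(scores, labels)),
               c(max(0, ci[1]), min(1, ci[3])), tolerance = 1e-9)
})

test_that("DeLong intervals nest, truncate, and shrink like 1/sqrt(n)", {
  set.seed(9)
  scores <- stats::rnorm(40)
  labels <- stats::runif(40) < stats::plogis(2 * scores)
  if (!any(labels) || all(labels)) labels[1:2] <- c(TRUE, FALSE)
  ci95 <- auc_ci(scores, labels, 0.95)
  ci99 <- auc_ci(scores, labels, 0.99)
  expect_lte(ci99[["low"]], ci95[["low"]])
  expect_gte(ci99[["high"]], ci95[["high"]])

  expect_warning(ci <- auc_ci(c(1, 2, 9, 10), c(0, 0, 1, 1)), "degenerate")
  expect_equal(unname(ci), c(1, 1))

  width_at <- function(n, seed) {
    set.seed(seed)
    s <- c(stats::rnorm(n / 2, 1), stats::rnorm(n / 2, 0))
    l <- rep(c(TRUE, FALSE), each = n / 2)
    diff(auc_ci(s, l))
  }
  w1 <- mean(vapply(1:20, function(s) width_at(60, s), 0))
  w4 <- mean(vapply(1:20, function(s) width_at(240, s), 0))
  expect_equal(w1 / w4, 2, tolerance = 0.25)
})

test_that("youden_threshold matches exhaustive enumeration", {
  got <- youden_threshold(c(0.2, 0.3, 0.7, 0.9), c(0, 0, 1, 1))
  expect_equal(got$sensitivity, 1)
  expect_equal(got$specificity, 1)
  expect_equal(got$threshold, 0.7)

  flat <- youden_threshold(rep(1, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(flat$youden, 0)

  set.seed(11)
  for (i in 1:40) {
    n <- sample(6:14, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    scores <- round(stats::rnorm(n), 1)
    got <- youden_threshold(scores, labels)
    ref <- youden_enum(scores, labels)
    expect_equal(got$youden, ref$j)
    expect_equal(got$sensitivity, ref$sens)
    expect_equal(got$threshold, ref$thr)
  }
})

test_that("LOOCV LDA scores equal explicit per-holdout fits", {
  # 4-sample toy problem, enumerated by hand formulas
  X <- matrix(c(0.1, 0.3, 1.2, 1.0, 0.5, -0.2, 0.7, 0.2), 4)
  y <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(loocv_lda_scores(X, y, 1L), loocv_enum(X, y, 1L),
               tolerance = 1e-9)

  # larger random problems, against both the hand oracle and MASS
  set.seed(14)
  for (i in 1:5) {
    n <- sample(8:12, 1)
    X <- matrix(stats::rnorm(n * 3), n)
    y <- c(TRUE, TRUE, FALSE, FALSE,
           sample(c(TRUE, FALSE), n - 4, replace = TRUE))
    got <- loocv_lda_scores(X, y, 2L)
    expect_equal(got, loocv_enum(X, y, 2L), tolerance = 1e-9)
    mass <- vapply(seq_len(n), function(j) {
      fit <- MASS::lda(X[-j, 1:2, drop = FALSE], grouping = factor(y[-j]))
      stats::predict(fit, X[j, 1:2, drop = FALSE])$posterior[, "TRUE"]
    }, 0)
    expect_equal(got, unname(mass), tolerance = 1e-6)
  }
})

test_that("the LOOCV sweep flags unusable PC counts and picks the argmax", {
  set.seed(20)
  n <- 30
  X <- matrix(stats::rnorm(n * 6), n)
  signal <- X[, 1] * 2
  y <- stats::runif(n) < stats::plogis(signal)
  if (!any(y) || all(y)) y[1:2] <- c(TRUE, FALSE)
  expect_warning(curve <- loocv_sweep(X, y, pc_range = 1:10), "skipping")
  expect_true(all(curve$n_pcs <= 6L))
  expect_equal(best_n_pcs(curve), curve$n_pcs[which.max(curve$auc)])
})

test_that("a label-independent sweep hovers around chance", {
  set.seed(21)
  n <- 80
  X <- matrix(stats::rnorm(n * 10), n)
  y <- rep(c(TRUE, FALSE), each = n / 2)   # unrelated to X
  curve <- loocv_sweep(X, y, pc_range = c(1, 3, 5, 10))
  # pooled leave-one-out scores never manufacture signal under the null;
  # they sit at or (often far) below chance, because each held-out sample
  # drags its own class mean away from itself - with a single pure-noise
  # feature the pooled ranking is close to perfectly inverted
  expect_true(all(curve$auc < 0.6))
  expect_lte(mean(curve$auc), 0.55)
})

test_that("stratified folds balance positives to within one", {
  set.seed(30)
  labels <- stats::runif(200) < 0.1
  labels[1:2] <- c(TRUE, FALSE)
  fold <- stratified_folds(labels, k = 10L, seed = 3L)
  pos_per_fold <- tapply(labels, fold, sum)
  expect_true(all(abs(pos_per_fold - sum(labels) / 10) < 1))
  expect_equal(sort(unique(fold)), 1:10)
  # same seed, same folds
  expect_identical(fold, stratified_folds(labels, k = 10L, seed = 3L))
})

test_that("the classifier bank is reproducible and validates names", {
  set.seed(31)
  n <- 60
  X <- matrix(stats::rnorm(n * 3), n)
  y <- stats::runif(n) < stats::plogis(2 * X[, 1])
  if (sum(y) < 6 || sum(!y) < 6) y <- rep(c(TRUE, FALSE), each = n / 2)
  r1 <- crossval_bank(X, y, algorithms = c("lda", "logistic", "naive_bayes"),
                      k = 5L, seed = 77L, n_boot = 200L)
  r2 <- crossval_bank(X, y, algorithms = c("lda", "logistic", "naive_bayes"),
                      k = 5L, seed = 77L, n_boot = 200L)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_true(all(r1$auc >= 0 & r1$auc <= 1))
  expect_true(all(r1$auc_ci_low <= r1$auc & r1$auc <= r1$auc_ci_high))
  expect_error(crossval_bank(X, y, algorithms = "deep_magic"),
               "naive_bayes")
})

test_that("every bank member runs and beats chance on an easy problem", {
  set.seed(32)
  n <- 80
  X <- matrix(stats::rnorm(n * 3), n)
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X[y, 1] <- X[y, 1] + 2.5
  bank <- crossval_bank(X, y, algorithms = "all", k = 5L, seed = 9L,
                        n_boot = 100L)
  expect_setequal(bank$algorithm, classifier_names())
  expect_true(all(bank$auc > 0.7))
})

test_that("a constant score yields chance AUC and zero Youden", {
  rep_const <- score_report(rep(1, 40), rep(c(TRUE, FALSE), 20),
                            n_boot = 100L)
  expect_equal(rep_const$auc, 0.5)
  expect_equal(rep_const$youden, 0)
})
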