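test_that("Kennard-Stone picks extremes first and matches the oracle", {
  X <- matrix(c(0, 1, 10), ncol = 1)
  expect_setequal(kennard_stone_split(X, 2)$calibration, c(1, 3))
  set.seed(9)
  for (i in 1:5) {
    X <- matrix(rnorm(8 * 3), 8, 3)
    n_cal <- sample(3:7, 1)
    expect_equal(kennard_stone_split(X, n_cal)$calibration,
                 ks_oracle(X, n_cal))
  }
  # n_cal = n-1 leaves out the most interior point
  X <- matrix(c(0, 0.1, 5, 10, 20), ncol = 1)
  expect_equal(kennard_stone_split(X, 4)$validation, ks_oracle(X, 4) |>
                 setdiff(x = 1:5))
})

test_that("Kennard-Stone selection is invariant to row permutation", {
  set.seed(2)
  X <- matrix(rnorm(10 * 4), 10, 4)
  sel <- sort(kennard_stone_split(X, 6)$calibration)
  perm <- sample(10)
  sel_p <- kennard_stone_split(X[perm, ], 6)$calibration
  expect_setequal(perm[sel_p], sel)
})

test_that("NIPALS PLS matches the independent SIMPLS oracle", {
  set.seed(5)
  for (i in 1:5) {
    X <- matrix(rnorm(10 * 6), 10, 6)
    y <- rnorm(10) > 0
    y <- as.numeric(y)
    if (length(unique(y)) < 2) next
    for (nlv in c(1, 3)) {
      fit <- fit_plsda(X, y, n_lv = nlv)
      b <- pls1_simpls_oracle(X, y, nlv)
      expect_lt(max(abs(fit$coefficients - b)) / max(abs(b)), 1e-8)
    }
  }
})

test_that("PLS score vectors are mutually orthogonal", {
  set.seed(6)
  X <- matrix(rnorm(20 * 12), 20, 12)
  y <- rep(c(0, 1), 10)
  fit <- fit_plsda(X, y, n_lv = 5)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-10)
  # R2Y non-decreasing
  expect_true(all(diff(fit$R2Y) >= -1e-12))
})

test_that("a response spanned by one column is fitted exactly with 1 LV", {
  set.seed(7)
  X <- cbind(rep(c(0, 1), 5), 0)      # y is literally column 1
  y <- X[, 1]
  fit <- fit_plsda(X, y, n_lv = 1)
  expect_equal(fit$R2Y[1], 1, tolerance = 1e-12)
})

test_that("full-rank PLS equals ordinary least squares", {
  set.seed(8)
  X <- matrix(rnorm(12 * 4), 12, 4)
  y <- rep(c(0, 1), 6)
  fit <- fit_plsda(X, y, n_lv = 4)
  b_ols <- coef(lm(y ~ X))[-1]
  expect_equal(unname(fit$coefficients), unname(b_ols), tolerance = 1e-8)
})

test_that("the compiled kernel reproduces the R NIPALS fit", {
  set.seed(10)
  Xtr <- matrix(rnorm(14 * 9), 14, 9)
  ytr <- rep(c(0, 1), 7)
  Xte <- matrix(rnorm(5 * 9), 5, 9)
  for (scale in c(FALSE, TRUE)) {
    cpp <- moca:::.pls1_predict_cpp(Xtr, ytr, Xte, 4L, scale)
    for (a in 1:4) {
      fit <- fit_plsda(Xtr, ytr, n_lv = a, scale = scale)
      expect_equal(unname(cpp[, a]), unname(predict(fit, Xte)),
                   tolerance = 1e-10)
    }
  }
})

test_that("leave-one-out cross-validation equals the explicit refit loop", {
  set.seed(11)
  X <- matrix(rnorm(8 * 5), 8, 5)
  y <- rep(c(0, 1), 4)
  cv <- cross_validate(X, y, n_lv_max = 2, folds = "loo")
  expect_equal(unname(cv$cv_pred[, 2]), loo_oracle(X, y, 2),
               tolerance = 1e-9)
  # Q2 never exceeds R2Y at the same component count
  fit <- fit_plsda(X, y, n_lv = 2)
  expect_lte(cv$q2[2], fit$R2Y[2])
})

test_that("pure-noise responses cross-validate to negative Q2 on average", {
  q2 <- c()
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 15), 20, 15)
    y <- rep(c(0, 1), 10)
    q2 <- c(q2, cross_validate(X, y, n_lv_max = 5)$q2)
  }
  # chance class-correlated directions give an occasional positive cell,
  # but positives stay rare and the distribution is firmly negative
  expect_lt(mean(q2 > 0), 0.15)
  expect_lt(mean(q2), 0)
})

test_that("classification metrics follow the confusion-matrix arithmetic", {
  # (TP, FN, TN, FP) = (4, 1, 3, 2)
  y <- c(rep(1, 5), rep(0, 5))
  pred <- c(1, 1, 1, 1, 0, 0, 0, 0, 1, 1)
  m <- classification_metrics(y, pred)
  expect_equal(m$se, 0.8)
  expect_equal(m$sp, 0.6)
  expect_equal(m$accuracy, 0.7)
  p <- classification_metrics(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(p$se, 1); expect_equal(p$sp, 0); expect_equal(p$accuracy, 0.5)
  perfect <- classification_metrics(c(1, 0), c(0.9, 0.1))
  expect_equal(c(perfect$se, perfect$sp, perfect$accuracy), c(1, 1, 1))
})

test_that("VIP scores are normalized and rank informative variables first", {
  set.seed(12)
  X <- matrix(rnorm(20 * 10), 20, 10)
  y <- rep(c(0, 1), 10)
  fit <- fit_plsda(X, y, n_lv = 3)
  vip <- vip_scores(fit)
  expect_equal(mean(vip^2), 1, tolerance = 1e-12)
  # one informative variable among noise has maximal VIP
  top <- 0
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(24 * 12), 24, 12)
    y <- rep(c(0, 1), 12)
    X[, 4] <- y + rnorm(24, 0, 0.2)
    fit <- fit_plsda(X, y, n_lv = 2, scale = TRUE)
    top <- top + (which.max(vip_scores(fit)) == 4)
  }
  expect_gte(top, 9)
  # single-variable model: VIP identically 1
  X1 <- matrix(rnorm(10), ncol = 1)
  y1 <- as.numeric(X1 > 0)
  expect_equal(vip_scores(fit_plsda(X1, y1, n_lv = 1)), 1)
})

test_that("S-plot coordinates match their definitions", {
  set.seed(13)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rep(c(0, 1), 15)
  X[, 1] <- y + rnorm(30, 0, 0.1)
  fit <- fit_plsda(X, y, n_lv = 2)
  sp <- s_plot(fit, X)
  expect_true(all(abs(sp$p_corr[!sp$excluded]) <= 1 + 1e-12))
  # explicit covariance loop oracle
  Xs <- sweep(sweep(X, 2, fit$x_mean), 2, fit$x_scale, "/")
  t1 <- fit$scores[, 1]
  for (j in 1:8) {
    expect_equal(sp$p[j], sum((t1 - mean(t1)) *
                                (Xs[, j] - mean(Xs[, j]))) / (30 - 1),
                 tolerance = 1e-10)
  }
  # a feature equal to t1 has correlation exactly 1
  X2 <- cbind(X, t1)
  fit2 <- fit_plsda(X2, y, n_lv = 1)
  sp2 <- s_plot(fit2, X2)
  expect_gt(sp2$p_corr[9], 0.999)
  # zero-variance feature excluded with a message
  X3 <- cbind(X, 1)
  expect_message(sp3 <- s_plot(fit, cbind(X[, -8], 1)), "zero-variance")
})

test_that("pure-noise features rarely clear the p(corr) threshold", {
  inside <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 1000
    t1 <- rnorm(n)
    x <- rnorm(n)
    inside <- inside + (abs(cor(t1, x)) < 0.3)
  }
  expect_equal(inside, 20)
})

test_that("the identity permutation reproduces the original model", {
  set.seed(14)
  ft <- generate_feature_table(synthetic_config(n_batches = 6))
  X <- ft$areas; y <- as.numeric(ft$class_labels == "SF")
  fit <- fit_plsda(X, y, n_lv = 2, scale = TRUE)
  cv <- cross_validate(X, y, n_lv_max = 2, scale = TRUE)
  fit2 <- fit_plsda(X, y[seq_along(y)], n_lv = 2, scale = TRUE)
  expect_identical(fit$R2Y, fit2$R2Y)
  cv2 <- cross_validate(X, y[seq_along(y)], n_lv_max = 2, scale = TRUE)
  expect_identical(cv$q2, cv2$q2)
})

test_that("permutation testing validates real signal and flags noise", {
  ft <- generate_feature_table(synthetic_config(seed = 3))
  pr <- permutation_test(ft$areas, ft$class_labels, n_lv = 2, n_perm = 50,
                         scale = TRUE, seed = 1)
  expect_lt(pr$q2_intercept, 0)
  expect_true(all(pr$permutations$r2 < pr$original_r2))
  expect_true(pr$valid)
  expect_warning(
    permutation_test(ft$areas, ft$class_labels, n_lv = 2, n_perm = 10,
                     scale = TRUE, seed = 1),
    "20 permutations")
})

test_that("CV-ANOVA arithmetic matches a hand-computed toy case", {
  rm_model <- c(0.1, -0.2, 0.1, 0.3, -0.1, 0.2)
  rm_null <- c(0.5, -0.6, 0.4, 0.7, -0.5, 0.6)
  out <- cv_anova(rm_model, rm_null, n_lv = 2)
  ss1 <- sum(rm_model^2)      # 0.2
  ss0 <- sum(rm_null^2)       # 1.87
  f <- ((ss0 - ss1) / 2) / (ss1 / 3)
  expect_equal(out$f, f)
  expect_equal(out$p, pf(f, 2, 3, lower.tail = FALSE))
  # identical residuals: no evidence
  same <- cv_anova(rm_null, rm_null, n_lv = 2)
  expect_equal(same$f, 0)
  expect_equal(same$p, 1)
})

test_that("CV-ANOVA detects the class structure in informative data", {
  sig <- 0
  for (seed in 1:5) {
    ft <- generate_feature_table(synthetic_config(seed = seed))
    ca <- cv_anova_plsda(ft$areas, ft$class_labels, n_lv = 2, scale = TRUE)
    sig <- sig + (ca$p < 0.05)
  }
  expect_equal(sig, 5)
})

test_that("PCA matches the eigendecomposition oracle", {
  set.seed(15)
  X <- matrix(rnorm(5 * 4), 5, 4)
  out <- pca(X, n_comp = 3)
  ev <- eigen(cov(X))
  expect_equal(unname(out$explained_variance),
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-10)
  expect_equal(crossprod(out$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # rank-1 data: first component carries everything
  X1 <- outer(rnorm(6), rnorm(4))
  out1 <- pca(X1, n_comp = 2)
  expect_equal(unname(out1$explained_variance[1]), 1, tolerance = 1e-10)
})
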