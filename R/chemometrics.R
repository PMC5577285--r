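# Latent-variable modelling: Kennard-Stone splitting, NIPALS PLS-DA,
# cross-validation, VIP, S-plot, permutation testing, CV-ANOVA, PCA.

#' Kennard-Stone calibration/validation split
#'
#' Deterministic max-min Euclidean selection: the first two calibration
#' samples are the pair at maximal distance; each subsequent pick maximizes
#' its minimum distance to the already-selected set. Ties are resolved by
#' the lowest row index.
#'
#' @param X Sample matrix (rows = samples).
#' @param n_cal Number of calibration samples, `2 <= n_cal < nrow(X)`.
#' @return A list with integer index vectors `calibration` (in selection
#'   order) and `validation`.
#' @export
kennard_stone_split <- function(X, n_cal) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_cal < 2 || n_cal >= n) stop("need 2 <= n_cal < n_samples")
  D <- as.matrix(dist(X))
  # maximal pair, lowest indices on ties
  best <- c(1L, 2L); bd <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > bd) { bd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_cal) {
    rest <- setdiff(seq_len(n), sel)
    mind <- apply(D[rest, sel, drop = FALSE], 1, min)
    sel <- c(sel, rest[which.max(mind)])
  }
  list(calibration = sel, validation = setdiff(seq_len(n), sel))
}

#' Fit a PLS-DA model (NIPALS PLS1)
#'
#' Class labels are coded 0/1 (positive class `"SF"` = 1) and regressed on
#' the (centred, optionally unit-variance scaled) predictor matrix by
#' NIPALS. The continuous prediction is thresholded at 0.5 for class calls.
#'
#' @param X Predictor matrix (samples x variables).
#' @param y Class labels (`"SF"`/`"NSF"`, factor, or numeric 0/1).
#' @param n_lv Number of latent variables; truncated with a warning if it
#'   exceeds the rank of `X`.
#' @param scale Unit-variance scaling (`TRUE` is the convention for feature
#'   tables; NIR spectra are usually only centred).
#' @param threshold Classification threshold on the continuous prediction.
#' @return An object of class `plsda` with weights `W`, loadings `P`,
#'   y-loadings `q`, scores `T`, cumulative coefficient paths, `R2X`/`R2Y`
#'   per cumulative component, `rmsec`, and fitted values.
#' @export
fit_plsda <- function(X, y, n_lv = 2, scale = FALSE, threshold = 0.5) {
  X <- as.matrix(X)
  y <- .code_labels(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  stopifnot(nrow(X) == length(y))
  x_mean <- colMeans(X)
  x_scale <- if (scale) {
    s <- apply(X, 2, sd); s[s < 1e-12] <- 1; s
  } else rep(1, ncol(X))
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  y_mean <- mean(y)
  yc <- y - y_mean
  ss_y <- sum(yc^2)
  ss_x <- sum(Xc^2)

  p <- ncol(X)
  W <- P <- matrix(0, p, n_lv)
  Tm <- matrix(0, nrow(X), n_lv)
  q <- numeric(n_lv)
  r2y <- r2x <- numeric(n_lv)
  a_used <- 0L
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-13) break
    w <- w / nw
    t_a <- drop(Xc %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-13) break
    p_a <- drop(crossprod(Xc, t_a)) / tt
    q_a <- sum(yc * t_a) / tt
    Xc <- Xc - tcrossprod(t_a, p_a)
    yc <- yc - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    r2y[a] <- 1 - sum(yc^2) / ss_y
    r2x[a] <- 1 - sum(Xc^2) / ss_x
    a_used <- a
  }
  if (a_used < n_lv) {
    warning("rank exhausted: truncating to ", a_used, " latent variables")
    n_lv <- a_used
    W <- W[, seq_len(n_lv), drop = FALSE]
    P <- P[, seq_len(n_lv), drop = FALSE]
    Tm <- Tm[, seq_len(n_lv), drop = FALSE]
    q <- q[seq_len(n_lv)]; r2y <- r2y[seq_len(n_lv)]
    r2x <- r2x[seq_len(n_lv)]
  }
  if (n_lv == 0) stop("no usable latent variable (X'y is null)")
  b <- drop(W %*% solve(crossprod(P, W), q))
  fitted <- drop(sweep(sweep(as.matrix(X), 2, x_mean), 2, x_scale, "/") %*% b) +
    y_mean
  model <- structure(list(
    n_lv = n_lv, W = W, P = P, q = q, scores = Tm, coefficients = b,
    x_mean = x_mean, x_scale = x_scale, y_mean = y_mean, scale = scale,
    threshold = threshold, R2X = r2x, R2Y = r2y,
    rmsec = sqrt(mean((y - fitted)^2)), fitted = fitted, y = y
  ), class = "plsda")
  model
}

#' Predict from a PLS-DA model
#'
#' @param object A fitted [fit_plsda()] model.
#' @param newdata Matrix of new samples (same variables).
#' @param type `"response"` for the continuous prediction, `"class"` for
#'   thresholded 0/1 calls.
#' @param ... Unused.
#' @return Numeric predictions (or 0/1 class calls).
#' @export
predict.plsda <- function(object, newdata, type = c("response", "class"),
                          ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$x_mean), 2, object$x_scale, "/")
  yhat <- drop(Xs %*% object$coefficients) + object$y_mean
  if (type == "class") as.numeric(yhat >= object$threshold) else yhat
}

#' @export
print.plsda <- function(x, ...) {
  cat("<plsda> ", x$n_lv, " LV; R2Y = ", round(x$R2Y[x$n_lv], 4),
      ", R2X = ", round(x$R2X[x$n_lv], 4),
      ", RMSEC = ", signif(x$rmsec, 4), "\n", sep = "")
  invisible(x)
}

# Build fold index list: "loo" or stratified k-fold.
.make_folds <- function(y, folds, seed = NULL) {
  n <- length(y)
  if (identical(folds, "loo")) return(as.list(seq_len(n)))
  k <- as.integer(folds)
  stopifnot(k >= 2)
  if (!is.null(seed)) set.seed(seed)
  fold_id <- integer(n)
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold_id[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) which(fold_id == f))
}

#' Cross-validate a PLS-DA model over component counts
#'
#' Computes cross-validated predictions at every component count `1..
#' n_lv_max`; `Q2 = 1 - PRESS/SS_tot` with `SS_tot` taken about the
#' training-fold means, and `RMSECV = sqrt(PRESS/n)`. The selected
#' component count minimizes RMSECV, with ties broken toward fewer
#' components. Leave-one-out is the default scheme (the sample sizes here
#' are small); numeric `folds` gives stratified k-fold. A training fold
#' missing a class is an error.
#'
#' @param X Predictor matrix.
#' @param y Class labels or 0/1.
#' @param n_lv_max Maximum component count (capped at the training rank).
#' @param folds `"loo"` or an integer fold count.
#' @param scale Unit-variance scaling (see [fit_plsda()]).
#' @param seed Seed for fold assignment (k-fold only).
#' @return A list: `q2` and `rmsecv` per component count, chosen `n_lv`,
#'   and the cross-validated prediction matrix `cv_pred` (n x n_lv_max).
#' @export
cross_validate <- function(X, y, n_lv_max = 10, folds = "loo", scale = FALSE,
                           seed = NULL) {
  X <- as.matrix(X)
  y <- .code_labels(y)
  n <- length(y)
  n_lv_max <- max(1L, min(n_lv_max, n - 2L, ncol(X)))
  fold_list <- .make_folds(y, folds, seed)
  preds <- matrix(NA_real_, n, n_lv_max)
  sstot <- 0
  for (te in fold_list) {
    tr <- setdiff(seq_len(n), te)
    if (length(unique(y[tr])) < 2) {
      stop("a training fold lacks one of the classes; re-stratify")
    }
    preds[te, ] <- .pls1_predict_cpp(X[tr, , drop = FALSE], y[tr],
                                     X[te, , drop = FALSE], n_lv_max, scale)
    sstot <- sstot + sum((y[te] - mean(y[tr]))^2)
  }
  press <- colSums((preds - y)^2)
  q2 <- 1 - press / sstot
  rmsecv <- sqrt(press / n)
  list(q2 = q2, rmsecv = rmsecv, n_lv = which.min(rmsecv), cv_pred = preds)
}

# Fast LOO PRESS/RMSECV via the compiled kernel (used by sipls).
.loo_rmsecv <- function(X, y, n_lv_max, scale = FALSE) {
  n <- length(y)
  n_lv_max <- max(1L, min(n_lv_max, n - 2L, ncol(X)))
  preds <- .pls1_loo_cpp(X, y, n_lv_max, scale)
  sqrt(colSums((preds - y)^2) / n)
}

#' Classification metrics for a two-class model
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and total accuracy,
#' with `"SF"` (code 1) as the positive class, plus the RMSE of the
#' continuous prediction (RMSEP on a validation set, RMSEC on the
#' calibration set). A metric whose class is absent is `NA`.
#'
#' @param y_true True labels or 0/1 codes.
#' @param y_pred Continuous predictions (thresholded here) or 0/1 calls.
#' @param threshold Decision threshold.
#' @return A list with `se`, `sp`, `accuracy`, `rmse`.
#' @export
classification_metrics <- function(y_true, y_pred, threshold = 0.5) {
  y <- .code_labels(y_true)
  cls <- as.numeric(y_pred >= threshold)
  tp <- sum(cls == 1 & y == 1); fn <- sum(cls == 0 & y == 1)
  tn <- sum(cls == 0 & y == 0); fp <- sum(cls == 1 & y == 0)
  list(
    se = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(y),
    rmse = sqrt(mean((y - y_pred)^2))
  )
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a(w_ja^2 SSY_a) / sum_a(SSY_a) )` where `SSY_a =
#' q_a^2 t_a't_a` is the response variance captured by component `a`. The
#' squared VIPs average to exactly 1.
#'
#' @param model A fitted [fit_plsda()] model.
#' @return Numeric VIP per variable.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda"))
  ssy <- model$q^2 * colSums(model$scores^2)
  if (sum(ssy) <= 0) stop("model explains no response variance")
  p <- nrow(model$W)
  sqrt(p * drop(model$W^2 %*% ssy) / sum(ssy))
}

#' S-plot coordinates
#'
#' For each variable: `p = cov(t1, x_j)` (model-scaled units) and `p(corr) =
#' cor(t1, x_j)`, with `t1` the first model score vector and `x_j` the
#' variable on the model's centring/scaling. Zero-variance variables have
#' undefined correlation and are flagged (`excluded = TRUE`) with a message.
#'
#' @param model A fitted [fit_plsda()] model.
#' @param X The data matrix the model was fitted on.
#' @return A data frame with columns `feature`, `p`, `p_corr`, `excluded`.
#' @export
s_plot <- function(model, X) {
  stopifnot(inherits(model, "plsda"))
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, model$x_mean), 2, model$x_scale, "/")
  t1 <- model$scores[, 1]
  pj <- drop(crossprod(Xs, t1)) / (nrow(X) - 1)
  sds <- apply(Xs, 2, sd)
  excluded <- sds == 0
  pc <- rep(NA_real_, ncol(X))
  pc[!excluded] <- pj[!excluded] / (sd(t1) * sds[!excluded])
  if (any(excluded)) {
    message(sum(excluded), " zero-variance feature(s) excluded from S-plot")
  }
  feats <- colnames(X) %||% sprintf("V%d", seq_len(ncol(X)))
  data.frame(feature = feats, p = pj, p_corr = pc, excluded = excluded,
             stringsAsFactors = FALSE)
}

#' Select variables from an S-plot
#'
#' Applies magnitude thresholds `|p| > p_thr` and `|p_corr| > pcorr_thr`;
#' the covariance threshold is configurable because its scale depends on the
#' model's variable scaling.
#'
#' @param splot Output of [s_plot()].
#' @param p_thr Covariance magnitude threshold.
#' @param pcorr_thr Correlation magnitude threshold.
#' @return The subset of rows passing both thresholds.
#' @export
select_splot <- function(splot, p_thr = 0.05, pcorr_thr = 0.3) {
  keep <- !splot$excluded & abs(splot$p) > p_thr &
    abs(splot$p_corr) > pcorr_thr
  splot[keep, , drop = FALSE]
}

#' Permutation test of PLS-DA model validity
#'
#' Refits the model (same component count, same cross-validation scheme)
#' under `n_perm` random permutations of the class labels, recording the
#' absolute correlation of each permuted label vector with the original,
#' the fitted `R2Y` and the cross-validated `Q2`. The R2 and Q2 intercepts
#' are the least-squares regression lines through all points (including the
#' original model at correlation 1) evaluated at correlation 0. The model
#' is judged valid when the Q2 intercept is negative and no permuted R2
#' reaches the original R2.
#'
#' @param X Predictor matrix.
#' @param y Class labels.
#' @param n_lv Component count of the model under test.
#' @param n_perm Number of permutations (default 200; fewer than 20 warns).
#' @param folds Cross-validation scheme.
#' @param scale Variable scaling.
#' @param seed RNG seed for the permutations.
#' @return An object of class `permutation_result`: per-permutation
#'   `correlation`, `r2`, `q2`; `r2_intercept`, `q2_intercept`;
#'   `original_r2`, `original_q2`; logical `valid`.
#' @export
permutation_test <- function(X, y, n_lv, n_perm = 200, folds = "loo",
                             scale = FALSE, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (n_perm < 20) warning("fewer than 20 permutations: unstable intercepts")
  X <- as.matrix(X)
  y <- .code_labels(y)
  if (!is.null(seed)) set.seed(seed)
  fit0 <- fit_plsda(X, y, n_lv = n_lv, scale = scale)
  n_lv <- fit0$n_lv
  cv0 <- cross_validate(X, y, n_lv_max = n_lv, folds = folds, scale = scale)
  r2_0 <- fit0$R2Y[n_lv]; q2_0 <- cv0$q2[n_lv]
  res <- matrix(NA_real_, n_perm, 3,
                dimnames = list(NULL, c("correlation", "r2", "q2")))
  for (i in seq_len(n_perm)) {
    yp <- sample(y)
    fit <- suppressWarnings(fit_plsda(X, yp, n_lv = n_lv, scale = scale))
    cv <- cross_validate(X, yp, n_lv_max = fit$n_lv, folds = folds,
                         scale = scale)
    res[i, ] <- c(abs(cor(yp, y)), fit$R2Y[fit$n_lv], cv$q2[fit$n_lv])
  }
  cc <- c(res[, "correlation"], 1)
  r2_int <- unname(coef(lm(c(res[, "r2"], r2_0) ~ cc))[1])
  q2_int <- unname(coef(lm(c(res[, "q2"], q2_0) ~ cc))[1])
  structure(list(
    permutations = as.data.frame(res), n_perm = n_perm,
    r2_intercept = r2_int, q2_intercept = q2_int,
    original_r2 = r2_0, original_q2 = q2_0,
    valid = (q2_int < 0) && (max(res[, "r2"]) < r2_0)
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> ", x$n_perm, " permutations\n",
      "  original R2Y = ", round(x$original_r2, 4),
      ", Q2 = ", round(x$original_q2, 4), "\n",
      "  intercepts: R2 = ", round(x$r2_intercept, 4),
      ", Q2 = ", round(x$q2_intercept, 4), "\n",
      "  verdict: ", if (x$valid) "valid" else "NOT valid", "\n", sep = "")
  invisible(x)
}

#' CV-ANOVA: F-test on cross-validated predictive residuals
#'
#' Compares the cross-validated residuals of the fitted model against those
#' of the null (training-mean) model on identical folds:
#' `F = ((SS0 - SS1)/(df0 - df1)) / (SS1/df1)` with `df0 = n - 1` and
#' `df1 = n - 1 - n_lv`. If the model does not beat the null
#' (`SS1 >= SS0`), `F = 0` and `p = 1`. This is one documented variant of
#' the cross-validated-residuals ANOVA; degrees-of-freedom bookkeeping
#' differs across software implementations.
#'
#' @param residuals_model Cross-validated residuals of the model.
#' @param residuals_mean Cross-validated residuals of the mean-only model on
#'   the same folds.
#' @param n_lv Number of latent variables consumed by the model.
#' @return A list with `f`, `p`, `df1`, `df2`, `ss_model`, `ss_null`.
#' @export
cv_anova <- function(residuals_model, residuals_mean, n_lv) {
  stopifnot(length(residuals_model) == length(residuals_mean), n_lv >= 1)
  n <- length(residuals_model)
  ss1 <- sum(residuals_model^2)
  ss0 <- sum(residuals_mean^2)
  df0 <- n - 1
  df1 <- n - 1 - n_lv
  if (df1 <= 0) stop("too few samples for ", n_lv, " latent variables")
  if (ss1 >= ss0) {
    return(list(f = 0, p = 1, df1 = df0 - df1, df2 = df1,
                ss_model = ss1, ss_null = ss0))
  }
  f <- ((ss0 - ss1) / (df0 - df1)) / (ss1 / df1)
  list(f = f, p = pf(f, df0 - df1, df1, lower.tail = FALSE),
       df1 = df0 - df1, df2 = df1, ss_model = ss1, ss_null = ss0)
}

#' CV-ANOVA for a PLS-DA model specification
#'
#' Convenience wrapper: runs the model and the mean-only null on identical
#' cross-validation folds and applies [cv_anova()].
#'
#' @param X Predictor matrix.
#' @param y Class labels.
#' @param n_lv Component count.
#' @param folds Cross-validation scheme.
#' @param scale Variable scaling.
#' @return As [cv_anova()].
#' @export
cv_anova_plsda <- function(X, y, n_lv, folds = "loo", scale = FALSE) {
  y <- .code_labels(y)
  cv <- cross_validate(X, y, n_lv_max = n_lv, folds = folds, scale = scale)
  fold_list <- .make_folds(y, folds)
  null_resid <- numeric(length(y))
  for (te in fold_list) {
    tr <- setdiff(seq_along(y), te)
    null_resid[te] <- y[te] - mean(y[tr])
  }
  nlv_eff <- ncol(cv$cv_pred)
  cv_anova(y - cv$cv_pred[, nlv_eff], null_resid, nlv_eff)
}

#' Principal component analysis
#'
#' Centred (optionally unit-variance scaled) PCA via singular value
#' decomposition, reporting explained-variance fractions.
#'
#' @param X Data matrix.
#' @param n_comp Number of components (truncated at the rank).
#' @param scale Unit-variance scaling.
#' @return A list with `scores`, `loadings`, `explained_variance` (fraction
#'   per component).
#' @export
pca <- function(X, n_comp = 2, scale = FALSE) {
  X <- as.matrix(X)
  pc <- prcomp(X, center = TRUE, scale. = scale)
  k <- min(n_comp, ncol(pc$rotation))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained_variance = ev[seq_len(k)])
}
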