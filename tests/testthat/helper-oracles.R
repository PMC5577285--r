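# Independent oracles used to cross-check the package implementations.
# Each deliberately takes a different algorithmic route from the code under
# test.

# SIMPLS (de Jong) PLS1 regression vector: covariance-deflation route,
# independent of the NIPALS X-deflation used by fit_plsda. For a single
# response the two algorithms agree exactly.
pls1_simpls_oracle <- function(X, y, nlv) {
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  p <- ncol(X)
  s <- crossprod(X, yc)
  R <- matrix(0, p, nlv)
  V <- matrix(0, p, 0)
  q <- numeric(nlv)
  for (a in seq_len(nlv)) {
    r <- s
    t <- X %*% r
    nt <- sqrt(sum(t^2))
    t <- t / nt
    r <- r / nt
    pr <- crossprod(X, t)
    q[a] <- sum(yc * t)
    v <- pr
    if (ncol(V) > 0) v <- v - V %*% crossprod(V, pr)
    v <- v / sqrt(sum(v^2))
    V <- cbind(V, v)
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r
  }
  drop(R %*% q)
}

# Greedy max-min Kennard-Stone re-derived with explicit scalar loops.
ks_oracle <- function(X, n_cal) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(1L, 2L); bd <- -1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d(i, j) > bd) { bd <- d(i, j); best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_cal) {
    rest <- setdiff(seq_len(n), sel)
    md <- vapply(rest, function(r)
      min(vapply(sel, function(s) d(r, s), numeric(1))), numeric(1))
    sel <- c(sel, rest[which.max(md)])
  }
  sel
}

# Synchronous 2D correlation by the explicit double loop over wavenumber
# pairs.
cos2d_loop_oracle <- function(X) {
  m <- nrow(X)
  Yt <- sweep(X, 2, colMeans(X))
  p <- ncol(X)
  Phi <- matrix(0, p, p)
  for (a in seq_len(p)) for (b in seq_len(p)) {
    Phi[a, b] <- sum(Yt[, a] * Yt[, b]) / (m - 1)
  }
  Phi
}

# Leave-one-out PLS predictions via explicit refits with fit_plsda.
loo_oracle <- function(X, y, n_lv, scale = FALSE) {
  n <- length(y)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- suppressWarnings(
      fit_plsda(X[-i, , drop = FALSE], y[-i], n_lv = n_lv, scale = scale))
    pred[i] <- predict(fit, X[i, , drop = FALSE])
  }
  pred
}

default_times <- c(0, 4, 12, 16, 20, 24, 36)
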