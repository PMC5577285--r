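# Discriminatory waveband localisation: exhaustive synergy-interval PLS and
# generalized two-dimensional correlation spectroscopy.

#' Partition a grid into contiguous intervals
#'
#' Equal-size contiguous intervals; remainder points are assigned to the
#' final interval. Intervals are closed on both ends and lie on the grid.
#'
#' @param n Grid length.
#' @param n_intervals Number of intervals.
#' @return A list of integer index vectors.
#' @export
spectral_intervals <- function(n, n_intervals) {
  stopifnot(n_intervals >= 1, n_intervals <= n)
  base <- n %/% n_intervals
  starts <- (seq_len(n_intervals) - 1L) * base + 1L
  ends <- c(starts[-1L] - 1L, n)
  Map(function(s, e) s:e, starts, ends)
}

#' Synergy interval PLS (SiPLS) waveband selection
#'
#' Splits the wavenumber grid into `n_intervals` contiguous intervals and
#' exhaustively cross-validates a PLS-DA model on every union of
#' `n_combine` intervals (`choose(n_intervals, n_combine)` candidates, each
#' over `1..n_lv_max` components). Candidates are ranked by RMSECV, ties
#' broken toward fewer components and then lower interval indices. When a
#' calibration subset is supplied, ranking uses the calibration set and
#' validation-set Se/Sp/accuracy are reported per candidate.
#'
#' @param spectra A labelled [spectra_set()] (possibly preprocessed).
#' @param labels Optional labels overriding `spectra$class_labels`.
#' @param n_intervals Number of grid intervals (default 20).
#' @param n_combine Number of intervals per union (default 3).
#' @param n_lv_max Maximum latent variables (default 10).
#' @param cal_idx Optional calibration sample indices (e.g. from
#'   [kennard_stone_split()]); remaining samples form the validation set.
#' @param scale Variable scaling for the PLS models.
#' @return A data frame ranked best-first with columns `intervals` (e.g.
#'   `"3+7+12"`), `wavebands` (cm^-1 spans), `n_lv`, `RMSECV`, and (when a
#'   split is given) `Se`, `Sp`, `Accuracy`. The interval index lists are in
#'   the `"interval_members"` attribute; the partition in `"intervals"`.
#' @export
sipls <- function(spectra, labels = NULL, n_intervals = 20, n_combine = 3,
                  n_lv_max = 10, cal_idx = NULL, scale = FALSE) {
  stopifnot(inherits(spectra, "spectra_set"))
  y <- .code_labels(labels %||% spectra$class_labels)
  if (n_combine > n_intervals) stop("n_combine must be <= n_intervals")
  wn <- spectra$wavenumbers
  X <- spectra$absorbance
  ivs <- spectral_intervals(length(wn), n_intervals)
  combos <- combn(n_intervals, n_combine)
  has_split <- !is.null(cal_idx)
  if (has_split) {
    val_idx <- setdiff(seq_len(nrow(X)), cal_idx)
    Xc <- X[cal_idx, , drop = FALSE]; yc <- y[cal_idx]
    Xv <- X[val_idx, , drop = FALSE]; yv <- y[val_idx]
  } else {
    Xc <- X; yc <- y
  }
  nlv_cap <- max(1L, min(n_lv_max, length(yc) - 2L))
  m <- ncol(combos)
  rmsecv <- numeric(m); nlv <- integer(m)
  se <- sp <- acc <- rep(NA_real_, m)
  for (k in seq_len(m)) {
    cols <- unlist(ivs[combos[, k]])
    rc <- .loo_rmsecv(Xc[, cols, drop = FALSE], yc, nlv_cap, scale = scale)
    nlv[k] <- which.min(rc)              # ties -> fewer components
    rmsecv[k] <- rc[nlv[k]]
    if (has_split) {
      fit <- suppressWarnings(fit_plsda(Xc[, cols, drop = FALSE], yc,
                                        n_lv = nlv[k], scale = scale))
      mets <- classification_metrics(yv, predict(fit, Xv[, cols, drop = FALSE]))
      se[k] <- mets$se; sp[k] <- mets$sp; acc[k] <- mets$accuracy
    }
  }
  span <- vapply(seq_len(m), function(k) {
    paste(vapply(combos[, k], function(i) {
      paste0(wn[ivs[[i]][1]], "-", wn[ivs[[i]][length(ivs[[i]])]])
    }, character(1)), collapse = ", ")
  }, character(1))
  tab <- data.frame(
    intervals = apply(combos, 2, paste, collapse = "+"),
    wavebands = span, n_lv = nlv, RMSECV = rmsecv,
    stringsAsFactors = FALSE
  )
  if (has_split) { tab$Se <- se; tab$Sp <- sp; tab$Accuracy <- acc }
  # rank: RMSECV, then fewer LVs, then lower interval indices (input order
  # of combn is already lexicographic, so a stable sort suffices)
  ord <- order(tab$RMSECV, tab$n_lv)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "interval_members") <- lapply(seq_len(m), function(k)
    combos[, k])[ord]
  attr(tab, "intervals") <- ivs
  tab
}

#' Wavenumber span of a ranked SiPLS combination
#'
#' @param sipls_result A [sipls()] result table.
#' @param rank Row rank (1 = best).
#' @return A data frame with one row per member interval: `interval`,
#'   `wn_lo`, `wn_hi`, and the column index vector as attribute `"columns"`.
#' @export
sipls_bands <- function(sipls_result, rank = 1) {
  ivs <- attr(sipls_result, "intervals")
  members <- attr(sipls_result, "interval_members")[[rank]]
  wn_attr <- lapply(ivs[members], range)
  cols <- unlist(ivs[members])
  out <- data.frame(interval = members,
                    lo_idx = vapply(ivs[members], min, numeric(1)),
                    hi_idx = vapply(ivs[members], max, numeric(1)))
  attr(out, "columns") <- cols
  out
}

#' Generalized 2D correlation spectroscopy (synchronous/asynchronous)
#'
#' Computes Noda's generalized 2D correlation matrices across a perturbation
#' series of spectra: dynamic spectra are deviations from the reference
#' (the mean spectrum by convention), the synchronous matrix is
#' `Phi = Y~' Y~ / (m-1)`, and the asynchronous matrix uses the
#' Hilbert-Noda transform `Psi = Y~' N Y~ / (m-1)` with
#' `N[j,k] = 0` if `j == k`, else `1/(pi (k - j))`. The autocorrelation
#' curve is the diagonal of the synchronous matrix.
#'
#' The perturbation order is the row order of the spectra set, except that
#' a `time_h` covariate, when present, reorders rows by time; for two-class
#' sets generated by this package NSF rows precede SF rows (a two-level
#' perturbation).
#'
#' @param spectra A [spectra_set()] with at least two spectra.
#' @param reference `"mean"` (Noda convention) or `"none"`.
#' @param asynchronous Also compute the asynchronous matrix.
#' @return An object of class `cos2d_result`: `synchronous`, optional
#'   `asynchronous`, `autocorrelation`, `wavenumbers`.
#' @export
cos2d <- function(spectra, reference = c("mean", "none"),
                  asynchronous = TRUE) {
  stopifnot(inherits(spectra, "spectra_set"))
  reference <- match.arg(reference)
  X <- spectra$absorbance
  if (!is.null(spectra$time_h)) {
    X <- X[order(spectra$time_h), , drop = FALSE]
  }
  m <- nrow(X)
  if (m < 2 && reference == "none") {
    stop("need >= 2 spectra (single spectrum with reference = \"none\")")
  }
  if (m < 2) stop("need >= 2 spectra for a perturbation series")
  Yt <- if (reference == "mean") sweep(X, 2, colMeans(X)) else X
  Phi <- crossprod(Yt) / (m - 1)
  res <- list(synchronous = Phi, autocorrelation = diag(Phi),
              wavenumbers = spectra$wavenumbers)
  if (asynchronous) {
    jk <- outer(seq_len(m), seq_len(m), function(j, k) {
      ifelse(j == k, 0, 1 / (pi * (k - j)))
    })
    res$asynchronous <- crossprod(Yt, jk %*% Yt) / (m - 1)
  }
  structure(res, class = "cos2d_result")
}

#' Autocorrelation difference between two 2D-COS results
#'
#' Difference of the synchronous-matrix diagonals (e.g. SF minus NSF) and
#' the wavenumber at which it is maximal — the zone where the
#' fumigation-specific absorption emerges.
#'
#' @param sf,nsf [cos2d()] results on identical grids.
#' @return A list: `wavenumbers`, `difference` (same length as the grid),
#'   `argmax_wavenumber`, `max_difference`.
#' @export
autocorrelation_difference <- function(sf, nsf) {
  stopifnot(inherits(sf, "cos2d_result"), inherits(nsf, "cos2d_result"))
  if (length(sf$wavenumbers) != length(nsf$wavenumbers) ||
      any(sf$wavenumbers != nsf$wavenumbers)) {
    stop("wavenumber grids do not match")
  }
  d <- sf$autocorrelation - nsf$autocorrelation
  i <- which.max(d)
  list(wavenumbers = sf$wavenumbers, difference = d,
       argmax_wavenumber = sf$wavenumbers[i], max_difference = d[i])
}
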