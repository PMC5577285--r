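# Spectral preprocessing bank: scatter correction, detrending, derivatives,
# denoising. Methods operate row-wise on the absorbance matrix and never
# change the sample count or labels.

#' Define a preprocessing method
#'
#' @param method One of `raw`, `msc`, `snv`, `baseline`, `normalization`,
#'   `st`, `wds`, `sg`:
#'   \describe{
#'     \item{raw}{identity.}
#'     \item{msc}{multiplicative scatter correction: each spectrum is
#'       regressed on a reference spectrum (`x = a*ref + b`) and corrected
#'       as `(x - b)/a`. The reference defaults to the mean spectrum of the
#'       set it is fitted on and is recorded so a validation set can be
#'       corrected with the calibration reference.}
#'     \item{snv}{standard normal variate: rows centred and scaled to unit
#'       sd.}
#'     \item{baseline}{subtract a per-spectrum linear trend (detrend).}
#'     \item{normalization}{scale each row to unit Euclidean norm.}
#'     \item{st}{absorbance ("spectroscopic") transform `log10(1/x)`;
#'       requires strictly positive input, errors otherwise.}
#'     \item{wds}{wavelet denoising: periodic Daubechies-4 transform,
#'       decomposition level `floor(log2(n)) - 4`, soft universal
#'       threshold.}
#'     \item{sg}{Savitzky-Golay least-squares polynomial smoothing and
#'       derivatives; edges use polynomial fits on truncated one-sided
#'       windows so output length equals input length. Derivatives are
#'       returned per cm^-1 (divided by `wn_step^deriv`).}
#'   }
#' @param window Odd window length in points (SG), must exceed `polyorder`.
#' @param polyorder Polynomial order (SG).
#' @param deriv Derivative order 0, 1 or 2 (SG); must be `<= polyorder`.
#' @param label Optional display label (defaults to a compact description).
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = c("raw", "msc", "snv", "baseline",
                                       "normalization", "st", "wds", "sg"),
                            window = 9, polyorder = 2, deriv = 1,
                            label = NULL) {
  method <- match.arg(method)
  if (method == "sg") {
    if (window %% 2 != 1) stop("SG window must be odd")
    if (window <= polyorder) stop("SG window must exceed polyorder")
    if (!deriv %in% 0:2) stop("deriv must be 0, 1 or 2")
    if (deriv > polyorder) stop("deriv must be <= polyorder")
  }
  if (is.null(label)) {
    label <- if (method == "sg") {
      sprintf("SG(%d)+%s", window,
              c("0" = "smooth", "1" = "1st", "2" = "2nd")[as.character(deriv)])
    } else toupper(method)
  }
  structure(list(method = method, window = window, polyorder = polyorder,
                 deriv = deriv, label = label), class = "preprocess_spec")
}

#' Apply a preprocessing method to a spectra set
#'
#' @param spectra A [spectra_set()].
#' @param spec A [preprocess_spec()] or a method name string.
#' @param params Optional parameters fitted on another set (currently the
#'   MSC reference spectrum), as returned in the `"params"` attribute of a
#'   previous call; used to preprocess a validation set with
#'   calibration-derived parameters.
#' @return A [spectra_set()] of the same shape, with a `"params"` attribute
#'   holding fitted parameters where applicable.
#' @export
preprocess <- function(spectra, spec, params = NULL) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (is.character(spec)) spec <- preprocess_spec(spec)
  X <- spectra$absorbance
  out_params <- NULL
  Y <- switch(spec$method,
    raw = X,
    snv = {
      sds <- apply(X, 1, sd)
      if (any(sds == 0)) {
        stop("constant spectrum (zero sd) under SNV: sample ",
             spectra$sample_ids[which(sds == 0)[1]])
      }
      (X - rowMeans(X)) / sds
    },
    msc = {
      ref <- if (!is.null(params$msc_reference)) params$msc_reference else
        colMeans(X)
      out_params <- list(msc_reference = ref)
      t(apply(X, 1, function(x) {
        fit <- lm.fit(cbind(1, ref), x)
        a <- fit$coefficients[2]; b <- fit$coefficients[1]
        if (abs(a) < 1e-12) stop("MSC slope ~ 0; degenerate spectrum")
        (x - b) / a
      }))
    },
    baseline = t(apply(X, 1, function(x) {
      i <- seq_along(x)
      x - lm.fit(cbind(1, i), x)$fitted.values
    })),
    normalization = X / sqrt(rowSums(X^2)),
    st = {
      if (any(X <= 0)) {
        stop("spectroscopic transform requires strictly positive values")
      }
      log10(1 / X)
    },
    wds = t(apply(X, 1, .wds_denoise)),
    sg = {
      if (spec$window > ncol(X)) stop("SG window larger than grid")
      step <- abs(diff(spectra$wavenumbers[1:2]))
      C <- .sg_matrix(ncol(X), spec$window, spec$polyorder, spec$deriv)
      (X %*% t(C)) / step^spec$deriv
    }
  )
  res <- spectra_set(spectra$wavenumbers, Y, spectra$sample_ids,
                     spectra$class_labels, spectra$time_h, spectra$batch)
  attr(res, "params") <- out_params
  res
}

#' Savitzky-Golay convolution coefficients
#'
#' Least-squares polynomial-fit weights for one output point given window
#' offsets; exposed for verification against published coefficient tables.
#'
#' @param offsets Integer offsets of the window points relative to the
#'   evaluation point (e.g. `-2:2`).
#' @param polyorder Polynomial order.
#' @param deriv Derivative order.
#' @return Weight vector `w` such that `sum(w * y[window])` estimates the
#'   `deriv`-th derivative (per point) at offset 0.
#' @export
sg_coefficients <- function(offsets, polyorder, deriv = 0) {
  stopifnot(length(offsets) > polyorder, deriv <= polyorder)
  A <- outer(offsets, 0:polyorder, `^`)
  # row (deriv+1) of the pseudo-inverse, times deriv!
  Pinv <- solve(crossprod(A), t(A))
  Pinv[deriv + 1, ] * factorial(deriv)
}

# Full n x n Savitzky-Golay operator with truncated one-sided edge windows.
.sg_matrix <- function(n, window, polyorder, deriv) {
  h <- (window - 1) %/% 2
  C <- matrix(0, n, n)
  central <- sg_coefficients(-h:h, polyorder, deriv)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    if (lo == i - h && hi == i + h) {
      C[i, lo:hi] <- central
    } else {
      C[i, lo:hi] <- sg_coefficients((lo:hi) - i, polyorder, deriv)
    }
  }
  C
}

# --- Daubechies-4 wavelet denoising (periodic boundary, power-of-2 pad) ---

.DB4_LO <- c(0.48296291314453414, 0.83651630373780772,
             0.22414386804201339, -0.12940952255126037)
.DB4_HI <- c(-0.12940952255126037, -0.22414386804201339,
             0.83651630373780772, -0.48296291314453414)

.dwt_step <- function(x, filt) {
  n <- length(x)
  idx <- outer(seq(1, n, by = 2) - 1, seq_along(filt) - 1, `+`) %% n + 1
  drop(matrix(x[idx], ncol = length(filt)) %*% filt)
}

.idwt_step <- function(approx, detail) {
  n <- 2 * length(approx)
  x <- numeric(n)
  for (k in seq_along(approx)) {
    pos <- ((2 * (k - 1)) + seq_along(.DB4_LO) - 1) %% n + 1
    x[pos] <- x[pos] + approx[k] * .DB4_LO + detail[k] * .DB4_HI
  }
  x
}

.wds_denoise <- function(x) {
  n <- length(x)
  n2 <- 2^ceiling(log2(n))
  xp <- c(x, rev(x)[seq_len(n2 - n)])       # symmetric pad
  level <- max(1L, floor(log2(n)) - 4L)
  approx <- xp
  details <- vector("list", level)
  for (l in seq_len(level)) {
    details[[l]] <- .dwt_step(approx, .DB4_HI)
    approx <- .dwt_step(approx, .DB4_LO)
  }
  sigma <- mad(details[[1]])
  thr <- sigma * sqrt(2 * log(n2))
  soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  for (l in rev(seq_len(level))) {
    approx <- .idwt_step(approx, soft(details[[l]]))
  }
  approx[seq_len(n)]
}

#' Default preprocessing bank
#'
#' The eleven-method comparison bank: raw spectra, MSC, SNV, baseline
#' detrending, unit-norm normalization, the absorbance transform (ST),
#' wavelet denoising (WDS), and Savitzky-Golay first/second derivatives
#' with 9- and 11-point windows.
#'
#' @return A list of [preprocess_spec()] objects.
#' @export
default_preprocess_bank <- function() {
  list(
    preprocess_spec("raw"), preprocess_spec("msc"), preprocess_spec("snv"),
    preprocess_spec("baseline"), preprocess_spec("normalization"),
    preprocess_spec("st"), preprocess_spec("wds"),
    preprocess_spec("sg", window = 9, polyorder = 2, deriv = 1),
    preprocess_spec("sg", window = 11, polyorder = 2, deriv = 1),
    preprocess_spec("sg", window = 9, polyorder = 2, deriv = 2),
    preprocess_spec("sg", window = 11, polyorder = 2, deriv = 2)
  )
}

#' Compare preprocessing methods by PLS-DA model diagnostics
#'
#' For each candidate method: the sample set is split once (Kennard-Stone,
#' on the raw spectra, identical split for every method), the calibration
#' set is preprocessed (recording any fitted parameters such as the MSC
#' reference), the validation set is preprocessed with the calibration
#' parameters, the latent-variable count is chosen by cross-validated
#' RMSECV over `1..n_lv_max`, and calibration/validation diagnostics are
#' tabulated. Methods that fail on the data are reported as failed rows,
#' never dropped silently.
#'
#' @param spectra A labelled [spectra_set()].
#' @param specs List of [preprocess_spec()]s (default: the full bank).
#' @param n_cal Calibration-set size for the Kennard-Stone split.
#' @param n_lv_max Maximum latent variables to consider.
#' @param folds Cross-validation scheme passed to [cross_validate()].
#' @return A data frame, one row per method, with columns `method`, `n_lv`,
#'   `RMSECV`, `RMSEC`, `RMSEP`, `Se`, `Sp`, `Accuracy`, `status`, ranked
#'   by RMSECV then accuracy; failed methods sort last.
#' @export
compare_preprocessing <- function(spectra, specs = default_preprocess_bank(),
                                  n_cal = 16, n_lv_max = 10, folds = "loo") {
  stopifnot(inherits(spectra, "spectra_set"), !is.null(spectra$class_labels))
  y_all <- .code_labels(spectra$class_labels)
  if (min(table(y_all)) < 2) stop("need >= 2 samples per class")
  split <- kennard_stone_split(spectra$absorbance, n_cal)
  rows <- lapply(specs, function(sp) {
    res <- tryCatch({
      cal <- preprocess(spectra[split$calibration], sp)
      val <- preprocess(spectra[split$validation], sp,
                        params = attr(cal, "params"))
      Xc <- cal$absorbance; yc <- y_all[split$calibration]
      Xv <- val$absorbance; yv <- y_all[split$validation]
      cv <- cross_validate(Xc, yc, n_lv_max = n_lv_max, folds = folds)
      fit <- fit_plsda(Xc, yc, n_lv = cv$n_lv)
      pv <- predict(fit, Xv)
      mets <- classification_metrics(yv, pv)
      data.frame(method = sp$label, n_lv = cv$n_lv,
                 RMSECV = cv$rmsecv[cv$n_lv], RMSEC = fit$rmsec,
                 RMSEP = mets$rmse, Se = mets$se, Sp = mets$sp,
                 Accuracy = mets$accuracy, status = "ok",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(method = sp$label, n_lv = NA_integer_, RMSECV = NA_real_,
                 RMSEC = NA_real_, RMSEP = NA_real_, Se = NA_real_,
                 Sp = NA_real_, Accuracy = NA_real_,
                 status = paste0("failed: ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    res
  })
  tab <- do.call(rbind, rows)
  ord <- order(is.na(tab$RMSECV), tab$RMSECV, -tab$Accuracy)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "split") <- split
  tab
}
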