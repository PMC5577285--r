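#' Construct a spectra set
#'
#' Container for a set of NIR absorbance spectra on a shared uniform
#' wavenumber grid, with optional class labels (`"SF"` / `"NSF"`) and an
#' optional fumigation-time covariate. Absorbance is stored as log(1/R).
#'
#' @param wavenumbers Strictly monotone, uniformly spaced grid (cm^-1);
#'   stored ascending.
#' @param absorbance Numeric matrix, one row per sample, one column per grid
#'   point.
#' @param sample_ids Character vector of sample identifiers.
#' @param class_labels Optional factor/character of `"SF"`/`"NSF"` labels.
#' @param time_h Optional numeric vector of fumigation times (hours).
#' @param batch Optional batch identifiers (pairing metadata: an SF sample
#'   and its untreated counterpart share a batch id).
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumbers, absorbance, sample_ids = NULL,
                        class_labels = NULL, time_h = NULL, batch = NULL) {
  absorbance <- as.matrix(absorbance)
  wavenumbers <- as.numeric(wavenumbers)
  n <- nrow(absorbance)
  if (length(wavenumbers) != ncol(absorbance)) {
    stop("grid length (", length(wavenumbers), ") != spectrum length (",
         ncol(absorbance), ")")
  }
  d <- diff(wavenumbers)
  if (any(d == 0)) stop("duplicate wavenumbers in grid")
  if (!(all(d > 0) || all(d < 0))) stop("wavenumber grid is not monotone")
  if (max(abs(d)) - min(abs(d)) > 1e-6 * max(abs(d))) {
    stop("wavenumber grid is not uniform")
  }
  if (wavenumbers[1] > wavenumbers[length(wavenumbers)]) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, rev(seq_along(wavenumbers)), drop = FALSE]
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(n))
  stopifnot(length(sample_ids) == n)
  if (!is.null(class_labels)) {
    class_labels <- as.character(class_labels)
    stopifnot(length(class_labels) == n, all(class_labels %in% c("SF", "NSF")))
  }
  if (!is.null(time_h)) stopifnot(length(time_h) == n, all(time_h >= 0))
  if (!is.null(batch)) stopifnot(length(batch) == n)
  rownames(absorbance) <- sample_ids
  colnames(absorbance) <- NULL
  structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         sample_ids = sample_ids, class_labels = class_labels,
         time_h = time_h, batch = batch),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$absorbance), " spectra x ",
      length(x$wavenumbers), " points (",
      min(x$wavenumbers), "-", max(x$wavenumbers), " cm-1, step ",
      diff(x$wavenumbers[1:2]), ")\n", sep = "")
  if (!is.null(x$class_labels)) {
    cat("  classes:", paste(names(table(x$class_labels)),
                            table(x$class_labels), collapse = ", "), "\n")
  }
  if (!is.null(x$time_h)) {
    cat("  time course:", paste(x$time_h, collapse = ", "), "h\n")
  }
  invisible(x)
}

#' Subset a spectra set by sample
#'
#' @param x A `spectra_set`.
#' @param i Sample indices (row subscript).
#' @param ... Unused.
#' @return A `spectra_set` with the selected samples.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$wavenumbers, x$absorbance[i, , drop = FALSE],
              x$sample_ids[i],
              if (!is.null(x$class_labels)) x$class_labels[i],
              if (!is.null(x$time_h)) x$time_h[i],
              if (!is.null(x$batch)) x$batch[i])
}

#' Construct an LC-MS feature table
#'
#' Sample-by-feature peak-area matrix; every feature carries an m/z and a
#' retention time. Areas must be non-negative.
#'
#' @param areas Numeric matrix (samples x features), non-negative.
#' @param feature_mz Numeric m/z per feature.
#' @param feature_rt Numeric retention time (minutes) per feature.
#' @param sample_ids,class_labels As in [spectra_set()].
#' @param feature_meta Optional data frame of per-feature metadata (e.g. the
#'   synthetic generator records feature type and parent links here).
#' @param time_h Optional per-sample fumigation time (hours).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(areas, feature_mz, feature_rt, sample_ids = NULL,
                          class_labels = NULL, feature_meta = NULL,
                          time_h = NULL) {
  areas <- as.matrix(areas)
  p <- ncol(areas)
  if (any(areas < 0, na.rm = TRUE)) stop("negative peak area")
  stopifnot(length(feature_mz) == p, length(feature_rt) == p)
  n <- nrow(areas)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(n))
  stopifnot(length(sample_ids) == n)
  if (!is.null(class_labels)) {
    class_labels <- as.character(class_labels)
    stopifnot(length(class_labels) == n, all(class_labels %in% c("SF", "NSF")))
  }
  if (is.null(colnames(areas))) colnames(areas) <- sprintf("F%03d", seq_len(p))
  rownames(areas) <- sample_ids
  if (!is.null(feature_meta)) stopifnot(nrow(feature_meta) == p)
  if (!is.null(time_h)) stopifnot(length(time_h) == n)
  structure(
    list(areas = areas, feature_mz = as.numeric(feature_mz),
         feature_rt = as.numeric(feature_rt), sample_ids = sample_ids,
         class_labels = class_labels, feature_meta = feature_meta,
         time_h = time_h, feature_ids = colnames(areas)),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$areas), " samples x ", ncol(x$areas),
      " features (m/z ", round(min(x$feature_mz), 1), "-",
      round(max(x$feature_mz), 1), ")\n", sep = "")
  if (!is.null(x$class_labels)) {
    cat("  classes:", paste(names(table(x$class_labels)),
                            table(x$class_labels), collapse = ", "), "\n")
  }
  invisible(x)
}

# 0/1 coding of class labels; SF is the positive class throughout.
.code_labels <- function(labels, positive = "SF") {
  if (is.numeric(labels)) return(as.numeric(labels))
  as.numeric(as.character(labels) == positive)
}
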