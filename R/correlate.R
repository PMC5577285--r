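# Cross-omics correlation layer: NIR band absorbance vs total marker
# abundance, across samples or across a fumigation time-course.

#' Mean absorbance over a wavenumber band
#'
#' Averages absorbance over the grid points inside the closed interval
#' `band` (a single-point band returns that point's value). Averaging over
#' a band rather than a single grid point buys noise robustness; pass a
#' degenerate band `c(w, w)` for single-point mode.
#'
#' @param spectra A [spectra_set()].
#' @param band Length-2 numeric interval in cm^-1 (default 5000-5200, the
#'   sulfur S-H/S-OH combination band).
#' @return Named numeric vector of per-sample mean absorbance.
#' @export
band_absorbance <- function(spectra, band = c(5000, 5200)) {
  stopifnot(inherits(spectra, "spectra_set"), length(band) == 2)
  band <- sort(band)
  sel <- spectra$wavenumbers >= band[1] & spectra$wavenumbers <= band[2]
  if (!any(sel)) stop("band [", band[1], ", ", band[2],
                      "] does not overlap the grid")
  v <- rowMeans(spectra$absorbance[, sel, drop = FALSE])
  names(v) <- spectra$sample_ids
  v
}

#' Correlate the NIR and LC-MS layers
#'
#' Pearson correlation (with its two-sided t-distribution p-value) between
#' per-sample NIR band absorbance and per-sample total marker area.
#'
#' @param band_values Per-sample band absorbance (e.g. [band_absorbance()]).
#' @param marker_totals Per-sample total marker area, same length (>= 3).
#' @return A list with `r`, `p`, `n`.
#' @export
correlate_layers <- function(band_values, marker_totals) {
  stopifnot(length(band_values) == length(marker_totals),
            length(band_values) >= 3)
  if (sd(band_values) == 0 || sd(marker_totals) == 0) {
    stop("zero variance in one of the layers")
  }
  ct <- cor.test(band_values, marker_totals, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(band_values))
}

#' Time-course curve container
#'
#' @param times Sampling times in hours (sorted).
#' @param values Finite response values (band absorbance, total area, ...).
#' @param units Free-text unit tag.
#' @return An object of class `timecourse_curve`.
#' @export
timecourse_curve <- function(times, values, units = "") {
  stopifnot(length(times) == length(values), !is.unsorted(times),
            all(is.finite(values)))
  structure(list(times = times, values = values, units = units),
            class = "timecourse_curve")
}

#' Detect the plateau time of a saturating curve
#'
#' The earliest sampled time from which every later value (inclusive) stays
#' within `rel_tol * (max - min)` of the curve maximum. The plateau must
#' contain at least two sampled points, so a strictly rising curve that
#' only "arrives" at its final sample has no plateau. A constant curve
#' plateaus at its first time point. Larger `rel_tol` never yields a later
#' plateau.
#'
#' @param curve A [timecourse_curve()] (or `times` vector, with `values`).
#' @param values Response values when `curve` is a plain vector.
#' @param rel_tol Relative tolerance (default 0.05).
#' @return The plateau time in hours, or `NA` if the curve never plateaus.
#' @export
plateau_time <- function(curve, values = NULL, rel_tol = 0.05) {
  if (inherits(curve, "timecourse_curve")) {
    times <- curve$times; v <- curve$values
  } else {
    times <- curve; v <- values
  }
  stopifnot(length(times) == length(v), length(times) >= 3)
  rng <- max(v) - min(v)
  if (rng == 0) return(times[1])
  ok <- abs(v - max(v)) <= rel_tol * rng
  n <- length(v)
  for (i in seq_len(n - 1L)) {         # plateau needs >= 2 points
    if (all(ok[i:n])) return(times[i])
  }
  NA_real_
}

#' Run the full discrimination-and-correlation pipeline
#'
#' Convenience wrapper chaining the stages on a synthetic configuration:
#' spectra generation, Savitzky-Golay 9-point first-derivative
#' preprocessing, Kennard-Stone 16/10 split, SiPLS waveband selection,
#' PLS-DA on the selected wavebands with validation metrics, marker
#' screening on the feature table, and the time-course correlation of the
#' two layers.
#'
#' @param config A [synthetic_config()].
#' @param n_cal Calibration-set size.
#' @param n_intervals,n_combine,n_lv_max SiPLS settings.
#' @param band Correlation band (cm^-1).
#' @return A list with elements `sipls` (ranked table), `validation`
#'   (Se/Sp/accuracy of the top-waveband model), `markers`
#'   (a `marker_screen`), `timecourse` (curves, plateau times, and the
#'   layer correlation), and the intermediate objects.
#' @export
run_moca <- function(config = synthetic_config(), n_cal = 16,
                     n_intervals = 20, n_combine = 3, n_lv_max = 10,
                     band = c(5000, 5200)) {
  spectra <- generate_spectra(config)
  pre <- preprocess(spectra, preprocess_spec("sg", window = 9,
                                             polyorder = 2, deriv = 1))
  split <- kennard_stone_split(pre$absorbance, n_cal)
  st <- sipls(pre, n_intervals = n_intervals, n_combine = n_combine,
              n_lv_max = n_lv_max, cal_idx = split$calibration)
  validation <- list(se = st$Se[1], sp = st$Sp[1], accuracy = st$Accuracy[1])

  features <- generate_feature_table(config)
  markers <- screen_markers(features)

  tc <- generate_timecourse(config)
  nir_curve <- timecourse_curve(tc$spectra$time_h,
                                band_absorbance(tc$spectra, band),
                                units = "log(1/R)")
  der <- tc$features$feature_meta$type == "sulfur_derivative"
  area_curve <- timecourse_curve(
    tc$features$time_h,
    rowSums(tc$features$areas[, der, drop = FALSE]), units = "area")
  corr <- correlate_layers(nir_curve$values, area_curve$values)
  list(
    spectra = spectra, preprocessed = pre, split = split, sipls = st,
    validation = validation, markers = markers,
    timecourse = list(nir = nir_curve, markers = area_curve,
                      plateau_nir = plateau_time(nir_curve),
                      plateau_markers = plateau_time(area_curve),
                      correlation = corr)
  )
}
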