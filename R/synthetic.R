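#' Configuration of the synthetic SF/NSF data generator
#'
#' Defines the study conditions the generator emulates: paired fumigated
#' (SF) and untreated (NSF) batches measured by NIR over 4,000-10,000 cm^-1
#' at 8 cm^-1 resolution, with an SF-specific absorption band around
#' 5,100 cm^-1 (the 5,000-5,200 cm^-1 S-H/S-OH region), multiplicative and
#' additive scatter, and LC-MS feature tables in which steroidal-saponin
#' features acquire sulfate (+SO3) or sulfite (+SO2) derivative features
#' elevated in SF samples. A small background conversion is present in NSF
#' samples too (environmental sulfur), so derivative levels are non-zero
#' without fumigation.
#'
#' @param n_batches Number of batches; each yields one NSF and one SF sample.
#' @param wn_min,wn_max,wn_step Wavenumber grid (cm^-1).
#' @param sulfur_band_center,sulfur_band_width Center and width (cm^-1) of
#'   the SF-specific Gaussian band; the Gaussian sigma is `width/2`.
#' @param sulfur_effect Peak absorbance added to SF spectra at the band
#'   center.
#' @param scatter_mult_sd,scatter_add_sd Per-spectrum multiplicative gain
#'   (around 1) and additive offset standard deviations.
#' @param noise_sd Additive i.i.d. Gaussian noise sd on spectra; also the
#'   log-sd of multiplicative log-normal noise on peak areas.
#' @param n_saponin_features,n_flavone_features,n_noise_features Feature
#'   counts; each saponin feature is paired with one sulfur-derivative
#'   feature, so the default 12/12/36 yields a 72-feature table.
#' @param conversion_fraction Fraction of each saponin converted to its
#'   sulfur derivative in SF samples (0-1).
#' @param baseline_sulfur NSF background conversion, as a fraction of the SF
#'   conversion level (derivative area in NSF =
#'   `baseline_sulfur * conversion_fraction * parent area`).
#' @param kinetics_rate First-order rate constant (1/h) of the saturating
#'   fumigation time-course `A(t) = A_max (1 - exp(-k t))`; the default 0.13
#'   puts `A(24 h) >= 0.95 A_max`, i.e. a plateau from 24 h on.
#' @param seed RNG seed; identical config (including seed) gives
#'   bit-identical output.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_batches = 13,
                             wn_min = 4000, wn_max = 10000, wn_step = 8,
                             sulfur_band_center = 5100,
                             sulfur_band_width = 100,
                             sulfur_effect = 0.05,
                             scatter_mult_sd = 0.05,
                             scatter_add_sd = 0.02,
                             noise_sd = 0.001,
                             n_saponin_features = 12,
                             n_flavone_features = 12,
                             n_noise_features = 36,
                             conversion_fraction = 0.3,
                             baseline_sulfur = 0.05,
                             kinetics_rate = 0.13,
                             seed = 1L) {
  cfg <- list(n_batches = n_batches, wn_min = wn_min, wn_max = wn_max,
              wn_step = wn_step, sulfur_band_center = sulfur_band_center,
              sulfur_band_width = sulfur_band_width,
              sulfur_effect = sulfur_effect,
              scatter_mult_sd = scatter_mult_sd,
              scatter_add_sd = scatter_add_sd, noise_sd = noise_sd,
              n_saponin_features = n_saponin_features,
              n_flavone_features = n_flavone_features,
              n_noise_features = n_noise_features,
              conversion_fraction = conversion_fraction,
              baseline_sulfur = baseline_sulfur,
              kinetics_rate = kinetics_rate, seed = as.integer(seed))
  if (cfg$wn_step <= 0) stop("wn_step must be positive")
  if (cfg$wn_min >= cfg$wn_max) stop("wn_min must be < wn_max")
  if (cfg$conversion_fraction < 0 || cfg$conversion_fraction > 1) {
    stop("conversion_fraction must be in [0, 1]")
  }
  sds <- c(cfg$scatter_mult_sd, cfg$scatter_add_sd, cfg$noise_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (cfg$n_batches < 1) stop("n_batches must be >= 1")
  if (cfg$n_saponin_features < 1 || cfg$n_flavone_features < 1 ||
      cfg$n_noise_features < 1) {
    stop("feature counts must be >= 1")
  }
  if (cfg$baseline_sulfur < 0) stop("baseline_sulfur must be >= 0")
  if (cfg$kinetics_rate <= 0) stop("kinetics_rate must be positive")
  class(cfg) <- "synthetic_config"
  cfg
}

.wn_grid <- function(config) {
  seq(config$wn_min, config$wn_max, by = config$wn_step)
}

# Gaussian band on the grid, unit peak height, sigma = width/2.
.gauss_band <- function(wn, center, width) {
  exp(-(wn - center)^2 / (2 * (width / 2)^2))
}

# Constituent-band layout is a deterministic function of the config seed:
# 8 shared Gaussian bands with centers in the combination (4000-4900) and
# first combination-overtone (4900-7100) regions, giving the collinear,
# fluctuating structure real NIR spectra of plant material show there.
.constituent_bands <- function(config, n_bands = 8) {
  set.seed(config$seed)
  lo <- max(config$wn_min, 4000)
  hi <- min(config$wn_max, 7100)
  if (lo >= hi) { lo <- config$wn_min; hi <- config$wn_max }
  list(center = runif(n_bands, lo, hi),
       width  = runif(n_bands, 150, 400),
       amp    = runif(n_bands, 0.10, 0.40))
}

#' Generate paired SF/NSF NIR spectra
#'
#' Simulates `2 * n_batches` absorbance spectra: a shared smooth baseline
#' plus shared constituent Gaussian bands (with per-batch concentration
#' variation common to both members of a pair), an SF-specific sulfur band,
#' per-spectrum multiplicative gain and additive offset (scatter), and
#' additive Gaussian noise. NSF samples carry the small background
#' `baseline_sulfur` fraction of the sulfur band.
#'
#' @param config A [synthetic_config()].
#' @return A [spectra_set()] with class labels (`NSF` rows first, then `SF`)
#'   and batch pairing metadata.
#' @export
generate_spectra <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  wn <- .wn_grid(config)
  if (config$sulfur_band_center < config$wn_min ||
      config$sulfur_band_center > config$wn_max) {
    stop("sulfur_band_center lies outside the wavenumber grid")
  }
  bands <- .constituent_bands(config)       # seeds the RNG with config$seed
  npt <- length(wn)
  nb <- config$n_batches
  n <- 2L * nb

  baseline <- 0.35 + 4e-5 * (wn - config$wn_min) +
    0.10 * .gauss_band(wn, config$wn_min + 0.7 * (config$wn_max - config$wn_min),
                       0.6 * (config$wn_max - config$wn_min))
  sband <- .gauss_band(wn, config$sulfur_band_center, config$sulfur_band_width)

  # per-batch constituent concentrations (shared by the NSF/SF pair)
  conc <- matrix(exp(rnorm(nb * length(bands$amp), 0, 0.15)),
                 nrow = nb)
  # per-batch sulfur susceptibility (mild batch-to-batch variation)
  sus <- exp(rnorm(nb, 0, 0.05))

  X <- matrix(0, n, npt)
  classes <- rep(c("NSF", "SF"), each = nb)
  batch <- rep(sprintf("B%02d", seq_len(nb)), times = 2)
  for (i in seq_len(n)) {
    b <- ((i - 1L) %% nb) + 1L
    chem <- baseline
    for (k in seq_along(bands$amp)) {
      chem <- chem + bands$amp[k] * conc[b, k] *
        .gauss_band(wn, bands$center[k], bands$width[k])
    }
    amp <- if (classes[i] == "SF") config$sulfur_effect * sus[b] else
      config$baseline_sulfur * config$sulfur_effect * sus[b]
    chem <- chem + amp * sband
    gain <- 1 + rnorm(1, 0, config$scatter_mult_sd)
    offset <- rnorm(1, 0, config$scatter_add_sd)
    X[i, ] <- gain * chem + offset + rnorm(npt, 0, config$noise_sd)
  }
  spectra_set(wn, X,
              sample_ids = paste0(batch, "_", classes),
              class_labels = classes, batch = batch)
}

#' Generate a paired SF/NSF LC-MS feature table
#'
#' Each saponin feature has a paired sulfur-derivative feature at the parent
#' m/z plus exactly 79.9568 (SO3) or 63.9619 (SO2). In SF samples a fraction
#' `conversion_fraction` of the parent is converted to the derivative; all
#' samples additionally carry the background conversion
#' `baseline_sulfur * conversion_fraction`, which depletes the parent
#' correspondingly, so parent + derivative area is conserved per batch up to
#' the multiplicative log-normal measurement noise. Flavone and noise
#' features are class-independent.
#'
#' @param config A [synthetic_config()].
#' @return A [feature_table()]; `$feature_meta` records each feature's type
#'   (`saponin_parent`, `sulfur_derivative`, `flavone`, `noise`), the parent
#'   feature id and adduct for derivatives.
#' @export
generate_feature_table <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 101L)
  nb <- config$n_batches
  n  <- 2L * nb
  ns <- config$n_saponin_features
  nf <- config$n_flavone_features
  nn <- config$n_noise_features
  cf <- config$conversion_fraction
  b0 <- config$baseline_sulfur * cf

  sap_base <- exp(rnorm(ns, log(500), 0.5))     # mean parent areas
  sap_mz <- sort(runif(ns, 700, 1200))
  sap_rt <- runif(ns, 10, 80)
  adduct <- sample(names(.SULFUR_SHIFTS), ns, replace = TRUE)
  der_mz <- sap_mz + unname(.SULFUR_SHIFTS[adduct])
  der_rt <- pmax(1, sap_rt + rnorm(ns, -1, 0.5)) # derivatives elute nearby
  fla_base <- exp(rnorm(nf, log(300), 0.5))
  fla_mz <- runif(nf, 250, 500)
  fla_rt <- runif(nf, 5, 60)
  noi_base <- exp(rnorm(nn, log(30), 0.8))
  noi_mz <- runif(nn, 150, 1300)
  noi_rt <- runif(nn, 2, 95)

  conc <- matrix(exp(rnorm(nb * ns, 0, 0.2)), nb, ns)   # batch x saponin
  fla_conc <- matrix(exp(rnorm(nb * nf, 0, 0.2)), nb, nf)

  classes <- rep(c("NSF", "SF"), each = nb)
  batch <- rep(sprintf("B%02d", seq_len(nb)), times = 2)
  p <- 2L * ns + nf + nn
  A <- matrix(0, n, p)
  for (i in seq_len(n)) {
    b <- ((i - 1L) %% nb) + 1L
    tot <- sap_base * conc[b, ]
    frac <- if (classes[i] == "SF") cf + b0 else b0
    parent <- tot * (1 - frac)
    deriv  <- tot * frac
    fla <- fla_base * fla_conc[b, ]
    noi <- noi_base * exp(rnorm(nn, 0, 0.3))
    row <- c(parent, deriv, fla, noi)
    A[i, ] <- row * exp(rnorm(p, 0, config$noise_sd))
  }
  ids <- c(sprintf("SAP%02d", seq_len(ns)), sprintf("DER%02d", seq_len(ns)),
           sprintf("FLA%02d", seq_len(nf)), sprintf("NOI%02d", seq_len(nn)))
  colnames(A) <- ids
  meta <- data.frame(
    feature_id = ids,
    type = rep(c("saponin_parent", "sulfur_derivative", "flavone", "noise"),
               c(ns, ns, nf, nn)),
    parent_id = c(rep(NA_character_, ns), sprintf("SAP%02d", seq_len(ns)),
                  rep(NA_character_, nf + nn)),
    adduct = c(rep(NA_character_, ns), adduct, rep(NA_character_, nf + nn)),
    stringsAsFactors = FALSE
  )
  feature_table(A, c(sap_mz, der_mz, fla_mz, noi_mz),
                c(sap_rt, der_rt, fla_rt, noi_rt),
                sample_ids = paste0(batch, "_", classes),
                class_labels = classes, feature_meta = meta)
}

#' Saturating first-order fumigation kinetics
#'
#' `A(t) = a0 + (a_max - a0) * (1 - exp(-rate * t))`.
#'
#' @param t Time in hours (vector).
#' @param rate Rate constant (1/h).
#' @param a_max Plateau level.
#' @param a0 Level at `t = 0`.
#' @return Amplitudes at `t`.
#' @export
saturating_kinetics <- function(t, rate, a_max = 1, a0 = 0) {
  stopifnot(rate > 0, all(t >= 0))
  a0 + (a_max - a0) * (1 - exp(-rate * t))
}

#' Generate a fumigation time-course
#'
#' Simulates repeated measurement of a single batch at the given fumigation
#' times: the sulfur band amplitude in the NIR spectrum and the total
#' sulfur-derivative conversion in the feature table both follow the
#' saturating kinetics `A(t) = A_max (1 - exp(-k t))` above the NSF
#' background. Because one physical sample is re-measured, the scatter gain
#' and offset are drawn once and shared across time points; detector noise
#' is fresh at each time.
#'
#' @param config A [synthetic_config()].
#' @param times Non-negative, sorted fumigation times in hours (default: the
#'   seven sampled times 0-36 h).
#' @return A list with elements `spectra` (a [spectra_set()] with `time_h`)
#'   and `features` (a [feature_table()] with `time_h`), one sample per time.
#' @export
generate_timecourse <- function(config = synthetic_config(),
                                times = c(0, 4, 12, 16, 20, 24, 36)) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(times) == 0) stop("times must be non-empty")
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times)) stop("times must be sorted increasing")
  wn <- .wn_grid(config)
  bands <- .constituent_bands(config)     # seeds RNG with config$seed
  set.seed(config$seed + 202L)
  sband <- .gauss_band(wn, config$sulfur_band_center, config$sulfur_band_width)
  baseline <- 0.35 + 4e-5 * (wn - config$wn_min) +
    0.10 * .gauss_band(wn, config$wn_min + 0.7 * (config$wn_max - config$wn_min),
                       0.6 * (config$wn_max - config$wn_min))
  chem0 <- baseline
  conc <- exp(rnorm(length(bands$amp), 0, 0.15))
  for (k in seq_along(bands$amp)) {
    chem0 <- chem0 + bands$amp[k] * conc[k] *
      .gauss_band(wn, bands$center[k], bands$width[k])
  }
  a0 <- config$baseline_sulfur * config$sulfur_effect
  amp <- saturating_kinetics(times, config$kinetics_rate,
                             a_max = config$sulfur_effect, a0 = a0)
  gain <- 1 + rnorm(1, 0, config$scatter_mult_sd)
  offset <- rnorm(1, 0, config$scatter_add_sd)
  m <- length(times)
  X <- matrix(0, m, length(wn))
  for (i in seq_len(m)) {
    X[i, ] <- gain * (chem0 + amp[i] * sband) + offset +
      rnorm(length(wn), 0, config$noise_sd)
  }
  ids <- sprintf("T%03dh", times)
  spectra <- spectra_set(wn, X, sample_ids = ids, time_h = times,
                         class_labels = ifelse(times > 0, "SF", "NSF"))

  # feature table: conversion fraction follows the same kinetics
  ns <- config$n_saponin_features
  sap_base <- exp(rnorm(ns, log(500), 0.5))
  sap_mz <- sort(runif(ns, 700, 1200))
  sap_rt <- runif(ns, 10, 80)
  adduct <- sample(names(.SULFUR_SHIFTS), ns, replace = TRUE)
  cf0 <- config$baseline_sulfur * config$conversion_fraction
  frac <- saturating_kinetics(times, config$kinetics_rate,
                              a_max = config$conversion_fraction + cf0,
                              a0 = cf0)
  A <- matrix(0, m, 2L * ns)
  for (i in seq_len(m)) {
    parent <- sap_base * (1 - frac[i])
    deriv <- sap_base * frac[i]
    A[i, ] <- c(parent, deriv) * exp(rnorm(2L * ns, 0, config$noise_sd))
  }
  ids_f <- c(sprintf("SAP%02d", seq_len(ns)), sprintf("DER%02d", seq_len(ns)))
  colnames(A) <- ids_f
  meta <- data.frame(
    feature_id = ids_f,
    type = rep(c("saponin_parent", "sulfur_derivative"), each = ns),
    parent_id = c(rep(NA_character_, ns), sprintf("SAP%02d", seq_len(ns))),
    adduct = c(rep(NA_character_, ns), adduct),
    stringsAsFactors = FALSE
  )
  features <- feature_table(A, c(sap_mz, sap_mz + unname(.SULFUR_SHIFTS[adduct])),
                            c(sap_rt, pmax(1, sap_rt - 1)),
                            sample_ids = ids, feature_meta = meta,
                            time_h = times,
                            class_labels = ifelse(times > 0, "SF", "NSF"))
  list(spectra = spectra, features = features)
}

#' Generate a neutral-loss ladder MS/MS peak list
#'
#' Builds the fragment series of successive neutral losses from a precursor
#' (peaks at each cumulative loss), optionally adding uniform-random decoy
#' peaks.
#'
#' @param precursor_mz Precursor m/z.
#' @param losses Positive neutral-loss masses (Da), applied in order; their
#'   cumulative sum must stay below the precursor.
#' @param noise_peaks Number of random decoy peaks to add.
#' @param seed Optional RNG seed for reproducible decoys/intensities.
#' @return A data frame with columns `mz` and `intensity`, sorted by m/z.
#' @export
generate_ms2 <- function(precursor_mz, losses, noise_peaks = 0, seed = NULL) {
  stopifnot(precursor_mz > 0, length(losses) >= 1, all(losses > 0))
  frags <- precursor_mz - cumsum(losses)
  if (any(frags <= 0)) stop("cumulative neutral loss >= precursor m/z")
  if (!is.null(seed)) set.seed(seed)
  int <- runif(length(frags), 0.3, 1)
  if (noise_peaks > 0) {
    frags <- c(frags, runif(noise_peaks, 50, precursor_mz - 1))
    int <- c(int, runif(noise_peaks, 0.01, 0.25))
  }
  ord <- order(frags)
  structure(data.frame(mz = frags[ord], intensity = int[ord]),
            precursor_mz = precursor_mz)
}
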