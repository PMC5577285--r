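# Physical constants for mass arithmetic.
#
# Monoisotopic atomic masses and isotopic abundances pinned to the IUPAC/CIAAW
# 2021 tables (AME2020 masses). All masses in Da (u).

.ELECTRON_MASS <- 0.000548579909
.PROTON_MASS   <- 1.007276466621

.MONO_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.00307400443,
  O = 15.99491461957,
  S = 31.97207117440
)

# Isotope data used for the M+2 fine-structure lines: mass of the heavy
# isotope and its natural abundance relative to the light one.
.ISOTOPES <- list(
  C13 = list(mass = 13.00335483507, abundance = 0.0107,  light = 0.9893),
  O18 = list(mass = 17.99915961286, abundance = 0.00205, light = 0.99757),
  S34 = list(mass = 33.96786700,    abundance = 0.0425,  light = 0.9499)
)

#' Built-in neutral-loss table for glycoside/sulfur fragmentation ladders
#'
#' Nominal and exact masses of the neutral losses commonly observed in MS/MS
#' spectra of (sulfated/sulfited) steroidal saponins: glycosyl residue losses
#' (rhamnosyl 146, glucosyl 162, xylosyl 132), loss of an intact glucose
#' (180), water (18), and the sulfur moieties SO3 (80, sulfate) and SO2
#' (64, sulfite).
#'
#' @return A data frame with columns `name`, `nominal` (Da) and `exact` (Da).
#' @examples
#' neutral_loss_table()
#' @export
neutral_loss_table <- function() {
  data.frame(
    name    = c("rhamnosyl", "glucosyl", "glucose", "xylosyl", "water",
                "SO3", "SO2"),
    nominal = c(146, 162, 180, 132, 18, 80, 64),
    exact   = c(146.0579, 162.0528, 180.0634, 132.0423, 18.010565,
                79.956815, 63.961901),
    stringsAsFactors = FALSE
  )
}

# Exact m/z shifts the synthetic generator stamps on sulfur-derivative
# features (Da added to the parent feature m/z).
.SULFUR_SHIFTS <- c(SO3 = 79.9568, SO2 = 63.9619)
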