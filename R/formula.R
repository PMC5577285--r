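#' Parse an elemental formula in Hill notation
#'
#' Parses strings such as `"C50H81O26S"` into a named integer vector of
#' element counts over the alphabet C, H, N, O, S (the elements occurring in
#' steroidal saponins, homoisoflavones and their sulfate/sulfite
#' derivatives). Unknown element tokens are a hard error naming the token.
#'
#' @param x A single formula string, e.g. `"C44H70O16"`.
#' @return An object of class `elemental_formula`: a named integer vector of
#'   element counts.
#' @examples
#' parse_formula("C44H70O16")
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1]]
  parts <- regmatches(x, gregexpr("[A-Z][a-z]?[0-9]*", x))[[1]]
  if (sum(nchar(parts)) != nchar(x)) {
    bad <- gsub("[A-Z][a-z]?[0-9]*", "", x)
    stop("unparseable formula token \"", bad, "\" in \"", x, "\"")
  }
  counts <- integer(0)
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    n  <- gsub("[^0-9]", "", p)
    n  <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.MONO_MASS)) {
      stop("unknown element token \"", el, "\" in formula \"", x, "\"")
    }
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  elemental_formula(counts)
}

#' Construct an elemental formula from element counts
#'
#' @param counts Named integer vector (names from C, H, N, O, S); counts must
#'   be non-negative and at least one atom present.
#' @return An `elemental_formula` object.
#' @export
elemental_formula <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("formula must contain at least one atom")
  if (any(counts < 0)) stop("negative element count")
  bad <- setdiff(names(counts), names(.MONO_MASS))
  if (length(bad)) stop("unknown element token \"", bad[1], "\"")
  counts <- vapply(counts, as.integer, integer(1))
  # Hill order: C, H, then alphabetical
  ord <- c(intersect(c("C", "H"), names(counts)),
           sort(setdiff(names(counts), c("C", "H"))))
  structure(counts[ord], class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula> ", format(x), "  (monoisotopic ",
      sprintf("%.6f", monoisotopic_mz(x, "neutral")), " Da)\n", sep = "")
  invisible(x)
}

#' Sum two elemental formulas
#'
#' Element-wise addition of atom counts, used to build sulfate/sulfite
#' derivative compositions (parent + SO3 or parent + SO2).
#'
#' @param a,b `elemental_formula` objects (or parseable strings).
#' @return An `elemental_formula`.
#' @export
formula_add <- function(a, b) {
  if (is.character(a)) a <- parse_formula(a)
  if (is.character(b)) b <- parse_formula(b)
  els <- union(names(a), names(b))
  counts <- vapply(els, function(e) {
    (if (e %in% names(a)) a[[e]] else 0L) + (if (e %in% names(b)) b[[e]] else 0L)
  }, integer(1))
  elemental_formula(counts)
}

#' Monoisotopic m/z of an elemental composition
#'
#' Sums the most-abundant-isotope atomic masses of the composition. Three
#' charge conventions are supported:
#' \describe{
#'   \item{`neutral`}{the neutral molecule mass.}
#'   \item{`anion_deprotonated`}{`[M-H]-` of the *neutral* composition:
#'     neutral mass minus one proton.}
#'   \item{`anion_composition`}{the composition already lists the anion's
#'     atoms (one H fewer than the neutral molecule, as printed in
#'     high-resolution MS reports); one electron mass is added.}
#' }
#'
#' @param formula An `elemental_formula` or formula string.
#' @param convention Charge convention, see Details.
#' @return The m/z (Da per unit charge), double precision.
#' @examples
#' monoisotopic_mz("H2O")                          # 18.010565
#' monoisotopic_mz("C50H81O26S", "anion_composition")
#' @export
monoisotopic_mz <- function(formula,
                            convention = c("neutral", "anion_deprotonated",
                                           "anion_composition")) {
  convention <- match.arg(convention)
  if (is.character(formula)) formula <- parse_formula(formula)
  m <- sum(.MONO_MASS[names(formula)] * unclass(formula))
  switch(convention,
    neutral            = m,
    anion_deprotonated = m - .PROTON_MASS,
    anion_composition  = m + .ELECTRON_MASS
  )
}

#' Parts-per-million mass error
#'
#' @param observed,theoretical Positive m/z values.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(observed > 0), all(theoretical > 0))
  1e6 * (observed - theoretical) / theoretical
}
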