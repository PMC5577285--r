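# LC-MS marker screening: the three-criteria screen (S-plot position, VIP,
# t test), sulfate/sulfite candidate generation, high-resolution extracted
# ion matching, fine-isotope diagnostics, and neutral-loss ladder
# annotation.

#' Generate sulfate/sulfite derivative candidates from a compound library
#'
#' For each library compound and each adduct, forms the derivative
#' composition (parent + SO3 or parent + SO2) and its deprotonated-molecule
#' target m/z, the screening targets for high-resolution extracted ion
#' chromatograms.
#'
#' @param library A data frame with columns `name` and `formula` (neutral
#'   compositions), e.g. from [read_compound_library()].
#' @param adducts Subset of `c("SO3", "SO2")`.
#' @return A data frame: `name`, `adduct`, `formula` (derivative), `parent_mz`
#'   and `target_mz` (both `[M-H]-`).
#' @export
sulfur_candidates <- function(library, adducts = c("SO3", "SO2")) {
  stopifnot(is.data.frame(library), nrow(library) > 0,
            all(c("name", "formula") %in% colnames(library)))
  adducts <- match.arg(adducts, several.ok = TRUE)
  add_formula <- list(SO3 = elemental_formula(c(S = 1L, O = 3L)),
                      SO2 = elemental_formula(c(S = 1L, O = 2L)))
  rows <- list()
  for (i in seq_len(nrow(library))) {
    parent <- parse_formula(library$formula[i])
    pmz <- monoisotopic_mz(parent, "anion_deprotonated")
    for (ad in adducts) {
      der <- formula_add(parent, add_formula[[ad]])
      rows[[length(rows) + 1L]] <- data.frame(
        name = library$name[i], adduct = ad, formula = format(der),
        parent_mz = pmz,
        target_mz = monoisotopic_mz(der, "anion_deprotonated"),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Extract features matching a target m/z within a ppm window
#'
#' The feature-table analogue of a high-resolution extracted ion
#' chromatogram: returns the features whose m/z lies within `tol_ppm` of the
#' target, sorted by absolute ppm error. An empty result is allowed.
#'
#' @param features A [feature_table()] or a numeric vector of m/z values.
#' @param target Target m/z.
#' @param tol_ppm Tolerance in ppm (> 0).
#' @return A data frame with `feature`, `mz`, `ppm`.
#' @export
extract_hreic <- function(features, target, tol_ppm = 5) {
  stopifnot(tol_ppm > 0, target > 0)
  if (inherits(features, "feature_table")) {
    mz <- features$feature_mz
    ids <- features$feature_ids
  } else {
    ids <- names(features) %||% sprintf("F%03d", seq_along(features))
    mz <- unname(as.numeric(features))
  }
  ppm <- ppm_error(mz, target)
  keep <- which(abs(ppm) <= tol_ppm)
  out <- data.frame(feature = ids[keep], mz = mz[keep], ppm = ppm[keep],
                    stringsAsFactors = FALSE)
  out[order(abs(out$ppm)), , drop = FALSE]
}

#' Fine structure of the M+2 isotope cluster
#'
#' The three near-isobaric M+2 isotopologues that confirm sulfur
#' incorporation: one 34S (shift +1.99580 Da), two 13C (+2.00671) and one
#' 18O (+2.00424), with abundances relative to the monoisotopic peak from
#' the element counts and natural isotope abundances (`n_S * r_S34`,
#' `choose(n_C, 2) * r_C13^2`, `n_O * r_O18`, each `r` the heavy/light
#' abundance ratio). The required resolving power is `m/dm` for the
#' 34S vs 13C2 pair — the two lines whose separation is diagnostic of
#' sulfur (13C2 dominates the non-sulfur cluster at these carbon counts).
#'
#' @param formula An `elemental_formula` or string; must contain S for the
#'   34S line.
#' @param convention Charge convention for the base m/z (see
#'   [monoisotopic_mz()]).
#' @return A list: `lines` (data frame `label`, `shift`, `abundance`),
#'   `base_mz`, `resolving_power` (NA when either pair member is absent).
#' @export
m2_fine_structure <- function(formula, convention = "anion_composition") {
  if (is.character(formula)) formula <- parse_formula(formula)
  cnt <- function(el) if (el %in% names(formula)) formula[[el]] else 0L
  lines <- list()
  shift <- c(
    S34 = .ISOTOPES$S34$mass - .MONO_MASS[["S"]],
    C13x2 = 2 * (.ISOTOPES$C13$mass - .MONO_MASS[["C"]]),
    O18 = .ISOTOPES$O18$mass - .MONO_MASS[["O"]]
  )
  if (cnt("S") >= 1) {
    r <- .ISOTOPES$S34$abundance / .ISOTOPES$S34$light
    lines$S34 <- c(shift[["S34"]], cnt("S") * r)
  }
  if (cnt("C") >= 2) {
    r <- .ISOTOPES$C13$abundance / .ISOTOPES$C13$light
    lines$C13x2 <- c(shift[["C13x2"]], choose(cnt("C"), 2) * r^2)
  }
  if (cnt("O") >= 1) {
    r <- .ISOTOPES$O18$abundance / .ISOTOPES$O18$light
    lines$O18 <- c(shift[["O18"]], cnt("O") * r)
  }
  if (length(lines) == 0) {
    return(list(lines = data.frame(label = character(), shift = numeric(),
                                   abundance = numeric()),
                base_mz = NA_real_, resolving_power = NA_real_))
  }
  tab <- data.frame(
    label = names(lines),
    shift = vapply(lines, `[`, numeric(1), 1),
    abundance = vapply(lines, `[`, numeric(1), 2),
    stringsAsFactors = FALSE
  )
  base <- monoisotopic_mz(formula, convention)
  rp <- if (all(c("S34", "C13x2") %in% tab$label)) {
    base / abs(shift[["C13x2"]] - shift[["S34"]])
  } else NA_real_
  list(lines = tab, base_mz = base, resolving_power = rp)
}

#' Annotate an MS/MS spectrum with a neutral-loss ladder
#'
#' Depth-first search with backtracking over sequences of allowed neutral
#' losses starting from the precursor, where every step must land on an
#' observed peak within tolerance. The best annotation maximizes the
#' matched-peak count, with ties broken toward fewer steps and then smaller
#' total absolute mass error. Reports whether a sulfur step (SO3 sulfate /
#' SO2 sulfite) occurs.
#'
#' @param precursor_mz Precursor m/z.
#' @param ms2 Peak list data frame (`mz`, `intensity`) or numeric m/z
#'   vector.
#' @param loss_table Data frame of allowed losses (default
#'   [neutral_loss_table()]).
#' @param tol Matching tolerance in Da (default 0.5, suited to nominal-mass
#'   ladders; use ~0.01 for exact-mass peaks).
#' @param use_exact Match with exact loss masses instead of nominal.
#' @param max_depth Maximum ladder length searched.
#' @return A list of class `ladder_annotation`: `sequence` (loss names),
#'   `fragments` (matched peak m/z in ladder order), `n_matched`,
#'   `total_error`, `sulfur_call` (`"sulfate"`, `"sulfite"` or `"none"`).
#' @export
annotate_ladder <- function(precursor_mz, ms2,
                            loss_table = neutral_loss_table(),
                            tol = 0.5, use_exact = FALSE, max_depth = 8) {
  peaks <- if (is.data.frame(ms2)) ms2$mz else as.numeric(ms2)
  if (length(peaks) == 0) stop("empty peak list")
  peaks <- sort(unique(peaks))
  masses <- if (use_exact) loss_table$exact else loss_table$nominal
  nm <- loss_table$name

  best <- list(n = -1L, steps = Inf, err = Inf, seq = character(0),
               frag = numeric(0))
  consider <- function(seqv, fragv, errv) {
    n <- length(fragv)
    if (n > best$n ||
        (n == best$n && length(seqv) < best$steps) ||
        (n == best$n && length(seqv) == best$steps && errv < best$err)) {
      best <<- list(n = n, steps = length(seqv), err = errv,
                    seq = seqv, frag = fragv)
    }
  }
  recurse <- function(current, seqv, fragv, errv, depth) {
    consider(seqv, fragv, errv)
    if (depth >= max_depth) return()
    for (k in seq_along(masses)) {
      target <- current - masses[k]
      if (target <= 0) next
      d <- abs(peaks - target)
      hit <- which(d <= tol)
      if (length(hit)) {
        hit <- hit[which.min(d[hit])]
        recurse(peaks[hit], c(seqv, nm[k]), c(fragv, peaks[hit]),
                errv + d[hit], depth + 1L)
      }
    }
  }
  recurse(precursor_mz, character(0), numeric(0), 0, 0L)
  sulfur <- if ("SO3" %in% best$seq) "sulfate" else
    if ("SO2" %in% best$seq) "sulfite" else "none"
  structure(list(precursor_mz = precursor_mz, sequence = best$seq,
                 fragments = best$frag, n_matched = best$n,
                 total_error = best$err, sulfur_call = sulfur),
            class = "ladder_annotation")
}

#' @export
print.ladder_annotation <- function(x, ...) {
  cat("<ladder_annotation> precursor m/z ", x$precursor_mz, "\n  ",
      paste(paste0("-", x$sequence, "-> ", round(x$fragments, 4)),
            collapse = " "), "\n  sulfur call: ", x$sulfur_call, "\n",
      sep = "")
  invisible(x)
}

#' Filter features by relative mean peak area
#'
#' Keeps features whose mean area is at least `min_fraction` of the total
#' mean area (boundary inclusive). Raw areas are preserved, not
#' renormalized.
#'
#' @param table A [feature_table()].
#' @param min_fraction Relative-area threshold in (0, 1); default 0.01
#'   (the 1% relative-peak-area rule).
#' @return The filtered [feature_table()].
#' @export
relative_area_filter <- function(table, min_fraction = 0.01) {
  stopifnot(inherits(table, "feature_table"),
            min_fraction > 0, min_fraction < 1)
  mu <- colMeans(table$areas, na.rm = TRUE)
  keep <- mu / sum(mu) >= min_fraction
  if (!any(keep)) stop("relative-area filter removed every feature")
  .subset_features(table, which(keep))
}

.subset_features <- function(table, j) {
  feature_table(table$areas[, j, drop = FALSE], table$feature_mz[j],
                table$feature_rt[j], table$sample_ids, table$class_labels,
                if (!is.null(table$feature_meta))
                  table$feature_meta[j, , drop = FALSE],
                table$time_h)
}

# Drop features missing (NA or zero variance with all-NA) in >50% of
# samples; impute remaining NAs with half the minimum positive area.
.clean_missing <- function(table, max_missing = 0.5) {
  A <- table$areas
  miss_frac <- colMeans(is.na(A))
  keep <- miss_frac <= max_missing
  if (!all(keep)) {
    message(sum(!keep), " feature(s) dropped (missing in >",
            round(100 * max_missing), "% of samples)")
    table <- .subset_features(table, which(keep))
    A <- table$areas
  }
  if (anyNA(A)) {
    half_min <- min(A[A > 0], na.rm = TRUE) / 2
    A[is.na(A)] <- half_min
    message("missing areas imputed with half the minimum positive area")
    table$areas <- A
  }
  table
}

#' Screen discriminatory LC-MS markers by the three-criteria rule
#'
#' A feature is a marker hit when it passes all three criteria
#' simultaneously: S-plot position (`|p| > p_thr` and `|p(corr)| >
#' pcorr_thr`), VIP above `vip_thr`, and a Welch two-sided t test below
#' `t_thr` between classes. t-test p-values are reported both raw (the
#' screening criterion) and Benjamini-Hochberg adjusted. Features missing
#' in more than half the samples are dropped and remaining gaps imputed
#' with half the minimum positive area before screening. Optionally, hits
#' are annotated as sulfate/sulfite derivatives by searching for a parent
#' feature at m/z minus the exact SO3/SO2 shift within a ppm tolerance.
#'
#' @param table A labelled [feature_table()].
#' @param model Optional fitted [fit_plsda()] model on the (cleaned) table;
#'   fitted here (unit-variance scaling, component count by leave-one-out
#'   RMSECV) when `NULL`.
#' @param p_thr,pcorr_thr,vip_thr,t_thr The three-criteria thresholds
#'   (defaults: 0.05 covariance magnitude, 0.3 correlation magnitude,
#'   VIP 1.5, t-test p 0.05).
#' @param annotate_sulfur Attempt parent/adduct annotation of hits.
#' @param tol_ppm Annotation tolerance (ppm on the implied parent m/z).
#' @param n_lv_max Component search range when fitting internally.
#' @return A list of class `marker_screen`: `hits` (data frame with one row
#'   per marker: statistics, direction, and annotation columns), `stats`
#'   (the same statistics for every screened feature), `model`, and the
#'   per-criterion hit-count summary `criteria_n`.
#' @export
screen_markers <- function(table, model = NULL, p_thr = 0.05,
                           pcorr_thr = 0.3, vip_thr = 1.5, t_thr = 0.05,
                           annotate_sulfur = TRUE, tol_ppm = 5,
                           n_lv_max = 10) {
  stopifnot(inherits(table, "feature_table"), !is.null(table$class_labels))
  table <- .clean_missing(table)
  X <- table$areas
  y <- .code_labels(table$class_labels)
  if (is.null(model)) {
    cv <- cross_validate(X, y, n_lv_max = n_lv_max, folds = "loo",
                         scale = TRUE)
    model <- fit_plsda(X, y, n_lv = cv$n_lv, scale = TRUE)
  }
  sp <- s_plot(model, X)
  vip <- vip_scores(model)
  tt <- apply(X, 2, function(x) {
    g1 <- x[y == 1]; g0 <- x[y == 0]
    if (sd(g1) == 0 && sd(g0) == 0) return(NA_real_)
    t.test(g1, g0)$p.value
  })
  direction <- ifelse(colMeans(X[y == 1, , drop = FALSE]) >=
                        colMeans(X[y == 0, , drop = FALSE]),
                      "up_in_SF", "down_in_SF")
  stats <- data.frame(
    feature = table$feature_ids, mz = table$feature_mz,
    rt = table$feature_rt, p = sp$p, p_corr = sp$p_corr, vip = vip,
    t_p = tt, t_p_bh = p.adjust(tt, "BH"), direction = direction,
    stringsAsFactors = FALSE
  )
  crit_splot <- !sp$excluded & abs(sp$p) > p_thr & abs(sp$p_corr) > pcorr_thr
  crit_vip <- vip > vip_thr
  crit_t <- !is.na(tt) & tt < t_thr
  hit <- crit_splot & crit_vip & crit_t
  hits <- stats[hit, , drop = FALSE]
  hits$parent_feature <- NA_character_
  hits$adduct <- NA_character_
  hits$annotation_ppm <- NA_real_
  if (annotate_sulfur && nrow(hits) > 0) {
    for (i in seq_len(nrow(hits))) {
      bestppm <- Inf
      for (ad in names(.SULFUR_SHIFTS)) {
        shift_exact <- monoisotopic_mz(
          elemental_formula(c(S = 1L, O = if (ad == "SO3") 3L else 2L)),
          "neutral")
        implied <- hits$mz[i] - shift_exact
        if (implied <= 0) next
        cand <- extract_hreic(table, implied, tol_ppm)
        cand <- cand[cand$feature != hits$feature[i], , drop = FALSE]
        if (nrow(cand) > 0 && abs(cand$ppm[1]) < abs(bestppm)) {
          bestppm <- cand$ppm[1]
          hits$parent_feature[i] <- cand$feature[1]
          hits$adduct[i] <- ad
          hits$annotation_ppm[i] <- cand$ppm[1]
        }
      }
    }
  }
  rownames(hits) <- NULL
  structure(list(
    hits = hits, stats = stats, model = model,
    criteria_n = c(splot = sum(crit_splot), vip = sum(crit_vip),
                   t_test = sum(crit_t), intersection = sum(hit)),
    thresholds = c(p = p_thr, p_corr = pcorr_thr, vip = vip_thr, t = t_thr)
  ), class = "marker_screen")
}

#' @export
print.marker_screen <- function(x, ...) {
  cat("<marker_screen> ", x$criteria_n[["intersection"]],
      " marker hits (S-plot ", x$criteria_n[["splot"]], ", VIP ",
      x$criteria_n[["vip"]], ", t test ", x$criteria_n[["t_test"]],
      ")\n", sep = "")
  if (nrow(x$hits)) {
    print(head(x$hits[, c("feature", "mz", "p", "p_corr", "vip", "t_p",
                          "direction", "adduct")], 10))
  }
  invisible(x)
}
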