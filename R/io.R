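# Readers and writers. All CSV is comma-separated, "." decimal, UTF-8.
# Every failure path is a typed error with a message naming the offender;
# nothing is silently coerced.

#' Write a spectra set to CSV
#'
#' Layout: optional comment lines `# class: ...` / `# time_h: ...` / `#
#' batch: ...`, then a header `wavenumber,<sample ids...>` and one row per
#' grid point (first column wavenumber, one column per sample).
#'
#' @param x A [spectra_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectra_set"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(x$class_labels)) {
    writeLines(paste0("# class: ", paste(x$class_labels, collapse = ",")), con)
  }
  if (!is.null(x$time_h)) {
    writeLines(paste0("# time_h: ", paste(x$time_h, collapse = ",")), con)
  }
  if (!is.null(x$batch)) {
    writeLines(paste0("# batch: ", paste(x$batch, collapse = ",")), con)
  }
  df <- data.frame(wavenumber = x$wavenumbers, t(x$absorbance),
                   check.names = FALSE)
  colnames(df) <- c("wavenumber", x$sample_ids)
  writeLines(paste(colnames(df), collapse = ","), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectra set from CSV or JCAMP-DX
#'
#' CSV files use the [write_spectra()] layout; wavenumber rows may appear in
#' any order and are sorted ascending on read. A non-uniform grid is
#' resampled by linear interpolation onto a uniform grid of the same length
#' and range, with a warning. Duplicate wavenumbers or NaN/missing cells are
#' hard errors naming the offending row/sample. The JCAMP-DX reader supports
#' the `XYDATA=(X++(Y..Y))` form, one spectrum per file.
#'
#' @param path Input file.
#' @param format `"csv"` or `"jcamp"`.
#' @return A [spectra_set()].
#' @export
read_spectra <- function(path, format = c("csv", "jcamp")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "jcamp") return(.read_jcamp(path))
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*(\\w+):\\s*(.*)$", ml))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- strsplit(m[3], ",")[[1]]
  }
  df <- read.csv(text = lines[!grepl("^#", lines)], check.names = FALSE)
  if (ncol(df) < 2) stop("spectra CSV needs a wavenumber column plus samples")
  wn <- df[[1]]
  if (anyDuplicated(wn)) {
    stop("duplicate wavenumbers at rows ",
         paste(which(duplicated(wn)), collapse = ", "))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-finite absorbance in sample \"", colnames(mat)[bad[1, 2]],
         "\" at wavenumber ", wn[bad[1, 1]])
  }
  ord <- order(wn)
  wn <- wn[ord]
  mat <- mat[ord, , drop = FALSE]
  d <- diff(wn)
  if (max(d) - min(d) > 1e-6 * max(d)) {
    warning("non-uniform wavenumber grid; resampling by linear interpolation")
    grid <- seq(min(wn), max(wn), length.out = length(wn))
    mat <- apply(mat, 2, function(y) approx(wn, y, xout = grid)$y)
    wn <- grid
  }
  spectra_set(wn, t(mat), sample_ids = colnames(mat),
              class_labels = meta$class,
              time_h = if (!is.null(meta$time_h)) as.numeric(meta$time_h),
              batch = meta$batch)
}

.read_jcamp <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  getfield <- function(key) {
    ln <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (length(ln) == 0) return(NULL)
    sub(paste0("^##", key, "="), "", ln[1])
  }
  xy <- grep("^##XYDATA=", lines)
  if (length(xy) == 0) stop("no ##XYDATA record in JCAMP file ", path)
  form <- getfield("XYDATA")
  if (!grepl("X\\+\\+\\(Y\\.\\.Y\\)", form)) {
    stop("unsupported JCAMP XYDATA form: ", form)
  }
  xf <- as.numeric(getfield("XFACTOR") %||% "1")
  yf <- as.numeric(getfield("YFACTOR") %||% "1")
  npt <- as.numeric(getfield("NPOINTS"))
  end <- grep("^##END", lines)
  end <- if (length(end)) min(end[end > xy[1]]) else length(lines) + 1L
  dat <- lines[(xy[1] + 1L):(end - 1L)]
  xs <- numeric(0); ys <- numeric(0)
  for (ln in dat) {
    tok <- as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]])
    if (length(tok) < 2) next
    x0 <- tok[1] * xf
    yv <- tok[-1] * yf
    xs <- c(xs, x0)
    ys <- c(ys, yv)
  }
  # reconstruct full x grid from line-start x values and counts per line
  first <- as.numeric(getfield("FIRSTX")) %||% xs[1]
  last <- as.numeric(getfield("LASTX"))
  n <- if (!is.na(npt) && length(npt)) npt else length(ys)
  if (length(ys) != n) stop("JCAMP NPOINTS (", n, ") != values read (",
                            length(ys), ")")
  wn <- seq(first, if (!is.null(last)) last else xs[length(xs)],
            length.out = n)
  title <- getfield("TITLE") %||% "jcamp"
  spectra_set(wn, matrix(ys, nrow = 1), sample_ids = title)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Write a single spectrum as JCAMP-DX
#'
#' Minimal `XYDATA=(X++(Y..Y))` writer (one spectrum; the first sample of
#' the set is written).
#'
#' @param x A [spectra_set()].
#' @param path Output file.
#' @param sample Row index of the spectrum to write.
#' @return `path`, invisibly.
#' @export
write_jcamp <- function(x, path, sample = 1L) {
  stopifnot(inherits(x, "spectra_set"))
  wn <- x$wavenumbers
  y <- x$absorbance[sample, ]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("##TITLE=", x$sample_ids[sample]),
    "##JCAMP-DX=4.24", "##DATA TYPE=NEAR INFRARED SPECTRUM",
    "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
    "##XFACTOR=1", "##YFACTOR=1e-8",
    paste0("##FIRSTX=", wn[1]), paste0("##LASTX=", wn[length(wn)]),
    paste0("##NPOINTS=", length(wn)),
    "##XYDATA=(X++(Y..Y))"), con)
  idx <- split(seq_along(wn), ceiling(seq_along(wn) / 8))
  for (ii in idx) {
    writeLines(paste(c(format(wn[ii[1]], scientific = FALSE),
                       sprintf("%.0f", y[ii] / 1e-8)), collapse = " "), con)
  }
  writeLines("##END=", con)
  invisible(path)
}

#' Write an LC-MS feature table to CSV
#'
#' Layout: header `sample_id,class,<feature ids...>`, then two metadata rows
#' with `sample_id` equal to `mz` and `rt` holding per-feature m/z and
#' retention time, then one row per sample.
#'
#' @param x A [feature_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  cls <- if (is.null(x$class_labels)) rep("", nrow(x$areas)) else x$class_labels
  hdr <- c("sample_id", "class", colnames(x$areas))
  rows <- rbind(
    c("mz", "", format(x$feature_mz, digits = 10, trim = TRUE)),
    c("rt", "", format(x$feature_rt, digits = 8, trim = TRUE)),
    cbind(x$sample_ids, cls,
          matrix(format(x$areas, digits = 10, trim = TRUE), nrow(x$areas)))
  )
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = ","), con)
  writeLines(apply(rows, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read an LC-MS feature table from CSV
#'
#' Expects the [write_feature_table()] layout. Negative areas and missing
#' `mz`/`rt` metadata rows are hard errors.
#'
#' @param path Input file.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (!all(c("sample_id", "class") == colnames(df)[1:2])) {
    stop("feature table must start with sample_id,class columns")
  }
  mzrow <- which(df$sample_id == "mz")
  rtrow <- which(df$sample_id == "rt")
  if (length(mzrow) != 1 || length(rtrow) != 1) {
    stop("feature table must contain exactly one mz and one rt metadata row")
  }
  feat <- colnames(df)[-(1:2)]
  mz <- as.numeric(df[mzrow, -(1:2)])
  rt <- as.numeric(df[rtrow, -(1:2)])
  dat <- df[-c(mzrow, rtrow), , drop = FALSE]
  areas <- matrix(as.numeric(as.matrix(dat[, -(1:2), drop = FALSE])),
                  nrow = nrow(dat))
  if (any(!is.na(areas) & areas < 0)) {
    bad <- which(areas < 0, arr.ind = TRUE)[1, ]
    stop("negative area for sample \"", dat$sample_id[bad[1]],
         "\", feature \"", feat[bad[2]], "\"")
  }
  colnames(areas) <- feat
  cls <- dat$class
  if (all(!nzchar(cls))) cls <- NULL
  feature_table(areas, mz, rt, sample_ids = dat$sample_id,
                class_labels = cls)
}

#' Write MS/MS peak lists as MGF
#'
#' @param peaklists A peak list (data frame with `mz`, `intensity` and a
#'   `precursor_mz` attribute) or a list of them.
#' @param path Output file.
#' @param titles Optional titles, one per peak list.
#' @return `path`, invisibly.
#' @export
write_ms2 <- function(peaklists, path, titles = NULL) {
  if (is.data.frame(peaklists)) peaklists <- list(peaklists)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(peaklists)) {
    pl <- peaklists[[i]]
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", if (!is.null(titles)) titles[i] else
      paste0("spectrum_", i)), con)
    pre <- attr(pl, "precursor_mz")
    if (!is.null(pre)) writeLines(paste0("PEPMASS=", pre), con)
    writeLines("CHARGE=1-", con)
    writeLines(sprintf("%.6f %.4f", pl$mz, pl$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read MS/MS peak lists from an MGF file
#'
#' Supports standard `BEGIN IONS`/`END IONS` records with `TITLE`, `PEPMASS`
#' and `mz intensity` peak lines.
#'
#' @param path Input MGF file.
#' @return A list of peak-list data frames (`mz`, `intensity`), each with
#'   `precursor_mz` and `title` attributes.
#' @export
read_ms2 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends)) {
    stop("malformed MGF: unmatched BEGIN IONS/END IONS in ", path)
  }
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    blk <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    title <- sub("^TITLE=", "", grep("^TITLE=", blk, value = TRUE)[1])
    pep <- grep("^PEPMASS=", blk, value = TRUE)
    pre <- if (length(pep)) as.numeric(strsplit(sub("^PEPMASS=", "", pep[1]),
                                                "[[:space:]]+")[[1]][1]) else NA
    pk <- blk[grepl("^[0-9]", blk)]
    if (length(pk) == 0) stop("MGF record ", i, " has no peaks")
    m <- do.call(rbind, lapply(strsplit(trimws(pk), "[[:space:]]+"),
                               function(v) as.numeric(v[1:2])))
    df <- data.frame(mz = m[, 1], intensity = m[, 2])
    attr(df, "precursor_mz") <- pre
    attr(df, "title") <- title
    out[[i]] <- df
  }
  out
}

#' Read a compound library
#'
#' CSV with columns `name` and `formula` (Hill notation, neutral
#' composition). Every formula is parsed eagerly so malformed entries fail
#' at read time naming the offending token.
#'
#' @param path Input CSV file.
#' @return A data frame with columns `name`, `formula` (string) and
#'   `neutral_mass` (monoisotopic Da).
#' @export
read_compound_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "formula") %in% colnames(df))) {
    stop("compound library needs columns: name, formula")
  }
  df$neutral_mass <- vapply(df$formula, function(f)
    monoisotopic_mz(parse_formula(f), "neutral"), numeric(1))
  rownames(df) <- NULL
  df
}
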