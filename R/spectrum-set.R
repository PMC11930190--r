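# Core containers: SpectrumSet and ConcentrationTable.
#
# A SpectrumSet is the exchange object of the whole pipeline: a descending
# wavenumber grid, an n_samples x n_points absorbance matrix, one class label
# per sample. Everything downstream (pretreatment, splitting, 2DCOS, PLS)
# consumes and returns SpectrumSets so band windows stay addressable.

#' Construct a SpectrumSet
#'
#' @param wavenumbers numeric grid in cm^-1, strictly monotonic. Ascending
#'   grids are flipped to the descending FTIR convention (with a message).
#' @param absorbance numeric matrix, one row per sample, `length(wavenumbers)`
#'   columns.
#' @param labels class label per sample (factor or character); optional.
#' @param sample_ids character ids; default `"s001"...`.
#' @return an object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavenumbers, absorbance, labels = NULL,
                         sample_ids = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  if (anyNA(wavenumbers)) stop("wavenumbers contain NA")
  d <- diff(wavenumbers)
  if (any(d == 0) || (any(d > 0) && any(d < 0)))
    stop("wavenumber grid must be strictly monotonic")
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (ncol(absorbance) != length(wavenumbers))
    stop("absorbance must have one column per wavenumber")
  if (anyNA(absorbance)) stop("absorbance contains missing values")
  if (all(d > 0)) {
    message("ascending wavenumber grid: flipping to descending convention")
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, seq(ncol(absorbance), 1), drop = FALSE]
  }
  n <- nrow(absorbance)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (length(sample_ids) != n) stop("sample_ids length mismatch")
  if (!is.null(labels)) {
    if (length(labels) != n) stop("labels length must equal sample count")
    labels <- as.factor(labels)
  }
  rownames(absorbance) <- sample_ids
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 labels = labels, sample_ids = sample_ids),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d samples x %d points, %.0f-%.0f cm-1\n",
              nrow(x$absorbance), length(x$wavenumbers),
              x$wavenumbers[1], x$wavenumbers[length(x$wavenumbers)]))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$absorbance)

#' Subset a SpectrumSet by samples
#'
#' @param x a `spectrum_set`.
#' @param i sample index vector.
#' @param ... unused.
#' @return a `spectrum_set` with the selected rows.
#' @export
`[.spectrum_set` <- function(x, i, ...) {
  spectrum_set(x$wavenumbers, x$absorbance[i, , drop = FALSE],
               labels = if (!is.null(x$labels)) x$labels[i],
               sample_ids = x$sample_ids[i])
}

#' Restrict a SpectrumSet to a wavenumber window
#'
#' @param x a `spectrum_set`.
#' @param upper,lower window bounds in cm^-1 (inclusive).
#' @return a `spectrum_set` on the points with `lower <= v <= upper`.
#' @export
band_window <- function(x, upper, lower) {
  keep <- x$wavenumbers <= max(upper, lower) & x$wavenumbers >= min(upper, lower)
  if (!any(keep)) stop("empty band window")
  spectrum_set(x$wavenumbers[keep], x$absorbance[, keep, drop = FALSE],
               labels = x$labels, sample_ids = x$sample_ids)
}

#' Construct a ConcentrationTable
#'
#' Samples x compounds matrix of non-negative concentrations with a taste
#' class annotation (umami/sweet/bitter/sour/other) per compound.
#'
#' @param values numeric matrix (samples x compounds), all `>= 0`.
#' @param compound_names unique compound names.
#' @param taste_class character vector, one per compound.
#' @param sample_ids character ids.
#' @return an object of class `concentration_table`.
#' @export
concentration_table <- function(values, compound_names,
                                taste_class = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("concentration values contain NA")
  if (any(values < 0)) stop("concentrations must be non-negative")
  compound_names <- as.character(compound_names)
  if (length(compound_names) != ncol(values))
    stop("one compound name per column required")
  if (anyDuplicated(compound_names)) stop("compound names must be unique")
  if (is.null(taste_class)) taste_class <- rep("other", ncol(values))
  if (length(taste_class) != ncol(values)) stop("taste_class length mismatch")
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(nrow(values)))
  colnames(values) <- compound_names
  rownames(values) <- sample_ids
  structure(list(values = values, compound_names = compound_names,
                 taste_class = as.character(taste_class),
                 sample_ids = as.character(sample_ids)),
            class = "concentration_table")
}

#' @export
print.concentration_table <- function(x, ...) {
  cat(sprintf("<concentration_table> %d samples x %d compounds\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read spectra from a wide CSV
#'
#' Expects column 1 `wavenumber_cm-1` and one absorbance column per sample;
#' labels optionally joined from a companion CSV with columns
#' `sample_id, temperature_class`.
#'
#' @param path spectra CSV path.
#' @param labels_path optional labels CSV path.
#' @return a `spectrum_set`.
#' @export
read_spectra <- function(path, labels_path = NULL) {
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("spectra CSV needs a wavenumber column plus samples")
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("non-numeric cells in spectra CSV")
  wn <- df[[1]]
  mat <- t(as.matrix(df[, -1, drop = FALSE]))
  ids <- colnames(df)[-1]
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- read.csv(labels_path, check.names = FALSE)
    if (!all(c("sample_id", "temperature_class") %in% names(lab)))
      stop("labels CSV must have sample_id and temperature_class columns")
    idx <- match(ids, lab$sample_id)
    if (anyNA(idx)) stop("labels missing for some sample ids")
    labels <- lab$temperature_class[idx]
  }
  spectrum_set(wn, mat, labels = labels, sample_ids = ids)
}

#' Write spectra to a wide CSV (lossless round-trip)
#'
#' @param x a `spectrum_set`.
#' @param path output CSV; a companion `<path-sans-ext>_labels.csv` is written
#'   when labels are present.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  df <- data.frame(wn = x$wavenumbers, check.names = FALSE)
  names(df) <- "wavenumber_cm-1"
  ab <- t(x$absorbance)
  colnames(ab) <- x$sample_ids
  df <- cbind(df, as.data.frame(ab, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  if (!is.null(x$labels)) {
    lp <- sub("\\.csv$", "_labels.csv", path)
    write.csv(data.frame(sample_id = x$sample_ids,
                         temperature_class = as.character(x$labels)),
              lp, row.names = FALSE)
  }
  invisible(path)
}

#' Read a concentration table from CSV
#'
#' @param path CSV with a `sample_id` column and one numeric column per
#'   compound; an optional companion `<path-sans-ext>_classes.csv`
#'   (compound, taste_class) supplies taste annotations.
#' @return a `concentration_table`.
#' @export
read_concentrations <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("concentration CSV needs sample_id")
  ids <- as.character(df$sample_id)
  vals <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  taste <- NULL
  cp <- sub("\\.csv$", "_classes.csv", path)
  if (file.exists(cp)) {
    cl <- read.csv(cp, check.names = FALSE)
    taste <- cl$taste_class[match(colnames(vals), cl$compound)]
  }
  concentration_table(vals, colnames(vals), taste_class = taste,
                      sample_ids = ids)
}

#' Write a concentration table to CSV
#'
#' @param x a `concentration_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentrations <- function(x, path) {
  df <- data.frame(sample_id = x$sample_ids, check.names = FALSE)
  df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  write.csv(data.frame(compound = x$compound_names,
                       taste_class = x$taste_class),
            sub("\\.csv$", "_classes.csv", path), row.names = FALSE)
  invisible(path)
}
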