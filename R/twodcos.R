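# Generalized two-dimensional correlation spectroscopy (synchronous maps).
#
# Dynamic spectra are deviations from a reference (usually the series mean);
# the synchronous map is Phi = S^T S / (m - 1), i.e. the covariance of the
# dynamic spectra across the perturbation axis. Per-sample rank-1 maps
# (outer product of one dynamic spectrum with itself) provide one image per
# sample for supervised learning.

#' Dynamic spectra (deviations from a reference)
#'
#' @param spectra a `spectrum_set` or m x p matrix.
#' @param reference reference spectrum; default the mean of the m spectra.
#' @return a `dynamic_spectra` object: `matrix` (m x p), `reference`,
#'   `wavenumbers`.
#' @export
dynamic_spectra <- function(spectra, reference = NULL) {
  wn <- NULL
  if (inherits(spectra, "spectrum_set")) {
    wn <- spectra$wavenumbers
    X <- spectra$absorbance
  } else X <- as.matrix(spectra)
  if (is.null(reference)) reference <- colMeans(X)
  if (length(reference) != ncol(X))
    stop("reference grid does not match spectra")
  structure(list(matrix = sweep(X, 2, reference, "-"),
                 reference = as.numeric(reference), wavenumbers = wn),
            class = "dynamic_spectra")
}

#' Synchronous 2D correlation map
#'
#' `Phi = S^T S / (m - 1)` for the m x p dynamic matrix S: the sample
#' covariance of spectral intensities across the perturbation axis.
#' Symmetric with non-negative auto-peaks on the diagonal.
#'
#' @param dyn a [dynamic_spectra()] object or m x p matrix of deviations.
#' @return a `sync_map`: `matrix` (p x p), `m`, `wavenumbers`.
#' @export
synchronous_map <- function(dyn) {
  wn <- NULL
  if (inherits(dyn, "dynamic_spectra")) {
    wn <- dyn$wavenumbers
    S <- dyn$matrix
  } else S <- as.matrix(dyn)
  m <- nrow(S)
  if (m < 2) stop("synchronous map needs m >= 2 spectra")
  Phi <- crossprod(S) / (m - 1)
  Phi <- (Phi + t(Phi)) / 2  # enforce exact symmetry against rounding
  structure(list(matrix = Phi, m = m, wavenumbers = wn), class = "sync_map")
}

#' Per-sample rank-1 synchronous map
#'
#' The m = 1 outer-product convention: `Phi = s s^T` with
#' `s = spectrum - reference`. One image per sample, as required for
#' supervised classification of correlation maps.
#'
#' @param spectrum numeric p-vector (one sample).
#' @param reference numeric p-vector (usually the global mean spectrum).
#' @param wavenumbers optional grid.
#' @return a `sync_map` with `m = 1`.
#' @export
per_sample_map <- function(spectrum, reference, wavenumbers = NULL) {
  spectrum <- as.numeric(spectrum)
  reference <- as.numeric(reference)
  if (length(spectrum) != length(reference))
    stop("spectrum and reference grids do not match")
  s <- spectrum - reference
  structure(list(matrix = tcrossprod(s), m = 1, wavenumbers = wavenumbers),
            class = "sync_map")
}

#' @export
print.sync_map <- function(x, ...) {
  cat(sprintf("<sync_map> %d x %d (m = %d)\n", nrow(x$matrix),
              ncol(x$matrix), x$m))
  invisible(x)
}

#' Characterization band windows
#'
#' The four characterization bands of dried porcini spectra plus the full
#' range: O-H/C-H stretch, protein/fingerprint, polysaccharide, and ring
#' region.
#'
#' @return named list of `c(upper, lower)` cm^-1 windows.
#' @export
band_windows <- function() {
  list(full = c(4000, 400), oh_ch = c(3400, 2800),
       protein = c(1850, 1200), polysaccharide = c(1200, 750),
       ring = c(630, 400))
}

# Resampling weights from p points to `size` points. Downsampling uses
# bin averaging (anti-aliasing: sharp bands must not fall between sample
# positions); upsampling uses linear interpolation. Returns a size x p
# matrix with rows summing to 1.
resample_weights <- function(p, size) {
  W <- matrix(0, size, p)
  if (size <= p) {
    bin <- ceiling(seq_len(p) * size / p)
    for (i in seq_len(size)) {
      j <- which(bin == i)
      W[i, j] <- 1 / length(j)
    }
  } else {
    pos <- seq(1, p, length.out = size)
    lo <- pmin(floor(pos), p - 1)
    fr <- pos - lo
    W[cbind(seq_len(size), lo)] <- 1 - fr
    W[cbind(seq_len(size), lo + 1)] <- W[cbind(seq_len(size), lo + 1)] + fr
  }
  W
}

resample_vec <- function(x, size) as.numeric(resample_weights(length(x), size) %*% x)

# Jet-style colormap: intensity in [0,1] -> RGB in [0,1].
jet_rgb <- function(z) {
  r <- pmin(pmax(1.5 - abs(4 * z - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * z - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * z - 1), 0), 1)
  cbind(r, g, b)
}

#' Render a synchronous map as an RGB raster
#'
#' Restricts the map to a band window, bilinearly resamples it to a fixed
#' square size, min-max normalizes intensities to `[0, 1]`, and applies a
#' jet-style colormap. Deterministic for fixed inputs. A constant map
#' renders as a uniform mid-scale image.
#'
#' @param map a `sync_map` (must carry wavenumbers when `window` is used).
#' @param window `c(upper, lower)` cm^-1, or `NULL` for the whole map.
#' @param size output raster side (pixels).
#' @return numeric array `size x size x 3` in `[0, 1]`.
#' @export
render_map <- function(map, window = NULL, size = 224) {
  M <- map$matrix
  if (!is.null(window)) {
    if (is.null(map$wavenumbers)) stop("map carries no wavenumber grid")
    keep <- map$wavenumbers <= max(window) & map$wavenumbers >= min(window)
    if (!any(keep)) stop("empty band window")
    M <- M[keep, keep, drop = FALSE]
  }
  # separable resampling to size x size
  Rrow <- resample_weights(nrow(M), size)
  Ms <- Rrow %*% M %*% t(Rrow)
  rng <- range(Ms)
  Z <- if (rng[2] - rng[1] < .Machine$double.eps) {
    matrix(0.5, size, size)
  } else (Ms - rng[1]) / (rng[2] - rng[1])
  rgb <- jet_rgb(as.numeric(Z))
  array(rgb, dim = c(size, size, 3))
}

#' Build per-sample 2DCOS images for a spectrum set
#'
#' For every sample, the rank-1 synchronous map of its deviation from the
#' global mean spectrum is rendered inside `window`. Spectra are
#' scatter-corrected (SNV) first by default: per-sample rank-1 maps of raw
#' deviations are dominated by multiplicative/additive scatter, which
#' carries no class information. Because bilinear resampling of the outer
#' product `s s^T` is separable, the deviation vector is resampled first
#' and the outer product taken afterwards, which is exactly equivalent and
#' avoids materializing p x p maps.
#'
#' @param spectra a `spectrum_set`.
#' @param window `c(upper, lower)` cm^-1 window (default full spectrum).
#' @param size raster side in pixels.
#' @param scatter_correct apply SNV before the deviation (default TRUE).
#' @return array `n x size x size x 3`, with the class labels attached as
#'   attribute `labels`.
#' @export
sample_map_images <- function(spectra, window = c(4000, 400), size = 64,
                              scatter_correct = TRUE) {
  if (scatter_correct) spectra <- snv(spectra)
  keep <- spectra$wavenumbers <= max(window) &
    spectra$wavenumbers >= min(window)
  if (!any(keep)) stop("empty band window")
  X <- spectra$absorbance[, keep, drop = FALSE]
  ref <- colMeans(X)
  n <- nrow(X)
  out <- array(0, dim = c(n, size, size, 3))
  Rw <- resample_weights(ncol(X), size)
  for (i in seq_len(n)) {
    s <- as.numeric(Rw %*% (X[i, ] - ref))
    M <- tcrossprod(s)
    rng <- range(M)
    Z <- if (rng[2] - rng[1] < .Machine$double.eps) matrix(0.5, size, size)
         else (M - rng[1]) / (rng[2] - rng[1])
    out[i, , , ] <- array(jet_rgb(as.numeric(Z)), dim = c(size, size, 3))
  }
  attr(out, "labels") <- spectra$labels
  attr(out, "sample_ids") <- spectra$sample_ids
  out
}

#' Write a rendered map (or image array slice) to a portable pixmap
#'
#' Images are written as plain-text PPM (P3), or PNG when the `png` package
#' is installed.
#'
#' @param img `size x size x 3` array in `[0, 1]`.
#' @param path output path (`.ppm` or `.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (grepl("\\.png$", path)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("png package not available; write a .ppm instead")
    png::writePNG(img, path)
    return(invisible(path))
  }
  v <- round(255 * aperm(img, c(3, 2, 1)))  # channel-fastest, row-major
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("P3\n%d %d\n255", dim(img)[2], dim(img)[1]), con)
  writeLines(paste(as.integer(v), collapse = " "), con)
  invisible(path)
}
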