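# Synthetic ATR-FTIR data generator.
#
# The generator states a world with the structure the downstream analysis
# assumes: five drying-temperature classes whose band intensities shift with
# temperature at the characteristic mushroom peaks (proteins, aliphatics,
# polysaccharides, ring compounds), multiplicative scatter, a slow polynomial
# baseline, and iid detector noise. Taste-compound concentrations are linear
# in the 1800-1200 cm^-1 fingerprint band, so PLSR has a true coupling to
# recover.

#' Default descending wavenumber grid
#'
#' Arithmetic grid from `start` down to `end` at `step` cm^-1 spacing; the
#' default 4000-400 cm^-1 at 4 cm^-1 gives 901 points.
#'
#' @param start,end grid limits in cm^-1.
#' @param step spacing in cm^-1 (> 0).
#' @return descending numeric grid.
#' @export
#' @examples
#' length(default_grid())  # 901
default_grid <- function(start = 4000, end = 400, step = 4) {
  if (step <= 0) stop("step must be positive")
  hi <- max(start, end); lo <- min(start, end)
  if (step > hi - lo) stop("step larger than grid range")
  seq(hi, lo, by = -step)
}

#' Characteristic peak library for dried porcini powder
#'
#' Fifteen Gaussian bands at the characteristic positions of dried mushroom
#' ATR-FTIR spectra: the 3200 cm^-1 O-H/N-H broadband, aliphatic CH2 at
#' 2928/2840, amide I/II at 1620/1554, COO- at 1400, amide III at 1228, the
#' polysaccharide complex (1147, 1100, 1017, 918), glucan markers (890, 760)
#' and ring modes (620, 526). `class_deltas` encode how each band intensity
#' moves across the five drying temperatures (35-75 deg C); protein/amide
#' bands fall with temperature, polysaccharide bands rise, and some bands
#' peak at the mild 45 deg C treatment.
#'
#' @return data.frame with columns `center`, `width`, `base_amplitude` and a
#'   5-column `class_deltas` matrix.
#' @export
default_peaks <- function() {
  tbl <- data.frame(
    center = c(3200, 2928, 2840, 1620, 1554, 1400, 1228, 1147, 1100, 1017,
               918, 890, 760, 620, 526),
    width = c(25, 10, 10, 14, 12, 10, 10, 8, 8, 10, 8, 8, 8, 8, 8),
    base_amplitude = c(0.32, 0.12, 0.08, 0.30, 0.18, 0.15, 0.10, 0.20, 0.25,
                       0.50, 0.12, 0.08, 0.06, 0.10, 0.09)
  )
  # Four temperature-response motifs (the patterns real metabolite trends
  # show): monotone fall, monotone rise, a peak at the mild 45 deg C
  # treatment, and a mid-range 55-65 deg C plateau. Spreading the motifs
  # over the bands makes the five class-mean spectra span a full
  # 4-dimensional configuration rather than a single monotone direction.
  deltas <- rbind(
    c( 0.100,  0.050,  0.000, -0.050, -0.100),  # 3200: water/N-H falls
    c(-0.040,  0.080,  0.020, -0.020, -0.040),  # 2928: aliphatics peak at 45
    c( 0.060,  0.030,  0.000, -0.030, -0.060),  # 2840: falls
    c(-0.100, -0.050,  0.000,  0.050,  0.100),  # 1620: amide I rises
    c(-0.040,  0.000,  0.080,  0.000, -0.040),  # 1554: amide II mid peak
    c(-0.020,  0.080,  0.040,  0.000, -0.040),  # 1400: COO- peak at 45
    c(-0.030, -0.030, -0.010,  0.040,  0.060),  # 1228: amide III high-T
    c(-0.020,  0.000,  0.050,  0.000, -0.020),  # 1147: mid peak
    c( 0.000, -0.030, -0.030,  0.030,  0.060),  # 1100: high-T rise
    c(-0.120, -0.060,  0.000,  0.060,  0.120),  # 1017: glucans rise
    c( 0.000,  0.000,  0.000,  0.000,  0.000),  # 918: temperature-inert
    c(-0.010, -0.005,  0.000,  0.005,  0.010),  # 890
    c( 0.000,  0.000,  0.000,  0.000,  0.000),  # 760: temperature-inert
    c( 0.050,  0.000, -0.050,  0.000,  0.050),  # 620: extremes up
    c(-0.050,  0.050,  0.000, -0.050,  0.050)   # 526: alternating
  )
  colnames(deltas) <- c("35", "45", "55", "65", "75")
  tbl$class_deltas <- deltas
  validate_peaks(tbl)
  tbl
}

validate_peaks <- function(peaks) {
  if (nrow(peaks) == 0) stop("empty peak list")
  if (any(peaks$width <= 0)) stop("peak widths must be positive")
  if (any(peaks$center < 400 | peaks$center > 4000))
    stop("peak centers must lie in [400, 4000] cm^-1")
  invisible(peaks)
}

#' Experiment design for the synthetic generator
#'
#' Defaults mirror the discrimination study: five temperatures with sample
#' counts 22/18/18/21/20 (99 spectra) on the 4000-400 cm^-1, 4 cm^-1 grid.
#' For the quantification study use `samples_per_class = rep(6, 5)`
#' (30 spectra). Scatter, baseline and noise scales are package choices for
#' realistic bench variability (noise_sd 0.004 AU against adjacent-class
#' band shifts of 0.02-0.06 AU keeps discriminating bands >= 5 noise-sd
#' apart; see the methods vignette for the calibration rationale).
#'
#' @param class_labels temperature names, coldest first.
#' @param samples_per_class positive integer counts, one per class.
#' @param grid_start,grid_end,grid_step grid parameters in cm^-1.
#' @param scatter_slope_sd sd of the multiplicative scatter slope around 1.
#' @param scatter_offset_sd sd of the additive scatter offset (AU).
#' @param baseline_coeffs_sd sds of the degree-0..2 baseline polynomial
#'   coefficients (on a grid normalized to `[-1, 1]`).
#' @param noise_sd iid detector noise sd (AU).
#' @param seed integer seed for the whole design.
#' @return an `experiment_design` list.
#' @export
experiment_design <- function(class_labels = c("35", "45", "55", "65", "75"),
                              samples_per_class = c(22, 18, 18, 21, 20),
                              grid_start = 4000, grid_end = 400, grid_step = 4,
                              scatter_slope_sd = 0.03,
                              scatter_offset_sd = 0.02,
                              baseline_coeffs_sd = c(0.03, 0.012, 0.005),
                              noise_sd = 0.004, seed = 1L) {
  if (length(samples_per_class) != length(class_labels))
    stop("samples_per_class length must match class_labels")
  if (any(samples_per_class <= 0)) stop("all class counts must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(class_labels = as.character(class_labels),
                 samples_per_class = as.integer(samples_per_class),
                 grid_start = grid_start, grid_end = grid_end,
                 grid_step = grid_step,
                 scatter_slope_sd = scatter_slope_sd,
                 scatter_offset_sd = scatter_offset_sd,
                 baseline_coeffs_sd = baseline_coeffs_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "experiment_design")
}

#' Generate synthetic ATR-FTIR spectra
#'
#' For a sample of class k the absorbance at wavenumber v is
#' `slope * sum_i (base_i + delta_i[k]) * G(v; center_i, width_i) + offset +
#' baseline(v) + eps(v)` with `slope ~ 1 + N(0, scatter_slope_sd)`,
#' `offset ~ N(0, scatter_offset_sd)`, a per-sample random degree-2
#' polynomial baseline, and iid `N(0, noise_sd)` noise. Fully reproducible
#' for a fixed design seed.
#'
#' @param design an [experiment_design()].
#' @param peaks a peak table as from [default_peaks()]; `class_deltas` must
#'   have one column per class.
#' @return a `spectrum_set` with one row per sample.
#' @export
generate_spectra <- function(design = experiment_design(),
                             peaks = default_peaks()) {
  validate_peaks(peaks)
  k <- length(design$class_labels)
  if (ncol(peaks$class_deltas) != k)
    stop("class_deltas must have one column per class")
  wn <- default_grid(design$grid_start, design$grid_end, design$grid_step)
  u <- (wn - mean(wn)) / (diff(range(wn)) / 2)  # grid normalized to [-1, 1]
  # Gaussian design matrix: one column per peak
  G <- vapply(seq_len(nrow(peaks)), function(i)
    exp(-(wn - peaks$center[i])^2 / (2 * peaks$width[i]^2)),
    numeric(length(wn)))
  clean <- vapply(seq_len(k), function(j)
    as.numeric(G %*% (peaks$base_amplitude + peaks$class_deltas[, j])),
    numeric(length(wn)))

  n <- sum(design$samples_per_class)
  labels <- rep(design$class_labels, design$samples_per_class)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stage_seed(design$seed, "spectra"))
  bsd <- design$baseline_coeffs_sd
  mat <- matrix(0, n, length(wn))
  for (s in seq_len(n)) {
    j <- match(labels[s], design$class_labels)
    slope <- 1 + rnorm(1, 0, design$scatter_slope_sd)
    offset <- rnorm(1, 0, design$scatter_offset_sd)
    bc <- rnorm(length(bsd), 0, bsd)
    baseline <- as.numeric(cbind(1, u, u^2)[, seq_along(bc), drop = FALSE] %*% bc)
    eps <- if (design$noise_sd > 0) rnorm(length(wn), 0, design$noise_sd) else 0
    mat[s, ] <- slope * clean[, j] + offset + baseline + eps
  }
  spectrum_set(wn, mat, labels = labels)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Default spectrum-concentration coupling for the 11 taste compounds
#'
#' Each compound reads the fingerprint band through a Gaussian weight profile
#' centred on one of the amide/carboxylate bands inside 1800-1200 cm^-1, so
#' concentrations are linear functionals of the band absorbance.
#'
#' @param wavenumbers full descending grid.
#' @param band upper/lower band limits in cm^-1.
#' @return list with `compounds`, `taste_class`, and a weight matrix `W`
#'   (band points x compounds) defined on the in-band grid points.
#' @export
default_coupling <- function(wavenumbers, band = c(1800, 1200)) {
  compounds <- c("L-tyrosine", "L-arginine", "L-alanine", "L-serine",
                 "L-methionine", "adipic acid", "lactic acid",
                 "tartaric acid", "creatine", "pantothenic acid", "taurine")
  taste <- c("bitter", "bitter", "sweet", "sweet", "other",
             "sour", "sour", "sour", "umami", "other", "other")
  inb <- wavenumbers <= max(band) & wavenumbers >= min(band)
  v <- wavenumbers[inb]
  centers <- c(1620, 1554, 1400, 1228, 1680, 1310, 1580, 1450, 1260, 1350, 1530)
  widths <- c(30, 25, 30, 25, 35, 30, 25, 30, 25, 30, 25)
  sign2 <- c(1, -1, 1, 1, -1, 1, -1, 1, 1, -1, 1)
  W <- vapply(seq_along(compounds), function(j) {
    w <- exp(-(v - centers[j])^2 / (2 * widths[j]^2))
    # a weaker secondary lobe makes compounds non-collinear
    w + 0.4 * sign2[j] * exp(-(v - (centers[j] - 120))^2 / (2 * 40^2))
  }, numeric(length(v)))
  colnames(W) <- compounds
  list(compounds = compounds, taste_class = taste, W = W,
       wavenumbers = v, band = sort(band, decreasing = TRUE))
}

#' Generate taste-compound concentrations coupled to the fingerprint band
#'
#' `concentration_j = x_band . w_j + intercept_j + N(0, noise_sd_j)`, clipped
#' at zero (clip events are counted in the generation log). The per-compound
#' noise sd is set from the signal: `noise_sd_j = sd(signal_j) / snr`, so the
#' stated signal-to-noise ratio holds for every compound. The ground-truth
#' weights, intercepts and noise sds are attached for recovery tests.
#'
#' @param spectra a `spectrum_set` (raw, full grid).
#' @param coupling a coupling as from [default_coupling()]; weights must live
#'   inside the band.
#' @param snr target signal-to-noise ratio (default 10).
#' @param noise_sd optional fixed per-compound noise sd overriding `snr`.
#' @param seed integer seed.
#' @return a `concentration_table` with attributes `truth` (list: `W`,
#'   `intercept`, `noise_sd`, `band`) and `n_clipped`.
#' @export
generate_concentrations <- function(spectra,
                                    coupling = default_coupling(spectra$wavenumbers),
                                    snr = 10, noise_sd = NULL, seed = 1L) {
  band <- coupling$band
  inb <- spectra$wavenumbers <= max(band) & spectra$wavenumbers >= min(band)
  if (!isTRUE(all.equal(spectra$wavenumbers[inb], coupling$wavenumbers)))
    stop("coupling weights reference points outside the spectral band")
  X <- spectra$absorbance[, inb, drop = FALSE]
  signal <- X %*% coupling$W
  sds <- apply(signal, 2, sd)
  if (is.null(noise_sd)) noise_sd <- sds / snr
  noise_sd <- rep_len(noise_sd, ncol(signal))
  # keep typical concentrations positive: baseline offset per compound
  intercept <- pmax(0, -apply(signal, 2, min)) + 2 * sds
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stage_seed(seed, "concentrations"))
  eps <- matrix(rnorm(length(signal), 0, rep(noise_sd, each = nrow(signal))),
                nrow(signal), ncol(signal))
  raw <- sweep(signal + eps, 2, intercept, "+")
  n_clipped <- sum(raw < 0)
  if (n_clipped > 0)
    message(sprintf("generation log: %d negative concentration draw(s) clipped to 0",
                    n_clipped))
  vals <- pmax(raw, 0)
  out <- concentration_table(vals, coupling$compounds,
                             taste_class = coupling$taste_class,
                             sample_ids = spectra$sample_ids)
  attr(out, "truth") <- list(W = coupling$W, intercept = intercept,
                             noise_sd = noise_sd, band = band)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Write an experiment design to YAML
#'
#' @param design an `experiment_design`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  yaml::write_yaml(unclass(design), path)
  invisible(path)
}

#' Read an experiment design from YAML
#'
#' @param path YAML file as written by [write_design()].
#' @return an `experiment_design`.
#' @export
read_design <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(experiment_design, x)
}
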