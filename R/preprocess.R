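# Spectral pretreatments: MSC, SNV, Savitzky-Golay smoothing/derivatives,
# and ordered combinations. All operations are row-wise; the only state that
# crosses samples is the MSC reference, which is learned on calibration data
# and reused on held-out data.

#' Multiplicative scatter correction
#'
#' Each spectrum x is regressed on the reference (x = a * ref + b by least
#' squares) and replaced by `(x - b) / a`.
#'
#' @param spectra a `spectrum_set`.
#' @param reference reference spectrum; default the mean spectrum of
#'   `spectra` (requires >= 2 samples).
#' @return a `spectrum_set` with attribute `reference` for reuse on held-out
#'   data.
#' @export
msc <- function(spectra, reference = NULL) {
  X <- spectra$absorbance
  if (is.null(reference)) {
    if (nrow(X) < 2)
      stop("internal mean reference requires at least 2 samples")
    reference <- colMeans(X)
  }
  if (length(reference) != ncol(X)) stop("reference length mismatch")
  vr <- sum((reference - mean(reference))^2)
  if (vr < .Machine$double.eps) stop("zero-variance MSC reference")
  rc <- reference - mean(reference)
  a <- as.numeric(X %*% rc) / vr                       # per-row slope
  b <- rowMeans(X) - a * mean(reference)               # per-row intercept
  if (any(abs(a) < .Machine$double.eps)) stop("degenerate MSC slope (0)")
  out <- sweep(sweep(X, 1, b, "-"), 1, a, "/")
  res <- spectrum_set(spectra$wavenumbers, out, labels = spectra$labels,
                      sample_ids = spectra$sample_ids)
  attr(res, "reference") <- reference
  res
}

#' Standard normal variate
#'
#' Row-wise standardization: every spectrum gets mean 0 and sample sd 1.
#'
#' @param spectra a `spectrum_set`.
#' @return a `spectrum_set`.
#' @export
snv <- function(spectra) {
  X <- spectra$absorbance
  s <- apply(X, 1, sd)
  if (any(s < .Machine$double.eps)) stop("constant row: SNV undefined")
  out <- sweep(sweep(X, 1, rowMeans(X), "-"), 1, s, "/")
  spectrum_set(spectra$wavenumbers, out, labels = spectra$labels,
               sample_ids = spectra$sample_ids)
}

# Savitzky-Golay design pseudo-inverse for window positions z and the given
# polynomial order: row (d+1) gives the d-th derivative filter (up to d!).
sg_pinv <- function(z, polyorder) {
  A <- outer(z, 0:polyorder, "^")
  solve(crossprod(A), t(A))
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Row-wise local-polynomial convolution. Interior points use the centred
#' window; the first and last `(window - 1) / 2` points are evaluated
#' off-centre from a polynomial fitted to the boundary window. Derivatives
#' are scaled by the (signed) grid step, so units are absorbance per cm^-1
#' (first) or per cm^-2 (second); on the conventional descending grid the
#' step is negative.
#'
#' @param spectra a `spectrum_set`.
#' @param window odd window length > `polyorder`.
#' @param polyorder polynomial order.
#' @param deriv_order derivative order in `{0, 1, 2}`, `<= polyorder`.
#' @return a `spectrum_set`.
#' @export
savitzky_golay <- function(spectra, window = 15, polyorder = 2,
                           deriv_order = 0) {
  if (window %% 2 != 1) stop("SG window must be odd")
  if (polyorder >= window) stop("SG polyorder must be < window")
  if (!deriv_order %in% 0:2) stop("deriv_order must be 0, 1 or 2")
  if (deriv_order > polyorder) stop("deriv_order must be <= polyorder")
  X <- spectra$absorbance
  p <- ncol(X)
  if (p < window) stop("spectrum shorter than SG window")
  h <- (window - 1) / 2
  step <- spectra$wavenumbers[2] - spectra$wavenumbers[1]  # signed, cm^-1
  Cc <- sg_pinv(-h:h, polyorder)          # centred filters
  cc <- factorial(deriv_order) * Cc[deriv_order + 1, ]
  out <- matrix(0, nrow(X), p)
  # interior: accumulate shifted columns (vectorized over samples)
  mid <- (h + 1):(p - h)
  acc <- matrix(0, nrow(X), length(mid))
  for (k in -h:h) acc <- acc + cc[k + h + 1] * X[, mid + k, drop = FALSE]
  out[, mid] <- acc
  # edges: off-centre evaluation of the boundary-window polynomial fit.
  # Fit on points z = 0..window-1; the d-th derivative at position e is
  # sum_j j!/(j-d)! * e^(j-d) * beta_j with beta = Cb %*% y.
  Cb <- sg_pinv(0:(window - 1), polyorder)
  dpow <- function(e) {
    j <- 0:polyorder
    co <- ifelse(j >= deriv_order,
                 factorial(j) / factorial(pmax(j - deriv_order, 0)) *
                   e^pmax(j - deriv_order, 0), 0)
    co
  }
  Eleft <- t(vapply(0:(h - 1), function(e) as.numeric(dpow(e) %*% Cb),
                    numeric(window)))
  out[, 1:h] <- X[, 1:window, drop = FALSE] %*% t(Eleft)
  Eright <- t(vapply((window - h):(window - 1),
                     function(e) as.numeric(dpow(e) %*% Cb),
                     numeric(window)))
  out[, (p - h + 1):p] <- X[, (p - window + 1):p, drop = FALSE] %*% t(Eright)
  if (deriv_order > 0) out <- out / step^deriv_order
  spectrum_set(spectra$wavenumbers, out, labels = spectra$labels,
               sample_ids = spectra$sample_ids)
}

#' Parse a pretreatment chain specification
#'
#' Accepts the chain names used in the model-comparison tables: `"Raw"`,
#' `"FD"`, `"SD"`, `"S-G"`, `"MSC"`, `"SNV"` and `+`-joined combinations
#' such as `"FD+MSC"` (applied left to right). FD/SD are Savitzky-Golay
#' derivatives (window 15, polyorder 2/3); `"S-G"` is SG smoothing.
#'
#' @param spec chain string, or an already-built chain (returned unchanged).
#' @param sg_window,fd_polyorder,sd_polyorder SG parameter defaults.
#' @return a `pretreatment_chain`: list of steps with parameters.
#' @export
pretreatment_chain <- function(spec, sg_window = 15, fd_polyorder = 2,
                               sd_polyorder = 3) {
  if (inherits(spec, "pretreatment_chain")) return(spec)
  tokens <- trimws(strsplit(spec, "+", fixed = TRUE)[[1]])
  tokens <- tokens[tokens != ""]
  steps <- list()
  for (tk in tokens) {
    up <- toupper(tk)
    st <- switch(up,
      "RAW" = NULL,
      "FD" = list(step = "SG", window = sg_window, polyorder = fd_polyorder,
                  deriv_order = 1),
      "SD" = list(step = "SG", window = sg_window, polyorder = sd_polyorder,
                  deriv_order = 2),
      "S-G" = , "SG" = list(step = "SG", window = sg_window,
                            polyorder = fd_polyorder, deriv_order = 0),
      "MSC" = list(step = "MSC"),
      "SNV" = list(step = "SNV"),
      stop("unknown pretreatment token: ", tk))
    if (!is.null(st)) steps[[length(steps) + 1]] <- st
  }
  n_scatter <- sum(vapply(steps, function(s) s$step %in% c("MSC", "SNV"),
                          logical(1)))
  if (n_scatter > 1) stop("at most one scatter-correction step per chain")
  structure(list(name = spec, steps = steps), class = "pretreatment_chain")
}

#' Apply a pretreatment chain
#'
#' Steps run strictly in listed order. Stateful steps (MSC with an internal
#' mean reference) learn their state when `fitted_state` is `NULL` and reuse
#' it otherwise, so held-out data are corrected against the
#' calibration-derived reference and never leak into it.
#'
#' @param spectra a `spectrum_set`.
#' @param chain a [pretreatment_chain()] or chain string.
#' @param fitted_state state returned by a previous call on calibration
#'   data, or `NULL` to fit.
#' @return list with elements `spectra` and `state`.
#' @export
apply_chain <- function(spectra, chain, fitted_state = NULL) {
  chain <- pretreatment_chain(chain)
  fitting <- is.null(fitted_state)
  state <- if (fitting) list() else fitted_state
  out <- spectra
  for (i in seq_along(chain$steps)) {
    st <- chain$steps[[i]]
    key <- paste0("step", i)
    out <- switch(st$step,
      SG = savitzky_golay(out, st$window, st$polyorder, st$deriv_order),
      SNV = snv(out),
      MSC = {
        if (fitting) {
          r <- msc(out)
          state[[key]] <- list(reference = attr(r, "reference"))
          r
        } else {
          if (is.null(state[[key]]))
            stop("stateful chain applied to new data without fitted_state")
          msc(out, reference = state[[key]]$reference)
        }
      })
  }
  list(spectra = out, state = state)
}

#' Chain names of the discrimination comparison table
#'
#' @return character vector of the ten standard chain specifications.
#' @export
standard_chains <- function() {
  c("Raw", "FD", "SD", "S-G", "MSC", "SNV",
    "FD+MSC", "FD+SNV", "SD+MSC", "SD+SNV")
}
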