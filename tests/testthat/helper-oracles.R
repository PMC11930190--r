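# Shared oracles and fixtures. Oracles are deliberately naive (double loops,
# exhaustive search) and independent of the implementation paths they check.

# Brute-force Kennard-Stone: literal max-min selection with lowest-index
# tie-breaking, O(n^3).
ks_oracle <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(dist(X))
  best <- c(1L, 2L); bd <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (D[i, j] > bd) { bd <- D[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < n) {
    rem <- setdiff(seq_len(n), sel)
    md <- sapply(rem, function(r) min(D[r, sel]))
    sel <- c(sel, rem[which.max(md)])
  }
  as.integer(sel)
}

# Brute-force synchronous map: explicit double loop over wavenumber pairs.
sync_oracle <- function(S) {
  S <- as.matrix(S)
  m <- nrow(S); p <- ncol(S)
  Phi <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p))
    Phi[i, j] <- sum(S[, i] * S[, j]) / (m - 1)
  Phi
}

# The default discrimination spectra are used by several files; generate once.
.fixture_env <- new.env()
default_spectra <- function() {
  if (is.null(.fixture_env$sp)) .fixture_env$sp <- generate_spectra()
  .fixture_env$sp
}

# Small noiseless design for exact structural checks.
clean_design <- function(n_per = 3) {
  experiment_design(samples_per_class = rep(n_per, 5), noise_sd = 0,
                    scatter_slope_sd = 0, scatter_offset_sd = 0,
                    baseline_coeffs_sd = c(0, 0, 0))
}
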