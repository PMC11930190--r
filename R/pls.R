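# NIPALS partial least squares core (PLS1/PLS2).
#
# X and Y are column-mean-centered; spectra are deliberately not
# unit-variance scaled (band intensities carry the signal). The latent
# decomposition is the classical NIPALS sequence; regression coefficients
# are recovered through W* = W (P'W)^-1. With n_components = min(n-1, p) on
# full-rank data the predictions coincide with ordinary least squares.

#' Fit a PLS latent-variable model
#'
#' @param X numeric matrix (n x p), calibration predictors.
#' @param Y numeric matrix (n x q) or vector, calibration responses.
#' @param ncomp number of latent components requested; silently truncated
#'   when a residual matrix becomes numerically empty.
#' @param tol NIPALS convergence tolerance on the score vector.
#' @return a `pls_model` with weights `W`, loadings `P`, `Q`, scores `T`,
#'   coefficients `B` (centered scale), centering vectors, per-component
#'   explained sums of squares, and `ncomp` actually used.
#' @export
pls_fit <- function(X, Y, ncomp, tol = 1e-10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y row mismatch")
  if (ncomp < 1) stop("ncomp must be >= 1")
  ncomp <- min(ncomp, n - 1, p)
  xmean <- colMeans(X); ymean <- colMeans(Y)
  Xc <- sweep(X, 2, xmean); Yc <- sweep(Y, 2, ymean)
  ssx_tot <- sum(Xc^2); ssy_tot <- sum(Yc^2)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, q, ncomp); Ts <- matrix(0, n, ncomp)
  ssy_comp <- numeric(ncomp); r2x_cum <- numeric(ncomp)
  Xr <- Xc; Yr <- Yc
  a <- 0
  while (a < ncomp) {
    if (sum(Xr^2) < 1e-12 * max(ssx_tot, 1) || sum(Yr^2) < tol) break
    u <- Yr[, which.max(colSums(Yr^2))]
    t_old <- rep(Inf, n)
    tt <- NULL
    for (it in seq_len(500)) {
      w <- crossprod(Xr, u)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      tt <- Xr %*% w
      qv <- crossprod(Yr, tt)[, 1] / sum(tt^2)
      u <- Yr %*% qv / sum(qv^2)
      if (sum((tt - t_old)^2) < tol^2 * sum(tt^2)) break
      t_old <- tt
    }
    if (is.null(tt) || sum(tt^2) < tol) break
    a <- a + 1
    pv <- crossprod(Xr, tt)[, 1] / sum(tt^2)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; Ts[, a] <- tt
    ssy_comp[a] <- sum(tt^2) * sum(qv^2)
    Xr <- Xr - tt %*% t(pv)
    Yr <- Yr - tt %*% t(qv)
    r2x_cum[a] <- 1 - sum(Xr^2) / ssx_tot
  }
  if (a == 0) stop("no usable PLS component (zero-variance data)")
  W <- W[, 1:a, drop = FALSE]; P <- P[, 1:a, drop = FALSE]
  Q <- Q[, 1:a, drop = FALSE]; Ts <- Ts[, 1:a, drop = FALSE]
  Wstar <- W %*% solve(crossprod(P, W))
  B <- Wstar %*% t(Q)
  structure(list(W = W, P = P, Q = Q, T = Ts, B = B, Wstar = Wstar,
                 xmean = xmean, ymean = ymean, ncomp = a,
                 ssy_comp = ssy_comp[1:a], ssy_tot = ssy_tot,
                 r2x = r2x_cum[1:a]),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata matrix with the calibration variables.
#' @param ... unused.
#' @return predicted response matrix (original scale).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(sweep(newdata, 2, object$xmean) %*% object$B, 2, object$ymean, "+")
}

# Venetian-blind fold assignment along the Kennard-Stone order: the sample
# at K-S position i goes to fold ((i - 1) mod k) + 1, so every fold spans
# the feature space.
venetian_folds <- function(X, k) {
  ord <- kennard_stone_order(X)
  folds <- integer(nrow(X))
  folds[ord] <- ((seq_along(ord) - 1) %% k) + 1
  folds
}

#' Cross-validated PRESS curve for PLS
#'
#' @param X,Y calibration data.
#' @param max_comp largest component count to assess.
#' @param folds integer fold assignment per sample, or a fold count (then
#'   venetian blinds along the K-S order).
#' @return list: `press` (per component), `rmsecv`, `q2`, `best` (component
#'   count minimizing RMSECV), `folds`.
#' @export
pls_cv <- function(X, Y, max_comp = 10, folds = 7) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (length(folds) == 1) folds <- venetian_folds(X, min(folds, n))
  max_comp <- min(max_comp, n - max(table(folds)) - 1, ncol(X))
  max_comp <- max(max_comp, 1)
  press <- numeric(max_comp)
  for (f in sort(unique(folds))) {
    hold <- folds == f
    fit <- pls_fit(X[!hold, , drop = FALSE], Y[!hold, , drop = FALSE],
                   ncomp = max_comp)
    Xh <- sweep(X[hold, , drop = FALSE], 2, fit$xmean)
    # predictions for every truncation a = 1..max_comp
    for (a in seq_len(max_comp)) {
      aa <- min(a, fit$ncomp)
      Wa <- fit$W[, 1:aa, drop = FALSE]; Pa <- fit$P[, 1:aa, drop = FALSE]
      Ba <- Wa %*% solve(crossprod(Pa, Wa)) %*% t(fit$Q[, 1:aa, drop = FALSE])
      Yh <- sweep(Xh %*% Ba, 2, fit$ymean, "+")
      press[a] <- press[a] + sum((Y[hold, , drop = FALSE] - Yh)^2)
    }
  }
  ssy <- sum(sweep(Y, 2, colMeans(Y))^2)
  list(press = press, rmsecv = sqrt(press / length(Y)),
       q2 = 1 - press / ssy, best = which.min(press), folds = folds)
}
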