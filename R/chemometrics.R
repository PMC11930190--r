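# Chemometric models: PCA, PLS-DA with VIP and permutation diagnostics,
# per-compound PLSR calibration with RPD, and the pretreatment chain search.

#' Principal component analysis
#'
#' Column-mean-centered SVD (optionally unit-variance scaled, the convention
#' for metabolite concentration tables).
#'
#' @param X numeric matrix or `spectrum_set`.
#' @param n_components number of components to keep.
#' @param scale logical; autoscale columns before the SVD.
#' @return list with `scores`, `loadings`, `explained` (variance fractions,
#'   non-increasing, summing to <= 1), `center`, `scale`.
#' @export
pca_fit <- function(X, n_components = 2, scale = FALSE) {
  if (inherits(X, "spectrum_set")) X <- X$absorbance
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("PCA needs at least 2 samples")
  n_components <- min(n_components, n - 1, ncol(X))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  scl <- rep(1, ncol(X))
  if (scale) {
    scl <- apply(X, 2, sd)
    if (any(scl < .Machine$double.eps)) stop("constant column: cannot autoscale")
    Xc <- sweep(Xc, 2, scl, "/")
  }
  sv <- svd(Xc, nu = n_components, nv = n_components)
  ev <- sv$d^2
  list(scores = sv$u %*% diag(sv$d[seq_len(n_components)], n_components),
       loadings = sv$v,
       explained = (ev / sum(ev))[seq_len(n_components)],
       center = ctr, scale = scl)
}

one_hot <- function(labels) {
  labels <- as.factor(labels)
  Y <- matrix(0, length(labels), nlevels(labels),
              dimnames = list(NULL, levels(labels)))
  Y[cbind(seq_along(labels), as.integer(labels))] <- 1
  Y
}

#' Fit a PLS-DA classifier
#'
#' One-hot class membership is regressed on X by NIPALS PLS; the component
#' count minimizes RMSECV over venetian-blind folds laid along the
#' Kennard-Stone order; samples are assigned to the argmax of the predicted
#' membership row.
#'
#' @param X calibration matrix or `spectrum_set`.
#' @param labels calibration class labels (>= 2 classes).
#' @param X_test,test_labels optional held-out partition for RMSEP and test
#'   accuracy.
#' @param max_components component ceiling (default 10).
#' @param cv_folds venetian-blind fold count (default 7).
#' @return list with `model` (a `pls_model` plus class levels) and `report`
#'   (R2X, R2Y, Q2, RMSECV, RMSEP, train/test accuracy, assignments).
#' @export
fit_plsda <- function(X, labels, X_test = NULL, test_labels = NULL,
                      max_components = 10, cv_folds = 7) {
  if (inherits(X, "spectrum_set")) X <- X$absorbance
  X <- as.matrix(X)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("PLS-DA needs at least 2 classes")
  Y <- one_hot(labels)
  cv <- pls_cv(X, Y, max_comp = max_components, folds = cv_folds)
  a <- cv$best
  fit <- pls_fit(X, Y, ncomp = a)
  Yhat <- predict(fit, X)
  pred <- factor(levels(labels)[max.col(Yhat, ties.method = "first")],
                 levels = levels(labels))
  r2y <- 1 - sum((Y - Yhat)^2) / fit$ssy_tot
  report <- list(
    n_components = fit$ncomp,
    R2X = fit$r2x[fit$ncomp], R2Y = r2y, Q2 = cv$q2[a],
    RMSECV = cv$rmsecv[a], RMSEP = NA_real_,
    train_accuracy = mean(pred == labels),
    test_accuracy = NA_real_,
    train_assignments = pred, test_assignments = NULL)
  if (!is.null(X_test)) {
    if (inherits(X_test, "spectrum_set")) X_test <- X_test$absorbance
    if (nrow(X_test) == 0) stop("empty test partition")
    Yt <- one_hot(factor(test_labels, levels = levels(labels)))
    Yth <- predict(fit, X_test)
    predt <- factor(levels(labels)[max.col(Yth, ties.method = "first")],
                    levels = levels(labels))
    report$RMSEP <- sqrt(mean((Yt - Yth)^2))
    report$test_accuracy <- mean(as.character(predt) ==
                                   as.character(test_labels))
    report$test_assignments <- predt
  }
  model <- fit
  model$levels <- levels(labels)
  list(model = model, report = report)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a(SSY_a * (w_aj / ||w_a||)^2) / sum_a SSY_a)`;
#' the mean squared VIP is 1 by construction.
#'
#' @param model a fitted `pls_model`.
#' @return numeric VIP per variable.
#' @export
vip_scores <- function(model) {
  ssy <- model$ssy_comp
  if (sum(ssy) <= 0) stop("model explains no Y variance; VIP undefined")
  W <- model$W
  p <- nrow(W)
  wn2 <- colSums(W^2)
  contrib <- sweep(W^2, 2, ssy / wn2, "*")
  sqrt(p * rowSums(contrib) / sum(ssy))
}

#' Label-permutation test for a PLS-DA model
#'
#' Labels are permuted `n_perm` times with a seeded generator; the full
#' pipeline (venetian-blind component selection included) is refit on each
#' permutation. Reported are the permuted (R2Y, Q2) pairs, the correlation
#' of each permuted one-hot matrix with the original, the intercepts of the
#' regressions of R2Y and Q2 on that correlation (the true model enters at
#' correlation 1), and an overfitting flag raised when at least 5% of the
#' permuted Q2 values reach the true Q2.
#'
#' @param X calibration matrix.
#' @param labels class labels.
#' @param n_perm number of permutations (the reference workflow uses 200).
#' @param max_components,cv_folds forwarded to [fit_plsda()].
#' @param seed integer seed.
#' @return list: `permuted` (data.frame cor/R2Y/Q2), `true` (R2Y, Q2),
#'   `intercepts`, `p_value` (share of permuted Q2 >= true Q2), `overfit`.
#' @export
permutation_test <- function(X, labels, n_perm = 200, max_components = 10,
                             cv_folds = 7, seed = 1L) {
  if (inherits(X, "spectrum_set")) X <- X$absorbance
  if (n_perm < 1) stop("n_perm must be >= 1")
  labels <- droplevels(as.factor(labels))
  Y <- one_hot(labels)
  true_fit <- fit_plsda(X, labels, max_components = max_components,
                        cv_folds = cv_folds)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stage_seed(seed, "permutation"))
  res <- matrix(0, n_perm, 3, dimnames = list(NULL, c("cor", "R2Y", "Q2")))
  for (b in seq_len(n_perm)) {
    perm <- sample(length(labels))
    lp <- labels[perm]
    fp <- fit_plsda(X, lp, max_components = max_components,
                    cv_folds = cv_folds)
    res[b, ] <- c(mean(diag(abs(cor(one_hot(lp), Y)))),
                  fp$report$R2Y, fp$report$Q2)
  }
  df <- as.data.frame(res)
  xc <- c(df$cor, 1)
  int_r2y <- unname(coef(lm(c(df$R2Y, true_fit$report$R2Y) ~ xc))[1])
  int_q2 <- unname(coef(lm(c(df$Q2, true_fit$report$Q2) ~ xc))[1])
  pval <- mean(df$Q2 >= true_fit$report$Q2)
  list(permuted = df,
       true = c(R2Y = true_fit$report$R2Y, Q2 = true_fit$report$Q2),
       intercepts = c(R2Y = int_r2y, Q2 = int_q2),
       p_value = pval, overfit = pval >= 0.05)
}

#' Fit a PLSR calibration for one compound
#'
#' Univariate PLS regression with CV-selected component count; reports
#' calibration R2c, prediction R2p, RMSEP, and RPD = sd(reference values of
#' the prediction partition) / RMSEP. A numerically zero RMSEP (noiseless
#' limit) caps the RPD at 1e6 with a flag.
#'
#' @param X,y calibration predictors and response.
#' @param X_test,y_test prediction partition.
#' @param max_components,cv_folds model-selection controls.
#' @return list with `model` and `report` (R2c, R2p, RMSEP, RPD,
#'   n_components, rpd_capped).
#' @export
fit_plsr <- function(X, y, X_test, y_test, max_components = 10,
                     cv_folds = 7) {
  if (inherits(X, "spectrum_set")) X <- X$absorbance
  if (inherits(X_test, "spectrum_set")) X_test <- X_test$absorbance
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("fewer than 2 calibration samples")
  y <- as.numeric(y)
  cv <- pls_cv(X, matrix(y), max_comp = max_components, folds = cv_folds)
  fit <- pls_fit(X, matrix(y), ncomp = cv$best)
  yc <- predict(fit, X)[, 1]
  r2c <- 1 - sum((y - yc)^2) / sum((y - mean(y))^2)
  yp <- predict(fit, X_test)[, 1]
  y_test <- as.numeric(y_test)
  rmsep <- sqrt(mean((y_test - yp)^2))
  r2p <- 1 - sum((y_test - yp)^2) / sum((y_test - mean(y_test))^2)
  capped <- rmsep < .Machine$double.eps * max(1, sd(y_test))
  rpd <- if (capped) 1e6 else sd(y_test) / rmsep
  list(model = fit,
       report = list(n_components = fit$ncomp, R2c = r2c, R2p = r2p,
                     RMSEP = rmsep, RPD = rpd, RMSECV = cv$rmsecv[cv$best],
                     Q2 = cv$q2[cv$best], rpd_capped = capped))
}

#' Search pretreatment chains for the best model
#'
#' Every chain is fitted with identical splits. For classification the best
#' chain maximizes test accuracy with ties broken by lower RMSECV, then
#' lower RMSEP, then listing order; for regression it maximizes R2p with
#' ties broken by higher RPD, then listing order.
#'
#' @param spectra a `spectrum_set` (raw).
#' @param target class labels (classification) or a numeric vector
#'   (regression).
#' @param chains character vector of chain specs (default
#'   [standard_chains()]).
#' @param split a `split_indices` with partitions `calibration` and `test`
#'   (first two partitions are used).
#' @param max_components,cv_folds model controls.
#' @return list: `table` (one row per chain with all metrics), `best` (chain
#'   name), `reports` (per-chain full reports).
#' @export
chain_search <- function(spectra, target, chains = standard_chains(), split,
                         max_components = 10, cv_folds = 7) {
  if (length(chains) == 0) stop("no chains supplied")
  cal <- split[[1]]; tst <- split[[2]]
  classification <- is.factor(target) || is.character(target)
  reports <- vector("list", length(chains))
  rows <- vector("list", length(chains))
  for (i in seq_along(chains)) {
    fitted <- apply_chain(spectra[cal], chains[i])
    Xc <- fitted$spectra$absorbance
    Xt <- apply_chain(spectra[tst], chains[i],
                      fitted_state = fitted$state)$spectra$absorbance
    if (classification) {
      r <- fit_plsda(Xc, target[cal], Xt, target[tst],
                     max_components = max_components, cv_folds = cv_folds)
      reports[[i]] <- r
      rows[[i]] <- data.frame(
        chain = chains[i], n_components = r$report$n_components,
        R2X = r$report$R2X, R2Y = r$report$R2Y, Q2 = r$report$Q2,
        RMSECV = r$report$RMSECV, RMSEP = r$report$RMSEP,
        train_accuracy = r$report$train_accuracy,
        test_accuracy = r$report$test_accuracy)
    } else {
      r <- fit_plsr(Xc, target[cal], Xt, target[tst],
                    max_components = max_components, cv_folds = cv_folds)
      reports[[i]] <- r
      rows[[i]] <- data.frame(
        chain = chains[i], n_components = r$report$n_components,
        R2c = r$report$R2c, R2p = r$report$R2p, RMSEP = r$report$RMSEP,
        RPD = r$report$RPD, RMSECV = r$report$RMSECV)
    }
  }
  tab <- do.call(rbind, rows)
  if (classification) {
    ord <- order(-tab$test_accuracy, tab$RMSECV, tab$RMSEP,
                 seq_len(nrow(tab)))
  } else {
    ord <- order(-tab$R2p, -tab$RPD, seq_len(nrow(tab)))
  }
  list(table = tab, best = tab$chain[ord[1]], best_index = ord[1],
       reports = setNames(reports, chains))
}
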