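test_that("PCA matches an eigen oracle", {
  set.seed(41)
  X <- matrix(rnorm(50), 10, 5)
  p <- pca_fit(X, n_components = 4)
  ev <- eigen(cov(X))$values
  expect_equal(p$explained, (ev / sum(ev))[1:4], tolerance = 1e-10)
  expect_lt(max(abs(colMeans(p$scores))), 1e-10)
  expect_true(all(diff(p$explained) <= 1e-12))
  # rank-1 data concentrates on the first component
  r1 <- tcrossprod(rnorm(8), rnorm(5))
  expect_equal(pca_fit(r1, 2)$explained[1], 1, tolerance = 1e-10)
  expect_error(pca_fit(matrix(1, 1, 3)), "at least 2")
})

test_that("PLS at full rank reproduces least squares", {
  set.seed(42)
  X <- matrix(rnorm(25 * 6), 25, 6)
  y <- rnorm(25)
  f <- pls_fit(X, y, ncomp = 6)
  expect_equal(predict(f, X)[, 1], unname(fitted(lm(y ~ X))),
               tolerance = 1e-8)
})

test_that("PLS-DA separates well-separated classes with one component", {
  set.seed(43)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2))
  lab <- rep(c("a", "b"), each = 20)
  r <- fit_plsda(X, lab, max_components = 1)
  expect_equal(r$report$n_components, 1)
  expect_equal(r$report$train_accuracy, 1)
})

test_that("single-component PLS matches its closed form", {
  set.seed(44)
  X <- matrix(rnorm(8), 4, 2)
  y <- c(1, 1, -1, -1)
  f <- pls_fit(X, y, ncomp = 1)
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  w <- crossprod(Xc, yc); w <- w / sqrt(sum(w^2))
  tt <- Xc %*% w
  qv <- sum(tt * yc) / sum(tt^2)
  pv <- crossprod(Xc, tt) / sum(tt^2)
  B <- w %*% solve(crossprod(pv, w)) %*% qv
  expect_equal(unname(f$B), unname(B), tolerance = 1e-10)
  # 1-component VIP collapses to |w_j| * sqrt(p) / ||w||
  expect_equal(vip_scores(f), sqrt(2) * abs(as.numeric(w)),
               tolerance = 1e-10)
})

test_that("Q2 from CV never exceeds calibration R2Y", {
  set.seed(45)
  for (rep in 1:5) {
    X <- matrix(rnorm(30 * 8), 30, 8)
    lab <- rep(c("a", "b", "c"), each = 10)
    r <- fit_plsda(X, lab, max_components = 5, cv_folds = 5)
    expect_gte(r$report$R2Y, r$report$Q2)
  }
})

test_that("VIP normalization and signal recovery", {
  set.seed(46)
  X <- matrix(rnorm(40 * 25), 40, 25)
  lab <- rep(c("a", "b"), each = 20)
  X[lab == "b", 7] <- X[lab == "b", 7] + 3
  r <- fit_plsda(X, lab, max_components = 5)
  v <- vip_scores(r$model)
  expect_equal(sum(v^2), 25, tolerance = 1e-8)
  expect_equal(which.max(v), 7)
  expect_gt(v[7], 1)
})

test_that("permutation test separates signal from null", {
  set.seed(47)
  X <- rbind(matrix(rnorm(60, 0), 15, 4), matrix(rnorm(60, 6), 15, 4))
  lab <- rep(c("a", "b"), each = 15)
  pt <- permutation_test(X, lab, n_perm = 20, max_components = 3,
                         cv_folds = 5, seed = 9)
  expect_equal(nrow(pt$permuted), 20)
  expect_true(all(pt$permuted$Q2 < pt$true["Q2"]))
  expect_false(pt$overfit)
  # single permutation returns a single pair
  p1 <- permutation_test(X, lab, n_perm = 1, max_components = 2,
                         cv_folds = 5, seed = 1)
  expect_equal(nrow(p1$permuted), 1)
})

test_that("permutation test is seed-reproducible", {
  set.seed(48)
  X <- matrix(rnorm(20 * 5), 20, 5)
  lab <- rep(c("a", "b"), each = 10)
  a <- permutation_test(X, lab, n_perm = 5, max_components = 2,
                        cv_folds = 4, seed = 3)
  b <- permutation_test(X, lab, n_perm = 5, max_components = 2,
                        cv_folds = 4, seed = 3)
  expect_identical(a$permuted, b$permuted)
})

test_that("PLSR handles the noiseless limit and the null", {
  set.seed(49)
  # low-rank X with y an exact linear functional: noiseless calibration
  Tt <- matrix(rnorm(30 * 3), 30, 3)
  P <- matrix(rnorm(3 * 12), 3, 12)
  X <- Tt %*% P
  y <- as.numeric(Tt %*% c(1, -2, 0.5))
  f <- fit_plsr(X[1:21, ], y[1:21], X[22:30, ], y[22:30],
                max_components = 6, cv_folds = 7)
  expect_equal(f$report$R2c, 1, tolerance = 1e-6)
  expect_equal(f$report$R2p, 1, tolerance = 1e-6)
  expect_true(f$report$rpd_capped)
  expect_equal(f$report$RPD, 1e6)
  # permuted response: no predictive power, RPD near 1
  yp <- sample(y)
  g <- fit_plsr(X[1:21, ], yp[1:21], X[22:30, ], yp[22:30],
                max_components = 6, cv_folds = 7)
  expect_lt(g$report$R2p, 0.5)
  expect_lt(g$report$RPD, 2)
  # RPD identity
  expect_equal(g$report$RPD * g$report$RMSEP, sd(yp[22:30]),
               tolerance = 1e-9)
  expect_error(fit_plsr(X[1, , drop = FALSE], y[1], X, y), "fewer than 2")
})

test_that("chain search ranks chains by the declared tie rules", {
  sp <- default_spectra()[1:40]
  split <- ks_split(sp, c(calibration = 0.7, test = 0.3))
  # duplicated chains: deterministic first-listed winner
  cs <- chain_search(sp, sp$labels, c("FD", "FD"), split,
                     max_components = 4, cv_folds = 5)
  expect_equal(cs$best_index, 1)
  expect_equal(nrow(cs$table), 2)
  expect_error(chain_search(sp, sp$labels, character(0), split), "no chains")
})

test_that("chain search report has one row per chain with all metrics", {
  sp <- generate_spectra(experiment_design(samples_per_class = rep(6, 5)))
  ct <- generate_concentrations(sp, seed = 2)
  xb <- band_window(sp, 1800, 1200)
  split <- ks_split(xb, c(calibration = 0.7, test = 0.3))
  cs <- chain_search(xb, ct$values[, 1], c("Raw", "FD", "SNV"), split,
                     max_components = 5, cv_folds = 5)
  expect_equal(nrow(cs$table), 3)
  expect_true(all(c("R2c", "R2p", "RMSEP", "RPD") %in% names(cs$table)))
  expect_true(cs$best %in% cs$table$chain)
})
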