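test_that("default grid follows the instrument convention", {
  g <- default_grid()
  expect_equal(g[1], 4000)
  expect_equal(g[length(g)], 400)
  expect_length(g, 901)
  expect_length(default_grid(step = 2), 1801)
  expect_error(default_grid(step = 5000), "step larger")
})

test_that("generator reproduces the study layout and is seed-deterministic", {
  sp <- default_spectra()
  expect_s3_class(sp, "spectrum_set")
  expect_equal(dim(sp$absorbance), c(99, 901))
  expect_equal(as.integer(table(sp$labels)), c(22, 18, 18, 21, 20))
  sp2 <- generate_spectra()
  expect_identical(sp$absorbance, sp2$absorbance)
  # different seed changes the draws
  d <- experiment_design(seed = 2L)
  expect_false(identical(generate_spectra(d)$absorbance, sp$absorbance))
})

test_that("noise-free degenerate case gives identical rows per class", {
  s0 <- generate_spectra(clean_design())
  for (cl in levels(s0$labels)) {
    rows <- s0$absorbance[s0$labels == cl, , drop = FALSE]
    expect_equal(max(abs(sweep(rows, 2, rows[1, ]))), 0)
  }
})

test_that("class means differ exactly at peaks with nonzero deltas", {
  s0 <- generate_spectra(clean_design())
  pk <- default_peaks()
  means <- t(sapply(levels(s0$labels), function(cl)
    colMeans(s0$absorbance[s0$labels == cl, , drop = FALSE])))
  spread <- apply(means, 2, function(x) diff(range(x)))
  active <- pk[rowSums(abs(pk$class_deltas)) > 0, ]
  # far outside every active peak's support the class means coincide
  far <- sapply(s0$wavenumbers, function(v)
    all(abs(v - active$center) > 8 * active$width))
  expect_true(any(far))
  expect_lt(max(spread[far]), 1e-12)
  # and at each active peak center they differ
  ctr_idx <- sapply(active$center, function(cc)
    which.min(abs(s0$wavenumbers - cc)))
  expect_true(all(spread[ctr_idx] > 1e-3))
})

test_that("sample variance at any wavenumber matches noise_sd^2", {
  d <- experiment_design(class_labels = "35", samples_per_class = 600,
                         scatter_slope_sd = 0, scatter_offset_sd = 0,
                         baseline_coeffs_sd = c(0, 0, 0), noise_sd = 0.004)
  pk <- default_peaks()[c(1, 4), ]
  pk$class_deltas <- pk$class_deltas[, 1, drop = FALSE]
  s <- generate_spectra(d, pk)
  v <- apply(s$absorbance[, c(10, 450, 880)], 2, var)
  expect_equal(unname(v), rep(0.004^2, 3), tolerance = 0.15)
})

test_that("generator input validation", {
  expect_error(generate_spectra(peaks = default_peaks()[0, ]), "empty peak")
  expect_error(experiment_design(samples_per_class = c(1, 2)), "match")
  expect_error(experiment_design(noise_sd = -1), "noise_sd")
  bad <- default_peaks(); bad$width[1] <- -1
  expect_error(generate_spectra(peaks = bad), "width")
})

test_that("concentrations are linear in the band with recoverable coupling", {
  sp <- generate_spectra(experiment_design(samples_per_class = rep(6, 5)))
  ct <- generate_concentrations(sp, noise_sd = 0, seed = 3)
  expect_equal(dim(ct$values), c(30, 11))
  truth <- attr(ct, "truth")
  inb <- sp$wavenumbers <= 1800 & sp$wavenumbers >= 1200
  X <- sp$absorbance[, inb]
  # noiseless: values exactly linear in band absorbances (least-squares
  # residual zero)
  for (j in c(1, 5, 11)) {
    fit <- lm.fit(cbind(1, X %*% truth$W[, j]), ct$values[, j])
    expect_lt(max(abs(fit$residuals)), 1e-9)
  }
})

test_that("negative concentration draws are clipped and logged", {
  sp <- generate_spectra(experiment_design(samples_per_class = rep(6, 5)))
  expect_message(
    ct <- generate_concentrations(sp, noise_sd = 1e3, seed = 1),
    "clipped")
  expect_gt(attr(ct, "n_clipped"), 0)
  expect_true(all(ct$values >= 0))
})

test_that("coupling outside the band is rejected", {
  sp <- default_spectra()
  cp <- default_coupling(sp$wavenumbers)
  cp$wavenumbers <- cp$wavenumbers + 400  # pretend weights sit elsewhere
  expect_error(generate_concentrations(sp, coupling = cp), "outside")
})

test_that("design YAML round-trips", {
  d <- experiment_design(seed = 7L)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_design(d, f)
  expect_equal(read_design(f), d)
})
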