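make_set <- function(mat, wn = NULL) {
  if (is.null(wn)) wn <- seq(4000, by = -4, length.out = ncol(mat))
  spectrum_set(wn, mat)
}

test_that("MSC removes exact affine distortions", {
  sp <- default_spectra()
  ref <- colMeans(sp$absorbance)
  distorted <- rbind(2 * ref + 3, 0.5 * ref - 1, ref)
  out <- msc(make_set(distorted), reference = ref)
  expect_equal(max(abs(sweep(out$absorbance, 2, ref))), 0, tolerance = 1e-10)
})

test_that("MSC-corrected spectra regress on the reference with slope 1, intercept 0", {
  sp <- default_spectra()
  out <- msc(sp)
  ref <- attr(out, "reference")
  for (i in c(1, 40, 99)) {
    co <- coef(lm(out$absorbance[i, ] ~ ref))
    expect_equal(unname(co[2]), 1, tolerance = 1e-10)
    expect_equal(unname(co[1]), 0, tolerance = 1e-10)
  }
})

test_that("MSC edge cases", {
  sp <- default_spectra()
  one <- sp[1]
  expect_error(msc(one), "at least 2")
  ok <- msc(one, reference = colMeans(sp$absorbance))
  expect_equal(dim(ok$absorbance), c(1, 901))
  expect_error(msc(one, reference = rep(1, 901)), "zero-variance")
})

test_that("SNV standardizes rows and is idempotent and affine-invariant", {
  sp <- default_spectra()
  out <- snv(sp)
  expect_lt(max(abs(rowMeans(out$absorbance))), 1e-12)
  expect_lt(max(abs(apply(out$absorbance, 1, sd) - 1)), 1e-12)
  again <- snv(out)
  expect_equal(again$absorbance, out$absorbance, tolerance = 1e-12)
  aff <- snv(make_set(3.2 * sp$absorbance + 0.7, sp$wavenumbers))
  expect_equal(aff$absorbance, out$absorbance, tolerance = 1e-10)
  expect_error(snv(make_set(matrix(1, 2, 901))), "constant")
})

test_that("Savitzky-Golay reproduces polynomials and their derivatives", {
  v <- default_grid()
  y1 <- 2 + 0.003 * v + 1e-6 * v^2
  y2 <- 5 - 0.001 * v
  sp <- make_set(rbind(y1, y2), v)
  sm <- savitzky_golay(sp, 15, 2, 0)
  expect_equal(sm$absorbance, sp$absorbance, tolerance = 1e-10)
  d1 <- savitzky_golay(sp, 15, 2, 1)
  expect_equal(d1$absorbance[1, ], 0.003 + 2e-6 * v, tolerance = 1e-10)
  expect_equal(d1$absorbance[2, ], rep(-0.001, 901), tolerance = 1e-10)
  d2 <- savitzky_golay(sp, 15, 3, 2)
  expect_equal(d2$absorbance[1, ], rep(2e-6, 901), tolerance = 1e-10)
})

test_that("Savitzky-Golay validates its parameters", {
  sp <- default_spectra()
  expect_error(savitzky_golay(sp, 14, 2, 1), "odd")
  expect_error(savitzky_golay(sp, 15, 15, 1), "polyorder")
  expect_error(savitzky_golay(sp, 15, 2, 3), "deriv_order")
  expect_no_error(savitzky_golay(sp, 5, 2, 1))
})

test_that("pretreatments are row-wise and grid-preserving", {
  sp <- default_spectra()
  for (f in list(snv, function(s) savitzky_golay(s, 15, 2, 1))) {
    out <- f(sp)
    expect_identical(out$wavenumbers, sp$wavenumbers)
    # removing other samples does not change a given row
    solo <- f(sp[c(3, 4)])
    expect_equal(solo$absorbance[1, ], out$absorbance[3, ], tolerance = 1e-12)
  }
})

test_that("chain parsing accepts the table names and validates structure", {
  ch <- pretreatment_chain("FD+MSC")
  expect_length(ch$steps, 2)
  expect_equal(ch$steps[[1]]$deriv_order, 1)
  expect_equal(ch$steps[[2]]$step, "MSC")
  expect_length(pretreatment_chain("Raw")$steps, 0)
  expect_error(pretreatment_chain("MSC+SNV"), "at most one scatter")
  expect_error(pretreatment_chain("FD+XYZ"), "unknown")
})

test_that("chains compose exactly and keep their fitted state", {
  sp <- default_spectra()
  cal <- sp[1:60]; tst <- sp[61:99]
  fitted <- apply_chain(cal, "FD+MSC")
  # manual composition oracle
  fd <- savitzky_golay(cal, 15, 2, 1)
  manual <- msc(fd)
  expect_equal(fitted$spectra$absorbance, manual$absorbance,
               tolerance = 1e-12)
  # held-out data corrected against the calibration-derived reference
  out_tst <- apply_chain(tst, "FD+MSC", fitted_state = fitted$state)
  manual_tst <- msc(savitzky_golay(tst, 15, 2, 1),
                    reference = attr(manual, "reference"))
  expect_equal(out_tst$spectra$absorbance, manual_tst$absorbance,
               tolerance = 1e-12)
  # stateful chain without fitted state on new data errors
  expect_error(apply_chain(tst, "FD+MSC", fitted_state = list()),
               "without fitted_state")
  # empty chain is the identity
  expect_equal(apply_chain(sp, "Raw")$spectra$absorbance, sp$absorbance)
})
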