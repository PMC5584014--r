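test_that("msc leaves the reference spectrum unchanged and inverts affine scatter", {
  s <- tiny_spectra(4, 30)
  m <- colMeans(s$absorbance)
  with_ref <- rbind(s$absorbance, m)
  sm <- spectra_set(with_ref, s$wavenumbers, c(s$sample_ids, "REF"))
  out <- msc(sm, reference = m)
  expect_equal(out$absorbance["REF", ], m, ignore_attr = TRUE,
               tolerance = 1e-12)
  # x' = 2 m + 0.5 corrects back to m exactly
  distorted <- spectra_set(rbind(2 * m + 0.5, m), s$wavenumbers, c("D", "R"))
  cor2 <- msc(distorted, reference = m)
  expect_equal(cor2$absorbance["D", ], m, ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("msc regression coefficients match explicit normal equations", {
  set.seed(31)
  X <- matrix(rnorm(5 * 20, 1, 0.2), 5, 20)
  s <- spectra_set(X, seq(8000, 6000, length.out = 20))
  out <- msc(s)
  m <- colMeans(X)
  for (i in 1:5) {
    fit <- stats::lm.fit(cbind(1, m), X[i, ])
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
    expect_equal(out$absorbance[i, ], (X[i, ] - a) / b, ignore_attr = TRUE,
                 tolerance = 1e-10)
  }
  # corrected spectra regress on the reference with slope 1, intercept 0
  for (i in 1:5) {
    fit <- stats::lm.fit(cbind(1, m), out$absorbance[i, ])
    expect_equal(unname(fit$coefficients), c(0, 1), tolerance = 1e-8)
  }
})

test_that("msc rejects degenerate references", {
  s <- tiny_spectra(3, 10)
  expect_error(msc(s, reference = rep(1, 10)), "zero variance")
  expect_error(msc(s[1, ]), "at least 2")
})

test_that("norris smoothing preserves constants and reduces noise variance", {
  const <- spectra_set(matrix(2.5, 2, 40), seq(9000, 5000, length.out = 40))
  expect_equal(norris_filter(const, 5)$absorbance, const$absorbance,
               tolerance = 1e-12)
  s <- tiny_spectra(3, 40)
  expect_identical(norris_filter(s, 1)$absorbance, s$absorbance)
  # variance oracle over many simulated white-noise spectra
  set.seed(8)
  noise <- matrix(rnorm(1000 * 50), 1000, 50)
  sn <- spectra_set(noise, seq(9000, 5000, length.out = 50))
  sm <- norris_filter(sn, 5)
  expect_lt(mean(apply(sm$absorbance, 1, var)),
            mean(apply(noise, 1, var)))
  expect_error(norris_filter(s, 4), "odd")
  expect_error(norris_filter(tiny_spectra(2, 5), 7), "exceeds")
})

test_that("the gap derivative is exact on polynomials and truncates the axis", {
  w <- seq(4000, 5000, length.out = 60)   # ascending axis
  lin <- spectra_set(matrix(3 * w + 7, 1, byrow = TRUE), w)
  d <- first_derivative(lin, gap = 5)
  expect_length(d$wavenumbers, 50)
  expect_equal(d$absorbance[1, ], rep(3, 50), ignore_attr = TRUE,
               tolerance = 1e-10)
  const <- spectra_set(matrix(4, 1, 60), w)
  expect_equal(first_derivative(const, 2)$absorbance[1, ], rep(0, 56),
               ignore_attr = TRUE, tolerance = 1e-12)
  quad <- spectra_set(matrix(w^2, 1, byrow = TRUE), w)
  dq <- first_derivative(quad, gap = 3)
  expect_equal(dq$absorbance[1, ], 2 * dq$wavenumbers, ignore_attr = TRUE,
               tolerance = 1e-8)
  # descending axis gives the same derivative values
  wd <- rev(w)
  quad_d <- spectra_set(matrix(wd^2, 1, byrow = TRUE), wd)
  dqd <- first_derivative(quad_d, gap = 3)
  expect_equal(dqd$absorbance[1, ], 2 * dqd$wavenumbers, ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_error(first_derivative(const, 30), "too short")
})

test_that("the chain is invariant to per-spectrum affine scatter (fixed reference)", {
  ds <- tiny_spectra(6, 120, seed = 13)
  X <- ds$absorbance
  m <- colMeans(X)
  set.seed(14)
  b <- runif(6, 0.7, 1.4); a <- rnorm(6, 0, 0.3)
  sd_ <- spectra_set(X * b + a, ds$wavenumbers, ds$sample_ids)
  chain <- function(s) first_derivative(norris_filter(msc(s, reference = m), 5), 5)
  expect_lt(max(abs(chain(ds)$absorbance - chain(sd_)$absorbance)), 1e-10)
})

test_that("smoothing plus derivative annihilates offsets and flattens linear drift", {
  ds <- tiny_spectra(4, 100, seed = 21)
  X <- ds$absorbance
  cfg <- preprocess_config(steps = c("norris", "first_derivative"))
  out_clean <- preprocess(ds, cfg)
  # additive constants vanish exactly
  shifted <- X + outer(c(0.2, -0.1, 0.3, 0), rep(1, 100))
  out_shift <- preprocess(spectra_set(shifted, ds$wavenumbers,
                                      ds$sample_ids), cfg)
  expect_lt(max(abs(out_clean$absorbance - out_shift$absorbance)), 1e-10)
  # a linear-in-wavenumber drift becomes a flat per-spectrum offset equal to
  # its slope (the derivative of the baseline), constant across the interior;
  # truncated smoothing windows distort the outermost two points of each edge
  slopes <- c(0.05, 0.1, -0.08, 0.02)
  drifted <- X + outer(slopes, seq(0, 1, length.out = 100))
  out_drift <- preprocess(spectra_set(drifted, ds$wavenumbers,
                                      ds$sample_ids), cfg)
  interior <- 3:(ncol(out_clean$absorbance) - 2)
  resid <- out_drift$absorbance[, interior] - out_clean$absorbance[, interior]
  dnu <- diff(ds$wavenumbers)[1] * 99  # axis span per unit ramp
  expect_lt(max(abs(sweep(resid, 1, slopes / dnu))), 1e-10)
})

test_that("preprocessing config controls the chain", {
  s <- tiny_spectra(3, 30)
  expect_identical(preprocess(s, preprocess_config(steps = character(0))), s)
  const <- spectra_set(matrix(rep(c(2, 5, 9), 60), 3, 60),
                       seq(9000, 5000, length.out = 60))
  out <- preprocess(const, preprocess_config(steps = c("norris",
                                                       "first_derivative")))
  expect_true(all(abs(out$absorbance) < 1e-10))
  expect_error(preprocess_config(steps = "snv"), "unknown")
  expect_error(preprocess_config(norris_segment = 4), "odd")
})
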