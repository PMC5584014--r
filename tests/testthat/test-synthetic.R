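test_that("the band library encodes the component band assignments", {
  lib <- default_band_library()
  expect_true(all(lib$center >= 4000 & lib$center <= 10000))
  expect_true(all(lib$width > 0) && all(lib$intensity >= 0))
  cel <- lib[lib$component == "cellulose", ]
  expect_true(any(abs(cel$center - 7316.5) < 1e-9))  # midpoint of 7305-7328
  wat <- lib[lib$component == "water", ]
  expect_true(any(wat$center >= 5150 & wat$center <= 5195))
  # every organic component plus water and ash is represented
  expect_setequal(unique(lib$component),
                  c("soluble_sugar", "cellulose", "hemicellulose", "lignin",
                    "water", "ash"))
})

test_that("composition generation honors class ranges and is deterministic", {
  ref <- generate_composition(70, 77, seed = 5)
  expect_equal(nrow(ref), 147)
  expect_equal(sum(ref$class == "sweet"), 70)
  sweet <- ref[ref$class == "sweet", ]
  bio <- ref[ref$class == "biomass", ]
  expect_true(all(sweet$soluble_sugar >= 10.8 & sweet$soluble_sugar <= 47.6))
  expect_true(all(bio$soluble_sugar >= 5.4 & bio$soluble_sugar <= 35.4))
  cmp <- c("soluble_sugar", "cellulose", "hemicellulose", "lignin", "ash")
  expect_true(all(rowSums(as.data.frame(ref)[, cmp]) <= 100))
  expect_identical(generate_composition(70, 77, seed = 5), ref)
  expect_false(identical(generate_composition(70, 77, seed = 6), ref))
})

test_that("generated correlation structure gives the expected TEY signs", {
  ref <- generate_composition(1000, 1000, seed = 9)
  expect_gt(cor(ref$soluble_sugar, ref$tey), 0)
  expect_lt(cor(ref$hemicellulose, ref$tey), 0)
  expect_lt(cor(ref$lignin, ref$tey), 0)
  expect_lt(cor(ref$ash, ref$tey), 0)
  expect_lt(cor(ref$soluble_sugar, ref$hemicellulose), 0)
})

test_that("an infeasible composition model errors instead of looping", {
  bad_corr <- diag(5)
  bad_corr[1, 2] <- bad_corr[2, 1] <- 0.999
  bad_corr[1, 3] <- bad_corr[3, 1] <- 0.999
  bad_corr[2, 3] <- bad_corr[3, 2] <- -0.999
  expect_error(composition_model(correlation = bad_corr), "positive-definite")
  m <- composition_model()
  m$class_params$sweet$lo[] <- c(46, 21, 21, 7, 5.5)  # nearly empty boxes
  expect_error(generate_composition(50, 0, model = m, seed = 1),
               "rejected|infeasible")
})

test_that("spectra generation follows the closed-form Beer-Lambert mixture", {
  ref <- tiny_reference(4)
  ax <- default_wavenumber_axis()
  expect_length(ax, 1557)
  s <- generate_spectra(ref, noise = zero_noise(), seed = 1)
  expect_equal(dim(s$absorbance), c(4, 1557))
  # zero-noise: identical compositions give identical spectra
  df <- as.data.frame(ref)
  df2 <- df; df2$sample_id <- paste0("X", df2$sample_id)
  dup <- reference_table(rbind(df, df2))
  s2 <- generate_spectra(dup, noise = zero_noise(), seed = 3)
  expect_equal(s2$absorbance[1:4, ], s2$absorbance[5:8, ],
               ignore_attr = TRUE, tolerance = 1e-15)
  # direct evaluation oracle at a cellulose band center: absorbance strictly
  # increases with the cellulose fraction, everything else held fixed
  lib <- default_band_library()
  cel_center <- 7316.5
  base <- df[1, ]
  grades <- do.call(rbind, lapply(1:5, function(i) {
    r <- base; r$sample_id <- paste0("G", i); r$cellulose <- 10 + 3 * i; r
  }))
  sg <- generate_spectra(reference_table(grades), noise = zero_noise(),
                         seed = 1)
  j <- which.min(abs(sg$wavenumbers - cel_center))
  expect_true(all(diff(sg$absorbance[, j]) > 0))
  # oracle value: sum over bands of intensity * gaussian * mass fraction
  nu <- sg$wavenumbers[j]
  oracle <- vapply(seq_len(nrow(grades)), function(i) {
    r <- grades[i, ]
    frac <- c(soluble_sugar = r$soluble_sugar, cellulose = r$cellulose,
              hemicellulose = r$hemicellulose, lignin = r$lignin,
              ash = r$ash) / 100
    tot <- 0
    for (b in seq_len(nrow(lib))) {
      f <- if (lib$component[b] == "water") 0.04 else frac[[lib$component[b]]]
      tot <- tot + f * lib$intensity[b] *
        exp(-(nu - lib$center[b])^2 / (2 * lib$width[b]^2))
    }
    tot
  }, numeric(1))
  expect_equal(sg$absorbance[, j], oracle, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("zero-noise spectra are linear in composition", {
  df <- as.data.frame(tiny_reference(2, seed = 3))
  half1 <- df[1, ]; half2 <- df[1, ]
  cmp <- c("soluble_sugar", "cellulose", "hemicellulose", "lignin", "ash")
  half1[cmp] <- df[1, cmp] * 0.6
  half2[cmp] <- df[1, cmp] * 0.4
  half1$sample_id <- "H1"; half2$sample_id <- "H2"
  fix_tey <- function(r) { r$tey <- tey_total(r$soluble_sugar, r$cellulose,
                                              r$hemicellulose); r }
  parts <- reference_table(rbind(fix_tey(half1), fix_tey(half2)))
  whole <- reference_table(df[1, , drop = FALSE])
  sp_parts <- generate_spectra(parts, noise = zero_noise(), water_fraction = 0)
  sp_whole <- generate_spectra(whole, noise = zero_noise(), water_fraction = 0)
  expect_equal(colSums(sp_parts$absorbance), sp_whole$absorbance[1, ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("spectra generation is deterministic and noise breaks ties", {
  ref <- tiny_reference(3)
  a <- generate_spectra(ref, seed = 11)
  b <- generate_spectra(ref, seed = 11)
  c_ <- generate_spectra(ref, seed = 12)
  expect_identical(a$absorbance, b$absorbance)
  expect_false(identical(a$absorbance, c_$absorbance))
  expect_error(generate_spectra(ref, bands = data.frame()), "band library")
})
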