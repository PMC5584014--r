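# Seed hygiene: every stochastic generator runs inside with_seed() so output
# is a pure function of (arguments, seed) and the caller's RNG state survives.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

#' Default NIR absorption band library
#'
#' One Gaussian band per (component, band-region) pair, centered at the
#' midpoint of the literature band regions for the stem components of
#' bioenergy sorghum: C-H/O-H/C-O deformation and stretching combinations in
#' 4000-4800 cm^-1, the water O-H band near 5170 cm^-1, and first-overtone
#' C-H stretches between 5780 and 7330 cm^-1. Soluble sugar, cellulose,
#' hemicellulose and lignin each receive the regions assigned to them; water
#' carries the strong 5150-5195 cm^-1 band.
#'
#' Ash is an inorganic mixture with no sharp NIR bands of its own and is, on
#' real spectra, determined only through its association with the organic
#' matrix. So that a synthetic population remains fully identifiable, the
#' library nevertheless gives ash two moderate "mineral-matrix" features (4600
#' and 5500 cm^-1) sized so that ash is about as recoverable from the default
#' noisy spectra as the organic components are. This is a synthetic-data
#' device, not a claim about ash spectroscopy; see the package vignette.
#'
#' @return A data frame of class `band_library` with columns `component`,
#'   `center` (cm^-1), `width` (Gaussian sigma, cm^-1) and `intensity`
#'   (absorbance per unit mass fraction).
#' @export
default_band_library <- function() {
  regions <- list(
    list(lo = 4015, hi = 4022, comps = c("cellulose", "lignin")),
    list(lo = 4285, hi = 4296, comps = "hemicellulose"),
    list(lo = 4392, hi = 4412, comps = c("cellulose", "hemicellulose", "lignin")),
    list(lo = 4760, hi = 4780, comps = "cellulose"),
    list(lo = 5150, hi = 5195, comps = c("water", "soluble_sugar")),
    list(lo = 5776, hi = 5796, comps = c("soluble_sugar", "cellulose", "lignin")),
    list(lo = 6329, hi = 6336, comps = "cellulose"),
    list(lo = 6775, hi = 6822, comps = c("soluble_sugar", "cellulose", "hemicellulose")),
    list(lo = 7305, hi = 7328, comps = "cellulose"))
  rows <- do.call(rbind, lapply(regions, function(r)
    data.frame(component = r$comps, center = (r$lo + r$hi) / 2,
               width = 45, intensity = 1, stringsAsFactors = FALSE)))
  ash <- data.frame(component = "ash", center = c(4600, 5500),
                    width = c(60, 70), intensity = c(2.5, 2.25),
                    stringsAsFactors = FALSE)
  lib <- rbind(rows, ash)
  band_library(lib)
}

#' Validate a band library
#'
#' @param df data frame with columns `component`, `center`, `width`,
#'   `intensity`.
#' @return The validated data frame with class `band_library`.
#' @export
band_library <- function(df) {
  need <- c("component", "center", "width", "intensity")
  if (!all(need %in% names(df)))
    stop("band library needs columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0) stop("band library is empty")
  if (any(df$center < 4000 | df$center > 10000))
    stop("band centers must lie in [4000, 10000] cm^-1")
  if (any(df$width <= 0)) stop("band widths must be positive")
  if (any(df$intensity < 0)) stop("band intensities must be non-negative")
  df <- as.data.frame(df)[, need]
  rownames(df) <- NULL
  class(df) <- c("band_library", "data.frame")
  df
}

#' Spectral distortion model
#'
#' Parameters of the per-spectrum distortions applied on top of the ideal
#' Beer-Lambert mixture: a lognormal multiplicative scatter factor, a random
#' linear baseline (offset plus slope across the axis), and additive white
#' noise per spectral point. These are exactly the artefacts the MSC /
#' Norris-smoothing / first-derivative preprocessing chain is designed to
#' remove.
#'
#' @param additive_sd sd of per-point additive noise, absorbance units.
#' @param multiplicative_sd sd of log scatter factor (factor = exp(N(0, sd))).
#' @param baseline_slope_sd sd of the baseline slope term (absorbance across
#'   the full axis span).
#' @param baseline_offset_sd sd of the baseline offset, absorbance units.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 0.002, multiplicative_sd = 0.05,
                        baseline_slope_sd = 0.01, baseline_offset_sd = 0.01) {
  m <- list(additive_sd = additive_sd, multiplicative_sd = multiplicative_sd,
            baseline_slope_sd = baseline_slope_sd,
            baseline_offset_sd = baseline_offset_sd)
  if (any(unlist(m) < 0)) stop("noise model sds must be non-negative")
  structure(m, class = "noise_model")
}

#' Zero-distortion noise model
#' @return A `noise_model` with all sds set to zero.
#' @export
zero_noise <- function() noise_model(0, 0, 0, 0)

#' Two-class composition model for bioenergy sorghum stems
#'
#' Per-class means, standard deviations and admissible ranges for the five
#' measured components (percent dry weight), plus a shared correlation matrix.
#' Defaults encode the study population this generator emulates: sweet sorghum
#' richer in stem soluble sugar (10.8-47.6%), biomass sorghum (5.4-35.4% sugar)
#' richer in cellulose, hemicellulose and lignin; ash averaging 3.8% in both
#' classes; hemicellulose positively correlated with lignin and ash and
#' negatively with the soluble and insoluble carbohydrates, which makes total
#' ethanol yield correlate positively with sugar/cellulose and negatively with
#' hemicellulose, lignin and ash. Class means are placed so that the mean
#' hexose yield of sweet stems is about 255 g/kg, the mean pentose yield of
#' biomass stems about 112 g/kg, and totals fall in the observed
#' 287-429 g/kg window.
#'
#' @param class_params named list (`sweet`, `biomass`), each a data frame with
#'   rownames = component and columns `mean`, `sd`, `lo`, `hi`.
#' @param correlation 5x5 correlation matrix over (soluble_sugar, cellulose,
#'   hemicellulose, lignin, ash); must be symmetric positive-definite.
#' @param max_component_sum upper bound on the per-sample sum of the five
#'   components, percent.
#' @return A list of class `composition_model`.
#' @export
composition_model <- function(class_params = NULL, correlation = NULL,
                              max_component_sum = 100) {
  comps <- PERCENT_PROPERTIES
  if (is.null(class_params)) {
    mk <- function(mean, sd, lo, hi)
      data.frame(mean = mean, sd = sd, lo = lo, hi = hi, row.names = comps)
    class_params <- list(
      sweet   = mk(c(29.0, 15.8, 15.4, 4.5, 3.8),
                   c(7.0, 2.2, 2.0, 0.9, 0.7),
                   c(10.8, 10.0, 9.5, 2.0, 2.0),
                   c(47.6, 22.0, 21.5, 7.5, 6.0)),
      biomass = mk(c(16.0, 23.2, 18.4, 6.5, 3.8),
                   c(5.5, 2.5, 2.2, 1.1, 0.7),
                   c(5.4, 16.0, 12.0, 3.5, 2.0),
                   c(35.4, 30.0, 25.0, 9.8, 6.0)))
  }
  if (is.null(correlation)) {
    correlation <- diag(5)
    dimnames(correlation) <- list(comps, comps)
    set_r <- function(a, b, r) {
      correlation[a, b] <<- r; correlation[b, a] <<- r
    }
    set_r("soluble_sugar", "cellulose", 0.15)
    set_r("soluble_sugar", "hemicellulose", -0.50)
    set_r("soluble_sugar", "lignin", -0.40)
    set_r("soluble_sugar", "ash", -0.30)
    set_r("cellulose", "hemicellulose", -0.30)
    set_r("cellulose", "lignin", -0.20)
    set_r("cellulose", "ash", -0.20)
    set_r("hemicellulose", "lignin", 0.40)
    set_r("hemicellulose", "ash", 0.30)
    set_r("lignin", "ash", 0.30)
  }
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      !all(diag(correlation) == 1))
    stop("correlation must be symmetric with unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("correlation matrix is not positive-definite (min eigenvalue ",
         format(min(ev)), ")")
  for (cl in names(class_params)) {
    cp <- class_params[[cl]]
    if (any(cp$lo < 0) || any(cp$hi > 100) || any(cp$lo >= cp$hi))
      stop("component ranges for class '", cl, "' must satisfy 0 <= lo < hi <= 100")
    if (any(cp$sd <= 0)) stop("component sds must be positive")
  }
  structure(list(class_params = class_params, correlation = correlation,
                 components = comps, max_component_sum = max_component_sum),
            class = "composition_model")
}

# Truncated multivariate-normal draws by rejection; honors the printed ranges
# exactly. Errors out rather than looping forever on an infeasible model.
rtruncmvn <- function(n, mean, sd, lo, hi, chol_R, max_sum,
                      max_reject = 1e4) {
  p <- length(mean)
  out <- matrix(NA_real_, n, p)
  got <- 0L
  rejections <- 0L
  while (got < n) {
    take <- max(n - got, 16L)
    z <- matrix(stats::rnorm(take * p), take, p) %*% chol_R
    x <- sweep(sweep(z, 2, sd, `*`), 2, mean, `+`)
    ok <- rowSums(sweep(x, 2, lo, `<`)) == 0 &
          rowSums(sweep(x, 2, hi, `>`)) == 0 &
          rowSums(x) <= max_sum
    rejections <- rejections + sum(!ok)
    if (rejections > max_reject)
      stop("composition model rejected more than ", max_reject,
           " draws; ranges/correlations are infeasible")
    x <- x[ok, , drop = FALSE]
    if (nrow(x)) {
      keep <- min(nrow(x), n - got)
      out[(got + 1):(got + keep), ] <- x[seq_len(keep), , drop = FALSE]
      got <- got + keep
    }
  }
  out
}

#' Generate a synthetic two-class composition table
#'
#' Draws per-sample compositions from class-wise truncated multivariate
#' normals (see [composition_model()]) and fills the TEY column from the
#' deterministic yield equations ([tey_total()]).
#'
#' @param n_sweet number of sweet sorghum samples.
#' @param n_biomass number of biomass sorghum samples.
#' @param model a [composition_model()].
#' @param seed integer seed; the output is a pure function of the arguments.
#' @return A [reference_table()] with `n_sweet + n_biomass` rows.
#' @export
generate_composition <- function(n_sweet = 70, n_biomass = 77,
                                 model = composition_model(), seed = 1) {
  stopifnot(n_sweet >= 0, n_biomass >= 0)
  chol_R <- chol(model$correlation)
  with_seed(seed, {
    blocks <- lapply(c(sweet = "sweet", biomass = "biomass"), function(cl) {
      n <- if (cl == "sweet") n_sweet else n_biomass
      if (n == 0) return(NULL)
      cp <- model$class_params[[cl]]
      x <- rtruncmvn(n, cp$mean, cp$sd, cp$lo, cp$hi, chol_R,
                     model$max_component_sum)
      colnames(x) <- model$components
      data.frame(class = cl, x, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, blocks)
    df$sample_id <- sprintf("%s%03d",
                            ifelse(df$class == "sweet", "SW", "BM"),
                            stats::ave(seq_len(nrow(df)), df$class, FUN = seq_along))
    df$tey <- tey_total(df$soluble_sugar, df$cellulose, df$hemicellulose)
    reference_table(df)
  })
}

#' Default wavenumber axis
#'
#' 1557 evenly spaced points spanning 4000-10000 cm^-1 (spacing about
#' 3.86 cm^-1), in the descending order of FT-NIR exports.
#'
#' @param n number of spectral variables.
#' @param descending logical; return the axis from 10000 down to 4000.
#' @return Numeric vector of wavenumbers, cm^-1.
#' @export
default_wavenumber_axis <- function(n = 1557, descending = TRUE) {
  ax <- seq(4000, 10000, length.out = n)
  if (descending) rev(ax) else ax
}

#' Generate synthetic NIR spectra for a composition table
#'
#' Ideal absorbance is a linear Beer-Lambert mixture: for each sample, each
#' component's mass fraction (percent / 100) scales that component's sum of
#' Gaussian bands; a fixed residual-moisture fraction drives the water band.
#' On top of the ideal mixture, per-spectrum distortions from the
#' [noise_model()] are applied: multiplicative scatter, a linear baseline, and
#' additive noise.
#'
#' @param reference a [reference_table()] giving per-sample compositions.
#' @param bands a [band_library()].
#' @param noise a [noise_model()].
#' @param axis wavenumber grid, cm^-1 (default [default_wavenumber_axis()]).
#' @param water_fraction residual moisture mass fraction driving the water
#'   band (dried powders; constant across samples).
#' @param seed integer seed for the distortion draws.
#' @return A [spectra_set()] aligned with `reference`.
#' @export
generate_spectra <- function(reference, bands = default_band_library(),
                             noise = noise_model(),
                             axis = default_wavenumber_axis(),
                             water_fraction = 0.04, seed = 1) {
  bands <- band_library(bands)
  n <- nrow(reference)
  p <- length(axis)
  comps <- unique(bands$component)
  # pure-component spectra, one row per component present in the library
  K <- t(vapply(comps, function(cm) {
    b <- bands[bands$component == cm, , drop = FALSE]
    rowSums(vapply(seq_len(nrow(b)), function(i)
      b$intensity[i] * exp(-(axis - b$center[i])^2 / (2 * b$width[i]^2)),
      numeric(p)))
  }, numeric(p)))
  Fm <- matrix(0, n, length(comps), dimnames = list(NULL, comps))
  for (cm in intersect(comps, PERCENT_PROPERTIES))
    Fm[, cm] <- reference[[cm]] / 100
  if ("water" %in% comps) Fm[, "water"] <- water_fraction
  A <- Fm %*% K
  with_seed(seed, {
    mult <- exp(stats::rnorm(n, 0, noise$multiplicative_sd))
    offs <- stats::rnorm(n, 0, noise$baseline_offset_sd)
    slop <- stats::rnorm(n, 0, noise$baseline_slope_sd)
    ramp <- (axis - min(axis)) / (max(axis) - min(axis))
    A <- A * mult + outer(offs, rep(1, p)) + outer(slop, ramp)
    if (noise$additive_sd > 0)
      A <- A + matrix(stats::rnorm(n * p, 0, noise$additive_sd), n, p)
    spectra_set(A, axis, reference$sample_id)
  })
}
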