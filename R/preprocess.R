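#' Preprocessing configuration
#'
#' Ordered pretreatment chain applied to raw spectra before any modeling.
#' The default order — multiplicative scatter correction, then Norris
#' segment smoothing, then gap first derivative — removes multiplicative
#' scatter, random noise and additive/linear baseline effects in that order.
#'
#' @param steps character vector, ordered subset of
#'   `c("msc", "norris", "first_derivative")`.
#' @param norris_segment odd smoothing window length in points (>= 1).
#' @param derivative_gap half-gap of the first derivative, in points (>= 1).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(steps = c("msc", "norris", "first_derivative"),
                              norris_segment = 5, derivative_gap = 5) {
  bad <- setdiff(steps, c("msc", "norris", "first_derivative"))
  if (length(bad)) stop("unknown preprocessing step(s): ",
                        paste(bad, collapse = ", "))
  if (norris_segment < 1 || norris_segment %% 2 == 0)
    stop("norris_segment must be an odd integer >= 1")
  if (derivative_gap < 1) stop("derivative_gap must be >= 1")
  structure(list(steps = steps, norris_segment = as.integer(norris_segment),
                 derivative_gap = as.integer(derivative_gap)),
            class = "preprocess_config")
}

#' Multiplicative scatter correction
#'
#' Each spectrum `x` is regressed on the reference spectrum `m` by ordinary
#' least squares, `x ~ a + b m`, and replaced by `(x - a) / b`. By default the
#' reference is the mean spectrum of the set, the standard MSC convention.
#'
#' @param s a [spectra_set()].
#' @param reference optional reference spectrum (numeric vector of the same
#'   length as the axis); defaults to the mean spectrum.
#' @return A corrected `spectra_set`.
#' @export
msc <- function(s, reference = NULL) {
  X <- s$absorbance
  if (is.null(reference)) {
    if (nrow(X) < 2)
      stop("msc needs at least 2 spectra when no reference is supplied")
    reference <- colMeans(X)
  }
  if (length(reference) != ncol(X))
    stop("reference spectrum length does not match the wavenumber axis")
  mc <- reference - mean(reference)
  denom <- sum(mc^2)
  if (denom < .Machine$double.eps)
    stop("msc reference spectrum has zero variance")
  b <- as.vector(X %*% mc - rowSums(X) * mean(mc)) / denom  # = cov(x, m)/var(m)
  a <- rowMeans(X) - b * mean(reference)
  if (any(abs(b) < 1e-12))
    stop("msc fit produced a zero slope for at least one spectrum")
  spectra_set((X - a) / b, s$wavenumbers, s$sample_ids)
}

#' Norris segment smoothing
#'
#' Moving-average smoothing with a window of `segment` points, the smoothing
#' half of the Norris derivative filter (the gap-difference derivative is
#' applied separately by [first_derivative()]). Edge points are smoothed with
#' truncated windows so the axis length is preserved.
#'
#' @param s a [spectra_set()].
#' @param segment odd window length in points.
#' @return A smoothed `spectra_set`.
#' @export
norris_filter <- function(s, segment = 5) {
  if (segment < 1 || segment %% 2 == 0)
    stop("segment must be an odd integer >= 1")
  p <- length(s$wavenumbers)
  if (segment > p) stop("smoothing window exceeds the axis length")
  if (segment == 1) return(s)
  half <- (segment - 1L) %/% 2L
  # truncated-window moving average via cumulative sums on each row
  X <- s$absorbance
  n <- nrow(X)
  cs <- cbind(0, t(apply(X, 1, cumsum)))          # n x (p+1)
  lo <- pmax(seq_len(p) - half, 1L)
  hi <- pmin(seq_len(p) + half, p)
  sm <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    matrix(hi - lo + 1L, n, p, byrow = TRUE)
  spectra_set(sm, s$wavenumbers, s$sample_ids)
}

#' Gap first derivative
#'
#' Central gap difference `d_i = (x[i+gap] - x[i-gap]) / (w[i+gap] - w[i-gap])`
#' in absorbance per cm^-1. The output loses `gap` points at each end and its
#' axis is truncated to match, so every emitted value is exact; downstream
#' variable indices refer to this truncated axis.
#'
#' @param s a [spectra_set()].
#' @param gap half-gap in points (>= 1).
#' @return A differentiated `spectra_set` with `2 * gap` fewer variables.
#' @export
first_derivative <- function(s, gap = 5) {
  gap <- as.integer(gap)
  if (gap < 1) stop("gap must be >= 1")
  p <- length(s$wavenumbers)
  if (p <= 2L * gap) stop("axis too short for derivative gap ", gap)
  idx <- (gap + 1L):(p - gap)
  dw <- s$wavenumbers[idx + gap] - s$wavenumbers[idx - gap]
  D <- (s$absorbance[, idx + gap, drop = FALSE] -
        s$absorbance[, idx - gap, drop = FALSE]) /
    matrix(dw, nrow(s$absorbance), length(idx), byrow = TRUE)
  spectra_set(D, s$wavenumbers[idx], s$sample_ids)
}

#' Apply a preprocessing chain
#'
#' Applies the configured steps in order; the default configuration is the
#' full MSC -> Norris smoothing -> first derivative chain.
#'
#' @param s a [spectra_set()].
#' @param config a [preprocess_config()].
#' @return The preprocessed `spectra_set`.
#' @export
preprocess <- function(s, config = preprocess_config()) {
  for (step in config$steps) {
    s <- switch(step,
      msc = msc(s),
      norris = norris_filter(s, config$norris_segment),
      first_derivative = first_derivative(s, config$derivative_gap))
  }
  s
}
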