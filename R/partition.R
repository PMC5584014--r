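#' Pairwise Euclidean distance matrix
#'
#' @param M numeric matrix, one observation per row.
#' @return A symmetric n x n matrix of Euclidean distances with zero diagonal.
#' @export
euclidean_distance_matrix <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2) stop("need at least 2 rows to compute pairwise distances")
  as.matrix(stats::dist(M, method = "euclidean"))
}

#' Joint X-Y (SPXY) distance matrix
#'
#' Combines spectral and response distances after normalizing each by its
#' maximum: `dxy = dx / max(dx) + dy / max(dy)`, so both spaces contribute on
#' the same scale. If the response carries no spread (`max(dy) = 0`) the y
#' term is dropped and the distance reduces to the normalized spectral
#' distance, i.e. the Kennard-Stone limit.
#'
#' @param dx spectral distance matrix.
#' @param dy response distance matrix of the same dimension.
#' @return The joint distance matrix.
#' @export
spxy_distance <- function(dx, dy) {
  dx <- as.matrix(dx); dy <- as.matrix(dy)
  if (!all(dim(dx) == dim(dy)))
    stop("dx and dy must have identical dimensions")
  mx <- max(dx)
  if (mx == 0) stop("all spectral distances are zero; cannot normalize")
  my <- max(dy)
  if (my == 0) return(dx / mx)
  dx / mx + dy / my
}

#' Kennard-Stone max-min selection
#'
#' Picks `k` indices covering the space uniformly: the first two are the most
#' distant pair, and each subsequent pick maximizes its minimum distance to
#' the already-selected set. Ties are broken toward the lowest index, making
#' the selection fully deterministic.
#'
#' @param d symmetric distance matrix.
#' @param k number of samples to select, `2 <= k <= n`.
#' @return Integer vector of selected indices, in selection order.
#' @export
kennard_stone <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k < 2 || k > n) stop("k must lie in [2, ", n, "]")
  # initial pair: argmax of d, lowest indices on ties
  m <- max(d)
  pair <- which(d == m, arr.ind = TRUE)
  pair <- pair[pair[, 1] < pair[, 2], , drop = FALSE]
  pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE][1, ]
  sel <- as.integer(pair)
  if (k == 2) return(sel)
  mind <- unname(pmin(d[, sel[1]], d[, sel[2]]))
  mind[sel] <- -Inf
  for (i in 3:k) {
    nxt <- which.max(mind)   # which.max returns the first (lowest) maximizer
    sel <- c(sel, nxt)
    mind <- pmin(mind, d[, nxt])
    mind[nxt] <- -Inf
  }
  unname(as.integer(sel))
}

#' Partition samples into calibration and validation subsets
#'
#' For `spxy` and `kennard_stone`, the selection algorithm picks the
#' calibration set of size `round((1 - validation_fraction) * n)` — extremes
#' are swept into calibration, which keeps the validation subset inside the
#' calibrated range — and the remainder forms the validation subset. `random`
#' draws the validation subset uniformly with the given seed. With the default
#' fraction, one of every four samples lands in validation (147 samples give a
#' 110/37 split).
#'
#' @param spectra a [spectra_set()] (normally already preprocessed; distances
#'   are computed on the matrix handed in).
#' @param reference a [reference_table()] aligned with `spectra`.
#' @param property which reference property supplies the y distances
#'   (one of `soluble_sugar`, `cellulose`, `hemicellulose`, `lignin`, `ash`,
#'   `tey`).
#' @param method `"spxy"`, `"kennard_stone"` or `"random"`.
#' @param validation_fraction fraction of samples reserved for validation,
#'   strictly inside (0, 1).
#' @param seed integer seed (used by `"random"` only).
#' @return A list of class `partition` with `property`, `method`,
#'   `calibration` and `validation` index vectors.
#' @export
make_partition <- function(spectra, reference, property,
                           method = c("spxy", "kennard_stone", "random"),
                           validation_fraction = 0.25, seed = 1) {
  method <- match.arg(method)
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must lie strictly inside (0, 1)")
  if (!property %in% names(reference))
    stop("unknown property '", property, "'")
  aligned <- align_samples(spectra, reference)
  n <- length(spectra$sample_ids)
  n_cal <- round((1 - validation_fraction) * n)
  if (n_cal < 2 || n_cal >= n)
    stop("validation fraction leaves an unusable calibration size")
  cal <- switch(method,
    random = with_seed(seed, sort(sample.int(n, n_cal))),
    kennard_stone = sort(kennard_stone(
      euclidean_distance_matrix(spectra$absorbance), n_cal)),
    spxy = {
      dx <- euclidean_distance_matrix(spectra$absorbance)
      y <- aligned$reference[[property]]
      dy <- as.matrix(stats::dist(matrix(y, ncol = 1)))
      sort(kennard_stone(spxy_distance(dx, dy), n_cal))
    })
  structure(list(property = property, method = method,
                 calibration = cal,
                 validation = setdiff(seq_len(n), cal)),
            class = "partition")
}
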