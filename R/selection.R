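selection_result <- function(method, scores, threshold, selected,
                             diagnostics = list()) {
  scores <- unname(as.numeric(scores))
  threshold <- unname(threshold)
  structure(list(method = method, scores = scores, threshold = threshold,
                 selected = sort(as.integer(selected)),
                 diagnostics = diagnostics),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result [%s]: %d of %d variables selected\n",
              x$method, length(x$selected), length(x$scores)))
  invisible(x)
}

# k-fold CV RMSECV (minimum over factor counts); folds assigned round-robin
# on a seeded permutation drawn from the caller's RNG stream.
kfold_rmsecv <- function(X, y, max_factors, n_folds = 5) {
  n <- nrow(X)
  n_folds <- min(n_folds, n)
  fold <- sample(rep_len(seq_len(n_folds), n))
  kmax <- min(max_factors, ncol(X), n - ceiling(n / n_folds) - 1)
  if (kmax < 1) kmax <- 1
  pred <- matrix(NA_real_, n, kmax)
  for (f in seq_len(n_folds)) {
    hold <- which(fold == f)
    fit <- fit_pls(X[-hold, , drop = FALSE], y[-hold],
                   min(kmax, length(y) - length(hold) - 1, ncol(X)))
    pv <- sweep(X[hold, , drop = FALSE], 2, fit$x_mean) %*% fit$coef_path +
      fit$y_mean
    if (fit$n_factors < kmax)
      pv <- cbind(pv, matrix(pv[, fit$n_factors], nrow(pv),
                             kmax - fit$n_factors))
    pred[hold, ] <- pv[, seq_len(kmax), drop = FALSE]
  }
  rmse <- sqrt(colMeans((pred - y)^2))
  list(rmsecv = min(rmse), n_factors = which.min(rmse))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Monte Carlo wavelength elimination by "survival of the fittest": at run
#' `i`, a PLS model is fitted on a random `mc_sample_ratio` subset of the
#' calibration samples using the currently retained variables; variables are
#' then resampled without replacement with probability proportional to their
#' absolute regression coefficients, keeping `ceiling(r_i * p)` of them, where
#' the exponentially decreasing function `r_i = a * exp(-k * i)` is fixed by
#' the boundary conditions `r_1 * p = p` (all variables at the first run) and
#' `r_nruns * p = 2` (two variables at the last). Each run's subset is scored
#' by 5-fold cross-validated RMSECV on the full calibration set, and the
#' subset with the smallest RMSECV wins.
#'
#' @param X calibration predictor matrix (p >= 2 columns).
#' @param y calibration response.
#' @param n_runs number of Monte Carlo runs (>= 2).
#' @param mc_sample_ratio fraction of samples drawn per run.
#' @param max_factors PLS factor cap for the internal fits.
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @return A `selection_result` whose `scores` are per-variable selection
#'   frequencies over the runs, with `diagnostics$rmsecv` (per-run RMSECV),
#'   `diagnostics$n_retained` (per-run subset size) and
#'   `diagnostics$best_run`.
#' @export
cars <- function(X, y, n_runs = 50, mc_sample_ratio = 0.8, max_factors = 10,
                 seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (p < 2) stop("CARS needs at least 2 variables")
  if (n_runs < 2) stop("n_runs must be >= 2")
  # EDF through (1, p) and (n_runs, 2): r_i = a * exp(-k i)
  kk <- log(p / 2) / (n_runs - 1)
  a <- exp(kk)
  with_seed(seed, {
    retained <- seq_len(p)
    freq <- integer(p)
    rmsecv_runs <- numeric(n_runs)
    nret_runs <- integer(n_runs)
    subsets <- vector("list", n_runs)
    for (i in seq_len(n_runs)) {
      sub <- sample.int(n, max(round(mc_sample_ratio * n), 4))
      kfit <- min(max_factors, length(sub) - 1, length(retained))
      fit <- fit_pls(X[sub, retained, drop = FALSE], y[sub], kfit)
      w <- abs(fit$coef_path[, fit$n_factors])
      if (all(w == 0)) stop("CARS encountered an all-zero coefficient vector")
      n_keep <- max(2L, min(length(retained), ceiling(a * exp(-kk * i) * p)))
      retained <- if (n_keep >= length(retained)) retained else
        sort(sample(retained, n_keep, prob = w / sum(w)))
      freq[retained] <- freq[retained] + 1L
      cv <- kfold_rmsecv(X[, retained, drop = FALSE], y, max_factors)
      rmsecv_runs[i] <- cv$rmsecv
      nret_runs[i] <- length(retained)
      subsets[[i]] <- retained
    }
    best <- which.min(rmsecv_runs)
    selection_result("CARS", freq / n_runs, NA_real_, subsets[[best]],
                     list(rmsecv = rmsecv_runs, n_retained = nret_runs,
                          best_run = best))
  })
}

#' Selectivity ratio (SR)
#'
#' Projects X onto the normalized PLS regression vector (the target
#' projection) and scores each variable by the ratio of its explained to
#' residual variance on that single component. Variables whose ratio exceeds
#' the F critical value at `alpha` with (n - 2, n - 3) degrees of freedom are
#' selected. A variable reconstructed exactly (zero residual variance) gets an
#' infinite score and is selected.
#'
#' @param X calibration predictor matrix.
#' @param y calibration response.
#' @param n_factors PLS factor count for the underlying model.
#' @param alpha significance level of the F threshold.
#' @return A `selection_result` with per-variable SR scores.
#' @export
selectivity_ratio <- function(X, y, n_factors, alpha = 0.05) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  fit <- fit_pls(X, y, n_factors)
  b <- fit$coefficients
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("zero regression vector; selectivity ratio undefined")
  Xc <- sweep(X, 2, fit$x_mean)
  t_tp <- as.vector(Xc %*% (b / nb))
  p_tp <- as.vector(crossprod(Xc, t_tp)) / sum(t_tp^2)
  explained <- sum(t_tp^2) * p_tp^2
  residual <- colSums(Xc^2) - explained
  residual[residual < 0] <- 0
  sr <- ifelse(residual <= .Machine$double.eps, Inf, explained / residual)
  threshold <- stats::qf(1 - alpha, n - 2, n - 3)
  selection_result("SR", sr, threshold, which(sr > threshold))
}

#' Variable importance for projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` with unit-norm NIPALS
#' weights and `SSY_a = q_a^2 t_a' t_a` the response variance captured by
#' factor `a`. The mean squared VIP over variables is exactly 1, so the
#' conventional cutoff `VIP > 1` selects the above-average contributors.
#'
#' @param X calibration predictor matrix.
#' @param y calibration response.
#' @param n_factors PLS factor count.
#' @param threshold selection cutoff (conventionally 1).
#' @return A `selection_result` with per-variable VIP scores.
#' @export
vip <- function(X, y, n_factors, threshold = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  p <- ncol(X)
  fit <- fit_pls(X, y, n_factors)
  ssy <- fit$y_loadings^2 * colSums(fit$scores^2)
  W2 <- sweep(fit$weights^2, 2, colSums(fit$weights^2), `/`)
  scores <- sqrt(p * as.vector(W2 %*% ssy) / sum(ssy))
  selection_result("VIP", scores, threshold, which(scores > threshold))
}

# shared stability engine for UVE / MC-UVE: B is a matrix of coefficient
# vectors (one row per submodel) over [real | artificial noise] variables.
uve_from_coefmat <- function(method, B, p, cutoff_quantile) {
  mu <- colMeans(B)
  sdv <- apply(B, 2, stats::sd)
  stability <- ifelse(sdv > 0, mu / sdv,
                      ifelse(mu == 0, 0, sign(mu) * Inf))
  cutoff <- as.numeric(stats::quantile(abs(stability[(p + 1):(2 * p)]),
                                       cutoff_quantile, names = FALSE))
  selected <- which(abs(stability[seq_len(p)]) > cutoff)
  selection_result(method, stability[seq_len(p)], cutoff, selected,
                   list(noise_stability = stability[(p + 1):(2 * p)]))
}

#' Uninformative variable elimination (UVE)
#'
#' Appends `p` artificial noise variables (uniform draws scaled to be
#' numerically negligible, so they cannot influence the fit yet still yield a
#' stability null), records the PLS coefficient vector of every leave-one-out
#' submodel, and scores each variable by its stability `c_j = mean(b_j) /
#' sd(b_j)` across submodels. The cutoff is the `cutoff_quantile` quantile
#' (default: the maximum) of the absolute noise-variable stabilities; real
#' variables above it are retained.
#'
#' @param X calibration predictor matrix.
#' @param y calibration response.
#' @param n_factors PLS factor count for the submodels.
#' @param noise_scale amplitude of the artificial noise variables relative to
#'   the data scale.
#' @param cutoff_quantile quantile of the noise-stability null used as cutoff.
#' @param seed integer seed for the noise draws.
#' @return A `selection_result` with per-variable stabilities and
#'   `diagnostics$noise_stability`.
#' @export
uve <- function(X, y, n_factors, noise_scale = 1e-10, cutoff_quantile = 1,
                seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 4) stop("UVE needs at least 4 samples")
  with_seed(seed, {
    noise <- matrix(stats::runif(n * p), n, p) *
      (noise_scale * max(abs(X), 1e-300))
    Xa <- cbind(X, noise)
    kfit <- min(n_factors, n - 2, ncol(Xa))
    B <- t(vapply(seq_len(n), function(i) {
      fit <- fit_pls(Xa[-i, , drop = FALSE], y[-i], kfit)
      fit$coef_path[, fit$n_factors]
    }, numeric(2 * p)))
    uve_from_coefmat("UVE", B, p, cutoff_quantile)
  })
}

#' Monte Carlo uninformative variable elimination (MC-UVE)
#'
#' As [uve()], but the coefficient stability is computed over `n_models`
#' random-subset refits (each on a `sample_ratio` fraction of the samples)
#' instead of the leave-one-out submodels.
#'
#' @inheritParams uve
#' @param n_models number of Monte Carlo submodels.
#' @param sample_ratio fraction of samples drawn per submodel.
#' @return A `selection_result` with per-variable stabilities and
#'   `diagnostics$noise_stability`.
#' @export
mc_uve <- function(X, y, n_factors, n_models = 500, sample_ratio = 0.8,
                   noise_scale = 1e-10, cutoff_quantile = 1, seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 4) stop("MC-UVE needs at least 4 samples")
  n_sub <- max(4L, round(sample_ratio * n))
  if (n_sub >= n) n_sub <- n - 1L
  with_seed(seed, {
    noise <- matrix(stats::runif(n * p), n, p) *
      (noise_scale * max(abs(X), 1e-300))
    Xa <- cbind(X, noise)
    kfit <- min(n_factors, n_sub - 1, ncol(Xa))
    B <- t(vapply(seq_len(n_models), function(i) {
      sub <- sample.int(n, n_sub)
      fit <- fit_pls(Xa[sub, , drop = FALSE], y[sub], kfit)
      fit$coef_path[, fit$n_factors]
    }, numeric(2 * p)))
    uve_from_coefmat("MC_UVE", B, p, cutoff_quantile)
  })
}

# consensus class labels by number of selecting methods, 5 down to 0
CONSENSUS_CLASSES <- c(MIV = 5L, VIV = 4L, IV = 3L, NV = 2L, LIV = 1L,
                       UIV = 0L)

#' Consensus categorization of selected variables
#'
#' Counts, for every variable, how many of the five selection methods chose
#' it, and maps the count to a characteristic-variable class: most important
#' (5 methods), very important (4), important (3), normal (2), less important
#' (1) and uninformative (0). Proportions are reported as percent of the total
#' variable count, rounded to one decimal.
#'
#' @param results list of exactly five `selection_result` objects from five
#'   distinct methods.
#' @param p total number of variables (defaults to the score length of the
#'   first result).
#' @return A list of class `consensus_map` with `method_count` (per-variable),
#'   `class` (per-variable factor), and a `summary` data frame with columns
#'   `class`, `n`, `pct`.
#' @export
categorize_consensus <- function(results, p = NULL) {
  if (length(results) != 5)
    stop("consensus categorization requires exactly five selection results")
  methods <- vapply(results, function(r) r$method, character(1))
  if (anyDuplicated(methods))
    stop("selection results must come from five distinct methods, got: ",
         paste(methods, collapse = ", "))
  if (is.null(p)) p <- length(results[[1]]$scores)
  counts <- integer(p)
  for (r in results) {
    if (length(r$selected) && max(r$selected) > p)
      stop("selection result [", r$method, "] indexes beyond p = ", p)
    counts[r$selected] <- counts[r$selected] + 1L
  }
  cls <- names(CONSENSUS_CLASSES)[match(counts, CONSENSUS_CLASSES)]
  n_by <- vapply(CONSENSUS_CLASSES, function(k) sum(counts == k), integer(1))
  summary <- data.frame(class = names(CONSENSUS_CLASSES),
                        n = as.integer(n_by),
                        pct = round(100 * n_by / p, 1),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(method_count = counts,
                 class = factor(cls, levels = names(CONSENSUS_CLASSES)),
                 summary = summary, methods = methods, p = p),
            class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  cat("consensus_map over", x$p, "variables (methods:",
      paste(x$methods, collapse = ", "), ")\n")
  print(x$summary)
  invisible(x)
}
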