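#' Fit a PLS1 regression by NIPALS
#'
#' Single-response partial least squares with mean centering and sequential
#' deflation. The model stores the full factor decomposition plus the
#' regression-coefficient path, so predictions are available at every factor
#' count from 1 to `n_factors` without refitting. Extraction stops early if the
#' residual covariance collapses (exact-fit regime).
#'
#' @param X numeric matrix of predictors (samples x variables).
#' @param y numeric response vector.
#' @param n_factors number of latent factors, at most `min(n - 1, p)`.
#' @return An object of class `pls_model` with elements `n_factors` (factors
#'   actually extracted), `x_mean`, `y_mean`, `weights` (p x k, unit columns),
#'   `loadings` (p x k), `scores` (n x k), `y_loadings` (length k), `coef_path`
#'   (p x k; column a holds the coefficient vector of the a-factor model) and
#'   `coefficients` (coefficients at the full factor count).
#' @export
fit_pls <- function(X, y, n_factors) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("X and y must not contain missing values")
  if (n_factors < 1 || n_factors > min(n - 1, p))
    stop("n_factors must lie in [1, min(n - 1, p)] = [1, ", min(n - 1, p), "]")
  if (stats::sd(y) == 0) stop("response has zero variance")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- X - rep(x_mean, each = n)
  yc <- y - y_mean
  W <- matrix(0, p, n_factors)
  P <- matrix(0, p, n_factors)
  Tm <- matrix(0, n, n_factors)
  q <- numeric(n_factors)
  k <- 0L
  for (a in seq_len(n_factors)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w * w))
    if (nw < 1e-12) break  # residual covariance exhausted
    w <- w / nw
    t_a <- as.vector(Xc %*% w)
    tt <- sum(t_a * t_a)
    if (tt < 1e-24) break
    p_a <- as.vector(crossprod(Xc, t_a)) / tt
    q_a <- sum(yc * t_a) / tt
    Xc <- Xc - tcrossprod(t_a, p_a)
    yc <- yc - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    k <- a
  }
  if (k == 0L) stop("no PLS factor could be extracted (X'y is zero)")
  W <- W[, seq_len(k), drop = FALSE]
  P <- P[, seq_len(k), drop = FALSE]
  Tm <- Tm[, seq_len(k), drop = FALSE]
  q <- q[seq_len(k)]
  PtW <- crossprod(P, W)
  coef_path <- vapply(seq_len(k), function(a) {
    as.vector(W[, seq_len(a), drop = FALSE] %*%
                solve(PtW[seq_len(a), seq_len(a), drop = FALSE],
                      q[seq_len(a)]))
  }, numeric(p))
  coef_path <- matrix(coef_path, nrow = p)
  structure(list(n_factors = k, x_mean = x_mean, y_mean = y_mean,
                 weights = W, loadings = P, scores = Tm, y_loadings = q,
                 coef_path = coef_path,
                 coefficients = coef_path[, k]),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata matrix of predictors with the same columns as the training
#'   matrix.
#' @param n_factors factor count to predict with (default: all extracted).
#' @param ... ignored.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_factors = NULL, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(n_factors)) n_factors <- object$n_factors
  if (n_factors < 1 || n_factors > object$n_factors)
    stop("n_factors must lie in [1, ", object$n_factors, "]")
  b <- object$coef_path[, n_factors]
  as.vector(sweep(newdata, 2, object$x_mean) %*% b) + object$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d factor(s), %d variables\n",
              x$n_factors, length(x$coefficients)))
  invisible(x)
}

#' Leave-one-out cross-validation of a PLS1 model
#'
#' Refits the model with each sample left out and predicts it at every factor
#' count up to `max_factors`, giving the RMSECV-by-factor-count profile used
#' for factor selection.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param max_factors largest factor count to evaluate (capped at
#'   `min(n - 2, p)` so every leave-one-out fit is well-posed).
#' @return A list of class `loo_cv` with `rmsecv` (vector indexed by factor
#'   count), `predictions` (n x max_factors matrix of held-out predictions)
#'   and `r2cv` (squared correlation of held-out predictions with y, by factor
#'   count).
#' @export
loo_cv <- function(X, y, max_factors) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("leave-one-out cross-validation needs at least 3 samples")
  kmax <- min(max_factors, n - 2, ncol(X))
  if (kmax < 1) stop("max_factors too small after capping at min(n - 2, p)")
  pred <- matrix(NA_real_, n, kmax)
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], kmax)
    xc <- X[i, ] - fit$x_mean
    pv <- as.vector(xc %*% fit$coef_path) + fit$y_mean
    # if extraction stopped early, the last available model extends rightward
    if (fit$n_factors < kmax)
      pv <- c(pv, rep(pv[fit$n_factors], kmax - fit$n_factors))
    pred[i, ] <- pv
  }
  err2 <- (pred - y)^2
  rmsecv <- sqrt(colMeans(err2))
  r2cv <- apply(pred, 2, function(ph) {
    if (stats::sd(ph) == 0) 0 else stats::cor(ph, y)^2
  })
  structure(list(rmsecv = rmsecv, predictions = pred, r2cv = r2cv),
            class = "loo_cv")
}

#' Parsimonious factor-count selection
#'
#' Returns the smallest factor count whose RMSECV lies within `tol` (default
#' 2%) of the global minimum, trading a negligible loss of cross-validated
#' accuracy for a simpler, more robust model.
#'
#' @param rmsecv numeric vector of RMSECV values indexed by factor count (as
#'   produced by [loo_cv()]), or a `loo_cv` object.
#' @param max upper bound on the returned factor count.
#' @param tol relative tolerance above the minimum RMSECV.
#' @return Integer factor count.
#' @export
select_factors <- function(rmsecv, max = 15, tol = 0.02) {
  if (inherits(rmsecv, "loo_cv")) rmsecv <- rmsecv$rmsecv
  if (!length(rmsecv)) stop("empty RMSECV vector")
  rmsecv <- rmsecv[seq_len(min(length(rmsecv), max))]
  best <- min(rmsecv)
  as.integer(which(rmsecv <= best * (1 + tol))[1])
}

#' Iterative calibration-outlier removal
#'
#' Fits a PLS model and drops samples that are extreme in either the X space
#' (score leverage above `leverage_mult` times the average leverage
#' `(k + 1) / n`) or the y space (absolute studentized residual above
#' `residual_z`), then refits; at most `max_rounds` rounds. If more than 10%
#' of the samples would be discarded the result is flagged rather than
#' trusted.
#'
#' @param X calibration predictor matrix.
#' @param y calibration response.
#' @param n_factors PLS factor count used for the diagnostic fits.
#' @param leverage_mult leverage threshold multiplier.
#' @param residual_z studentized-residual threshold.
#' @param max_rounds maximum removal rounds.
#' @return A list of class `outlier_removal` with `retained` (indices into the
#'   original rows), `removed`, and `flagged` (TRUE when more than 10% of
#'   samples were removed).
#' @export
remove_outliers <- function(X, y, n_factors, leverage_mult = 3,
                            residual_z = 2.5, max_rounds = 2) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  keep <- seq_len(nrow(X))
  for (round in seq_len(max_rounds)) {
    n <- length(keep)
    k <- min(n_factors, n - 2, ncol(X))
    fit <- fit_pls(X[keep, , drop = FALSE], y[keep], k)
    k <- fit$n_factors
    Tm <- fit$scores
    lev <- 1 / n + rowSums(sweep(Tm^2, 2, colSums(Tm^2), `/`))
    res <- y[keep] - predict(fit, X[keep, , drop = FALSE])
    dfree <- max(n - k - 1, 1)
    s <- sqrt(sum(res^2) / dfree)
    stud <- if (s > 0) res / (s * sqrt(pmax(1 - lev, 1e-8))) else res * 0
    bad <- lev > leverage_mult * (k + 1) / n | abs(stud) > residual_z
    if (!any(bad)) break
    keep <- keep[!bad]
  }
  removed <- setdiff(seq_len(nrow(X)), keep)
  structure(list(retained = keep, removed = removed,
                 flagged = length(removed) > 0.1 * nrow(X)),
            class = "outlier_removal")
}

#' Evaluate a calibrated PLS model
#'
#' Computes the full metric suite: RMSEC / RMSECV / RMSEP in property units,
#' R2 of calibration / cross-validation / external validation as squared
#' Pearson correlation between predicted and reference values, the ratio of
#' performance to deviation `RPD = sd(y_val) / RMSEP`, and the range error
#' ratio `RER = range(y) / RMSEP`. RER's range is taken over the full sample
#' set's reference values (calibration plus validation) unless `y_range` is
#' supplied. A perfect prediction (RMSEP = 0) yields infinite RPD/RER, flagged
#' via `degenerate = TRUE`.
#'
#' @param model a fitted `pls_model`.
#' @param X_cal,y_cal calibration data the model was fitted on.
#' @param X_val,y_val external validation data.
#' @param cv a `loo_cv` object (or a list with `rmsecv` and optionally `r2cv`)
#'   computed on the calibration data; may be `NULL` if no CV was run.
#' @param n_factors factor count at which to evaluate (default: model's).
#' @param y_range optional explicit reference range (length-2 numeric) for RER.
#' @return A list of class `evaluation_metrics` with fields `rmsec`, `rmsecv`,
#'   `rmsep`, `r2c`, `r2cv`, `r2v`, `rpd`, `rer`, `n_factors`, `n_cal`,
#'   `n_val`, `degenerate`.
#' @export
evaluate_model <- function(model, X_cal, y_cal, X_val, y_val, cv = NULL,
                           n_factors = NULL, y_range = NULL) {
  if (is.null(n_factors)) n_factors <- model$n_factors
  if (length(y_val) < 2) stop("external validation needs at least 2 samples")
  pred_cal <- predict(model, X_cal, n_factors)
  pred_val <- predict(model, X_val, n_factors)
  rmsec <- sqrt(mean((pred_cal - y_cal)^2))
  rmsep <- sqrt(mean((pred_val - y_val)^2))
  r2 <- function(a, b) if (stats::sd(a) == 0 || stats::sd(b) == 0) 0
                       else stats::cor(a, b)^2
  r2c <- r2(pred_cal, y_cal)
  r2v <- r2(pred_val, y_val)
  rmsecv <- r2cv <- NA_real_
  if (!is.null(cv)) {
    kk <- min(n_factors, length(cv$rmsecv))
    rmsecv <- cv$rmsecv[kk]
    if (!is.null(cv$r2cv)) r2cv <- cv$r2cv[kk]
  }
  if (is.null(y_range)) y_range <- range(c(y_cal, y_val))
  degenerate <- rmsep == 0
  rpd <- if (degenerate) Inf else stats::sd(y_val) / rmsep
  rer <- if (degenerate) Inf else diff(range(y_range)) / rmsep
  structure(list(rmsec = rmsec, rmsecv = rmsecv, rmsep = rmsep,
                 r2c = r2c, r2cv = r2cv, r2v = r2v,
                 rpd = rpd, rer = rer,
                 n_factors = as.integer(n_factors),
                 n_cal = length(y_cal), n_val = length(y_val),
                 degenerate = degenerate),
            class = "evaluation_metrics")
}

#' @export
print.evaluation_metrics <- function(x, ...) {
  cat(sprintf(
    "evaluation_metrics: k=%d  RMSEC=%.4g RMSECV=%.4g RMSEP=%.4g\n",
    x$n_factors, x$rmsec, x$rmsecv, x$rmsep))
  cat(sprintf("  R2C=%.4f R2CV=%.4f R2V=%.4f  RPD=%.3g RER=%.3g  (n=%d/%d)\n",
              x$r2c, x$r2cv, x$r2v, x$rpd, x$rer, x$n_cal, x$n_val))
  invisible(x)
}
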