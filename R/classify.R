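#' Principal component analysis of a spectra matrix
#'
#' Centered PCA via singular value decomposition (no scaling; absorbance
#' variables share units).
#'
#' @param X numeric matrix (samples x variables) or a [spectra_set()].
#' @param n_pcs number of components to retain, at most `min(n - 1, p)`.
#' @return A list of class `pca_model` with `n_pcs`, `center`, `loadings`
#'   (p x n_pcs), `scores` (n x n_pcs), `explained` (variance fractions) and
#'   `cumulative` (cumulative variance fractions).
#' @export
fit_pca <- function(X, n_pcs) {
  if (inherits(X, "spectra_set")) X <- X$absorbance
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n_pcs < 1 || n_pcs > min(n - 1, p))
    stop("n_pcs must lie in [1, min(n - 1, p)] = [1, ", min(n - 1, p), "]")
  ctr <- colMeans(X)
  Xc <- X - rep(ctr, each = n)
  sv <- svd(Xc, nu = n_pcs, nv = n_pcs)
  expl <- sv$d^2 / sum(sv$d^2)
  structure(list(n_pcs = as.integer(n_pcs), center = ctr,
                 loadings = sv$v,
                 scores = sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs),
                 explained = expl[seq_len(n_pcs)],
                 cumulative = cumsum(expl)[seq_len(n_pcs)],
                 singular_values = sv$d),
            class = "pca_model")
}

#' Project new spectra onto a fitted PCA model
#'
#' @param object a `pca_model`.
#' @param newdata matrix or [spectra_set()] with the training variables.
#' @param ... ignored.
#' @return Score matrix (n x n_pcs).
#' @export
predict.pca_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_set")) newdata <- newdata$absorbance
  sweep(as.matrix(newdata), 2, object$center) %*% object$loadings
}

#' Mahalanobis-distance linear discriminant classification
#'
#' Computes each class center in score space and the pooled within-class
#' covariance (classic LDA), then assigns every query to the class with the
#' smaller Mahalanobis distance to its center. A singular pooled covariance is
#' ridge-regularized by `1e-8` times its mean diagonal and the result is
#' flagged.
#'
#' @param train_scores training score matrix (n x d).
#' @param train_labels class labels, length n, at least 2 samples per class.
#' @param query_scores score matrix of queries (defaults to the training
#'   scores, i.e. resubstitution).
#' @return A list of class `mahalanobis_classifier_result` with `labels`
#'   (assigned classes), `distances` (query x class Mahalanobis distances),
#'   `centers`, `pooled_cov` and `regularized`.
#' @export
mahalanobis_classify <- function(train_scores, train_labels,
                                 query_scores = train_scores) {
  train_scores <- as.matrix(train_scores)
  query_scores <- as.matrix(query_scores)
  train_labels <- as.character(train_labels)
  classes <- sort(unique(train_labels))
  if (length(classes) < 2)
    stop("classification requires at least two classes, got: ",
         paste(classes, collapse = ", "))
  tab <- table(train_labels)
  if (any(tab < 2)) stop("every class needs at least 2 training samples")
  d <- ncol(train_scores)
  centers <- t(matrix(vapply(classes, function(cl)
    colMeans(train_scores[train_labels == cl, , drop = FALSE]), numeric(d)),
    nrow = d))
  rownames(centers) <- classes
  # pooled within-class covariance, n - g denominator
  S <- matrix(0, d, d)
  for (cl in classes) {
    Z <- scale(train_scores[train_labels == cl, , drop = FALSE],
               scale = FALSE)
    S <- S + crossprod(Z)
  }
  S <- S / (nrow(train_scores) - length(classes))
  regularized <- FALSE
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv))) {
    S <- S + diag(1e-8 * mean(diag(S)) + 1e-300, d)
    Sinv <- solve(S)
    regularized <- TRUE
  }
  dist2 <- vapply(seq_len(nrow(centers)), function(i) {
    Z <- sweep(query_scores, 2, centers[i, ])
    rowSums((Z %*% Sinv) * Z)
  }, numeric(nrow(query_scores)))
  dist2 <- matrix(dist2, nrow = nrow(query_scores),
                  dimnames = list(NULL, classes))
  dist2[dist2 < 0] <- 0
  structure(list(labels = classes[max.col(-dist2, ties.method = "first")],
                 distances = sqrt(dist2),
                 centers = centers, pooled_cov = S,
                 regularized = regularized),
            class = "mahalanobis_classifier_result")
}

#' Correct classification rate
#'
#' @param truth true class labels.
#' @param predicted predicted class labels.
#' @return Percentage of matching labels, in `[0, 100]`.
#' @export
classification_rate <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  100 * mean(as.character(truth) == as.character(predicted))
}

#' Classification-rate curve over principal component counts
#'
#' For each component count from 1 to `max_pcs`, fits PCA plus the
#' Mahalanobis-distance discriminant on all samples and scores the
#' resubstitution correct-classification rate, alongside the cumulative
#' explained spectral variance. Set `loo = TRUE` for leave-one-out rates
#' instead of resubstitution (slower, but an honest error estimate).
#'
#' @param X spectra matrix or [spectra_set()] (normally preprocessed).
#' @param labels class labels, one per sample.
#' @param max_pcs largest component count to evaluate (capped at
#'   `min(n - 1, p)`).
#' @param loo logical; use leave-one-out instead of resubstitution.
#' @return A data frame with columns `n_pcs`, `rate` (percent) and
#'   `cumulative_variance` (percent).
#' @export
rate_curve <- function(X, labels, max_pcs = 40, loo = FALSE) {
  if (inherits(X, "spectra_set")) X <- X$absorbance
  X <- as.matrix(X)
  labels <- as.character(labels)
  n <- nrow(X)
  max_pcs <- min(max_pcs, n - 1, ncol(X))
  if (loo) {
    rate <- vapply(seq_len(max_pcs), function(k) {
      pred <- vapply(seq_len(n), function(i) {
        pca <- fit_pca(X[-i, , drop = FALSE], k)
        cls <- mahalanobis_classify(pca$scores, labels[-i],
                                    predict(pca, X[i, , drop = FALSE]))
        cls$labels
      }, character(1))
      classification_rate(labels, pred)
    }, numeric(1))
    pca_all <- fit_pca(X, max_pcs)
  } else {
    pca_all <- fit_pca(X, max_pcs)
    rate <- vapply(seq_len(max_pcs), function(k) {
      cls <- mahalanobis_classify(pca_all$scores[, seq_len(k), drop = FALSE],
                                  labels)
      classification_rate(labels, cls$labels)
    }, numeric(1))
  }
  data.frame(n_pcs = seq_len(max_pcs), rate = rate,
             cumulative_variance = 100 * pca_all$cumulative[seq_len(max_pcs)])
}
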