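#' Nearest affine PCA subspace classifier
#'
#' Fits one affine approximation space per class from training feature
#' vectors (typically scattering vectors \eqn{S_J f}): class `k` is
#' represented by \eqn{A_{d,k} = \bar x_k + V_{d,k}}, where \eqn{\bar x_k}
#' estimates the expected feature vector and \eqn{V_{d,k}} is spanned by the
#' top `d` eigenvectors of the class sample covariance. A new vector is
#' assigned to the class whose affine space it is nearest to in Euclidean
#' projection residual,
#' \eqn{k(f) = \arg\min_k \|S_J f - P_{A_{d,k}}(S_J f)\|_2}.
#'
#' The per-class eigenbasis is computed by singular value decomposition of
#' the centered class rows (never by forming the \eqn{N_J \times N_J}
#' covariance), with divisor \eqn{n_k - 1} implicit: only the eigenvector
#' directions matter. The effective rank is
#' \eqn{d_k = \min(d, n_k - 1, N_J)}, further truncated at the numerical
#' rank, so a class whose training vectors are all identical degenerates
#' gracefully to distance-to-mean classification. Eigenvector signs are
#' fixed deterministically (largest-magnitude entry made positive), so
#' identical inputs give bit-identical models.
#'
#' @param x numeric matrix, `n` rows of feature vectors.
#' @param y class labels, length `n`; classes are ordered by `sort()` of
#'   their unique values and ties in prediction go to the first class in
#'   that order.
#' @param d target subspace rank per class (default 30).
#' @return An object of class `"affine_pca"`: list with `classes`, `means`
#'   (one column per class), `bases` (list of orthonormal `N_J x d_k`
#'   matrices), `d`, `d_k`, `n_k`, `n_features`, `singular_values`.
#' @seealso [predict.affine_pca()], [residual_to_class()]
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, mean = 4), 20))
#' fit <- affine_pca(x, rep(c("a", "b"), each = 20), d = 2)
#' predict(fit, x)$labels
#' @export
affine_pca <- function(x, y, d = 30) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (any(!is.finite(x))) stop("feature matrix contains non-finite values")
  y <- as.character(y)
  if (length(y) != nrow(x)) stop("length(y) must match nrow(x)")
  if (d < 1) stop("'d' must be >= 1")
  classes <- sort(unique(y))
  counts <- table(factor(y, classes))
  if (any(counts == 0))
    stop(sprintf("class '%s' has no training samples",
                 names(counts)[which(counts == 0)[1]]))
  p <- ncol(x)
  means <- matrix(0, p, length(classes), dimnames = list(NULL, classes))
  bases <- vector("list", length(classes))
  svals <- vector("list", length(classes))
  d_k <- integer(length(classes))
  for (k in seq_along(classes)) {
    xk <- x[y == classes[k], , drop = FALSE]
    n_k <- nrow(xk)
    mu <- colMeans(xk)
    means[, k] <- mu
    ctr <- sweep(xk, 2, mu)
    dk_cap <- min(d, n_k - 1L, p)
    if (dk_cap < 1L) {
      bases[[k]] <- matrix(0, p, 0)
      svals[[k]] <- numeric(0)
      d_k[k] <- 0L
      next
    }
    sv <- svd(ctr, nu = 0, nv = dk_cap)
    rank <- sum(sv$d > max(sv$d[1], 0) * 1e-10)
    dk <- as.integer(min(dk_cap, rank))
    basis <- sv$v[, seq_len(dk), drop = FALSE]
    if (dk > 0) {
      for (col in seq_len(dk)) {
        i_max <- which.max(abs(basis[, col]))
        if (basis[i_max, col] < 0) basis[, col] <- -basis[, col]
      }
    }
    bases[[k]] <- basis
    svals[[k]] <- sv$d[seq_len(dk)]
    d_k[k] <- dk
  }
  structure(
    list(classes = classes, means = means, bases = bases, d = d, d_k = d_k,
         n_k = as.integer(counts), n_features = p,
         singular_values = svals),
    class = "affine_pca"
  )
}

residual_matrix <- function(object, x) {
  if (ncol(x) != object$n_features)
    stop(sprintf("feature vectors have length %d but the model expects %d",
                 ncol(x), object$n_features))
  if (any(!is.finite(x))) stop("feature matrix contains non-finite values")
  K <- length(object$classes)
  R <- matrix(0, nrow(x), K, dimnames = list(NULL, object$classes))
  for (k in seq_len(K)) {
    W <- sweep(x, 2, object$means[, k])
    if (object$d_k[k] > 0) {
      B <- object$bases[[k]]
      W <- W - (W %*% B) %*% t(B)  # orthogonal complement, no cancellation
    }
    R[, k] <- sqrt(rowSums(W^2))
  }
  R
}

#' Distance from a feature vector to one class's affine space
#'
#' Euclidean norm of the component of `v - mean_k` orthogonal to the span
#' of the class basis: the projection residual the classifier minimizes.
#'
#' @param object a fitted [affine_pca()] model.
#' @param v numeric feature vector of length `n_features`.
#' @param k class label or index.
#' @return Nonnegative scalar.
#' @export
residual_to_class <- function(object, v, k) {
  if (is.character(k)) k <- match(k, object$classes)
  if (is.na(k) || k < 1 || k > length(object$classes)) stop("unknown class")
  if (length(v) != object$n_features)
    stop(sprintf("feature vector has length %d but the model expects %d",
                 length(v), object$n_features))
  unname(residual_matrix(object, matrix(v, 1))[1, k])
}

#' Predict classes by minimal projection residual
#'
#' @param object a fitted [affine_pca()] model.
#' @param newdata feature matrix (rows = samples) or a single vector.
#' @param ... unused.
#' @return A list with `labels` (assigned classes; ties broken by the
#'   smallest class index), `scores` (`n x K` matrix of negated residuals,
#'   usable as ranking scores for AUC), and `residuals` (`n x K`).
#' @export
predict.affine_pca <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, 1)
  R <- residual_matrix(object, as.matrix(newdata))
  idx <- max.col(-R, ties.method = "first")
  list(labels = object$classes[idx], scores = -R, residuals = R)
}

#' @export
print.affine_pca <- function(x, ...) {
  cat(sprintf(
    "Affine PCA subspace classifier: %d classes, %d features, target rank d = %d\n",
    length(x$classes), x$n_features, x$d))
  cat(paste0(sprintf("  %s: n = %d, d_k = %d", x$classes, x$n_k, x$d_k),
             collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.affine_pca <- function(object, ...) {
  df <- data.frame(
    class = object$classes,
    n = object$n_k,
    d_k = object$d_k,
    top_singular_value = vapply(object$singular_values,
                                function(s) if (length(s)) s[1] else 0,
                                numeric(1))
  )
  structure(list(table = df, d = object$d, n_features = object$n_features),
            class = "summary.affine_pca")
}

#' @export
print.summary.affine_pca <- function(x, ...) {
  cat(sprintf("Affine PCA classifier (d = %d, %d features)\n", x$d, x$n_features))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.affine_pca <- function(object, ...) object$means
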