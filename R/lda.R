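#' Shared-covariance linear discriminant classifier
#'
#' Fits a Gaussian discriminant with one mean per class, a covariance
#' matrix shared across classes (the linear case) and empirical class
#' priors, on one flattened feature vector per trial.  The pooled
#' within-class covariance is shrunk towards its diagonal,
#' `(1 - lambda) * S + lambda * diag(S)`, which keeps the fit
#' well-conditioned when flattened sliding-window vectors are long relative
#' to the trial count.
#'
#' The discriminant for class k is
#' `delta_k(x) = -log|Sigma|/2 - (x - mu_k)' Sigma^{-1} (x - mu_k)/2 +
#' log pi_k`; with a shared Sigma the pairwise decision boundaries are
#' linear in x.  `predict` returns the argmax class, breaking exact ties
#' towards the lexicographically first label.
#'
#' @param x numeric matrix, one row per trial.
#' @param labels class label per row (2 or more distinct values, each with
#'   at least 2 trials).
#' @param lambda shrinkage strength in `[0, 1]`.
#' @return an object of class `"mi_lda"` with elements `means` (classes x
#'   features), `cov`, `priors`, `lambda`, `classes`, and internals for
#'   stable evaluation.
#' @examples
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 3), 20))
#' fit <- mi_lda(x, rep(c("left", "right"), each = 20), lambda = 1e-3)
#' predict(fit, x[1, , drop = FALSE])
#' @export
mi_lda <- function(x, labels, lambda = 1e-3) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (lambda < 0 || lambda > 1) stop_config("lambda must be in [0, 1]")
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop_config("need at least 2 classes, got: ",
                paste(classes, collapse = ", "))
  counts <- table(factor(labels, classes))
  if (any(counts < 2L))
    stop_config("each class needs >= 2 trials; counts: ",
                paste(sprintf("%s=%d", names(counts), counts),
                      collapse = ", "))
  p <- ncol(x)
  means <- do.call(rbind, lapply(classes, function(k)
    colMeans(x[labels == k, , drop = FALSE])))
  rownames(means) <- classes
  centered <- x - means[match(labels, classes), , drop = FALSE]
  pooled <- crossprod(centered) / (nrow(x) - length(classes))
  # floor zero-variance diagonal entries so shrinkage can regularize even a
  # fully degenerate (zero) pooled covariance
  dg <- diag(pooled)
  dg <- pmax(dg, 1e-8 * max(dg, 1))
  sigma <- (1 - lambda) * pooled + lambda * diag(dg, p)
  # symmetrize against round-off, then factor once for all evaluations
  sigma <- (sigma + t(sigma)) / 2
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch))
    stop_config("covariance is singular; increase the shrinkage lambda")
  structure(list(means = means, cov = sigma, chol = ch,
                 logdet = 2 * sum(log(diag(ch))),
                 priors = as.numeric(counts) / nrow(x),
                 classes = classes, lambda = lambda, p = p),
            class = "mi_lda")
}

#' Gaussian discriminant scores
#'
#' Evaluates `delta_k(x)` for every class via the Cholesky factor of the
#' shared covariance (no explicit inverse is formed).
#'
#' @param object a fitted `mi_lda`.
#' @param x numeric vector or matrix of rows to score.
#' @return matrix of scores, rows matching `x`, columns the classes.
#' @export
discriminant <- function(object, x) {
  stopifnot(inherits(object, "mi_lda"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != object$p)
    stop_config("x has ", ncol(x), " features; model expects ", object$p)
  out <- matrix(NA_real_, nrow(x), length(object$classes),
                dimnames = list(NULL, object$classes))
  for (k in seq_along(object$classes)) {
    d <- sweep(x, 2L, object$means[k, ], `-`)
    # Mahalanobis term via triangular solve: z = L^-T d  =>  d' Sigma^-1 d
    z <- backsolve(object$chol, t(d), transpose = TRUE)
    out[, k] <- -0.5 * object$logdet - 0.5 * colSums(z^2) +
      log(object$priors[k])
  }
  out
}

#' @export
predict.mi_lda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  sc <- discriminant(object, newdata)
  if (type == "score") return(sc)
  # argmax with deterministic first-label tie-break (classes are sorted)
  object$classes[apply(sc, 1L, which.max)]
}

#' @export
coef.mi_lda <- function(object, ...) {
  list(means = object$means, cov = object$cov, priors = object$priors,
       lambda = object$lambda)
}

#' @export
print.mi_lda <- function(x, ...) {
  cat(sprintf("<mi_lda> %d classes (%s), %d features, lambda = %g\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              x$p, x$lambda))
  cat("priors:", paste(sprintf("%s=%.3f", x$classes, x$priors),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mi_lda <- function(object, ...) {
  cat(sprintf("Shared-covariance linear discriminant (%d features)\n",
              object$p))
  print(object)
  cat(sprintf("log|Sigma| = %.4f, condition number (Cholesky-based) = %.3g\n",
              object$logdet,
              (max(diag(object$chol)) / min(diag(object$chol)))^2))
  invisible(object)
}

#' Serialize a fitted discriminant to plain text
#'
#' Writes (and reads back) the class means, shared covariance, priors and
#' shrinkage strength as JSON for audit.
#'
#' @param object a fitted `mi_lda`.
#' @param path file path.
#' @export
write_mi_lda <- function(object, path) {
  jsonlite::write_json(list(classes = object$classes,
                            means = object$means, cov = object$cov,
                            priors = object$priors,
                            lambda = object$lambda),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_mi_lda
#' @export
read_mi_lda <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- as.matrix(j$means); rownames(m) <- j$classes
  fitlike <- list(means = m, cov = as.matrix(j$cov),
                  chol = chol(as.matrix(j$cov)),
                  priors = j$priors, classes = j$classes,
                  lambda = j$lambda, p = ncol(m))
  fitlike$logdet <- 2 * sum(log(diag(fitlike$chol)))
  structure(fitlike, class = "mi_lda")
}
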