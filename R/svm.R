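#' Fit an RBF-kernel support vector machine
#'
#' Solves the soft-margin C-SVC dual by sequential minimal optimisation
#' (maximal-violating-pair working sets), equivalent to the standard
#' primal: minimise 0.5 ||w||^2 + C * sum(xi_i) subject to
#' y_i (w . phi(x_i) + b) >= 1 - xi_i with the Gaussian kernel
#' K(u, v) = exp(-gamma ||u - v||^2).
#'
#' Inputs are used as given; scale features beforehand (the
#' cross-validation and final-training wrappers scale to [-1, 1] from
#' training ranges).
#'
#' @param x Numeric matrix (samples x features).
#' @param y Labels in {-1, +1}.
#' @param C Soft-margin penalty (> 0).
#' @param gamma RBF kernel width (> 0).
#' @param eps KKT violation tolerance for convergence (default 1e-3).
#' @param max_iter Iteration cap.
#' @param d2 Optional precomputed squared-distance matrix `sqdist(x, x)`.
#' @return An object of class `rbf_svm` holding the support vectors, dual
#'   coefficients (`alpha_i * y_i`), bias and kernel parameter.
#' @export
svm_fit <- function(x, y, C = 1, gamma = 1 / ncol(x), eps = 1e-3,
                    max_iter = 100000L, d2 = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be -1/+1")
  if (length(unique(y)) < 2L) stop("labels are degenerate (single class)")
  if (is.null(d2)) d2 <- sqdist_cpp(x, x)
  fit <- smo_train_cpp(d2, y, C, gamma, eps, as.integer(max_iter))
  sv <- fit$alpha > 0
  structure(
    list(sv_x = x[sv, , drop = FALSE],
         coef = fit$alpha[sv] * y[sv],
         b = fit$b, gamma = gamma, C = C,
         iterations = fit$iterations),
    class = "rbf_svm"
  )
}

#' Decision values of a fitted RBF SVM
#'
#' `f(x) = sum_i coef_i K(sv_i, x) + b`; the predicted label is the sign
#' (ties at exactly 0 go to +1).
#'
#' @param model An `rbf_svm`.
#' @param newx Numeric matrix on the same feature scale as training.
#' @return Numeric vector of decision values.
#' @export
svm_decision <- function(model, newx) {
  stopifnot(inherits(model, "rbf_svm"))
  newx <- as.matrix(newx)
  if (nrow(newx) == 0L) return(numeric(0))
  if (nrow(model$sv_x) == 0L) return(rep(model$b, nrow(newx)))
  K <- exp(-model$gamma * sqdist_cpp(newx, model$sv_x))
  drop(K %*% model$coef) + model$b
}

#' @export
print.rbf_svm <- function(x, ...) {
  cat(sprintf("rbf_svm: C = %g, gamma = %g, %d support vectors\n",
              x$C, x$gamma, nrow(x$sv_x)))
  invisible(x)
}

# [-1, 1] range scaling learned from training data; constant features -> 0
.scale_fit <- function(x) {
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  list(center = (lo + hi) / 2, half = (hi - lo) / 2)
}

.scale_apply <- function(x, sc) {
  half <- ifelse(sc$half == 0, 1, sc$half)
  out <- sweep(sweep(x, 2L, sc$center, "-"), 2L, half, "/")
  out[, sc$half == 0] <- 0
  out
}
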