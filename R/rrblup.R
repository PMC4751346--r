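#' Ridge-regression BLUP of marker effects
#'
#' Fits the genomic mixed model `y = 1 mu + Z u + e` with
#' `u ~ N(0, I sigma_u^2)` and `e ~ N(0, I sigma_e^2)`, the marker-effect
#' parameterization of GBLUP.  Variance components are estimated by
#' restricted maximum likelihood, profiled to a one-dimensional problem in
#' the ridge penalty `lambda = sigma_e^2 / sigma_u^2` via the spectral
#' decomposition of the genomic cross-product `Z Z'` projected off the
#' intercept; the REML criterion is maximized over `log(lambda)` on a fixed
#' interval.  The intercept is the generalized-least-squares estimate and
#' marker effects come from the dual (n x n) form
#' `u = Z' (Z Z' + lambda I)^{-1} (y - 1 mu)`.
#'
#' @param genotypes [genotype_matrix()] or plain numeric matrix (n x M) of
#'   imputed additive codes; column names identify markers.
#' @param y numeric response of length n (>= 3), typically standardized
#'   half-sib family means.
#' @param lambda optional fixed ridge penalty: `NULL` (default) estimates it
#'   by REML; a positive number skips REML; `Inf` gives the
#'   infinite-penalty limit (all effects zero, predictions at the training
#'   mean).
#' @param interval search interval for `log(lambda)` (natural log).
#' @param tol convergence tolerance of the one-dimensional optimization.
#' @return An object of class `rrblup`: list with `mu`, `u` (named marker
#'   effects), `sigma_u2`, `sigma_e2`, `lambda`, `logLik` (restricted),
#'   `fitted`, `y`, `markers`, `n`, `call`.
#' @examples
#' z <- matrix(sample(c(-1, 0, 1), 200, TRUE), 20, 10,
#'             dimnames = list(NULL, paste0("m", 1:10)))
#' y <- 2 + z %*% rnorm(10) + rnorm(20, sd = 0.5)
#' fit <- rrblup(z, y)
#' head(coef(fit))
#' @seealso [predict.rrblup()]
#' @export
rrblup <- function(genotypes, y, lambda = NULL, interval = c(-10, 10),
                   tol = 1e-6) {
  Z <- unclass(as.matrix(genotypes))
  storage.mode(Z) <- "double"
  y <- as.numeric(y)
  n <- nrow(Z)
  if (length(y) != n) stop("length(y) must equal nrow(genotypes)")
  if (n < 3L) stop("need at least 3 training individuals")
  if (anyNA(Z) || any(!is.finite(Z)))
    stop("genotypes must be finite and non-missing (impute first)")
  if (any(!is.finite(y))) stop("y must be finite")
  if (stats::var(y) == 0)
    stop("constant response: variance components are degenerate")
  cl <- match.call()
  markers <- colnames(Z)
  if (is.null(markers)) markers <- sprintf("m%d", seq_len(ncol(Z)))

  if (!is.null(lambda) && is.infinite(lambda)) {
    mu <- mean(y)
    u <- stats::setNames(rep(0, ncol(Z)), markers)
    return(structure(list(mu = mu, u = u, sigma_u2 = 0,
                          sigma_e2 = stats::var(y), lambda = Inf,
                          logLik = NA_real_, fitted = rep(mu, n), y = y,
                          markers = markers, n = n, call = cl),
                     class = "rrblup"))
  }

  K <- tcrossprod(Z)
  logLik <- NA_real_
  if (is.null(lambda)) {
    # REML profiled over lambda: project off the intercept, decompose once
    S <- diag(n) - matrix(1 / n, n, n)
    es <- eigen(S %*% K %*% S, symmetric = TRUE)
    xi <- es$values[seq_len(n - 1L)]        # last eigenvalue ~ 0 (intercept)
    xi[xi < 0] <- 0
    eta <- crossprod(es$vectors[, seq_len(n - 1L), drop = FALSE], y)[, 1L]
    df <- n - 1L
    reml_ll <- function(loglam) {
      lam <- exp(loglam)
      q <- sum(eta^2 / (xi + lam))
      0.5 * (df * (log(df / (2 * pi)) - 1 - log(q)) - sum(log(xi + lam)))
    }
    opt <- stats::optimize(reml_ll, interval = interval, maximum = TRUE,
                           tol = tol)
    lambda <- exp(opt$maximum)
    logLik <- opt$objective
    sigma_u2 <- sum(eta^2 / (xi + lambda)) / df
    sigma_e2 <- lambda * sigma_u2
  } else {
    if (lambda <= 0) stop("lambda must be > 0")
    sigma_u2 <- NA_real_
    sigma_e2 <- NA_real_
  }
  H <- K + diag(lambda, n)
  Hi_y <- solve(H, y)
  Hi_1 <- solve(H, rep(1, n))
  mu <- sum(Hi_y) / sum(Hi_1)
  u <- crossprod(Z, solve(H, y - mu))[, 1L]
  names(u) <- markers
  fitted <- as.numeric(mu + Z %*% u)
  structure(list(mu = mu, u = u, sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                 lambda = lambda, logLik = logLik, fitted = fitted, y = y,
                 markers = markers, n = n, call = cl),
            class = "rrblup")
}

#' Predict genomically estimated breeding values
#'
#' `GEBV = mu + Z_test u`.  Test markers must match the training markers;
#' identical sets in a different order are realigned, any other mismatch is
#' an error naming the offending markers.
#'
#' @param object an [rrblup()] fit.
#' @param newdata [genotype_matrix()] or matrix of test genotypes.
#' @param ... unused.
#' @return Named numeric vector of GEBVs.
#' @export
predict.rrblup <- function(object, newdata, ...) {
  Z <- unclass(as.matrix(newdata))
  Z <- align_markers(Z, object$markers)
  as.numeric(object$mu + Z %*% object$u)
}

align_markers <- function(Z, markers) {
  if (is.null(colnames(Z))) {
    if (ncol(Z) != length(markers))
      stop("test matrix has ", ncol(Z), " markers; model was trained on ",
           length(markers))
    return(Z)
  }
  missing <- setdiff(markers, colnames(Z))
  extra <- setdiff(colnames(Z), markers)
  if (length(missing) || length(extra))
    stop("marker mismatch between training and test genotypes",
         if (length(missing)) paste0("; absent from test: ",
           paste(utils::head(missing, 5L), collapse = ", "),
           if (length(missing) > 5L) ", ..."),
         if (length(extra)) paste0("; unknown to model: ",
           paste(utils::head(extra, 5L), collapse = ", "),
           if (length(extra) > 5L) ", ..."))
  Z[, markers, drop = FALSE]
}

#' @export
print.rrblup <- function(x, ...) {
  cat("Ridge-regression BLUP (marker-effect GBLUP)\n")
  cat(sprintf("  n = %d, markers = %d\n", x$n, length(x$u)))
  cat(sprintf("  mu = %.4g, lambda = %.4g, sigma_u2 = %.4g, sigma_e2 = %.4g\n",
              x$mu, x$lambda, x$sigma_u2, x$sigma_e2))
  invisible(x)
}

#' @export
summary.rrblup <- function(object, ...) {
  out <- list(call = object$call, n = object$n, n_markers = length(object$u),
              mu = object$mu, lambda = object$lambda,
              sigma_u2 = object$sigma_u2, sigma_e2 = object$sigma_e2,
              logLik = object$logLik,
              effect_range = range(object$u),
              train_cor = stats::cor(object$fitted, object$y))
  class(out) <- "summary.rrblup"
  out
}

#' @export
print.summary.rrblup <- function(x, ...) {
  cat("Ridge-regression BLUP fit\n\nCall: ")
  print(x$call)
  cat(sprintf("\nn = %d, markers = %d\n", x$n, x$n_markers))
  cat(sprintf("mu = %.4g  lambda = %.4g  sigma_u2 = %.4g  sigma_e2 = %.4g\n",
              x$mu, x$lambda, x$sigma_u2, x$sigma_e2))
  if (!is.na(x$logLik)) cat(sprintf("restricted logLik = %.3f\n", x$logLik))
  cat(sprintf("marker effects in [%.4g, %.4g]; training-set correlation %.3f\n",
              x$effect_range[1L], x$effect_range[2L], x$train_cor))
  invisible(x)
}

#' @export
coef.rrblup <- function(object, ...) {
  c("(Intercept)" = object$mu, object$u)
}

#' @export
fitted.rrblup <- function(object, ...) object$fitted

#' @export
residuals.rrblup <- function(object, ...) object$y - object$fitted
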