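#' Stratum normalization statistics
#'
#' Fits the per-stratum reference moments used by both population-level and
#' baseline-deviation analyses: per-parameter mean and standard deviation
#' over a collection of complete 5-parameter vectors, and the covariance
#' matrix of the z-scored vectors. If the covariance is not positive
#' definite, a ridge of `ridge * trace/5` is added to the diagonal.
#'
#' @param x numeric matrix of complete parameter vectors (one per row,
#'   5 columns in canonical order `hr, rr_trend, spo2, rso2, ibp_mean`).
#' @param stratum `"LOW_SAT"` or `"HIGH_SAT"` tag carried for bookkeeping.
#' @param ridge ridge fraction (default 1e-6).
#' @param min_vectors minimum number of vectors required (default 100).
#' @return An object of class `stratum_statistics` with elements `stratum`,
#'   `mean`, `sd`, `covariance`, `n`.
#' @export
fit_stratum_statistics <- function(x, stratum = "LOW_SAT", ridge = 1e-6,
                                   min_vectors = 100L) {
  x <- as.matrix(x)
  if (ncol(x) != 5L) stop("expected 5 parameter columns")
  if (anyNA(x)) stop("vectors must be complete (no missing values)")
  if (nrow(x) < min_vectors)
    stop("insufficient data: need at least ", min_vectors, " complete vectors")
  mu <- colMeans(x)
  s <- apply(x, 2L, sd)
  if (any(s == 0)) stop("zero-variance parameter: cannot normalize")
  z <- sweep(sweep(x, 2L, mu), 2L, s, "/")
  sigma <- cov(z)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    sigma <- sigma + diag(ridge * sum(diag(sigma)) / 5, 5L)
  colnames(sigma) <- rownames(sigma) <- PARAMS
  names(mu) <- names(s) <- PARAMS
  structure(list(stratum = stratum, mean = mu, sd = s, covariance = sigma,
                 n = nrow(x)),
            class = "stratum_statistics")
}

#' @export
print.stratum_statistics <- function(x, ...) {
  cat(sprintf("<stratum_statistics> %s, fitted on %d vectors\n", x$stratum, x$n))
  print(round(rbind(mean = x$mean, sd = x$sd), 2))
  invisible(x)
}

#' Normalize parameter vectors against stratum statistics
#'
#' Elementwise z-scoring `(value - mean) / sd` with the stratum reference
#' moments.
#'
#' @param x a complete 5-vector or a matrix of complete vectors (rows).
#' @param stats a [fit_stratum_statistics()] object.
#' @return z-scored vector or matrix of the same shape.
#' @export
normalize_vectors <- function(x, stats) {
  stopifnot(inherits(stats, "stratum_statistics"))
  if (is.null(dim(x))) {
    if (length(x) != 5L) stop("expected a 5-vector")
    if (anyNA(x)) stop("vector must be complete")
    return((x - stats$mean) / stats$sd)
  }
  if (ncol(x) != 5L) stop("expected 5 parameter columns")
  sweep(sweep(x, 2L, stats$mean), 2L, stats$sd, "/")
}

#' Mahalanobis distance of z-scored vectors
#'
#' Reduces a (z-scored) parameter vector to a single scalar,
#' `sqrt(z' Sigma^-1 z)`, the covariance-aware distance from the stratum
#' centre. Computed through the Cholesky factor of the covariance.
#'
#' @param z a 5-vector of z-scores or a matrix of them (rows). Rows with
#'   missing values yield `NA`.
#' @param covariance 5x5 positive-definite covariance matrix.
#' @return nonnegative numeric vector of distances.
#' @export
mahalanobis_distance <- function(z, covariance) {
  R <- tryCatch(chol(covariance),
                error = function(e) stop("covariance is not positive definite"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  out <- rep(NA_real_, nrow(z))
  ok <- !apply(z, 1L, anyNA)
  if (any(ok)) {
    y <- backsolve(R, t(z[ok, , drop = FALSE]), transpose = TRUE)
    out[ok] <- sqrt(colSums(y * y))
  }
  out
}
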