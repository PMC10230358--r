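#' One-class SVM configuration
#'
#' @param nu soft margin of the one-class SVM (default 0.05, i.e. 5%): an
#'   upper bound on the fraction of training vectors allowed outside the
#'   learned frontier, preventing overfitting to the presumed-stable set.
#' @param gamma RBF kernel scale, or `"auto"` for
#'   `1 / (5 * mean per-axis variance of the training z-scores)`.
#' @param train_fraction fraction of retained vectors used for training, the
#'   remainder held out for a sanity-check inlier rate (default 0.8).
#' @param prefilter_percentile Mahalanobis-distance percentile above which
#'   candidate training vectors are deemed unstable and discarded
#'   (default 80).
#' @param seed integer seed for the train/test split.
#' @return A classed list.
#' @export
svm_config <- function(nu = 0.05, gamma = "auto", train_fraction = 0.8,
                       prefilter_percentile = 80, seed = 1L) {
  stopifnot(nu > 0, nu < 1, train_fraction > 0, train_fraction < 1,
            prefilter_percentile > 0, prefilter_percentile <= 100)
  structure(list(nu = nu, gamma = gamma, train_fraction = train_fraction,
                 prefilter_percentile = prefilter_percentile,
                 seed = as.integer(seed)),
            class = "svm_config")
}

#' Static clinical cutoffs
#'
#' Per-parameter clinical limits applied to raw parameter values alongside
#' the SVM: a vector is unstable when any configured limit is crossed. The
#' shipped defaults (HR outside 60-230 beats/min, smoothed RR above
#' 90 breaths/min, mean IBP outside 20-90 mm Hg) are package defaults chosen
#' for clinical plausibility in neonates; any or all limits may be
#' overridden or dropped.
#'
#' @param hr,rr,ibp length-2 numeric `c(lower, upper)`; use `NA` for an
#'   unused bound, or `NULL` to drop the parameter entirely.
#' @return A classed list of limits.
#' @export
static_cutoffs <- function(hr = c(60, 230), rr = c(NA, 90), ibp = c(20, 90)) {
  lim <- list(hr = hr, rr = rr, ibp = ibp)
  lim <- lim[!vapply(lim, is.null, logical(1))]
  for (nm in names(lim)) {
    v <- lim[[nm]]
    if (length(v) != 2L) stop("cutoff for ", nm, " must be c(lower, upper)")
    if (!anyNA(v) && v[1L] >= v[2L]) stop("cutoff lower must be < upper for ", nm)
  }
  structure(lim, class = "static_cutoffs")
}

#' Check a parameter vector against static cutoffs
#'
#' @param v complete 5-vector (canonical order) or matrix of vectors.
#' @param cutoffs a [static_cutoffs()] object.
#' @return logical: `TRUE` where any configured limit is crossed.
#' @export
static_cutoff_check <- function(v, cutoffs) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L, dimnames = list(NULL, PARAMS))
  colnames(v) <- PARAMS
  viol <- rep(FALSE, nrow(v))
  map <- c(hr = "hr", rr = "rr_trend", ibp = "ibp_mean")
  for (nm in names(cutoffs)) {
    x <- v[, map[[nm]]]
    lim <- cutoffs[[nm]]
    if (!is.na(lim[1L])) viol <- viol | (!is.na(x) & x < lim[1L])
    if (!is.na(lim[2L])) viol <- viol | (!is.na(x) & x > lim[2L])
  }
  viol
}

#' Percentile prefilter on Mahalanobis distances
#'
#' Retains the indices of vectors whose distance does not exceed the
#' linearly interpolated `percentile`-th percentile; ties at the threshold
#' are retained (discarding is the exception). Vectors above the threshold
#' are deemed unstable and excluded from SVM training.
#'
#' @param distances numeric vector (length >= 5).
#' @param percentile percentile kept (default 80).
#' @return integer vector of retained indices.
#' @export
percentile_prefilter <- function(distances, percentile = 80) {
  if (length(distances) < 5L) stop("need at least 5 distances")
  thr <- quantile(distances, percentile / 100, type = 7, names = FALSE)
  which(distances <= thr)
}

# RBF one-class decision values from stored SVM parameters:
# f(z) = sum_i alpha_i * exp(-gamma ||sv_i - z||^2) - rho; inlier iff f > 0.
rbf_decision <- function(z, sv, coefs, rho, gamma) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  zz <- rowSums(z * z)
  ss <- rowSums(sv * sv)
  d2 <- outer(zz, ss, "+") - 2 * tcrossprod(z, sv)
  d2[d2 < 0] <- 0
  drop(exp(-gamma * d2) %*% coefs) - rho
}

#' Fit the population-level stability model of one stratum
#'
#' The population-level analysis learns what parameter combinations look
#' like during presumed-stable time in a stratum, then flags nonresemblant
#' combinations as unstable. Fitting proceeds: z-score the complete
#' parameter vectors against the stratum moments; reduce each to its
#' Mahalanobis distance; discard vectors above the `prefilter_percentile`th
#' distance percentile (presumed unstable); split the remainder at random
#' `train_fraction`:rest; fit a one-class SVM with a square-exponential
#' (RBF) kernel and soft margin `nu` on the training part. The held-out
#' part only logs a sanity-check inlier rate and is never used for tuning.
#'
#' @param x numeric matrix of complete parameter vectors (rows; canonical
#'   column order `hr, rr_trend, spo2, rso2, ibp_mean`).
#' @param stratum `"LOW_SAT"` or `"HIGH_SAT"`.
#' @param cutoffs a [static_cutoffs()] object.
#' @param config an [svm_config()].
#' @param stats optional precomputed [fit_stratum_statistics()]; fitted from
#'   `x` when `NULL`.
#' @param ridge ridge fraction for the covariance (default 1e-6).
#' @param min_vectors minimum number of vectors surviving the prefilter
#'   (default 500).
#' @param max_train cap on the number of vectors handed to the SVM solver;
#'   a seeded subsample of the training partition is used beyond it
#'   (default 10000, keeping the quadratic-cost fit tractable on pooled
#'   cohorts).
#' @return An object of class `stratum_model`.
#' @export
fit_stratum_model <- function(x, stratum = "LOW_SAT",
                              cutoffs = static_cutoffs(),
                              config = svm_config(), stats = NULL,
                              ridge = 1e-6, min_vectors = 500L,
                              max_train = 10000L) {
  x <- as.matrix(x)
  if (is.null(stats))
    stats <- fit_stratum_statistics(x, stratum = stratum, ridge = ridge)
  z <- normalize_vectors(x, stats)
  d <- mahalanobis_distance(z, stats$covariance)
  keep <- percentile_prefilter(d, config$prefilter_percentile)
  if (length(keep) < min_vectors)
    stop("insufficient data: only ", length(keep),
         " vectors survive the prefilter (need ", min_vectors, ")")
  zk <- z[keep, , drop = FALSE]
  # seeded split without disturbing the caller's RNG stream
  idx <- local_seed(config$seed, {
    itr <- sample(nrow(zk), size = round(config$train_fraction * nrow(zk)))
    sub <- if (length(itr) > max_train) sample(itr, max_train) else itr
    list(train = itr, sub = sub)
  })
  ztrain <- zk[idx$sub, , drop = FALSE]
  ztest <- zk[-idx$train, , drop = FALSE]
  gamma <- config$gamma
  if (identical(gamma, "auto"))
    gamma <- 1 / (5 * mean(apply(ztrain, 2L, var)))
  fit <- e1071::svm(ztrain, y = NULL, type = "one-classification",
                    kernel = "radial", nu = config$nu, gamma = gamma,
                    scale = FALSE)
  sv <- as.matrix(fit$SV)
  coefs <- as.numeric(fit$coefs)
  rho <- as.numeric(fit$rho)
  train_out <- mean(rbf_decision(ztrain, sv, coefs, rho, gamma) <= 0)
  test_in <- if (nrow(ztest)) mean(rbf_decision(ztest, sv, coefs, rho, gamma) > 0) else NA_real_
  model <- structure(
    list(stats = stats, sv = sv, coefs = coefs, rho = rho, gamma = gamma,
         cutoffs = cutoffs, config = config,
         prefilter_threshold = unname(quantile(d, config$prefilter_percentile / 100,
                                               type = 7)),
         fit_log = list(n_input = nrow(x), n_retained = length(keep),
                        n_train = nrow(ztrain), n_heldout = nrow(ztest),
                        n_support = nrow(sv),
                        train_outlier_rate = train_out,
                        heldout_inlier_rate = test_in)),
    class = "stratum_model")
  model
}

# evaluate expr with a temporary RNG state seeded from `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(seed)
  expr
}

#' @export
print.stratum_model <- function(x, ...) {
  fl <- x$fit_log
  cat(sprintf("<stratum_model> %s: one-class SVM (RBF, nu=%.3g, gamma=%.4g)\n",
              x$stats$stratum, x$config$nu, x$gamma))
  cat(sprintf("  fitted on %d of %d vectors (%d%% Mahalanobis prefilter), %d support vectors\n",
              fl$n_train, fl$n_input, x$config$prefilter_percentile, fl$n_support))
  cat(sprintf("  training outlier rate %.2f%%, held-out inlier rate %.2f%%\n",
              100 * fl$train_outlier_rate, 100 * fl$heldout_inlier_rate))
  invisible(x)
}

#' @export
summary.stratum_model <- function(object, ...) {
  print(object)
  cat("  static cutoffs:\n")
  for (nm in names(object$cutoffs))
    cat(sprintf("    %s: [%s, %s]\n", nm, object$cutoffs[[nm]][1L],
                object$cutoffs[[nm]][2L]))
  print(object$stats)
  invisible(object)
}

#' Classify parameter vectors with a fitted stratum model
#'
#' A complete vector is `UNSTABLE` when the one-class SVM deems it
#' nonresemblant of the stable training mass, or when any static clinical
#' cutoff is crossed; `STABLE` otherwise. Incomplete vectors yield `NA`
#' (the caller maps these to UNKNOWN).
#'
#' @param object a `stratum_model`.
#' @param newdata 5-vector or matrix of parameter vectors on the raw
#'   (unnormalized) scale.
#' @param ... unused.
#' @return character vector of `"STABLE"` / `"UNSTABLE"` / `NA`.
#' @export
predict.stratum_model <- function(object, newdata, ...) {
  v <- newdata
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  out <- rep(NA_character_, nrow(v))
  ok <- !apply(v, 1L, anyNA)
  if (any(ok)) {
    z <- normalize_vectors(v[ok, , drop = FALSE], object$stats)
    svm_out <- rbf_decision(z, object$sv, object$coefs, object$rho,
                            object$gamma) <= 0
    cut_out <- static_cutoff_check(v[ok, , drop = FALSE], object$cutoffs)
    out[ok] <- ifelse(svm_out | cut_out, "UNSTABLE", "STABLE")
  }
  out
}
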