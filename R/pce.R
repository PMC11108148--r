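# Polynomial chaos expansion by point collocation: orthonormal Legendre
# basis on the prior box, total-degree truncation, ordinary least squares.

# all multi-indices of dimension d with total degree <= order (matrix,
# one row per term; first row is the constant term)
.multi_index <- function(d, order) {
  idx <- matrix(0L, 1, d)
  for (k in seq_len(order)) {
    new <- list()
    prev <- idx[rowSums(idx) == k - 1, , drop = FALSE]
    for (r in seq_len(nrow(prev))) {
      for (j in seq_len(d)) {
        cand <- prev[r, ]
        cand[j] <- cand[j] + 1L
        new[[length(new) + 1L]] <- cand
      }
    }
    new <- unique(do.call(rbind, new))
    idx <- rbind(idx, new)
  }
  idx <- unique(idx)
  idx[order(rowSums(idx), apply(idx, 1, paste, collapse = ",")), , drop = FALSE]
}

# orthonormal Legendre polynomial values up to degree `order` at x in [-1,1]
# returns matrix length(x) x (order+1)
.legendre_orthonormal <- function(x, order) {
  n <- length(x)
  P <- matrix(0, n, order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2) {
    for (k in 1:(order - 1)) {
      P[, k + 2] <- ((2 * k + 1) * x * P[, k + 1] - k * P[, k]) / (k + 1)
    }
  }
  sweep(P, 2, sqrt(2 * seq(0, order) + 1), "*")
}

# basis design matrix for points (rows) on the prior box
.pce_basis <- function(x, prior, multi_index) {
  x <- as.matrix(x)
  d <- ncol(x)
  order <- max(rowSums(multi_index))
  onedim <- vector("list", d)
  for (j in seq_len(d)) {
    w <- prior$upper[j] - prior$lower[j]
    z <- if (w > 0) 2 * (x[, j] - prior$lower[j]) / w - 1 else rep(0, nrow(x))
    onedim[[j]] <- .legendre_orthonormal(z, order)
  }
  B <- matrix(1, nrow(x), nrow(multi_index))
  for (term in seq_len(nrow(multi_index))) {
    for (j in seq_len(d)) {
      deg <- multi_index[term, j]
      if (deg > 0) B[, term] <- B[, term] * onedim[[j]][, deg + 1]
    }
  }
  B
}

#' Fit a polynomial chaos surrogate by point collocation
#'
#' Expands each output in orthonormal (Legendre-type) polynomials on the
#' prior box, truncated at total degree `order`, and fits the coefficients
#' by ordinary least squares on the design evaluations. With independent
#' uniform inputs the basis is orthonormal under the input distribution, so
#' the surrogate mean is the constant coefficient and the variance is the
#' sum of squared non-constant coefficients; an order-`order` polynomial
#' target is reproduced exactly (to numerical precision).
#'
#' @param design an [collocation_design()] (or any `experimental_design`)
#'   whose rows were evaluated.
#' @param y numeric vector (one output) or matrix (rows = design rows,
#'   columns = outputs, e.g. time points).
#' @param order total polynomial degree (default 4).
#' @param ridge optional ridge penalty added on ill-conditioning; `NULL`
#'   disables the fallback.
#' @return an object of class `pce`: coefficients (terms x outputs),
#'   multi-index, prior, diagnostics (residual scale, condition number,
#'   rows used).
#' @export
pce_fit <- function(design, y, order = 4, ridge = 1e-10) {
  prior <- attr(design, "prior")
  if (is.null(prior)) stop("design must carry its prior")
  x <- as.matrix(unclass(design))
  y <- as.matrix(y)
  if (nrow(y) != nrow(x)) stop("evaluations must have one row per design row")
  ok <- stats::complete.cases(y)
  n_failed <- sum(!ok)
  if (mean(ok) < 0.95) {
    stop(sprintf("%d of %d rows failed (> 5%%); refusing to fit", n_failed, nrow(y)))
  }
  x <- x[ok, , drop = FALSE]; y <- y[ok, , drop = FALSE]
  mi <- .multi_index(ncol(x), order)
  if (nrow(x) < nrow(mi)) {
    stop(sprintf("under-determined fit: %d rows < %d terms", nrow(x), nrow(mi)))
  }
  B <- .pce_basis(x, prior, mi)
  sv <- svd(B)
  cond <- sv$d[1] / sv$d[length(sv$d)]
  if (!is.finite(cond) || cond > 1e10) {
    if (is.null(ridge)) stop(sprintf("rank-deficient basis (condition %.3g)", cond))
    # ridge fallback, logged in the object
    coefs <- solve(crossprod(B) + ridge * diag(ncol(B)), crossprod(B, y))
    used_ridge <- TRUE
  } else {
    coefs <- qr.coef(qr(B), y)
    used_ridge <- FALSE
  }
  coefs <- as.matrix(coefs)
  resid <- y - B %*% coefs
  structure(list(
    coefficients = coefs, multi_index = mi, prior = prior, order = order,
    diagnostics = list(condition = cond, ridge = used_ridge,
                       residual_rms = sqrt(colMeans(resid^2)),
                       n_used = nrow(x), n_failed = n_failed)),
    class = "pce")
}

#' @export
coef.pce <- function(object, ...) object$coefficients

#' @export
print.pce <- function(x, ...) {
  cat(sprintf("polynomial chaos surrogate: order %d, %d inputs, %d terms, %d outputs\n",
              x$order, ncol(x$multi_index), nrow(x$multi_index),
              ncol(x$coefficients)))
  cat(sprintf("  fitted on %d evaluations (%d excluded), condition %.3g%s\n",
              x$diagnostics$n_used, x$diagnostics$n_failed,
              x$diagnostics$condition,
              if (x$diagnostics$ridge) ", ridge fallback" else ""))
  invisible(x)
}

#' @export
summary.pce <- function(object, ...) {
  m <- pce_mean(object); v <- pce_variance(object)
  cat("surrogate mean:", format(m, digits = 6), "\n")
  cat("surrogate variance:", format(v, digits = 6), "\n")
  invisible(list(mean = m, variance = v))
}

#' Evaluate a polynomial chaos surrogate
#'
#' @param object a [pce_fit()] surrogate.
#' @param newdata matrix of parameter sets (columns in prior order).
#' @param ... unused.
#' @return matrix of predictions (rows = points, columns = outputs), or a
#'   vector for a single output.
#' @export
predict.pce <- function(object, newdata, ...) {
  B <- .pce_basis(as.matrix(newdata), object$prior, object$multi_index)
  out <- B %*% object$coefficients
  if (ncol(out) == 1) drop(out) else out
}

#' Surrogate mean and variance from coefficients
#'
#' @param s a [pce_fit()] surrogate.
#' @return numeric vector (one entry per output).
#' @export
pce_mean <- function(s) s$coefficients[1, ]

#' @rdname pce_mean
#' @export
pce_variance <- function(s) {
  if (nrow(s$coefficients) == 1) return(0 * s$coefficients[1, ])
  colSums(s$coefficients[-1, , drop = FALSE]^2)
}

#' Uncertainty summary through a surrogate
#'
#' Propagates the prior through the surrogate by Monte Carlo and reports
#' the mean, variance, and the 90% prediction interval (empirical 5th-95th
#' percentiles), alongside the coefficient-based mean and variance.
#'
#' @param s a [pce_fit()] surrogate.
#' @param n_draws Monte-Carlo sample size.
#' @param seed integer seed.
#' @param probs quantiles to report.
#' @return list with `mean`, `variance`, `quantiles` (matrix outputs x
#'   probs).
#' @export
surrogate_uq <- function(s, n_draws = 1e4, seed = 1,
                         probs = c(0.05, 0.95)) {
  set.seed(seed)
  d <- nrow(s$prior)
  u <- matrix(runif(n_draws * d), n_draws, d)
  xs <- .scale_to_prior(u, s$prior)
  ys <- as.matrix(predict(s, xs))
  qs <- t(apply(ys, 2, quantile, probs = probs, names = FALSE))
  colnames(qs) <- paste0("q", probs * 100)
  list(mean = pce_mean(s), variance = pce_variance(s), quantiles = qs)
}
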