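# First-order, total-order, grouped, time-resolved, weighted and
# generalized Sobol' indices, from polynomial chaos coefficients or from
# Saltelli-type Monte Carlo designs.

.sensitivity_result <- function(input, S1, ST, S1_raw, ST_raw, variance,
                                estimator, n) {
  structure(
    data.frame(input = input, S1 = S1, ST = ST, S1_raw = S1_raw,
               ST_raw = ST_raw, stringsAsFactors = FALSE),
    variance = variance, estimator = estimator, n = n,
    class = c("sensitivity_result", "data.frame"))
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sobol' indices (%s estimator, n = %s, Var[Y] = %.4g)\n",
              attr(x, "estimator"), attr(x, "n"), attr(x, "variance")))
  print(data.frame(input = x$input, S1 = signif(x$S1, 4), ST = signif(x$ST, 4)))
  invisible(x)
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Sobol' indices from polynomial chaos coefficients
#'
#' With an orthonormal basis under the (independent) input distribution,
#' the variance decomposes exactly over the multi-index set: the
#' first-order index of input i is the variance sum over terms involving
#' only input i, and the total-order index sums all terms involving i at
#' all, each divided by the total variance. With `groups`, "input i" is
#' replaced by the group of inputs.
#'
#' @param s a [pce_fit()] surrogate with a single output (or pick `output`).
#' @param groups optional character vector of group labels per input
#'   (defaults to the prior's groups if distinct, else one group per
#'   input).
#' @param output output column to decompose (default 1).
#' @return a `sensitivity_result` (S1, ST per input or group); if the
#'   surrogate variance is zero, indices are `NA` (undefined marker).
#' @export
pce_sobol <- function(s, groups = NULL, output = 1) {
  mi <- s$multi_index
  co <- s$coefficients[, output]
  V <- sum(co[-1]^2)
  if (is.null(groups)) groups <- s$prior$group
  glab <- unique(groups)
  # a constant model has zero variance up to least-squares round-off
  if (V <= 1e-24 * (abs(co[1]) + 1)^2) {
    return(.sensitivity_result(glab, NA_real_, NA_real_, NA_real_, NA_real_,
                               0, "pce", s$diagnostics$n_used))
  }
  S1 <- ST <- numeric(length(glab))
  for (k in seq_along(glab)) {
    ing <- groups == glab[k]
    any_g <- rowSums(mi[, ing, drop = FALSE]) > 0
    any_other <- rowSums(mi[, !ing, drop = FALSE]) > 0
    S1[k] <- sum(co[any_g & !any_other]^2) / V
    ST[k] <- sum(co[any_g]^2) / V
  }
  .sensitivity_result(glab, .clip01(S1), .clip01(ST), S1, ST, V, "pce",
                      s$diagnostics$n_used)
}

#' Monte-Carlo Sobol' indices from a Saltelli design
#'
#' Standard estimators on the (A, B, AB_i) blocks: Saltelli-2010
#' first-order, `S1_i = mean(f(B) (f(AB_i) - f(A))) / V`, and Jansen
#' total-order, `ST_i = mean((f(A) - f(AB_i))^2) / (2 V)`; `V` is the
#' variance over the combined A and B evaluations. Grouped designs are
#' handled transparently (a group is one input).
#'
#' @param design a [saltelli_design()].
#' @param y numeric vector of model outputs, one per design row (`NA`
#'   rows are dropped pairwise).
#' @return a `sensitivity_result` per input or group.
#' @export
saltelli_sobol <- function(design, y) {
  blocks <- attr(design, "blocks")
  groups <- attr(design, "groups")
  if (is.null(blocks) || is.null(groups)) stop("not a Saltelli design")
  y <- as.numeric(y)
  if (length(y) != nrow(design)) stop("need one evaluation per design row")
  fA <- y[blocks == "A"]; fB <- y[blocks == "B"]
  V <- stats::var(c(fA, fB), na.rm = TRUE)
  S1 <- ST <- S1r <- STr <- numeric(length(groups))
  for (k in seq_along(groups)) {
    fAB <- y[blocks == paste0("AB_", groups[k])]
    ok <- stats::complete.cases(fA, fB, fAB)
    s1 <- mean(fB[ok] * (fAB[ok] - fA[ok])) / V
    st <- mean((fA[ok] - fAB[ok])^2) / (2 * V)
    S1r[k] <- s1; STr[k] <- st
    # clipping enforces the full chain 0 <= S1 <= ST <= 1; raw estimates
    # are retained alongside
    ST[k] <- .clip01(st); S1[k] <- min(.clip01(s1), ST[k])
  }
  .sensitivity_result(groups, S1, ST, S1r, STr, V, "saltelli-jansen",
                      length(fA))
}

#' Time-resolved Sobol' indices
#'
#' Applies the variance decomposition pointwise in time on a common
#' analysis grid. For `method = "pce"` a single multi-output surrogate is
#' fitted (one output per grid point), which shares one least-squares
#' factorization across all time points; for `method = "saltelli"` the
#' Monte-Carlo estimators are applied column-wise.
#'
#' @param design an `experimental_design`.
#' @param Y outputs matrix: rows = design rows, columns = time points.
#' @param times numeric time grid (length `ncol(Y)`).
#' @param method `"pce"` or `"saltelli"`.
#' @param order polynomial order for the surrogate route.
#' @return an object of class `time_sensitivity`: list with `times`,
#'   matrices `S1` and `ST` (inputs x time), `variance`, `mean`, and the
#'   input labels.
#' @export
timewise_sobol <- function(design, Y, times, method = c("pce", "saltelli"),
                           order = 4) {
  method <- match.arg(method)
  Y <- as.matrix(Y)
  if (length(times) != ncol(Y)) stop("grid mismatch: times vs columns of Y")
  if (method == "pce") {
    s <- pce_fit(design, Y, order = order)
    mi <- s$multi_index
    co <- s$coefficients
    groups <- s$prior$group
    glab <- unique(groups)
    V <- colSums(co[-1, , drop = FALSE]^2)
    m <- co[1, ]
    S1 <- ST <- matrix(NA_real_, length(glab), ncol(Y),
                       dimnames = list(glab, NULL))
    pos <- V > 0
    for (k in seq_along(glab)) {
      ing <- groups == glab[k]
      any_g <- rowSums(mi[, ing, drop = FALSE]) > 0
      any_other <- rowSums(mi[, !ing, drop = FALSE]) > 0
      first <- any_g & !any_other
      S1[k, pos] <- colSums(co[first, pos, drop = FALSE]^2) / V[pos]
      ST[k, pos] <- colSums(co[any_g, pos, drop = FALSE]^2) / V[pos]
    }
    out <- list(times = times, S1 = S1, ST = ST, variance = V, mean = m,
                inputs = glab, estimator = "pce", surrogate = s)
  } else {
    blocks <- attr(design, "blocks")
    groups <- attr(design, "groups")
    if (is.null(blocks)) stop("saltelli method needs a Saltelli design")
    fA <- Y[blocks == "A", , drop = FALSE]
    fB <- Y[blocks == "B", , drop = FALSE]
    V <- apply(rbind(fA, fB), 2, stats::var)
    m <- colMeans(rbind(fA, fB))
    S1 <- ST <- matrix(NA_real_, length(groups), ncol(Y),
                       dimnames = list(groups, NULL))
    pos <- V > 0
    for (k in seq_along(groups)) {
      fAB <- Y[blocks == paste0("AB_", groups[k]), , drop = FALSE]
      S1[k, pos] <- colMeans(fB * (fAB - fA), na.rm = TRUE)[pos] / V[pos]
      ST[k, pos] <- colMeans((fA - fAB)^2, na.rm = TRUE)[pos] / (2 * V[pos])
    }
    out <- list(times = times, S1 = S1, ST = ST, variance = V, mean = m,
                inputs = groups, estimator = "saltelli-jansen")
  }
  structure(out, class = "time_sensitivity")
}

#' @export
print.time_sensitivity <- function(x, ...) {
  cat(sprintf("time-resolved Sobol' indices: %d inputs x %d time points (%s)\n",
              nrow(x$ST), length(x$times), x$estimator))
  n <- length(x$times)
  cat("  total-order at final time:\n")
  print(signif(x$ST[, n], 3))
  invisible(x)
}

#' @export
plot.time_sensitivity <- function(x, which = c("ST", "S1", "weighted",
                                               "generalized"), ...) {
  which <- match.arg(which)
  M <- switch(which, ST = x$ST, S1 = x$S1,
              weighted = weighted_total(x),
              generalized = generalized_sobol(x)$ST_gen)
  M <- pmin(pmax(M, 0), if (which == "weighted") Inf else 1)
  graphics::matplot(x$times, t(M), type = "l", lty = 1, xlab = "time (s)",
                    ylab = which, ...)
  graphics::legend("topleft", legend = rownames(M), col = seq_len(nrow(M)),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Weighted total-order Sobol' indices
#'
#' Pointwise-in-time total-order index multiplied by the output's standard
#' deviation at that time, so that periods of negligible variance carry
#' negligible weight. The result is in the units of the output.
#'
#' @param tr a [timewise_sobol()] result.
#' @return matrix (inputs x time) of `ST_i(t) * sqrt(Var[Y(t)])`.
#' @export
weighted_total <- function(tr) {
  sw <- sweep(pmin(pmax(tr$ST, 0), 1), 2, sqrt(pmax(tr$variance, 0)), "*")
  sw[, tr$variance == 0] <- 0
  sw
}

#' Generalized (time-integrated) Sobol' indices
#'
#' Cumulative variance-ratio form for functional outputs: at horizon `t`,
#' the generalized first-order index is the ratio of the time integrals
#' (trapezoid rule) of the first-order conditional variance and of the
#' total variance over `[0, t]`; the generalized total-order index uses
#' the total-effect conditional variance. Unlike pointwise indices these
#' weight each instant by its share of the integrated variance and are
#' stable where the pointwise ratio is ill-conditioned.
#'
#' @param tr a [timewise_sobol()] result.
#' @param t_end optional horizon; indices are reported as functions of
#'   time up to `t_end` (default: the full grid).
#' @return list with `times`, matrices `S1_gen` and `ST_gen` (inputs x
#'   time); columns where the integrated variance is zero are `NA`.
#' @export
generalized_sobol <- function(tr, t_end = NULL) {
  times <- tr$times
  keep <- if (is.null(t_end)) seq_along(times) else which(times <= t_end)
  times <- times[keep]
  V <- pmax(tr$variance[keep], 0)
  S1 <- pmin(pmax(tr$S1[, keep, drop = FALSE], 0), 1)
  ST <- pmin(pmax(tr$ST[, keep, drop = FALSE], 0), 1)
  cumtrap <- function(y) {
    n <- length(y)
    if (n == 1) return(0)
    c(0, cumsum((y[-1] + y[-n]) / 2 * diff(times)))
  }
  den <- cumtrap(V)
  S1g <- STg <- matrix(NA_real_, nrow(ST), length(times),
                       dimnames = list(rownames(ST), NULL))
  for (k in seq_len(nrow(ST))) {
    S1g[k, ] <- cumtrap(S1[k, ] * V) / den
    STg[k, ] <- cumtrap(ST[k, ] * V) / den
  }
  S1g[, den == 0] <- NA_real_
  STg[, den == 0] <- NA_real_
  list(times = times, S1_gen = S1g, ST_gen = STg)
}
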