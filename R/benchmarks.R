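# Synthetic benchmark functions with known sensitivity structure, and an
# independent quadrature oracle, so every estimator in the package can be
# validated in seconds without the stiff neuron model.

#' Gauss-Legendre nodes and weights on an interval
#'
#' Golub-Welsch: eigen-decomposition of the Jacobi matrix of the Legendre
#' recurrence; weights normalized so they sum to 1 (quadrature of an
#' expectation under the uniform distribution on `[a, b]`).
#'
#' @param n number of nodes.
#' @param a,b interval ends.
#' @return list with `nodes` and `weights`.
#' @export
gauss_legendre <- function(n, a = -1, b = 1) {
  if (n == 1) return(list(nodes = (a + b) / 2, weights = 1))
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (a + b) / 2 + (b - a) / 2 * x[ord], weights = w[ord])
}

#' Brute-force Sobol' indices by tensor-grid quadrature
#'
#' Independent oracle for the variance decomposition of a cheap function
#' of independent uniform inputs: expectations are computed on a tensor
#' Gauss-Legendre grid, the first-order conditional variance by
#' conditioning on one input at a time, and the total-order index through
#' the complementary conditional variance. For a polynomial integrand of
#' degree at most `2 n_nodes - 1` per dimension the quadrature is exact.
#'
#' @param fn vectorized function: matrix of points (rows) -> numeric.
#' @param lower,upper numeric vectors of input supports.
#' @param n_nodes Gauss-Legendre nodes per dimension.
#' @return list with `mean`, `variance`, `S1`, `ST` (per input).
#' @export
oracle_sobol <- function(fn, lower, upper, n_nodes = 24) {
  d <- length(lower)
  gl <- lapply(seq_len(d), function(j) gauss_legendre(n_nodes, lower[j], upper[j]))
  grids <- lapply(gl, `[[`, "nodes")
  X <- as.matrix(expand.grid(grids))
  colnames(X) <- NULL
  W <- Reduce(function(a, b) as.vector(outer(a, b)),
              lapply(gl, `[[`, "weights"))
  y <- fn(X)
  mu <- sum(W * y)
  V <- sum(W * (y - mu)^2)
  S1 <- ST <- numeric(d)
  # index of each point along dimension j
  idx <- as.matrix(expand.grid(lapply(gl, function(g) seq_along(g$nodes))))
  for (j in seq_len(d)) {
    # E[Y | X_j]: collapse all other dimensions
    wj <- gl[[j]]$weights
    cond_mean <- tapply(W * y, idx[, j], sum) / wj
    Vj <- sum(wj * (cond_mean - mu)^2)
    S1[j] <- Vj / V
    # E[Y | X_{-j}] via grouping on all other dims
    key <- apply(idx[, -j, drop = FALSE], 1, paste, collapse = ",")
    w_other <- tapply(W, key, sum)
    cm_other <- tapply(W * y, key, sum) / w_other
    V_other <- sum(w_other * (cm_other - mu)^2)
    ST[j] <- 1 - V_other / V
  }
  list(mean = mu, variance = V, S1 = S1, ST = ST)
}

#' Ishigami benchmark function
#'
#' `Y = sin x1 + a sin^2 x2 + b x3^4 sin x1` with independent
#' `U(-pi, pi)` inputs. The closed-form decomposition is
#' `V1 = (1 + b pi^4 / 5)^2 / 2`, `V2 = a^2 / 8`, `V3 = 0`,
#' `V13 = 8 b^2 pi^8 / 225`, total `V = V1 + V2 + V13`. Input 3 is a pure
#' interaction input: `S3 = 0` but `ST3 > 0`.
#'
#' @param a,b shape parameters.
#' @return object of class `benchmark_function`: list with `fn`
#'   (vectorized over rows), `lower`, `upper`, `S1`, `ST`, `variance`,
#'   `mean`.
#' @export
bench_ishigami <- function(a = 7, b = 0.1) {
  V1 <- (1 + b * pi^4 / 5)^2 / 2
  V2 <- a^2 / 8
  V13 <- 8 * b^2 * pi^8 / 225
  V <- V1 + V2 + V13
  structure(list(
    fn = function(x) {
      x <- as.matrix(x)
      sin(x[, 1]) + a * sin(x[, 2])^2 + b * x[, 3]^4 * sin(x[, 1])
    },
    lower = rep(-pi, 3), upper = rep(pi, 3),
    mean = a / 2, variance = V,
    S1 = c(V1, V2, 0) / V,
    ST = c(V1 + V13, V2, V13) / V),
    class = "benchmark_function")
}

#' Additive linear benchmark
#'
#' `Y = sum(c_i P_i)` with independent `U(0, 1)` inputs:
#' `S_i = ST_i = c_i^2 / sum(c_j^2)`.
#'
#' @param coefficients numeric vector of coefficients.
#' @return a `benchmark_function`; an all-zero coefficient vector is
#'   flagged degenerate (`variance` 0, indices `NA`).
#' @export
bench_linear <- function(coefficients) {
  cc <- as.numeric(coefficients)
  V <- sum(cc^2) / 12
  S <- if (V > 0) cc^2 / sum(cc^2) else rep(NA_real_, length(cc))
  structure(list(
    fn = function(x) as.numeric(as.matrix(x) %*% cc),
    lower = rep(0, length(cc)), upper = rep(1, length(cc)),
    mean = sum(cc) / 2, variance = V, S1 = S, ST = S,
    degenerate = V == 0),
    class = "benchmark_function")
}

#' Toy time-dependent process
#'
#' `Y(t) = t P1 + (1 - t) P2` with `P1, P2 ~ U(0, 1)` iid and
#' `t` in `[0, 1]`: pointwise `S1(t) = t^2 / (t^2 + (1 - t)^2)`,
#' `Var(t) = (t^2 + (1 - t)^2) / 12`, and the generalized first-order
#' index over the full interval is exactly `1/2` for each input.
#'
#' @param times evaluation grid in `[0, 1]`.
#' @return a `benchmark_function` whose `fn` maps an `n x 2` matrix to an
#'   `n x length(times)` matrix, with oracle fields `S1_t`, `variance_t`,
#'   `S1_gen`.
#' @export
bench_toy_process <- function(times = seq(0, 1, by = 0.01)) {
  structure(list(
    fn = function(x) {
      x <- as.matrix(x)
      outer(x[, 1], times) + outer(x[, 2], 1 - times)
    },
    lower = c(0, 0), upper = c(1, 1), times = times,
    variance_t = (times^2 + (1 - times)^2) / 12,
    S1_t = rbind(P1 = times^2 / (times^2 + (1 - times)^2),
                 P2 = (1 - times)^2 / (times^2 + (1 - times)^2)),
    S1_gen = c(P1 = 1 / 2, P2 = 1 / 2)),
    class = "benchmark_function")
}

#' Synthetic spiking-trace generator with polynomial feature maps
#'
#' A cheap, fully deterministic stand-in for the neuron model: given a
#' parameter vector in the unit box, it renders a voltage-like trace whose
#' extracted features are explicit polynomials of the parameters —
#' first-spike latency `q_L` (degree 2, with an interaction term), spike
#' count `round(q_N)`, and an optional depolarization-block plateau onset
#' `q_B`. Spikes are triangular bumps with a linear upstroke several grid
#' steps wide, so interpolated threshold-crossing times are exact and the
#' full pipeline (design -> extraction -> surrogate -> Sobol') recovers
#' `q_L`'s analytic variance decomposition to numerical precision. All
#' feature polynomials have total degree <= 4, so an order-4 expansion
#' represents them exactly.
#'
#' @param n_params number of parameters (>= 4).
#' @param times grid in s (uniform; default 1 ms spacing over 2 s).
#' @param onset stimulus onset (s).
#' @param with_block render a plateau starting at `q_B` (s).
#' @return list with `trace_fn(params)` -> `list(t, v)`, polynomial
#'   feature functions `q_L` (ms), `q_N`, `q_B` (s), and their supports.
#' @export
toy_spiker <- function(n_params = 5, times = seq(0, 2, by = 1e-3),
                       onset = 0.2, with_block = FALSE) {
  if (n_params < 4) stop("need at least 4 parameters")
  q_L <- function(p) {
    p <- as.matrix(p)
    20 + 8 * p[, 1] + 4 * p[, 2] + 6 * p[, 3] * p[, 4]
  }
  q_N <- function(p) {
    p <- as.matrix(p)
    8 + 6 * p[, 2] + 3 * p[, 1] * p[, 3]
  }
  q_B <- function(p) {
    p <- as.matrix(p)
    1.2 + 0.4 * p[, 1] - 0.2 * p[, 2]
  }
  dt <- times[2] - times[1]
  trace_fn <- function(params) {
    params <- matrix(as.numeric(params), nrow = 1)
    if (any(params < 0 | params > 1)) stop("params must lie in the unit box")
    lat <- q_L(params) / 1000
    n_sp <- round(q_N(params))
    t_first <- onset + lat
    t_block <- if (with_block) q_B(params) else Inf
    window_end <- min(if (with_block) t_block else max(times) - 0.05)
    isi <- (window_end - t_first) / max(n_sp, 1)
    rise <- 4 * dt
    if (isi < 2 * rise + 4 * dt) stop("grid too coarse to render requested spikes")
    v <- rep(-70, length(times))
    sp_t <- t_first + (seq_len(n_sp) - 1) * isi
    for (ts in sp_t) {
      # triangular bump: linear rise from -70 to +10 over `rise`, then fall
      seg <- times >= ts & times <= ts + rise
      v[seg] <- -70 + 80 * (times[seg] - ts) / rise
      seg2 <- times > ts + rise & times <= ts + 2 * rise
      v[seg2] <- 10 - 80 * (times[seg2] - ts - rise) / rise
    }
    if (with_block) {
      v[times >= t_block] <- -30
    }
    list(t = times, v = v)
  }
  list(trace_fn = trace_fn, q_L = q_L, q_N = q_N, q_B = q_B,
       n_params = n_params, times = times, onset = onset,
       lower = rep(0, n_params), upper = rep(1, n_params),
       with_block = with_block)
}
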