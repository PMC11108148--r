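# Parameter priors and experimental designs for uncertainty propagation.

#' Uniform parameter priors around nominal values
#'
#' Every uncertain parameter is assigned an independent uniform prior
#' `U(nominal - |sigma * nominal|, nominal + |sigma * nominal|)`, where the
#' single hyper-parameter `sigma` (a fraction) controls the uncertainty of
#' all parameters at once. `sigma = 0` gives a degenerate point mass at the
#' nominal values.
#'
#' @param nominals named numeric vector of nominal values.
#' @param sigma uncertainty fraction (>= 0), e.g. 0.05 for 5%.
#' @param groups optional named character vector (or list) mapping
#'   parameter names to group labels, for grouped sensitivity analysis.
#' @return an object of class `parameter_prior`: data.frame with columns
#'   `name`, `nominal`, `lower`, `upper`, `group`.
#' @export
build_priors <- function(nominals, sigma, groups = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (is.null(names(nominals)) || any(!nzchar(names(nominals)))) {
    stop("nominals must be named")
  }
  half <- abs(sigma * nominals)
  grp <- if (is.null(groups)) names(nominals) else {
    g <- unlist(groups)[names(nominals)]
    if (any(is.na(g))) stop("groups must cover every parameter")
    g
  }
  structure(
    data.frame(name = names(nominals), nominal = unname(nominals),
               lower = unname(nominals - half), upper = unname(nominals + half),
               group = unname(grp), stringsAsFactors = FALSE),
    sigma = sigma, class = c("parameter_prior", "data.frame"))
}

#' Uniform prior on an explicit box
#'
#' Companion to [build_priors()] for benchmark functions whose supports
#' are given directly rather than as a fraction of a nominal value.
#'
#' @param lower,upper numeric vectors of bounds.
#' @param names parameter names.
#' @param groups optional group labels.
#' @return a `parameter_prior`.
#' @export
box_prior <- function(lower, upper, names = paste0("p", seq_along(lower)),
                      groups = NULL) {
  if (length(lower) != length(upper) || any(upper < lower)) {
    stop("invalid bounds")
  }
  structure(
    data.frame(name = names, nominal = (lower + upper) / 2,
               lower = lower, upper = upper,
               group = if (is.null(groups)) names else groups,
               stringsAsFactors = FALSE),
    sigma = NA_real_, class = c("parameter_prior", "data.frame"))
}

#' @export
print.parameter_prior <- function(x, ...) {
  cat(sprintf("parameter prior: %d independent uniforms, sigma = %g%%\n",
              nrow(x), 100 * attr(x, "sigma")))
  print.data.frame(x, ...)
  invisible(x)
}

# scale a matrix of unit-cube samples onto the prior box
.scale_to_prior <- function(u, prior) {
  lo <- matrix(prior$lower, nrow(u), nrow(prior), byrow = TRUE)
  hi <- matrix(prior$upper, nrow(u), nrow(prior), byrow = TRUE)
  x <- lo + u * (hi - lo)
  colnames(x) <- prior$name
  x
}

.design <- function(x, scheme, prior, n_base = NA, second_order = NA,
                    seed = NA) {
  structure(x, scheme = scheme, prior = prior, n_base = n_base,
            second_order = second_order, seed = seed,
            class = c("experimental_design", class(x)))
}

#' Saltelli design for Monte-Carlo Sobol' index estimation
#'
#' Builds the standard radial design: two base matrices A and B of
#' `n_base` rows each, plus for every input (or group) `i` a matrix `AB_i`
#' equal to A with the columns of input `i` replaced from B (and, if
#' `second_order`, the complementary `BA_i`). Row count is
#' `n_base * (D + 2)`, or `n_base * (2 D + 2)` with second-order sampling,
#' where `D` is the number of inputs or groups. Base samples are drawn as a
#' randomized Latin hypercube over the prior box. Columns belonging to the
#' same group are swapped jointly, so a group behaves as a single input.
#'
#' @param prior a [build_priors()] object with at least one parameter.
#' @param n_base number of base samples (a power of two is customary).
#' @param second_order also generate the `BA_i` blocks.
#' @param seed integer seed; designs are reproducible under a fixed seed.
#' @return an `experimental_design` matrix (rows = parameter sets) with
#'   attributes `scheme`, `prior`, `n_base`, `second_order`, `seed` and
#'   `blocks` (the row index of every block).
#' @export
saltelli_design <- function(prior, n_base, second_order = FALSE, seed = 1) {
  if (!inherits(prior, "parameter_prior") || nrow(prior) == 0) {
    stop("prior must be a non-empty parameter_prior")
  }
  d <- nrow(prior)
  groups <- unique(prior$group)
  D <- length(groups)
  set.seed(seed)
  u <- lhs::randomLHS(n_base, 2 * d)
  A <- .scale_to_prior(u[, 1:d, drop = FALSE], prior)
  B <- .scale_to_prior(u[, d + (1:d), drop = FALSE], prior)
  blocks <- list(A = A, B = B)
  for (g in groups) {
    ABg <- A
    ABg[, prior$group == g] <- B[, prior$group == g]
    blocks[[paste0("AB_", g)]] <- ABg
  }
  if (second_order) {
    for (g in groups) {
      BAg <- B
      BAg[, prior$group == g] <- A[, prior$group == g]
      blocks[[paste0("BA_", g)]] <- BAg
    }
  }
  x <- do.call(rbind, blocks)
  block_id <- rep(names(blocks), each = n_base)
  out <- .design(x, "saltelli", prior, n_base, second_order, seed)
  attr(out, "blocks") <- block_id
  attr(out, "groups") <- groups
  out
}

#' Number of polynomial chaos basis terms
#'
#' @param d number of inputs.
#' @param order total polynomial degree.
#' @return `choose(d + order, order)`.
#' @export
n_pce_terms <- function(d, order) choose(d + order, order)

#' Point-collocation design for polynomial chaos fitting
#'
#' Space-filling randomized Latin hypercube draws from the prior box. The
#' default sample count is twice the number of polynomial basis terms,
#' the customary over-sampling factor for regression-based (point
#' collocation) polynomial chaos.
#'
#' @param prior a [build_priors()] object.
#' @param n_points number of design points; default `2 * n_pce_terms()`.
#' @param order polynomial order used to size the default.
#' @param seed integer seed.
#' @return an `experimental_design` matrix.
#' @export
collocation_design <- function(prior, n_points = NULL, order = 4, seed = 1) {
  if (!inherits(prior, "parameter_prior") || nrow(prior) == 0) {
    stop("prior must be a non-empty parameter_prior")
  }
  d <- nrow(prior)
  n_terms <- n_pce_terms(d, order)
  if (is.null(n_points)) n_points <- 2 * n_terms
  if (n_points < n_terms) {
    stop(sprintf("under-determined design: %d points < %d basis terms",
                 n_points, n_terms))
  }
  set.seed(seed)
  u <- lhs::randomLHS(n_points, d)
  x <- .scale_to_prior(u, prior)
  .design(x, "collocation", prior, n_points, FALSE, seed)
}

#' Persist a design and its evaluations as CSV with a JSON sidecar
#'
#' @param design an `experimental_design`.
#' @param evaluations optional numeric vector/matrix of model outputs, one
#'   row per design row.
#' @param path CSV output path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, evaluations = NULL, path) {
  df <- as.data.frame(unclass(design))
  if (!is.null(evaluations)) {
    ev <- as.matrix(evaluations)
    colnames(ev) <- paste0("y_", seq_len(ncol(ev)))
    df <- cbind(df, ev)
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(scheme = attr(design, "scheme"), n_base = attr(design, "n_base"),
               second_order = attr(design, "second_order"),
               seed = attr(design, "seed"),
               prior = as.data.frame(attr(design, "prior")))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
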