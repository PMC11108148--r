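# Orchestration of the three studies: factor fixing (grouped, resting
# state), dynamical-state UQ/GSA on spiking features, and time-resolved
# GSA of the extracellular K+ concentration.

#' Evaluate a design row-by-row through the neuron model
#'
#' @param design an `experimental_design` whose columns are membrane
#'   parameter names.
#' @param fun function(trajectory) -> named numeric vector of outputs.
#' @param stim a [stimulus_protocol()] or `NULL`.
#' @param cfg a [solver_config()].
#' @param y0 initial state (defaults to the calibrated resting state).
#' @param progress print progress every so many rows (0 = silent).
#' @return matrix: one row per design row (failed simulations give `NA`
#'   rows; the failure count is attached as attribute `n_failed`).
#' @export
evaluate_design <- function(design, fun, stim = NULL, cfg = solver_config(),
                            y0 = NULL, progress = 0) {
  x <- as.matrix(unclass(design))
  if (is.null(y0)) y0 <- edneg_resting_state()
  out <- NULL
  n_failed <- 0
  for (i in seq_len(nrow(x))) {
    p_i <- do.call(edneg_parameters, as.list(x[i, ]))
    val <- tryCatch(fun(edneg_simulate(p_i, y0, stim, cfg)),
                    error = function(e) NULL)
    if (is.null(out) && !is.null(val)) {
      out <- matrix(NA_real_, nrow(x), length(val),
                    dimnames = list(NULL, names(val)))
    }
    if (is.null(val)) n_failed <- n_failed + 1 else out[i, ] <- val
    if (progress > 0 && i %% progress == 0) {
      message(sprintf("  evaluated %d / %d", i, nrow(x)))
    }
  }
  if (is.null(out)) stop("all simulations failed")
  attr(out, "n_failed") <- n_failed
  out
}

#' Factor-fixing experiment: grouped sensitivity of the resting state
#'
#' Treats the 11 "non-dynamic" parameters (leaks, pumps, cotransporters)
#' and the 5 "dynamic" parameters (active-channel conductances) as two
#' grouped inputs with uniform priors at `sigma` around the nominal
#' values, runs the stimulus-free rest protocol for every Saltelli row,
#' and estimates the grouped total-order Sobol' index of each group for
#' the six resting-state QoIs by direct Monte Carlo (no surrogate).
#'
#' @param sigma uncertainty fraction (the study value is 0.15).
#' @param n_base Saltelli base sample count (full-scale value 512; the
#'   desk profile uses 64).
#' @param t_rest rest-protocol duration in s (full-scale 240; desk 60).
#' @param second_order generate second-order blocks (the full-scale
#'   design: 512 base samples over 2 groups -> 3072 rows).
#' @param seed integer seed.
#' @param progress as in [evaluate_design()].
#' @return list with `indices` (one `sensitivity_result` per QoI),
#'   `table` (QoI x group total-order matrix, the Table-3 shape),
#'   `design`, `evaluations`.
#' @export
run_factor_fixing <- function(sigma = 0.15, n_base = 64, t_rest = 60,
                              second_order = TRUE, seed = 1, progress = 0) {
  nominals <- edneg_nominal("all")
  groups <- setNames(ifelse(names(nominals) %in% .dynamic_names,
                            "dynamic", "non-dynamic"), names(nominals))
  prior <- build_priors(nominals, sigma, groups)
  design <- saltelli_design(prior, n_base, second_order = second_order,
                            seed = seed)
  cfg <- solver_config(dt_max = 5000, t_end = t_rest, grid_dt = t_rest * 1000)
  ev <- evaluate_design(design, resting_qois, stim = NULL, cfg = cfg,
                        progress = progress)
  idx <- lapply(colnames(ev), function(q) saltelli_sobol(design, ev[, q]))
  names(idx) <- colnames(ev)
  tab <- t(vapply(idx, function(r) setNames(r$ST, r$input), numeric(2)))
  list(indices = idx, table = tab, design = design, evaluations = ev)
}

.condition_stim <- function(condition) {
  switch(condition,
    physiological = stimulus_protocol(8e-5, 0.2, 5.5),
    pathological = stimulus_protocol(20e-5, 0.2, 5.5),
    stop("unknown condition: ", condition))
}

.dynamic_prior <- function(sigma) {
  build_priors(edneg_nominal("dynamic"), sigma)
}

#' Dynamical-state uncertainty quantification
#'
#' Propagates uniform uncertainty on the five active-channel conductances
#' through the stimulated model, for each uncertainty level in
#' `sigma_levels`. For `sigma = 0` the QoIs are a point mass at their
#' nominal-run values and sensitivity analysis is skipped; otherwise a
#' point-collocation design is simulated, the spiking QoIs extracted, an
#' order-`order` polynomial chaos surrogate fitted per QoI, and
#' first/total Sobol' indices computed from its coefficients. Rows whose
#' QoI is undefined (e.g. no depolarization block) are excluded from that
#' QoI's fit, with the excluded fraction reported.
#'
#' @param condition `"physiological"` (QoIs: spike count, final firing
#'   frequency, first-spike latency) or `"pathological"` (block onset,
#'   first-spike latency).
#' @param sigma_levels uncertainty fractions (study values
#'   `c(0, 0.01, 0.05, 0.10)`).
#' @param n_points collocation points per level (default
#'   `2 * n_pce_terms(5, order)` = 252).
#' @param order polynomial order (default 4).
#' @param t_end simulated time in s.
#' @param seed integer seed.
#' @param progress as in [evaluate_design()].
#' @return list keyed by sigma level: each with `qois` (evaluations),
#'   `summary` (quantile table), `standardized` quantiles, `indices`
#'   (per-QoI `sensitivity_result`), `excluded_fraction`.
#' @export
run_dynamical_uq <- function(condition = c("physiological", "pathological"),
                             sigma_levels = c(0, 0.01, 0.05, 0.10),
                             n_points = NULL, order = 4, t_end = 6, seed = 1,
                             progress = 0) {
  condition <- match.arg(condition)
  stim <- .condition_stim(condition)
  qois <- if (condition == "physiological") {
    c("n_ap", "f_final", "t_bfap")
  } else c("t_sdp", "t_bfap")
  cfg <- solver_config(t_end = t_end)
  y0 <- edneg_resting_state()
  fun <- function(tr) extract_qois(tr, qois = qois)
  probs <- c(0.01, 0.05, 0.25, 0.50, 0.75, 0.95, 0.99)

  out <- list()
  for (sg in sigma_levels) {
    key <- sprintf("sigma_%g", sg)
    if (sg == 0) {
      tr <- edneg_simulate(edneg_parameters(), y0, stim, cfg)
      v <- fun(tr)
      out[[key]] <- list(qois = matrix(v, 1, dimnames = list(NULL, names(v))),
                         summary = NULL, indices = NULL, point = v)
      next
    }
    prior <- .dynamic_prior(sg)
    design <- collocation_design(prior, n_points = n_points, order = order,
                                 seed = seed)
    ev <- evaluate_design(design, fun, stim = stim, cfg = cfg, y0 = y0,
                          progress = progress)
    qtab <- apply(ev, 2, quantile, probs = probs, na.rm = TRUE)
    ztab <- apply(ev, 2, function(col) {
      z <- (col - mean(col, na.rm = TRUE)) / sd(col, na.rm = TRUE)
      quantile(z, probs = probs, na.rm = TRUE)
    })
    idx <- excl <- list()
    for (q in colnames(ev)) {
      ok <- !is.na(ev[, q])
      excl[[q]] <- mean(!ok)
      if (mean(ok) < 0.95) {
        idx[[q]] <- NULL
        next
      }
      s <- pce_fit(.design(as.matrix(unclass(design))[ok, , drop = FALSE],
                           "collocation", attr(design, "prior")),
                   ev[ok, q], order = order)
      idx[[q]] <- pce_sobol(s)
    }
    out[[key]] <- list(qois = ev, summary = qtab, standardized = ztab,
                       indices = idx, excluded_fraction = unlist(excl))
  }
  attr(out, "condition") <- condition
  out
}

#' Time-resolved GSA of the extracellular K+ concentration
#'
#' At a fixed uncertainty level, simulates a point-collocation design
#' under the stimulation protocol, fits per-time-point surrogates of
#' `[K+]_se` on the analysis grid, and returns the standard, weighted and
#' generalized total-order Sobol' index trajectories together with the
#' surrogate mean and 90% prediction interval.
#'
#' @inheritParams run_dynamical_uq
#' @param sigma uncertainty fraction (study value 0.05).
#' @param grid_dt analysis-grid spacing in ms for the GSA (the trajectory
#'   grid; 1 ms resolves every spiking feature).
#' @param n_pi_draws Monte-Carlo draws through the surrogate for the
#'   prediction interval.
#' @return list with `timewise` (a `time_sensitivity`), `weighted`,
#'   `generalized`, `mean`, `pi90` (2 x time matrix), `design`.
#' @export
run_gsa_timecourse <- function(condition = c("physiological", "pathological"),
                               sigma = 0.05, n_points = NULL, order = 4,
                               t_end = 6, grid_dt = 1, seed = 1,
                               n_pi_draws = 1000, progress = 0) {
  condition <- match.arg(condition)
  stim <- .condition_stim(condition)
  cfg <- solver_config(t_end = t_end, grid_dt = grid_dt)
  y0 <- edneg_resting_state()
  prior <- .dynamic_prior(sigma)
  design <- collocation_design(prior, n_points = n_points, order = order,
                               seed = seed)
  ev <- evaluate_design(design, function(tr) concentration(tr, "K", "se"),
                        stim = stim, cfg = cfg, y0 = y0, progress = progress)
  times <- seq(0, t_end, by = grid_dt / 1000)
  tw <- timewise_sobol(design, ev, times, method = "pce", order = order)
  wt <- weighted_total(tw)
  gen <- generalized_sobol(tw)
  # prediction interval through the surrogate
  set.seed(seed + 1)
  u <- lhs::randomLHS(n_pi_draws, nrow(prior))
  draws <- predict(tw$surrogate, .scale_to_prior(u, prior))
  pi90 <- apply(draws, 2, quantile, probs = c(0.05, 0.95), names = FALSE)
  rownames(pi90) <- c("q5", "q95")
  list(timewise = tw, weighted = wt, generalized = gen, mean = tw$mean,
       pi90 = pi90, design = design, evaluations = ev)
}

#' Run the synthetic benchmark suite
#'
#' Exercises every estimator against the analytic oracles: Ishigami by
#' Monte Carlo and by polynomial chaos, the additive model, the toy time
#' process (pointwise, weighted and generalized indices), and the
#' end-to-end toy-spiker pipeline. Returns the deviations and a pass
#' flag per check.
#'
#' @param n_base Monte-Carlo base sample count for the Ishigami check.
#' @param seed integer seed.
#' @return data.frame with columns `check`, `max_error`, `tolerance`,
#'   `pass`.
#' @export
run_benchmarks <- function(n_base = 2^14, seed = 1) {
  checks <- list()
  add <- function(name, err, tol) {
    checks[[length(checks) + 1]] <<- data.frame(
      check = name, max_error = err, tolerance = tol, pass = err <= tol)
  }

  ish <- bench_ishigami()
  pr_ish <- box_prior(ish$lower, ish$upper, c("x1", "x2", "x3"))
  des <- saltelli_design(pr_ish, n_base, seed = seed)
  res <- saltelli_sobol(des, ish$fn(unclass(des)))
  add("ishigami_mc", max(abs(res$S1 - ish$S1), abs(res$ST - ish$ST)), 0.02)

  dp <- collocation_design(pr_ish, n_points = 2 * n_pce_terms(3, 10),
                           order = 10, seed = seed)
  sp <- pce_fit(dp, ish$fn(unclass(dp)), order = 10)
  rp <- pce_sobol(sp)
  add("ishigami_pce", max(abs(rp$S1 - ish$S1), abs(rp$ST - ish$ST)), 0.01)

  lin <- bench_linear(c(2, 1))
  prl <- box_prior(lin$lower, lin$upper)
  dl <- collocation_design(prl, order = 2, seed = seed)
  sl <- pce_fit(dl, lin$fn(unclass(dl)), order = 2)
  rl <- pce_sobol(sl)
  add("linear_additive", max(abs(rl$S1 - lin$S1)), 1e-6)

  toy <- bench_toy_process()
  prt <- box_prior(toy$lower, toy$upper, c("P1", "P2"))
  dt_ <- collocation_design(prt, order = 2, seed = seed)
  Y <- toy$fn(unclass(dt_))
  tw <- timewise_sobol(dt_, Y, toy$times, order = 2)
  keep <- toy$variance_t > 1e-12
  add("toy_pointwise", max(abs(tw$S1[, keep] - toy$S1_t[, keep])), 1e-3)
  gen <- generalized_sobol(tw)
  add("toy_generalized",
      max(abs(gen$S1_gen[, length(toy$times)] - toy$S1_gen)), 1e-3)
  wt <- weighted_total(tw)
  add("weighted_identity",
      max(abs(wt - pmin(pmax(tw$ST, 0), 1) *
                matrix(sqrt(tw$variance), nrow(wt), ncol(wt), byrow = TRUE))),
      1e-12)

  do.call(rbind, checks)
}
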