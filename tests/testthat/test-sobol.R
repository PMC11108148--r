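# Sobol' index estimators against analytic decompositions.

test_that("coefficient-based indices recover additive and interaction structure", {
  # additive 2 P1 + P2 on U(0,1)^2: V1 = 4/12, V2 = 1/12 -> S = (0.8, 0.2)
  pr <- box_prior(c(0, 0), c(1, 1), c("P1", "P2"))
  d <- collocation_design(pr, order = 2, seed = 1)
  s <- pce_fit(d, 2 * unclass(d)[, 1] + unclass(d)[, 2], order = 2)
  r <- pce_sobol(s)
  expect_equal(r$S1, c(0.8, 0.2), tolerance = 1e-10)
  expect_equal(r$ST, r$S1, tolerance = 1e-10)
  # pure interaction (centered inputs): S1 = 0, ST = 1 for both
  pri <- box_prior(c(-1, -1), c(1, 1), c("P1", "P2"))
  di <- collocation_design(pri, order = 2, seed = 2)
  si <- pce_fit(di, unclass(di)[, 1] * unclass(di)[, 2], order = 2)
  ri <- pce_sobol(si)
  expect_equal(ri$S1, c(0, 0), tolerance = 1e-12)
  expect_equal(ri$ST, c(1, 1), tolerance = 1e-10)
  # constant model: undefined marker, not NaN from a division
  sc <- pce_fit(di, rep(1, nrow(di)), order = 2)
  expect_true(all(is.na(pce_sobol(sc)$S1)))
})

test_that("Monte-Carlo estimators match the Ishigami closed forms", {
  ish <- bench_ishigami(7, 0.1)
  pr <- box_prior(ish$lower, ish$upper, c("x1", "x2", "x3"))
  des <- saltelli_design(pr, 2^14, seed = 10)
  r <- saltelli_sobol(des, ish$fn(unclass(des)))
  expect_lt(max(abs(r$S1 - ish$S1)), 0.02)
  expect_lt(max(abs(r$ST - ish$ST)), 0.02)
  # x3 is a pure interaction input: S3 ~ 0 but ST3 clearly positive
  expect_lt(r$S1[3], 0.02)
  expect_gt(r$ST[3], 0.2)
  # S_i <= S_Ti for every input after clipping
  expect_true(all(r$S1 <= r$ST + 1e-12))
})

test_that("grouped Monte-Carlo indices isolate the active group", {
  pr <- box_prior(rep(0, 4), rep(1, 4), paste0("p", 1:4),
                  groups = c("A", "A", "B", "B"))
  des <- saltelli_design(pr, 2^10, seed = 3)
  # only group A's parameters enter the model
  y <- unclass(des)[, 1] + 2 * unclass(des)[, 2]^2
  r <- saltelli_sobol(des, y)
  expect_gt(r$ST[r$input == "A"], 0.97)
  expect_lt(r$ST[r$input == "B"], 0.03)
})

test_that("pointwise-in-time indices follow the toy process exactly", {
  toy <- bench_toy_process(seq(0, 1, by = 0.02))
  pr <- box_prior(toy$lower, toy$upper, c("P1", "P2"))
  d <- collocation_design(pr, order = 2, seed = 4)
  tw <- timewise_sobol(d, toy$fn(unclass(d)), toy$times, order = 2)
  keep <- toy$variance_t > 1e-12
  expect_lt(max(abs(tw$S1[, keep] - toy$S1_t[, keep])), 1e-8)
  expect_lt(max(abs(tw$variance - toy$variance_t)), 1e-10)
  # symmetry at t = 0.5
  i <- which(abs(toy$times - 0.5) < 1e-9)
  expect_equal(unname(tw$S1[, i]), c(0.5, 0.5), tolerance = 1e-8)
  # a time-constant process has constant indices
  Yc <- outer(unclass(d)[, 1], rep(1, 11)) + 0.5
  twc <- timewise_sobol(d, Yc, seq(0, 1, length.out = 11), order = 2)
  expect_lt(max(abs(twc$ST["P1", ] - 1)), 1e-10)
  expect_error(timewise_sobol(d, Yc, 1:5), "grid mismatch")
})

test_that("weighted indices equal ST times the output standard deviation", {
  toy <- bench_toy_process(seq(0, 1, by = 0.02))
  pr <- box_prior(toy$lower, toy$upper, c("P1", "P2"))
  d <- collocation_design(pr, order = 2, seed = 5)
  tw <- timewise_sobol(d, toy$fn(unclass(d)), toy$times, order = 2)
  wt <- weighted_total(tw)
  # identity S^W = ST * sqrt(Var), pointwise to machine precision
  expect_equal(wt, pmin(pmax(tw$ST, 0), 1) *
                 matrix(sqrt(tw$variance), nrow(wt), ncol(wt), byrow = TRUE),
               tolerance = 1e-14)
  # at t = 1 the process is P1 alone: S1^W = 1 * sqrt(1/12)
  expect_equal(unname(wt["P1", ncol(wt)]), sqrt(1 / 12), tolerance = 1e-8)
  # zero variance forces zero weighted index regardless of ST
  Y0 <- cbind(toy$fn(unclass(d))[, -1], rep(2, nrow(d)))
  tw0 <- timewise_sobol(d, Y0, seq_len(ncol(Y0)), order = 2)
  expect_equal(unname(weighted_total(tw0)[, ncol(Y0)]), c(0, 0))
  # output scaling: c * Y scales S^W by |c| and leaves ST unchanged
  tw3 <- timewise_sobol(d, 3 * toy$fn(unclass(d)), toy$times, order = 2)
  expect_equal(weighted_total(tw3), 3 * wt, tolerance = 1e-10)
  expect_equal(tw3$ST, tw$ST, tolerance = 1e-10)
})

test_that("generalized indices integrate the toy process to exactly 1/2", {
  toy <- bench_toy_process(seq(0, 1, by = 0.01))
  pr <- box_prior(toy$lower, toy$upper, c("P1", "P2"))
  d <- collocation_design(pr, order = 2, seed = 6)
  tw <- timewise_sobol(d, toy$fn(unclass(d)), toy$times, order = 2)
  gen <- generalized_sobol(tw)
  n <- length(toy$times)
  expect_equal(unname(gen$S1_gen[, n]), c(0.5, 0.5), tolerance = 1e-3)
  expect_true(all(gen$ST_gen[, -1] >= -1e-12 & gen$ST_gen[, -1] <= 1 + 1e-12))
  # a time-constant process: generalized equals pointwise
  Yc <- outer(unclass(d)[, 1] + 0.3 * unclass(d)[, 2], rep(1, n))
  twc <- timewise_sobol(d, Yc, toy$times, order = 2)
  genc <- generalized_sobol(twc)
  expect_equal(genc$ST_gen[, n], twc$ST[, n], tolerance = 1e-9)
  # refining the grid leaves the integrated index unchanged (trapezoid limit)
  toy2 <- bench_toy_process(seq(0, 1, by = 0.005))
  d2 <- collocation_design(pr, order = 2, seed = 6)
  tw2 <- timewise_sobol(d2, toy2$fn(unclass(d2)), toy2$times, order = 2)
  gen2 <- generalized_sobol(tw2)
  expect_equal(gen2$S1_gen[, length(toy2$times)], gen$S1_gen[, n],
               tolerance = 1e-4)
})
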