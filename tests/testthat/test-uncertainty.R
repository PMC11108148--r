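# Priors, experimental designs, and the polynomial chaos surrogate.

test_that("uniform priors follow nominal +/- |sigma * nominal|", {
  pr <- build_priors(c(g_Ca = 11.8), 0.10)
  expect_equal(pr$lower, 10.62)
  expect_equal(pr$upper, 12.98)
  # sigma = 0: degenerate point mass
  pr0 <- build_priors(c(a = 2, b = -3), 0)
  expect_equal(pr0$lower, pr0$upper)
  # the full 16-parameter prior at 15%
  pr16 <- build_priors(edneg_nominal("all"), 0.15)
  expect_equal(nrow(pr16), 16)
  expect_equal(pr16$upper - pr16$lower, unname(2 * 0.15 * edneg_nominal("all")))
  expect_error(build_priors(c(a = 1), -0.1), "non-negative")
})

test_that("Saltelli designs have the scheme's exact row counts", {
  pr2 <- build_priors(c(a = 1, b = 2), 0.1)
  expect_equal(nrow(saltelli_design(pr2, 1, second_order = FALSE)[
    attr(saltelli_design(pr2, 1, second_order = FALSE), "blocks") == "A", ,
    drop = FALSE]), 1)
  # N (D + 2) without second order
  pr1 <- build_priors(c(a = 1), 0.1)
  expect_equal(nrow(saltelli_design(pr1, 1, second_order = FALSE)), 3)
  pr3 <- build_priors(c(a = 1, b = 2, c = 3), 0.1)
  expect_equal(nrow(saltelli_design(pr3, 8, second_order = TRUE)), 64)
  # the study design: 512 base samples over 2 groups, second order -> 3072
  groups <- setNames(rep(c("non-dynamic", "dynamic"), c(11, 5)),
                     names(edneg_nominal("all")))
  prg <- build_priors(edneg_nominal("all"), 0.15, groups)
  dg <- saltelli_design(prg, 512, second_order = TRUE)
  expect_equal(nrow(dg), 3072)
  # grouped columns swap jointly: AB_dynamic differs from A only on the group
  A <- dg[attr(dg, "blocks") == "A", , drop = FALSE]
  ABd <- dg[attr(dg, "blocks") == "AB_dynamic", , drop = FALSE]
  dyn <- prg$group == "dynamic"
  expect_true(all(A[, !dyn] == ABd[, !dyn]))
  expect_false(any(A[, dyn] == ABd[, dyn]))
})

test_that("designs are inside the prior box and seed-reproducible", {
  pr <- build_priors(c(a = 1, b = 10), 0.2)
  d1 <- saltelli_design(pr, 16, seed = 7)
  d2 <- saltelli_design(pr, 16, seed = 7)
  expect_identical(unclass(d1), unclass(d2))
  lo <- matrix(pr$lower, nrow(d1), 2, byrow = TRUE)
  hi <- matrix(pr$upper, nrow(d1), 2, byrow = TRUE)
  expect_true(all(d1 >= lo & d1 <= hi))
  c1 <- collocation_design(pr, seed = 3)
  c2 <- collocation_design(pr, seed = 3)
  expect_identical(unclass(c1), unclass(c2))
})

test_that("collocation sizing: order-4 in 5 inputs needs 126 terms, 252 points", {
  expect_equal(n_pce_terms(5, 4), 126)
  pr <- build_priors(setNames(1:5, paste0("g", 1:5)), 0.1)
  d <- collocation_design(pr, order = 4)
  expect_equal(nrow(d), 252)
  expect_error(collocation_design(pr, n_points = 100, order = 4),
               "under-determined")
})

test_that("the surrogate reproduces low-order polynomials exactly", {
  pr <- build_priors(c(x = 2, y = 3), 0.5)
  set.seed(1)
  d <- collocation_design(pr, order = 4, seed = 2)
  f <- function(m) 1 + m[, 1] - 0.5 * m[, 2]^2 + 0.25 * m[, 1]^3 * m[, 2]
  s <- pce_fit(d, f(unclass(d)), order = 4)
  held <- cbind(runif(50, pr$lower[1], pr$upper[1]),
                runif(50, pr$lower[2], pr$upper[2]))
  expect_lt(max(abs(predict(s, held) - f(held))), 1e-9)
})

test_that("additive linear target has variance sum(c^2)/12 on the unit box", {
  pr <- box_prior(c(0, 0), c(1, 1))
  d <- collocation_design(pr, order = 2, seed = 5)
  s <- pce_fit(d, 2 * unclass(d)[, 1] + unclass(d)[, 2], order = 2)
  expect_equal(unname(pce_variance(s)), 5 / 12, tolerance = 1e-10)
  expect_equal(unname(pce_mean(s)), 1.5, tolerance = 1e-10)
  # constant target: zero variance, mean equal to the constant
  s0 <- pce_fit(d, rep(3.25, nrow(d)), order = 2)
  expect_equal(unname(pce_variance(s0)), 0, tolerance = 1e-20)
  expect_equal(unname(pce_mean(s0)), 3.25)
})

test_that("coefficient-based moments match Monte Carlo through the surrogate", {
  pr <- box_prior(c(-1, -1, -1), c(1, 1, 1))
  d <- collocation_design(pr, order = 3, seed = 9)
  f <- function(m) m[, 1] + m[, 2]^2 * m[, 3] + 0.3 * m[, 3]^3
  s <- pce_fit(d, f(unclass(d)), order = 3)
  set.seed(11)
  mc <- f(matrix(runif(3e5 * 3, -1, 1), ncol = 3))
  expect_equal(unname(pce_mean(s)), mean(mc), tolerance = 5e-3)
  expect_lt(abs(unname(pce_variance(s)) - var(mc)) / var(mc), 1e-3 + 3 / sqrt(3e5))
})

test_that("surrogate uncertainty summaries match closed-form quantiles", {
  # constant surrogate: degenerate interval
  pr <- box_prior(0, 1, "x")
  d <- collocation_design(pr, order = 2, seed = 1)
  s0 <- pce_fit(d, rep(2, nrow(d)), order = 2)
  u0 <- surrogate_uq(s0, n_draws = 500, seed = 2)
  expect_equal(unname(u0$quantiles[1, ]), c(2, 2))
  # linear in one U(a, b): percentiles are the uniform quantiles
  a <- 3; b <- 7
  prl <- box_prior(a, b, "x")
  dl <- collocation_design(prl, order = 1, n_points = 8, seed = 3)
  sl <- pce_fit(dl, 2 * as.numeric(unclass(dl)), order = 1)
  ul <- surrogate_uq(sl, n_draws = 2e4, seed = 4)
  expect_equal(unname(ul$quantiles[1, ]),
               2 * (a + c(0.05, 0.95) * (b - a)), tolerance = 0.02)
  # prediction interval widens with the prior half-width (nested supports)
  widths <- sapply(c(0.05, 0.1, 0.2), function(sg) {
    prw <- build_priors(c(x = 10), sg)
    dw <- collocation_design(prw, order = 1, n_points = 8, seed = 5)
    sw <- pce_fit(dw, 3 * as.numeric(unclass(dw)), order = 1)
    diff(as.numeric(surrogate_uq(sw, n_draws = 5e3, seed = 6)$quantiles))
  })
  expect_true(all(diff(widths) > 0))
})

test_that("design persistence writes CSV plus JSON sidecar", {
  pr <- build_priors(c(a = 1, b = 2), 0.1)
  d <- saltelli_design(pr, 4, seed = 1)
  tmp <- file.path(tempdir(), "design.csv")
  write_design(d, evaluations = rowSums(unclass(d)), tmp)
  expect_true(file.exists(tmp))
  expect_true(file.exists(sub("csv$", "json", tmp)))
  meta <- jsonlite::read_json(sub("csv$", "json", tmp))
  expect_equal(meta$scheme, "saltelli")
  expect_equal(meta$seed, 1)
})
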