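test_that("reallocation moves time between exactly two parts", {
  b <- c(PA = 4, SB = 5, SL = 15)
  expect_equal(reallocate(b, "SB", "PA", 0.25), c(PA = 4.25, SB = 4.75, SL = 15))
  expect_equal(reallocate(b, "SB", "PA", 0), b)
  expect_equal(sum(reallocate(b, "SL", "SB", 1)), sum(b))
  expect_error(reallocate(b, "PA", "SB", 4.5), "infeasible")
})

test_that("predicted delta matches the hand-evaluated gradient formula", {
  a <- clr_gradient(ref$beta)
  # hand: 2.3025*ln(4.08/3.83) - 2.1311*ln(4.34/4.59) at the reported baseline
  expect_equal(predict_delta(a, ref$baseline, "SB", "PA", 0.25), 0.264945,
               tolerance = 1e-5)
  # antisymmetry in the endpoints
  b2 <- reallocate(ref$baseline, "SB", "PA", 0.25)
  expect_equal(predict_delta(a, b2, "PA", "SB", 0.25),
               -predict_delta(a, ref$baseline, "SB", "PA", 0.25))
  # continuity at zero
  expect_equal(predict_delta(a, ref$baseline, "SB", "PA", 0), 0)
})

test_that("delta is covariate-free, basis-invariant, and equals the model route", {
  withr::local_seed(71)
  x <- random_comps(120)
  d <- toy_survey(x)
  base <- substitution_baseline(d)
  fits <- lapply(c("PA", "SB", "SL"), function(p) {
    fit_qol_model(d, basis = pivot_basis(c("PA", "SB", "SL"), pivot = p))
  })
  deltas <- vapply(fits, predict_delta, numeric(1),
                   baseline = base, from = "SB", to = "PA", amount = 0.25)
  expect_lt(diff(range(deltas)), 1e-10)

  # full-model prediction difference with covariates held fixed
  fit <- fits[[1]]
  shifted <- reallocate(base, "SB", "PA", 0.25)
  newd <- tibble::tibble(
    age_years = c(3, 3), sex = c("girl", "girl"),
    pa_hours = c(base["PA"], shifted["PA"]),
    sb_hours = c(base["SB"], shifted["SB"]),
    sl_hours = c(base["SL"], shifted["SL"]),
    qol_total = NA_real_)
  expect_equal(diff(predict(fit, newd)),
               predict_delta(fit, base, "SB", "PA", 0.25),
               tolerance = 1e-10, ignore_attr = TRUE)
  # and the covariate values do not matter
  newd2 <- newd; newd2$age_years <- c(5, 5); newd2$sex <- c("boy", "boy")
  expect_equal(diff(predict(fit, newd2)), diff(predict(fit, newd)),
               tolerance = 1e-10)
})

test_that("first-order Taylor limit of delta per unit time", {
  a <- clr_gradient(ref$beta)
  b <- ref$baseline
  eps <- 1e-7
  limit <- a[["PA"]] / b[["PA"]] - a[["SB"]] / b[["SB"]]
  expect_equal(predict_delta(a, b, "SB", "PA", eps) / eps, limit,
               tolerance = 1e-5)
})

test_that("confidence intervals are symmetric, centred, and vanish without noise", {
  withr::local_seed(72)
  x <- random_comps(80)
  z <- ilr(x)
  d <- toy_survey(x)
  d$qol_total <- 70 + 2 * z[, 1] - z[, 2] + 0.3 * d$age_years  # noiseless
  fit <- suppressWarnings(fit_qol_model(d))
  base <- substitution_baseline(d)
  ci0 <- suppressWarnings(delta_ci(fit, base, "SB", "PA", 0.25))
  expect_equal(ci0$conf_low, ci0$delta, tolerance = 1e-6)
  expect_equal(ci0$conf_high, ci0$delta, tolerance = 1e-6)

  d$qol_total <- d$qol_total + rnorm(80, 0, 8)
  fit <- fit_qol_model(d)
  ci <- delta_ci(fit, base, "SB", "PA", 0.25)
  expect_lt(ci$conf_low, ci$delta)
  expect_gt(ci$conf_high, ci$delta)
  expect_equal(ci$conf_high - ci$delta, ci$delta - ci$conf_low)
  # normal quantile narrows the interval slightly
  cin <- delta_ci(fit, base, "SB", "PA", 0.25, quantile = "normal")
  expect_lt(cin$conf_high - cin$conf_low, ci$conf_high - ci$conf_low)
  expect_error(delta_ci(clr_gradient(ref$beta), base, "SB", "PA", 0.25),
               "covariance")
})

test_that("the substitution grid is complete, consistent and asymmetric", {
  withr::local_seed(73)
  x <- random_comps(150)
  d <- toy_survey(x)
  # outcome driven by the reference-scale gradient so effect signs are known
  d$qol_total <- 75 + drop(log(x) %*% clr_gradient(ref$beta)) +
    0.5 * d$age_years + rnorm(150, 0, 2)
  fit <- fit_qol_model(d)
  base <- substitution_baseline(d)
  g <- substitution_grid(fit, base)
  expect_equal(nrow(g), 24)  # 6 ordered pairs x 4 amounts
  expect_true(all(g$feasible))
  cell <- g[g$from == "SB" & g$to == "PA" & g$amount == 0.25, ]
  expect_equal(cell$delta, predict_delta(fit, base, "SB", "PA", 0.25))
  expect_equal(cell[, c("conf_low", "conf_high")],
               delta_ci(fit, base, "SB", "PA", 0.25)[, c("conf_low", "conf_high")],
               ignore_attr = TRUE)
  # |delta| grows with the amount when the gradient difference has fixed sign
  for (pair in list(c("SB", "PA"), c("PA", "SL"))) {
    path <- g[g$from == pair[1] & g$to == pair[2], ]
    expect_true(all(diff(abs(path$delta[order(path$amount)])) > 0))
  }
  # reciprocal reallocations: opposite signs, unequal magnitudes
  ab <- g[g$from == "SB" & g$to == "PA" & g$amount == 1, ]$delta
  ba <- g[g$from == "PA" & g$to == "SB" & g$amount == 1, ]$delta
  expect_lt(ab * ba, 0)
  expect_gt(abs(abs(ab) - abs(ba)), 1e-8)
  # percent-of-baseline uses the baseline prediction
  bs <- attr(g, "baseline_score")
  expect_equal(g$pct_of_baseline, 100 * g$delta / bs)

  # infeasible cells are reported, not fatal
  tight <- c(PA = 0.5, SB = 5, SL = 18.5)
  g2 <- substitution_grid(fit, tight)
  expect_true(any(!g2$feasible))
  expect_true(all(is.na(g2$delta[!g2$feasible])))
})
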