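test_that("variation matrix <-> clr covariance identities", {
  T <- default_variation()
  S <- varmat_to_clrcov(T)
  # rows annihilate the ones vector
  expect_lt(max(abs(rowSums(S))), 1e-12)
  # T_ij = S_ii + S_jj - 2 S_ij, checked entrywise by hand arithmetic
  for (i in 1:3) for (j in 1:3) {
    expect_equal(T[i, j], S[i, i] + S[j, j] - 2 * S[i, j], tolerance = 1e-12)
  }
  expect_equal(clrcov_to_varmat(S), T, tolerance = 1e-12)
  # zero dispersion round-trips to zero
  expect_equal(varmat_to_clrcov(matrix(0, 3, 3)), matrix(0, 3, 3),
               tolerance = 1e-15)
  # arbitrary centred covariance round-trips through its variation matrix
  A <- matrix(c(2, -1, 0, -1, 3, 1, 0, 1, 2), 3, 3)
  G <- diag(3) - 1 / 3
  S0 <- G %*% A %*% G
  expect_equal(varmat_to_clrcov(clrcov_to_varmat(S0)), S0, tolerance = 1e-10)
  # log-ratio sds 3, 1, 0.1 violate the triangle inequality -> rejected
  bad <- matrix(c(0, 9, 0.01, 9, 0, 1, 0.01, 1, 0), 3, 3)
  expect_error(varmat_to_clrcov(bad), "not a valid")
})

test_that("logistic-normal draws match the target dispersion and centre", {
  S <- varmat_to_clrcov(default_variation())
  withr::local_seed(91)
  x <- sample_compositions(20000, clr_cov = S)
  expect_equal(rowSums(x), rep(24, 20000), tolerance = 1e-9)
  emp <- variation_matrix(x)
  expect_lt(max(abs(emp - default_variation())), 0.02)
  centre <- comp_mean(x)$mean_hours
  target <- unname(close_composition(c(3.83, 4.59, 11.17)))
  expect_equal(centre, target, tolerance = 0.02)
  # degenerate dispersion: every row is the centre
  x0 <- sample_compositions(5, clr_cov = matrix(0, 3, 3))
  expect_equal(x0, matrix(rep(target, each = 5), 5,
                          dimnames = dimnames(x0)), tolerance = 1e-9)
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- survey_config(n = 50, seed = 123, items = TRUE)
  d1 <- generate_survey(cfg)
  d2 <- generate_survey(cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- generate_survey(survey_config(n = 50, seed = 124, items = TRUE))
  expect_false(identical(d1$pa_hours, d3$pa_hours))
  expect_equal(survey_truth(d1)$seed, 123L)
})

test_that("raw activity columns aggregate back to the drawn behaviours", {
  d <- generate_survey(survey_config(n = 30, seed = 5,
                                     missing_rates = c(qol_total = 0)))
  agg <- aggregate_behaviours(dplyr::select(d, -dplyr::all_of(unname(part_cols()))))
  expect_equal(agg$pa_hours, d$pa_hours, tolerance = 1e-12)
  expect_equal(agg$sb_hours, d$sb_hours, tolerance = 1e-12)
  expect_equal(agg$sl_hours, d$sl_hours, tolerance = 1e-12)
  expect_equal(d$pa_hours + d$sb_hours + d$sl_hours, rep(24, 30),
               tolerance = 1e-9)
})

test_that("noiseless outcomes are recovered exactly by the fit", {
  cfg <- survey_config(n = 200, seed = 9, sigma = 0,
                       missing_rates = c(qol_total = 0, age_years = 0, sex = 0))
  d <- generate_survey(cfg)
  fit <- suppressWarnings(fit_qol_model(d))
  a_hat <- clr_gradient(fit)
  expect_equal(a_hat, cfg$gradient, tolerance = 1e-8)
  co <- coef(fit$lm)
  expect_equal(unname(co[c("age_years", "sex")]), c(cfg$c_age, cfg$c_sex),
               tolerance = 1e-8)
  expect_equal(unname(co[["(Intercept)"]]), cfg$b0, tolerance = 1e-6)
  # zero effects and zero noise give a flat outcome
  flat <- generate_survey(survey_config(
    n = 20, seed = 2, sigma = 0, b0 = 80,
    gradient = c(PA = 0, SB = 0, SL = 0), c_age = 0, c_sex = 0,
    missing_rates = c(qol_total = 0)))
  expect_equal(flat$qol_total, rep(80, 20))
})

test_that("missingness lands at the configured rate; zero rate means none", {
  d0 <- generate_survey(survey_config(
    n = 500, seed = 3,
    missing_rates = c(qol_total = 0, age_years = 0, sex = 0)))
  expect_false(anyNA(d0))
  d <- generate_survey(survey_config(n = 5000, seed = 4,
                                     missing_rates = c(qol_total = 0.03)))
  miss <- mean(is.na(d$qol_total))
  ci <- qbinom(c(0.0005, 0.9995), 5000, 0.03) / 5000  # wide binomial band
  expect_gte(miss, ci[1])
  expect_lte(miss, ci[2])
  expect_error(survey_config(missing_rates = c(qol_total = 0.10)), "missing_rates")
})

test_that("item-level generation reproduces the target score up to the grid", {
  cfg <- survey_config(n = 150, seed = 6, items = TRUE, item_noise = 0,
                       sigma = 0, clip_outcome = TRUE,
                       missing_rates = c(qol_total = 0, age_years = 0, sex = 0))
  d <- generate_survey(cfg)
  expect_true(all(paste0("pedsql_q", 1:23) %in% names(d)))
  # toddler records leave q22/q23 blank
  expect_true(all(is.na(d$pedsql_q22[d$age_years < 5])))
  # with no item noise the scored total sits within half a grid step
  y <- 75.7 + drop(log(as.matrix(d[, unname(part_cols())])) %*%
                     unname(cfg$gradient)) +
    0.5 * d$age_years + 1 * (d$sex == "boy")
  y <- pmin(100, pmax(0, y))
  expect_lt(max(abs(d$qol_total - y)), 12.5)
  # item noise degrades internal consistency
  noisy <- generate_survey(survey_config(n = 400, seed = 7, items = TRUE,
                                         item_noise = 25,
                                         missing_rates = c(qol_total = 0)))
  young <- noisy[noisy$age_years >= 5, paste0("pedsql_q", 1:23)]
  a <- cronbach_alpha(young)
  expect_gt(a, 0.5)
  expect_lt(a, 0.999)
})
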