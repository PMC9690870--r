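test_that("closure rescales proportionally and rejects non-positive parts", {
  expect_equal(close_composition(c(8, 8, 8)), c(8, 8, 8))
  expect_equal(close_composition(c(1, 1, 2)), c(6, 6, 12))
  # scale factor 24 / 19.59
  expect_equal(close_composition(c(3.83, 4.59, 11.17)),
               c(4.69219, 5.62328, 13.68453), tolerance = 1e-5)
  expect_error(close_composition(c(0, 4, 20)), "replace_zeros")
  m <- close_composition(rbind(c(1, 1, 2), c(2, 2, 4)), kappa = 12)
  expect_equal(rowSums(m), c(12, 12))
})

test_that("multiplicative zero replacement preserves the total", {
  out <- replace_zeros(c(0, 4, 20), epsilon = 0.25)
  expect_equal(out, c(0.25, 4 * 23.75 / 24, 20 * 23.75 / 24))
  expect_equal(sum(out), 24)
  expect_equal(replace_zeros(c(3, 9, 12)), c(3, 9, 12))
  expect_error(replace_zeros(c(0, 0, 0)), "invalid record")
})

test_that("clr matches hand values and always sums to zero", {
  expect_equal(clr(c(8, 8, 8)), c(0, 0, 0))
  expect_equal(clr(c(12, 6, 6)), c(0.46210, -0.23105, -0.23105),
               tolerance = 1e-4)
  withr::local_seed(11)
  x <- random_comps(200)
  expect_lt(max(abs(rowSums(clr(x)))), 1e-10)
})

test_that("pivot basis has the stated contrasts, orthonormal zero-sum rows", {
  b <- pivot_basis(c("PA", "SB", "SL"))
  expect_equal(b$contrast[1, ], c(PA = sqrt(2 / 3), SB = -1 / sqrt(6), SL = -1 / sqrt(6)))
  expect_equal(b$contrast[2, ], c(PA = 0, SB = 1 / sqrt(2), SL = -1 / sqrt(2)))
  for (p in c("PA", "SB", "SL")) {
    V <- pivot_basis(c("PA", "SB", "SL"), pivot = p)$contrast
    expect_equal(V %*% t(V), diag(2), ignore_attr = TRUE)
    expect_equal(rowSums(V), c(0, 0))
  }
})

test_that("ilr matches hand values, is closure-invariant, inverts exactly", {
  expect_equal(unname(ilr(c(PA = 8, SB = 8, SL = 8))), c(0, 0))
  expect_equal(unname(ilr(c(PA = 12, SB = 6, SL = 6))),
               c(sqrt(2 / 3) * log(2), 0))
  v <- c(PA = 1.3, SB = 2.1, SL = 9.4)
  expect_equal(ilr(close_composition(7 * v)), ilr(close_composition(v)))
  expect_error(ilr(c(A = 1, B = 2, C = 3)), "labels")

  expect_equal(ilr_inverse(c(0, 0)), c(PA = 8, SB = 8, SL = 8))
  expect_equal(unname(ilr_inverse(c(sqrt(2 / 3) * log(2), 0))), c(12, 6, 6))
  rt <- ilr_inverse(ilr(c(PA = 4.693, SB = 5.624, SL = 13.684)))
  expect_equal(rt, close_composition(c(PA = 4.693, SB = 5.624, SL = 13.684)),
               tolerance = 1e-9)

  withr::local_seed(21)
  x <- random_comps(1000)
  err <- abs(ilr_inverse(ilr(x)) - x)
  expect_lt(max(err), 1e-8)
})

test_that("compositional mean is the geometric-mean centre", {
  x <- rbind(c(PA = 12, SB = 6, SL = 6), c(PA = 6, SB = 12, SL = 6))
  m <- comp_mean(x)
  expect_equal(m$mean_hours, c(8.8656, 8.8656, 6.2689), tolerance = 1e-4)
  # idempotence on identical rows
  same <- rbind(c(PA = 5, SB = 6, SL = 13), c(PA = 5, SB = 6, SL = 13))
  expect_equal(comp_mean(same)$mean_hours, c(5, 6, 13))
  # equals ilr-inverse of the mean ilr vector
  withr::local_seed(31)
  y <- random_comps(50)
  expect_equal(setNames(comp_mean(y)$mean_hours, colnames(y)),
               ilr_inverse(colMeans(ilr(y))), tolerance = 1e-9)
})

test_that("variation matrix: hand example, symmetry, closure invariance", {
  x <- rbind(c(PA = 12, SB = 6, SL = 6), c(PA = 6, SB = 12, SL = 6))
  T <- variation_matrix(x)
  expect_equal(T["PA", "SB"], 2 * log(2)^2, tolerance = 1e-12)
  expect_equal(T["PA", "SL"], log(2)^2 / 2, tolerance = 1e-12)
  expect_equal(T["SB", "SL"], log(2)^2 / 2, tolerance = 1e-12)
  expect_equal(T, t(T))
  expect_equal(diag(T), c(PA = 0, SB = 0, SL = 0))

  same <- rbind(c(PA = 5, SB = 6, SL = 13), c(PA = 5, SB = 6, SL = 13))
  expect_equal(max(abs(variation_matrix(same))), 0)
  expect_error(variation_matrix(same[1, , drop = FALSE]), "at least 2")

  withr::local_seed(41)
  y <- random_comps(30)
  scaled <- y * exp(stats::rnorm(30))  # per-row positive rescaling
  expect_equal(variation_matrix(y), variation_matrix(scaled), tolerance = 1e-12)

  lv <- variation_matrix(tibble::tibble(pa_hours = y[, 1], sb_hours = y[, 2],
                                        sl_hours = y[, 3]), long = TRUE)
  expect_equal(nrow(lv), 6)
  expect_equal(sort(unique(lv$part_1)), c("PA", "SB", "SL"))
})

test_that("ternary coordinates hit the triangle vertices", {
  v <- ternary_coordinates(rbind(c(PA = 24, SB = 1e-12, SL = 1e-12),
                                 c(PA = 1e-12, SB = 24, SL = 1e-12),
                                 c(PA = 1e-12, SB = 1e-12, SL = 24)))
  expect_equal(v$x, c(0, 1, 0.5), tolerance = 1e-10)
  expect_equal(v$y, c(0, 0, sqrt(3) / 2), tolerance = 1e-10)
})

test_that("add_ilr appends coordinates consistent with the matrix route", {
  withr::local_seed(51)
  x <- random_comps(20)
  d <- toy_survey(x)
  out <- add_ilr(d)
  expect_true(all(c("z1", "z2") %in% names(out)))
  expect_equal(cbind(z1 = out$z1, z2 = out$z2), ilr(x))
})
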