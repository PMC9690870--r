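#' Convert a variation matrix to a clr covariance (and back)
#'
#' The pairwise log-ratio variation matrix `T` and the centred-log-ratio
#' covariance `S` of the same data are linked by `S = -1/2 G T G` with
#' `G = I - (1/D) 11'`, equivalently `T[i,j] = S[i,i] + S[j,j] - 2 S[i,j]`.
#' `S` annihilates the ones vector and must be positive semi-definite on the
#' sum-zero subspace for `T` to be a valid dispersion.
#'
#' @param T Symmetric D x D matrix of pairwise log-ratio variances (zero
#'   diagonal, non-negative entries).
#' @return `varmat_to_clrcov`: the D x D clr covariance.
#' @export
varmat_to_clrcov <- function(T) {
  T <- as.matrix(T)
  D <- ncol(T)
  stopifnot(nrow(T) == D, max(abs(T - t(T))) < 1e-10, max(abs(diag(T))) < 1e-12,
            all(T >= 0))
  G <- diag(D) - 1 / D
  S <- -0.5 * G %*% T %*% G
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("variation matrix is not a valid compositional dispersion ",
         "(clr covariance has a negative eigenvalue)", call. = FALSE)
  }
  dimnames(S) <- dimnames(T)
  S
}

#' @rdname varmat_to_clrcov
#' @param S A clr covariance matrix (rows/columns sum to ~0).
#' @return `clrcov_to_varmat`: the variation matrix of `S`.
#' @export
clrcov_to_varmat <- function(S) {
  v <- diag(S)
  T <- outer(v, v, "+") - 2 * S
  diag(T) <- 0
  dimnames(T) <- dimnames(S)
  T
}

#' Survey generator configuration
#'
#' The stated world of the generator: a logistic-normal three-part daily
#' composition whose variation matrix matches the reported pooled-survey
#' magnitudes (pairwise log-ratio variances 0.36-0.50) and whose centre is
#' the reported 2021 mean day (PA 3.83, SB 4.59, SL 11.17 h, closed to 24 h);
#' a QoL outcome linear in the log parts with a clr gradient on the reported
#' 2021 effect scale, age and sex effects, and additive Gaussian noise; age
#' uniform on [2, 6); sex balanced; missingness under 5%.
#'
#' @param n Number of records.
#' @param seed Integer seed; all randomness in [generate_survey()] flows from
#'   it.
#' @param variation Target variation matrix (3 x 3). Default: pairwise
#'   variances PA-SB 0.50, PA-SL 0.36, SB-SL 0.41.
#' @param center Mean composition in hours (closed internally). Default
#'   `c(PA = 3.83, SB = 4.59, SL = 11.17)`.
#' @param kappa Closure constant. Default 24.
#' @param b0 Outcome intercept. Default 75.7 (puts the mean QoL near 77.6).
#' @param gradient clr gradient `a` (named, sums to 0). Default
#'   `c(2.82, -2.61, -0.21) / sqrt(1.5)` — the reported 2021 pivot
#'   coefficients on the clr scale.
#' @param c_age,c_sex Covariate effects (QoL points per year; boy vs girl).
#' @param sigma Residual standard deviation in QoL points. Default 13.
#' @param age_range Uniform age range in years. Default `c(2, 6)`.
#' @param p_boy Probability a child is a boy. Default 0.5.
#' @param missing_rates Named missingness probabilities for `qol_total`,
#'   `age_years`, `sex` (each must be < 0.05).
#' @param items If `TRUE`, generate raw PedsQL item responses whose score
#'   reproduces the drawn outcome up to the 0-4 grid.
#' @param item_noise Per-item noise (0-100 scale points) controlling
#'   internal consistency when `items = TRUE`. Default 12.
#' @param clip_outcome Clip QoL to [0, 100]. Off by default: truncation
#'   biases the linear-model recovery the generator exists to test.
#' @param year Calendar year stamped on the records. Default 2021.
#' @return A list of class `survey_config`.
#' @export
survey_config <- function(n = 1000, seed = 1L,
                          variation = default_variation(),
                          center = c(PA = 3.83, SB = 4.59, SL = 11.17),
                          kappa = 24, b0 = 75.7,
                          gradient = c(PA = 2.82, SB = -2.61, SL = -0.21) / sqrt(1.5),
                          c_age = 0.5, c_sex = 1, sigma = 13,
                          age_range = c(2, 6), p_boy = 0.5,
                          missing_rates = c(qol_total = 0.03, age_years = 0.02,
                                            sex = 0.02),
                          items = FALSE, item_noise = 12,
                          clip_outcome = FALSE, year = 2021) {
  stopifnot(n >= 1, is.numeric(seed), all(center > 0),
            abs(sum(gradient)) < 1e-6, sigma >= 0,
            all(missing_rates >= 0), all(missing_rates < 0.05))
  S <- varmat_to_clrcov(variation)
  structure(list(
    n = as.integer(n), seed = as.integer(seed), variation = variation,
    clr_cov = S, center = close_composition(center, kappa), kappa = kappa,
    b0 = b0, gradient = gradient[names(center)], c_age = c_age, c_sex = c_sex,
    sigma = sigma, age_range = age_range, p_boy = p_boy,
    missing_rates = missing_rates, items = items, item_noise = item_noise,
    clip_outcome = clip_outcome, year = year
  ), class = "survey_config")
}

#' Default target variation matrix
#'
#' Pairwise log-ratio variances on the reported 2021 scale: PA-SB 0.50,
#' PA-SL 0.36, SB-SL 0.41.
#'
#' @return 3 x 3 labelled variation matrix.
#' @export
default_variation <- function() {
  labs <- c("PA", "SB", "SL")
  T <- matrix(c(0, 0.50, 0.36,
                0.50, 0, 0.41,
                0.36, 0.41, 0), 3, 3, dimnames = list(labs, labs))
  T
}

#' Residual sd that yields a target model R-squared
#'
#' Under the generator, the explained variance is
#' `a' S a + c_age^2 var(age) + c_sex^2 p(1-p)` with `S` the clr covariance,
#' so `sigma^2 = explained * (1 - R2) / R2`.
#'
#' @param config A [survey_config()].
#' @param r2 Target coefficient of determination.
#' @return Residual standard deviation.
#' @export
sigma_for_r2 <- function(config, r2) {
  stopifnot(r2 > 0, r2 < 1)
  a <- config$gradient
  expl <- drop(t(a) %*% config$clr_cov %*% a) +
    config$c_age^2 * diff(config$age_range)^2 / 12 +
    config$c_sex^2 * config$p_boy * (1 - config$p_boy)
  sqrt(expl * (1 - r2) / r2)
}

#' Draw logistic-normal daily compositions
#'
#' clr vectors are drawn from a multivariate normal with mean `clr(center)`
#' and the (singular, sum-zero) clr covariance, exponentiated and closed.
#'
#' @param n Number of compositions.
#' @param center Mean composition (hours).
#' @param clr_cov clr covariance matrix (e.g. from [varmat_to_clrcov()]).
#' @param kappa Closure constant. Default 24.
#' @return n x 3 matrix of hours, columns named by the parts.
#' @export
sample_compositions <- function(n, center = c(PA = 3.83, SB = 4.59, SL = 11.17),
                                clr_cov = varmat_to_clrcov(default_variation()),
                                kappa = 24) {
  mu <- clr(close_composition(center, kappa))
  z <- MASS::mvrnorm(n, mu = mu, Sigma = clr_cov)
  if (n == 1) z <- matrix(z, 1)
  colnames(z) <- names(center)
  clr_inverse(z, kappa)
}

#' Draw QoL outcomes from the generating model
#'
#' `y = b0 + sum_p a_p ln x_p + c_age age + c_sex sex + e`,
#' `e ~ N(0, sigma^2)`.
#'
#' @param comps Matrix of compositions (hours), columns named by parts.
#' @param ages Numeric ages in years.
#' @param sexes 0/1 (girl/boy) vector, or character `"girl"`/`"boy"`.
#' @param config A [survey_config()].
#' @return Numeric QoL vector (clipped to [0, 100] only if the config says
#'   so).
#' @export
sample_outcome <- function(comps, ages, sexes, config) {
  sex01 <- if (is.numeric(sexes)) sexes else as.numeric(sexes == "boy")
  a <- config$gradient[colnames(comps)]
  y <- config$b0 + drop(log(comps) %*% a) + config$c_age * ages +
    config$c_sex * sex01 +
    stats::rnorm(nrow(comps), 0, config$sigma)
  if (config$clip_outcome) y <- pmin(100, pmax(0, y))
  y
}

## fixed split of each behaviour into its raw activity columns
activity_split <- function() {
  list(
    PA = c(chores_hours = 0.15, indoor_play_hours = 0.45, outdoor_play_hours = 0.40),
    SB = c(screen_learning_hours = 0.25, screen_entertainment_hours = 0.35,
           reading_hours = 0.20, crafts_hours = 0.20),
    SL = c(nap_hours = 0.15, night_sleep_hours = 0.85)
  )
}

## distribute a target 0-100 score over raw 0-4 items with per-item noise
make_items <- function(y, n_items, item_noise) {
  t(vapply(y, function(yi) {
    s <- pmin(100, pmax(0, yi + stats::rnorm(n_items, 0, item_noise)))
    as.integer(round((100 - s) / 25))
  }, integer(n_items)))
}

#' Generate a full synthetic survey wave
#'
#' Draws compositions, demographics and outcomes from the configured model,
#' expands the behaviours into raw activity-duration columns that aggregate
#' back exactly, optionally generates PedsQL item responses, and injects
#' missingness. Identical seeds give identical tables.
#'
#' @param config A [survey_config()].
#' @return Tibble of survey records (`id`, `year`, `age_years`, `sex`, raw
#'   activity columns, `pa_hours`/`sb_hours`/`sl_hours`, `qol_total`, and
#'   item columns when configured), with attributes `config` and `truth`
#'   (the generating parameters) readable via [survey_truth()].
#' @export
generate_survey <- function(config = survey_config()) {
  stopifnot(inherits(config, "survey_config"))
  withr::with_seed(config$seed, {
    n <- config$n
    x <- sample_compositions(n, config$center, config$clr_cov, config$kappa)
    ages <- stats::runif(n, config$age_range[1], config$age_range[2])
    sexes <- ifelse(stats::rbinom(n, 1, config$p_boy) == 1, "boy", "girl")
    y <- sample_outcome(x, ages, sexes, config)

    out <- tibble::tibble(id = seq_len(n), year = config$year,
                          age_years = ages, sex = sexes)
    for (lab in names(activity_split())) {
      w <- activity_split()[[lab]]
      for (col in names(w)) out[[col]] <- w[[col]] * x[, lab]
    }
    out$pa_hours <- x[, "PA"]; out$sb_hours <- x[, "SB"]; out$sl_hours <- x[, "SL"]

    if (config$items) {
      items <- make_items(y, 23, config$item_noise)
      colnames(items) <- paste0("pedsql_q", 1:23)
      toddler <- ages < 5
      items[toddler, c("pedsql_q22", "pedsql_q23")] <- NA_integer_
      out <- dplyr::bind_cols(out, tibble::as_tibble(items))
      out$qol_total <- score_pedsql(out)$qol_total
    } else {
      out$qol_total <- y
    }

    for (f in names(config$missing_rates)) {
      r <- config$missing_rates[[f]]
      if (r > 0 && f %in% names(out)) {
        out[[f]][stats::runif(n) < r] <- NA
      }
    }
    attr(out, "config") <- config
    attr(out, "truth") <- list(b0 = config$b0, gradient = config$gradient,
                               c_age = config$c_age, c_sex = config$c_sex,
                               sigma = config$sigma,
                               center = config$center,
                               variation = config$variation,
                               seed = config$seed)
    out
  })
}

#' Generating parameters of a synthetic survey
#' @param data A tibble returned by [generate_survey()].
#' @return Named list of true parameters (including the seed), or `NULL`.
#' @export
survey_truth <- function(data) attr(data, "truth")
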