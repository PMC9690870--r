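#' Specify and fit the adjusted compositional QoL model
#'
#' Linear regression of a quality-of-life score on the two ilr pivot
#' coordinates of the daily (PA, SB, SL) composition, adjusted for age and
#' sex: `y = b0 + b1 z1 + b2 z2 + c_age age + c_sex sex + e`. Sex is coded
#' girl = 0, boy = 1. Records with a missing outcome are excluded and
#' counted.
#'
#' @param data Cleaned survey records with the part columns, the outcome and
#'   the covariates.
#' @param outcome Outcome column name. Default `"qol_total"`.
#' @param parts Named character vector of part columns, see [part_cols()].
#' @param covariates Covariate column names. Default `c("age_years", "sex")`.
#' @param basis The [pivot_basis()] giving the ilr coordinates. Coefficients
#'   depend on the basis; predictions do not.
#' @param year Optional single year to filter on (`year` column).
#' @param epsilon Zero-replacement duration. Default 0.25 h.
#' @param kappa Closure constant. Default 24.
#' @return An object of class `qol_fit`: the underlying `lm` fit plus the
#'   basis, design metadata, `r_squared`, overall-F `p_value`, `n` and
#'   residual `df`. Methods: [tidy()], [glance()], `predict()`, `print()`.
#' @export
fit_qol_model <- function(data, outcome = "qol_total", parts = part_cols(),
                          covariates = c("age_years", "sex"),
                          basis = pivot_basis(names(parts)), year = NULL,
                          epsilon = 0.25, kappa = 24) {
  stopifnot(outcome %in% names(data), all(covariates %in% names(data)))
  data <- tibble::as_tibble(data)
  if (!is.null(year)) {
    stopifnot("year" %in% names(data))
    data <- data[!is.na(data$year) & data$year == year, , drop = FALSE]
  }
  dropped <- sum(is.na(data[[outcome]]))
  data <- data[!is.na(data[[outcome]]), , drop = FALSE]

  d <- build_design(data, basis = basis, parts = parts,
                    covariates = covariates, outcome = outcome,
                    epsilon = epsilon, kappa = kappa)
  p <- ncol(d$X)  # includes intercept
  if (nrow(d$X) <= p) stop("need more records than model terms", call. = FALSE)

  df_fit <- as.data.frame(d$X[, -1, drop = FALSE])
  df_fit$.y <- d$y
  fit <- stats::lm(.y ~ ., data = df_fit)
  if (fit$rank < p) stop("singular design matrix: collinear columns", call. = FALSE)
  sm <- summary(fit)
  # guard the degenerate constant-outcome case (0/0 in summary.lm's R^2)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((d$y - mean(d$y))^2)
  r2 <- if (tss < 1e-12) 0 else 1 - rss / tss
  fval <- (r2 / (p - 1)) / ((1 - r2) / fit$df.residual)
  structure(list(
    lm = fit,
    basis = basis,
    parts = parts,
    covariates = covariates,
    outcome = outcome,
    kappa = kappa,
    epsilon = epsilon,
    covariate_means = colMeans(d$X[, covariates, drop = FALSE]),
    n = nrow(d$X),
    df_residual = fit$df.residual,
    dropped_missing_outcome = dropped,
    r_squared = r2,
    p_value = stats::pf(fval, p - 1, fit$df.residual, lower.tail = FALSE),
    sigma = sm$sigma
  ), class = "qol_fit")
}

#' Build the regression design matrix
#'
#' Columns `(Intercept), z1, z2, <covariates>` and the outcome vector. Sex is
#' recoded girl = 0 / boy = 1 when given as character or factor.
#'
#' @inheritParams fit_qol_model
#' @return List with `X` (matrix) and `y` (numeric vector).
#' @export
build_design <- function(data, basis = pivot_basis(names(parts)),
                         parts = part_cols(), covariates = c("age_years", "sex"),
                         outcome = "qol_total", epsilon = 0.25, kappa = 24) {
  x <- comp_matrix(data, parts, kappa = kappa, epsilon = epsilon)
  z <- ilr(x, basis)
  cov_mat <- vapply(covariates, function(cn) code_covariate(data[[cn]], cn),
                    numeric(nrow(data)))
  cov_mat <- matrix(cov_mat, nrow = nrow(data),
                    dimnames = list(NULL, covariates))
  X <- cbind(`(Intercept)` = 1, z, cov_mat)
  list(X = X, y = as.numeric(data[[outcome]]))
}

code_covariate <- function(v, name) {
  if (is.numeric(v)) return(as.numeric(v))
  v <- tolower(as.character(v))
  known <- c(girl = 0, female = 0, f = 0, boy = 1, male = 1, m = 1)
  out <- unname(known[v])
  if (any(is.na(out) & !is.na(v))) {
    stop("cannot code covariate `", name, "`: values must be numeric or ",
         "girl/boy", call. = FALSE)
  }
  out
}

#' @export
print.qol_fit <- function(x, ...) {
  cat("<qol_fit>", x$outcome, "~ ilr(", paste(x$basis$labels, collapse = ", "),
      ") +", paste(x$covariates, collapse = " + "), "\n")
  cat(sprintf("  n = %d, R^2 = %.3f, overall p = %.3g\n",
              x$n, x$r_squared, x$p_value))
  print(round(stats::coef(x$lm), 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy qol_fit
#' @export
tidy.qol_fit <- function(x, ...) {
  sm <- summary(x$lm)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
                 statistic = sm[, 3], p_value = sm[, 4])
}

#' @method glance qol_fit
#' @export
glance.qol_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, p_value = x$p_value,
                 sigma = x$sigma, n = x$n, df_residual = x$df_residual)
}

#' @export
predict.qol_fit <- function(object, newdata, ...) {
  d <- build_design(newdata, basis = object$basis, parts = object$parts,
                    covariates = object$covariates, outcome = object$outcome,
                    epsilon = object$epsilon, kappa = object$kappa)
  drop(d$X %*% coef_vector(object))
}

## full coefficient vector in design-column order
coef_vector <- function(fit) {
  stats::coef(fit$lm)[c("(Intercept)", paste0("z", seq_len(length(fit$basis$labels) - 1)),
                        fit$covariates)]
}

## coefficient covariance in the same order
coef_vcov <- function(fit) {
  V <- stats::vcov(fit$lm)
  ord <- c("(Intercept)", paste0("z", seq_len(length(fit$basis$labels) - 1)),
           fit$covariates)
  V[ord, ord]
}

#' Per-behaviour pivot coefficients
#'
#' Refits the model three times, each with a pivot basis placing one
#' behaviour first, and reports that fit's first-coordinate coefficient: the
#' effect of the behaviour relative to the (geometric mean of the) remaining
#' behaviours. The three coefficients of one fitted effect surface sum to
#' zero exactly, up to numerical tolerance — a reported set that does not is
#' internally inconsistent.
#'
#' @inheritParams fit_qol_model
#' @return A tibble of class `pivot_betas` with one row per behaviour:
#'   `part`, `beta`, `std_error`, `statistic`, `p_value`, plus the model-level
#'   `r_squared`/`p_value` stored as attributes `glance`.
#' @export
pivot_betas <- function(data, outcome = "qol_total", parts = part_cols(),
                        covariates = c("age_years", "sex"), year = NULL,
                        epsilon = 0.25, kappa = 24) {
  labs <- names(parts)
  rows <- purrr::map(labs, function(p) {
    fit <- fit_qol_model(data, outcome = outcome, parts = parts,
                         covariates = covariates,
                         basis = pivot_basis(labs, pivot = p), year = year,
                         epsilon = epsilon, kappa = kappa)
    td <- tidy(fit)
    z1 <- td[td$term == "z1", ]
    tibble::tibble(part = p, beta = z1$estimate, std_error = z1$std_error,
                   statistic = z1$statistic, p_value = z1$p_value,
                   .glance = list(glance(fit)))
  })
  out <- dplyr::bind_rows(rows)
  gl <- out$.glance[[1]]
  out$.glance <- NULL
  structure(out, glance = gl, class = c("pivot_betas", class(out)))
}

#' Re-express pivot coefficients as a centred log-ratio gradient
#'
#' The fitted compositional effect, written on the clr scale:
#' `a_p = beta_p / sqrt(D / (D - 1))` (for D = 3, `beta_p / sqrt(3/2)`), so
#' that the predicted difference between two compositions is
#' `sum_p a_p * (ln x'_p - ln x_p)`. The gradient sums to zero. A beta set
#' whose sum exceeds 0.05 in absolute value cannot come from one fitted model
#' and triggers a warning.
#'
#' @param object A `qol_fit`, a `pivot_betas` table, or a named numeric
#'   vector of per-behaviour pivot coefficients.
#' @param ... Unused.
#' @return Named numeric clr-gradient vector summing to ~0.
#' @export
clr_gradient <- function(object, ...) UseMethod("clr_gradient")

#' @export
clr_gradient.qol_fit <- function(object, ...) {
  b <- stats::coef(object$lm)[paste0("z", seq_len(length(object$basis$labels) - 1))]
  a <- drop(crossprod(object$basis$contrast, b))
  names(a) <- object$basis$labels
  a[names(object$parts)]
}

#' @export
clr_gradient.pivot_betas <- function(object, ...) {
  clr_gradient(stats::setNames(object$beta, object$part))
}

#' @export
clr_gradient.numeric <- function(object, ...) {
  stopifnot(!is.null(names(object)))
  D <- length(object)
  s <- sum(object)
  if (abs(s) > 0.05) {
    warning(sprintf(paste0("pivot coefficients sum to %.2f, not 0: the set is ",
                           "internally inconsistent and the gradient is only ",
                           "approximate"), s))
  }
  object / sqrt(D / (D - 1))
}

#' One-way analysis of variance across groups
#'
#' Classical one-way F test (equal-variance), e.g. for differences in an
#' outcome or behaviour across survey years.
#'
#' @param data Data frame.
#' @param value Name of the numeric response column.
#' @param group Name of the grouping column.
#' @return Tibble with `statistic` (F), `df_between`, `df_within`, `p_value`.
#' @export
oneway_anova <- function(data, value, group) {
  y <- data[[value]]
  g <- factor(data[[group]])
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  a <- stats::anova(stats::lm(y ~ g))
  tibble::tibble(statistic = a$`F value`[1], df_between = a$Df[1],
                 df_within = a$Df[2], p_value = a$`Pr(>F)`[1])
}

#' Residual diagnostics for a fitted QoL model
#'
#' Linearity/normality are reported, not gatekept: residual skewness and
#' excess kurtosis, plus theoretical-vs-sample quantile pairs for an external
#' Q-Q plot.
#'
#' @param fit A `qol_fit`.
#' @param probs Quantile probabilities for the Q-Q data.
#' @return List with `summary` (tibble: skewness, excess kurtosis, residual
#'   sd) and `qq` (tibble: `theoretical`, `sample`).
#' @export
model_diagnostics <- function(fit, probs = stats::ppoints(100)) {
  r <- stats::residuals(fit$lm)
  m <- mean(r); s <- stats::sd(r)
  skew <- mean((r - m)^3) / s^3
  kurt <- mean((r - m)^4) / s^4 - 3
  list(
    summary = tibble::tibble(skewness = skew, excess_kurtosis = kurt,
                             residual_sd = s),
    qq = tibble::tibble(theoretical = stats::qnorm(probs, m, s),
                        sample = unname(stats::quantile(r, probs, type = 7)))
  )
}
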