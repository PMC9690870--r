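#' Reallocate time between two behaviours
#'
#' Moves `amount` hours from the donor to the recipient behaviour, leaving
#' the third part and the daily total unchanged — the elementary move of
#' isotemporal substitution.
#'
#' @param baseline Named positive vector of baseline hours (e.g.
#'   `c(PA = 3.83, SB = 4.59, SL = 11.17)`).
#' @param from,to Donor and recipient behaviour labels.
#' @param amount Hours to move; must be smaller than the donor's baseline
#'   hours.
#' @return The reallocated composition (named vector).
#' @export
#' @examples
#' reallocate(c(PA = 4, SB = 5, SL = 15), "SB", "PA", 0.25)
reallocate <- function(baseline, from, to, amount) {
  stopifnot(from %in% names(baseline), to %in% names(baseline),
            from != to, amount >= 0)
  if (amount >= baseline[[from]]) {
    stop(sprintf("infeasible reallocation: %.2f h exceeds the %.2f h available in %s",
                 amount, baseline[[from]], from), call. = FALSE)
  }
  baseline[from] <- baseline[[from]] - amount
  baseline[to] <- baseline[[to]] + amount
  baseline
}

## extract a clr gradient from whatever describes the fitted effect
as_gradient <- function(object) {
  if (inherits(object, "qol_fit") || inherits(object, "pivot_betas")) {
    clr_gradient(object)
  } else if (is.numeric(object) && !is.null(names(object))) {
    if (abs(sum(object)) < 1e-6) object else clr_gradient(object)
  } else {
    stop("`object` must be a qol_fit, a pivot_betas table, a clr gradient, ",
         "or named pivot coefficients", call. = FALSE)
  }
}

#' Predicted QoL change for one time reallocation
#'
#' The model is linear in the log parts, so the predicted change is
#' `delta = sum_p a_p * (ln x'_p - ln x_p)` with `a` the clr gradient and
#' `x'` the reallocated composition. Age and sex terms cancel in the
#' difference.
#'
#' @param object A fitted `qol_fit`, a `pivot_betas` table, a clr-gradient
#'   vector (sums to ~0), or named pivot coefficients (rescaled internally).
#' @inheritParams reallocate
#' @return Predicted outcome change in QoL points.
#' @export
predict_delta <- function(object, baseline, from, to, amount) {
  a <- as_gradient(object)
  stopifnot(setequal(names(a), names(baseline)))
  shifted <- reallocate(baseline, from, to, amount)
  sum(a[names(baseline)] * (log(shifted) - log(baseline))[names(baseline)])
}

#' Confidence interval for a reallocation's predicted change
#'
#' The change is linear in the fitted coefficients with contrast
#' `d = (0, dz1, dz2, 0, ...)` where `dz` is the ilr displacement of the
#' reallocation, so `Var(delta) = d' V d` with `V` the coefficient
#' covariance; the interval is `delta +/- q * sqrt(Var)` with `q` a
#' t quantile on the residual degrees of freedom (or a normal quantile).
#'
#' @param fit A `qol_fit` (carries the coefficient covariance).
#' @inheritParams reallocate
#' @param level Confidence level. Default 0.95.
#' @param quantile `"t"` (default) or `"normal"`.
#' @return Tibble with `delta`, `conf_low`, `conf_high`, `std_error`,
#'   `p_value`.
#' @export
delta_ci <- function(fit, baseline, from, to, amount, level = 0.95,
                     quantile = c("t", "normal")) {
  quantile <- match.arg(quantile)
  if (!inherits(fit, "qol_fit")) {
    stop("confidence intervals need a fitted model with a coefficient ",
         "covariance; got ", class(fit)[1], call. = FALSE)
  }
  shifted <- reallocate(baseline, from, to, amount)
  dz <- ilr(close_composition(shifted, fit$kappa), fit$basis) -
    ilr(close_composition(baseline, fit$kappa), fit$basis)
  d <- c(0, dz, numeric(length(fit$covariates)))
  delta <- predict_delta(fit, baseline, from, to, amount)
  se <- sqrt(drop(t(d) %*% coef_vcov(fit) %*% d))
  q <- if (quantile == "t") stats::qt(1 - (1 - level) / 2, fit$df_residual)
       else stats::qnorm(1 - (1 - level) / 2)
  p <- if (se == 0) as.numeric(delta != 0) * 0 else {
    tt <- delta / se
    if (quantile == "t") 2 * stats::pt(-abs(tt), fit$df_residual)
    else 2 * stats::pnorm(-abs(tt))
  }
  tibble::tibble(delta = delta, conf_low = delta - q * se,
                 conf_high = delta + q * se, std_error = se, p_value = p)
}

#' Baseline composition for substitution
#'
#' The compositional (geometric) mean closed to `kappa` is the standard
#' baseline for compositional isotemporal substitution; the arithmetic mean
#' of the raw hours is available for reproducing analyses that tabulated
#' arithmetic means.
#'
#' @inheritParams comp_mean
#' @param type `"geometric"` (default) or `"arithmetic"`.
#' @return Named baseline vector of hours. The arithmetic baseline is not
#'   closed (it keeps the raw-hours total).
#' @export
substitution_baseline <- function(data, parts = part_cols(),
                                  type = c("geometric", "arithmetic"),
                                  kappa = 24) {
  type <- match.arg(type)
  if (type == "geometric") {
    m <- comp_mean(data, parts, kappa)
    return(stats::setNames(m$mean_hours, m$part))
  }
  x <- as.matrix(data[, unname(parts), drop = FALSE])
  stats::setNames(colMeans(x), names(parts))
}

#' Grid of all pairwise reallocations
#'
#' Evaluates every ordered donor-to-recipient pair at each amount (default
#' 15, 30, 45, 60 minutes): 6 pairs x 4 amounts = 24 cells for three
#' behaviours. Each cell carries the predicted change, its confidence
#' interval (when `object` is a fitted model), the change as a percentage of
#' the baseline predicted score, and a significance flag. An infeasible cell
#' is reported with `feasible = FALSE`, not dropped.
#'
#' @inheritParams predict_delta
#' @param amounts Reallocation amounts in hours. Default `c(0.25, 0.5, 0.75, 1)`.
#' @param level Confidence level. Default 0.95.
#' @param baseline_score Baseline predicted score BS used for
#'   `pct_of_baseline`. For a `qol_fit` it defaults to the model prediction
#'   at the baseline composition with covariates at their sample means; for a
#'   bare gradient it must be supplied (otherwise the percentage is `NA`).
#' @return A tibble of class `qol_substitution`: `from`, `to`, `amount`,
#'   `delta`, `conf_low`, `conf_high`, `pct_of_baseline`, `significant`,
#'   `feasible`; attribute `baseline_score`.
#' @export
substitution_grid <- function(object, baseline, amounts = c(0.25, 0.5, 0.75, 1),
                              level = 0.95, baseline_score = NULL) {
  labs <- names(baseline)
  has_ci <- inherits(object, "qol_fit")
  if (is.null(baseline_score) && has_ci) {
    z <- ilr(close_composition(baseline, object$kappa), object$basis)
    baseline_score <- drop(c(1, z, object$covariate_means) %*% coef_vector(object))
  }
  pairs <- expand.grid(from = labs, to = labs, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  grid <- tidyr::expand_grid(amount = amounts,
                             tibble::as_tibble(pairs))[, c("from", "to", "amount")]
  rows <- purrr::pmap(grid, function(from, to, amount) {
    feasible <- amount < baseline[[from]]
    if (!feasible) {
      return(tibble::tibble(delta = NA_real_, conf_low = NA_real_,
                            conf_high = NA_real_, p_value = NA_real_,
                            feasible = FALSE))
    }
    if (has_ci) {
      ci <- delta_ci(object, baseline, from, to, amount, level = level)
      tibble::tibble(delta = ci$delta, conf_low = ci$conf_low,
                     conf_high = ci$conf_high, p_value = ci$p_value,
                     feasible = TRUE)
    } else {
      tibble::tibble(delta = predict_delta(object, baseline, from, to, amount),
                     conf_low = NA_real_, conf_high = NA_real_,
                     p_value = NA_real_, feasible = TRUE)
    }
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(rows))
  out$pct_of_baseline <- if (is.null(baseline_score)) NA_real_ else
    100 * out$delta / baseline_score
  out$significant <- !is.na(out$conf_low) &
    (out$conf_low > 0 | out$conf_high < 0)
  out <- dplyr::arrange(out, .data$amount, .data$from, .data$to)
  structure(out, baseline_score = baseline_score,
            class = c("qol_substitution", class(out)))
}

#' @method tidy qol_substitution
#' @export
tidy.qol_substitution <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "qol_substitution")
  attr(out, "baseline_score") <- NULL
  out
}
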