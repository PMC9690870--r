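#' Assign records to uniform quantile groups
#'
#' Cut points are the `i/k` sample quantiles (linear-interpolation
#' definition, R type 7); a score exactly on a cut point goes to the lower
#' group, deterministically. When ties collapse all cut points the whole
#' sample lands in group 1 with a warning.
#'
#' @param scores Numeric vector (e.g. QoL totals); `NA` allowed and returned
#'   as `NA` group.
#' @param k Number of groups. Default 4.
#' @return Integer vector of group indices in `1..k`, with the cut points as
#'   attribute `cut_points`.
#' @export
#' @examples
#' assign_quantiles(c(50, 60, 70, 80, 90, 95), k = 3)
assign_quantiles <- function(scores, k = 4) {
  ok <- !is.na(scores)
  if (sum(ok) < k) stop("need at least k = ", k, " scores", call. = FALSE)
  cuts <- stats::quantile(scores[ok], probs = seq_len(k - 1) / k, type = 7,
                          names = FALSE)
  if (length(unique(scores[ok])) == 1) {
    warning("all scores are equal; every record assigned to group 1")
    g <- rep(NA_integer_, length(scores))
    g[ok] <- 1L
    return(structure(g, cut_points = cuts))
  }
  g <- rep(NA_integer_, length(scores))
  # right-closed intervals: a score on a cut point falls in the lower group
  g[ok] <- 1L + vapply(scores[ok], function(s) sum(cuts < s), integer(1))
  structure(g, cut_points = cuts)
}

#' Quantile-group compositional profiles
#'
#' Groups records by outcome quantiles and expresses each group's
#' compositional mean relative to the overall compositional mean:
#' `ln(m_gp / m_p)` per group `g` and part `p`, where `m` are closed
#' compositional means. The pooled sample profiles to zero; the quantity is
#' invariant to the closure constant. This is the plotted quantity of a
#' compositional geometric-mean bar chart by outcome level.
#'
#' @inheritParams comp_mean
#' @param score Outcome column used for grouping. Default `"qol_total"`.
#' @param k Number of quantile groups. Default 4.
#' @param epsilon Zero-replacement duration. Default 0.25 h.
#' @return Long tibble: `quantile` (1..k), `part`, `log_ratio`, `n`. Empty
#'   groups yield `NA` log-ratios.
#' @export
quantile_profile <- function(data, score = "qol_total", parts = part_cols(),
                             k = 4, kappa = 24, epsilon = 0.25) {
  stopifnot(score %in% names(data))
  g <- assign_quantiles(data[[score]], k = k)
  x <- comp_matrix(data[!is.na(g), , drop = FALSE], parts, kappa, epsilon)
  g <- g[!is.na(g)]
  overall <- stats::setNames(comp_mean(x, kappa = kappa)$mean_hours,
                             colnames(x))
  purrr::map_dfr(seq_len(k), function(q) {
    rows <- g == q
    if (!any(rows)) {
      return(tibble::tibble(quantile = q, part = names(overall),
                            log_ratio = NA_real_, n = 0L))
    }
    m <- stats::setNames(comp_mean(x[rows, , drop = FALSE], kappa = kappa)$mean_hours,
                         colnames(x))
    tibble::tibble(quantile = q, part = names(overall),
                   log_ratio = unname(log(m / overall)), n = sum(rows))
  })
}
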