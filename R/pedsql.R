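#' PedsQL form layout for an age band
#'
#' The parent-proxy PedsQL has 21 items for the toddler band (ages 2-4) and 23
#' for the young-child band (ages 5+): physical functioning (8 items),
#' emotional (5), social (5) and school functioning (3 on the toddler form, 5
#' on the young-child form). The band boundary is the fifth birthday.
#'
#' @param age_years Numeric vector of child ages in years.
#' @return A list per unique layout is not needed: returns a character vector
#'   (`"toddler"` or `"young_child"`) aligned with `age_years`.
#' @export
pedsql_form <- function(age_years) {
  ifelse(age_years >= 5, "young_child", "toddler")
}

## item columns per dimension for each form
pedsql_dimensions <- function(form) {
  school <- if (form == "toddler") paste0("pedsql_q", 19:21) else paste0("pedsql_q", 19:23)
  list(
    physical  = paste0("pedsql_q", 1:8),
    emotional = paste0("pedsql_q", 9:13),
    social    = paste0("pedsql_q", 14:18),
    school    = school
  )
}

#' Transform a raw PedsQL item response to the 0-100 scale
#'
#' Raw responses run 0 ("never a problem") to 4 ("almost always") and are
#' reverse-mapped to 100, 75, 50, 25, 0: `score = 100 - 25 * raw`.
#'
#' @param raw Integer vector of raw responses in 0..4 (`NA` allowed).
#' @return Numeric vector of item scores on the 0-100 scale.
#' @export
#' @examples
#' pedsql_item_score(0:4)
pedsql_item_score <- function(raw) {
  bad <- !is.na(raw) & (raw < 0 | raw > 4 | raw != round(raw))
  if (any(bad)) {
    stop("raw PedsQL responses must be integers in 0..4 (got ",
         paste(unique(raw[bad]), collapse = ", "), ")", call. = FALSE)
  }
  100 - 25 * raw
}

## mean over answered items; NA when none answered
item_mean <- function(scores) {
  k <- sum(!is.na(scores))
  if (k == 0) return(NA_real_)
  sum(scores, na.rm = TRUE) / k
}

#' Score PedsQL item responses
#'
#' Computes, per child: the four dimension scores (mean of transformed scores
#' over answered items of the dimension), the physical summary (= physical
#' dimension), the psychosocial summary and the total score (mean over all
#' answered items of the form). A dimension with no answered item is missing;
#' a record with no answered item at all gets a missing total.
#'
#' @param data Data frame with item columns `pedsql_q1` .. `pedsql_q23`
#'   (q22-q23 absent or `NA` for the toddler form) holding raw 0-4 responses,
#'   and an age column selecting the form.
#' @param age Name of the age column. Default `"age_years"`.
#' @param psychosocial Either `"item_mean"` (mean over all answered
#'   emotional + social + school items — the literal scale-level rule, the
#'   default) or `"dimension_mean"` (mean of the three dimension scores).
#' @param min_items_prop Minimum proportion of a dimension's (or form's) items
#'   that must be answered for a score to be produced. Default 0 (any answered
#'   item scores); set to 0.5 for the conventional half-items rule.
#' @return The input data as a tibble with columns `qol_physical`,
#'   `qol_emotional`, `qol_social`, `qol_school`, `qol_psychosocial`,
#'   `qol_total` appended.
#' @export
score_pedsql <- function(data, age = "age_years",
                         psychosocial = c("item_mean", "dimension_mean"),
                         min_items_prop = 0) {
  psychosocial <- match.arg(psychosocial)
  stopifnot(age %in% names(data), min_items_prop >= 0, min_items_prop <= 1)
  forms <- pedsql_form(data[[age]])
  n <- nrow(data)

  all_items <- paste0("pedsql_q", 1:23)
  present <- intersect(all_items, names(data))
  scores <- matrix(NA_real_, n, length(all_items), dimnames = list(NULL, all_items))
  for (col in present) scores[, col] <- pedsql_item_score(data[[col]])

  gated_mean <- function(s, need) {
    k <- sum(!is.na(s))
    if (k == 0 || k < need) return(NA_real_)
    sum(s, na.rm = TRUE) / k
  }

  out <- matrix(NA_real_, n, 6, dimnames = list(NULL, c(
    "qol_physical", "qol_emotional", "qol_social", "qol_school",
    "qol_psychosocial", "qol_total")))
  for (i in seq_len(n)) {
    dims <- pedsql_dimensions(forms[i])
    dscore <- vapply(dims, function(cols) {
      gated_mean(scores[i, cols], ceiling(min_items_prop * length(cols)))
    }, numeric(1))
    psycho_cols <- unlist(dims[c("emotional", "social", "school")], use.names = FALSE)
    psych <- if (psychosocial == "item_mean") {
      gated_mean(scores[i, psycho_cols], ceiling(min_items_prop * length(psycho_cols)))
    } else {
      m <- dscore[c("emotional", "social", "school")]
      if (all(is.na(m))) NA_real_ else mean(m, na.rm = TRUE)
    }
    form_cols <- unlist(dims, use.names = FALSE)
    out[i, ] <- c(dscore[["physical"]], dscore[["emotional"]], dscore[["social"]],
                  dscore[["school"]], psych,
                  gated_mean(scores[i, form_cols],
                             ceiling(min_items_prop * length(form_cols))))
  }
  dplyr::bind_cols(tibble::as_tibble(data), tibble::as_tibble(out))
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))` for a
#' respondents-by-items matrix. Variances are unbiased (n-1). Alpha is
#' invariant to adding a constant to any item column.
#'
#' @param items Numeric matrix or data frame, n respondents x k items.
#' @param use `"complete"` (drop respondents with any missing item, default)
#'   or `"pairwise"` (pairwise-complete covariances).
#' @return Alpha as a single number; `NA` with a warning when the total score
#'   has zero variance.
#' @export
cronbach_alpha <- function(items, use = c("complete", "pairwise")) {
  use <- match.arg(use)
  x <- as.matrix(items)
  storage.mode(x) <- "double"
  k <- ncol(x)
  stopifnot(k >= 2)
  if (use == "complete") x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 complete respondents", call. = FALSE)
  S <- stats::cov(x, use = if (use == "pairwise") "pairwise.complete.obs" else "everything")
  total_var <- sum(S)
  if (!is.finite(total_var) || total_var <= 0) {
    warning("total score has zero variance; alpha undefined")
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(diag(S)) / total_var)
}
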