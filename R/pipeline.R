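#' Read / write survey tables
#'
#' Thin readr wrappers fixing the column types the pipeline expects.
#'
#' @param path CSV file path.
#' @return A tibble of survey records.
#' @export
read_survey <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_survey
#' @param data Survey tibble.
#' @return `write_survey`: the input, invisibly.
#' @export
write_survey <- function(data, path) {
  readr::write_csv(data, path)
  invisible(data)
}

#' Significance stars for a p-value
#'
#' `***` below 0.001, `**` below 0.01, `*` below 0.05, empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    .default = ""
  )
}

#' Run the full analysis over a cleaned survey table
#'
#' Reproduces the analysis flow end to end, per survey year: sample
#' descriptives with across-year ANOVA, compositional means and ternary
#' coordinates, pairwise log-ratio variation matrices, the adjusted ilr
#' regression with per-behaviour pivot coefficients, quantile compositional
#' profiles, and the isotemporal substitution grid for the substitution year
#' (by default the latest).
#'
#' @param data Cleaned records with `year`, `age_years`, `sex`, the part
#'   columns and the outcome.
#' @param outcome Outcome column. Default `"qol_total"`.
#' @param parts Part columns, see [part_cols()].
#' @param years Years to analyse. Default: all years present.
#' @param substitution_year Year whose fitted model drives the substitution
#'   grid. Default: the latest analysed year.
#' @param amounts Reallocation amounts in hours. Default 15/30/45/60 min.
#' @param quantiles Number of QoL quantile groups. Default 4.
#' @param baseline `"geometric"` (compositional mean, default) or
#'   `"arithmetic"` (raw-hours mean) substitution baseline.
#' @param epsilon,kappa Zero replacement and closure constants.
#' @return A list of class `qol_report` with tibbles `descriptives`,
#'   `anova`, `comp_means`, `ternary`, `variation`, `models`, `profiles`,
#'   `substitution`, and a `log` list (row counts, baseline, settings).
#' @export
analyse_survey <- function(data, outcome = "qol_total", parts = part_cols(),
                           years = NULL, substitution_year = NULL,
                           amounts = c(0.25, 0.5, 0.75, 1), quantiles = 4,
                           baseline = c("geometric", "arithmetic"),
                           epsilon = 0.25, kappa = 24) {
  baseline <- match.arg(baseline)
  stopifnot("year" %in% names(data), outcome %in% names(data))
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) stop("empty input: no records to analyse", call. = FALSE)
  if (is.null(years)) years <- sort(unique(data$year))
  data <- data[data$year %in% years, , drop = FALSE]
  if (is.null(substitution_year)) substitution_year <- max(years)

  by_year <- split(data, data$year)

  descriptives <- purrr::imap_dfr(by_year, function(d, yr) {
    tibble::tibble(
      year = as.integer(yr), n = nrow(d),
      age_mean = mean(d$age_years, na.rm = TRUE),
      age_sd = stats::sd(d$age_years, na.rm = TRUE),
      pct_girl = 100 * mean(d$sex == "girl", na.rm = TRUE),
      pa_mean = mean(d[[parts[["PA"]]]]), pa_sd = stats::sd(d[[parts[["PA"]]]]),
      sb_mean = mean(d[[parts[["SB"]]]]), sb_sd = stats::sd(d[[parts[["SB"]]]]),
      sl_mean = mean(d[[parts[["SL"]]]]), sl_sd = stats::sd(d[[parts[["SL"]]]]),
      qol_mean = mean(d[[outcome]], na.rm = TRUE),
      qol_sd = stats::sd(d[[outcome]], na.rm = TRUE)
    )
  })

  anova_tbl <- if (length(by_year) >= 2) {
    purrr::map_dfr(
      c(age_years = "age_years", stats::setNames(unname(parts), names(parts)),
        qol = outcome),
      function(col) oneway_anova(data[!is.na(data[[col]]), ], col, "year"),
      .id = "variable")
  } else tibble::tibble()

  comp_means <- purrr::imap_dfr(by_year, function(d, yr) {
    m <- comp_mean(replace_zeros(comp_matrix_raw(d, parts), epsilon), kappa = kappa)
    tibble::add_column(m, year = as.integer(yr), .before = 1)
  })
  wide <- tidyr::pivot_wider(comp_means, id_cols = "year",
                             names_from = "part", values_from = "mean_hours")
  ternary <- dplyr::bind_cols(
    wide["year"], ternary_coordinates(as.matrix(wide[names(parts)]), kappa = kappa))

  variation <- purrr::imap_dfr(by_year, function(d, yr) {
    v <- variation_matrix(replace_zeros(comp_matrix_raw(d, parts), epsilon),
                          long = TRUE)
    tibble::add_column(v, year = as.integer(yr), .before = 1)
  })
  variation <- dplyr::bind_rows(
    variation,
    tibble::add_column(
      variation_matrix(replace_zeros(comp_matrix_raw(data, parts), epsilon),
                       long = TRUE),
      year = NA_integer_, .before = 1))

  models <- purrr::imap_dfr(by_year, function(d, yr) {
    pb <- pivot_betas(d, outcome = outcome, parts = parts,
                      epsilon = epsilon, kappa = kappa)
    gl <- attr(pb, "glance")
    tibble::tibble(year = as.integer(yr), r_squared = gl$r_squared,
                   model_p = gl$p_value, n = gl$n,
                   part = pb$part, beta = pb$beta, std_error = pb$std_error,
                   p_value = pb$p_value, stars = significance_stars(pb$p_value))
  })

  profiles <- purrr::imap_dfr(by_year, function(d, yr) {
    ok <- !is.na(d[[outcome]])
    tibble::add_column(
      quantile_profile(d[ok, , drop = FALSE], score = outcome, parts = parts,
                       k = quantiles, kappa = kappa, epsilon = epsilon),
      year = as.integer(yr), .before = 1)
  })

  sub_data <- by_year[[as.character(substitution_year)]]
  fit <- fit_qol_model(sub_data, outcome = outcome, parts = parts,
                       epsilon = epsilon, kappa = kappa)
  xm <- replace_zeros(comp_matrix_raw(sub_data, parts), epsilon)
  base <- if (baseline == "geometric") {
    m <- comp_mean(xm, kappa = kappa)
    stats::setNames(m$mean_hours, m$part)
  } else {
    colMeans(xm)
  }
  substitution <- substitution_grid(fit, base, amounts = amounts)

  structure(list(
    descriptives = descriptives, anova = anova_tbl, comp_means = comp_means,
    ternary = ternary, variation = variation, models = models,
    profiles = profiles, substitution = substitution,
    log = list(n_input = nrow(data), years = years,
               substitution_year = substitution_year,
               baseline_type = baseline, baseline = base,
               baseline_score = attr(substitution, "baseline_score"),
               amounts = amounts, quantiles = quantiles,
               epsilon = epsilon, kappa = kappa)
  ), class = "qol_report")
}

## raw (unclosed) part matrix, used where closure happens later
comp_matrix_raw <- function(data, parts = part_cols()) {
  x <- as.matrix(data[, unname(parts), drop = FALSE])
  colnames(x) <- names(parts)
  storage.mode(x) <- "double"
  x
}

#' @export
print.qol_report <- function(x, ...) {
  cat("<qol_report>", length(x$log$years), "year(s):",
      paste(x$log$years, collapse = ", "), "\n")
  cat("  records:", x$log$n_input, "\n")
  cat("  substitution year:", x$log$substitution_year,
      sprintf("(baseline %s, BS = %.1f)\n", x$log$baseline_type,
              x$log$baseline_score))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' One CSV per table plus a JSON run log; numeric output is written at full
#' precision so a rerun on the same input is byte-identical.
#'
#' @param report A `qol_report` from [analyse_survey()].
#' @param dir Output directory (created if absent).
#' @return The paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "qol_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("descriptives", "anova", "comp_means", "ternary", "variation",
              "models", "profiles", "substitution")
  paths <- character(0)
  for (t in tables) {
    tab <- report[[t]]
    if (is.null(tab) || nrow(tibble::as_tibble(tab)) == 0) next
    p <- file.path(dir, paste0(t, ".csv"))
    readr::write_csv(tibble::as_tibble(tab), p)
    paths <- c(paths, p)
  }
  logp <- file.path(dir, "run_log.json")
  jsonlite::write_json(report$log, logp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, logp))
}
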