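#' Default activity-to-behaviour mapping
#'
#' Groups the raw recall-question durations into the three daily behaviours:
#' household chores plus indoor and outdoor play form physical activity (PA);
#' on-screen activities and non-digital sedentary pastimes (crafts, drawing,
#' reading print) form sedentary behaviour (SB); naps and night-time sleep
#' form sleep (SL).
#'
#' @return Named list: behaviour label -> character vector of raw duration
#'   columns.
#' @export
default_activity_mapping <- function() {
  list(
    PA = c("chores_hours", "indoor_play_hours", "outdoor_play_hours"),
    SB = c("screen_learning_hours", "screen_entertainment_hours",
           "reading_hours", "crafts_hours"),
    SL = c("nap_hours", "night_sleep_hours")
  )
}

#' Aggregate raw activity durations into PA, SB and SL
#'
#' Sums the mapped raw duration columns per record into `pa_hours`,
#' `sb_hours`, `sl_hours`. Every duration column in the data must be covered
#' by the mapping (or listed in `ignore`): an unmapped `*_hours` column is a
#' configuration error, not silently dropped time.
#'
#' @param data Survey records with raw duration columns (hours/day).
#' @param mapping As [default_activity_mapping()].
#' @param ignore Duration columns deliberately excluded from all behaviours.
#' @return The input with `pa_hours`, `sb_hours`, `sl_hours` appended, as a
#'   tibble.
#' @export
aggregate_behaviours <- function(data, mapping = default_activity_mapping(),
                                 ignore = character()) {
  mapped <- unlist(mapping, use.names = FALSE)
  miss <- setdiff(mapped, names(data))
  if (length(miss)) {
    stop("mapping refers to absent columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  raw_cols <- setdiff(grep("_hours$", names(data), value = TRUE),
                      c(unname(part_cols()), ignore))
  unmapped <- setdiff(raw_cols, mapped)
  if (length(unmapped)) {
    stop("duration columns not covered by the mapping: ",
         paste(unmapped, collapse = ", "),
         "; map them to a behaviour or list them in `ignore`", call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  target <- part_cols()
  for (lab in names(target)) {
    cols <- mapping[[lab]]
    if (is.null(cols)) stop("mapping lacks behaviour ", lab, call. = FALSE)
    out[[target[[lab]]]] <- rowSums(as.matrix(data[, cols, drop = FALSE]))
  }
  out
}

#' Default age-banded sleep plausibility ranges
#'
#' Guideline-based daily sleep bands (naps included): 11-14 h up to the third
#' birthday, 10-13 h from ages 3 to 6. Configurable because the study's exact
#' screening thresholds are not published.
#'
#' @return Tibble with `age_min`, `age_max`, `sl_min`, `sl_max` (hours).
#' @export
default_sleep_ranges <- function() {
  tibble::tribble(
    ~age_min, ~age_max, ~sl_min, ~sl_max,
    0,        3,        11,      14,
    3,        7,        10,      13
  )
}

#' Cleaning configuration
#'
#' @param sleep_ranges Age-banded plausible sleep ranges, see
#'   [default_sleep_ranges()].
#' @param max_total_hours Maximum allowed PA + SB + SL total. Default 24.
#' @param epsilon Zero-replacement duration passed downstream. Default 0.25 h.
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(sleep_ranges = default_sleep_ranges(),
                            max_total_hours = 24, epsilon = 0.25) {
  stopifnot(all(sleep_ranges$sl_min < sleep_ranges$sl_max),
            max_total_hours > 0, epsilon > 0)
  structure(list(sleep_ranges = sleep_ranges,
                 max_total_hours = max_total_hours,
                 epsilon = epsilon),
            class = "cleaning_config")
}

#' Plausibility-filter survey records
#'
#' Sleep is the anchor variable: a record is dropped when its SL falls outside
#' the plausible range for the child's age band, or when the PA + SB + SL
#' total exceeds the daily budget. Retained records are returned unmodified;
#' each rejection is logged with the rule that fired.
#'
#' @param data Records with `pa_hours`, `sb_hours`, `sl_hours`, `age_years`
#'   (and ideally `id`).
#' @param config A [cleaning_config()].
#' @return A list of class `filter_result`: `retained` (tibble), `rejected`
#'   (tibble `id`, `rule`), `retention_pct` (100 * retained / submitted).
#' @export
filter_records <- function(data, config = cleaning_config()) {
  stopifnot(inherits(config, "cleaning_config"))
  data <- tibble::as_tibble(data)
  if (!"id" %in% names(data)) data$id <- seq_len(nrow(data))
  sl <- data$sl_hours
  total <- data$pa_hours + data$sb_hours + data$sl_hours
  age <- data$age_years

  band <- config$sleep_ranges
  in_range <- rep(NA, nrow(data))
  for (b in seq_len(nrow(band))) {
    sel <- !is.na(age) & age >= band$age_min[b] & age < band$age_max[b]
    in_range[sel] <- sl[sel] >= band$sl_min[b] & sl[sel] <= band$sl_max[b]
  }
  # ages outside every band are not screened on sleep
  in_range[is.na(in_range)] <- TRUE

  rule <- dplyr::case_when(
    !in_range                        ~ "sleep_range",
    total > config$max_total_hours   ~ "total_hours",
    .default = NA_character_
  )
  keep <- is.na(rule)
  res <- list(
    retained = data[keep, , drop = FALSE],
    rejected = tibble::tibble(id = data$id[!keep], rule = rule[!keep]),
    retention_pct = retention_pct(sum(keep), nrow(data))
  )
  structure(res, class = "filter_result")
}

#' Retention percentage of a cleaning step
#'
#' @param retained,submitted Record counts.
#' @return `100 * retained / submitted`.
#' @export
#' @examples
#' retention_pct(8045, 9069) # 88.7
retention_pct <- function(retained, submitted) {
  stopifnot(submitted > 0, retained >= 0, retained <= submitted)
  100 * retained / submitted
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result> retained", nrow(x$retained), "of",
      nrow(x$retained) + nrow(x$rejected),
      sprintf("(%.1f%%)\n", x$retention_pct))
  if (nrow(x$rejected)) print(table(x$rejected$rule))
  invisible(x)
}

#' Impute missing demographics and quality of life
#'
#' Missing QoL totals are replaced by the mean QoL of records in the same
#' integer age group (`floor(age)`), falling back to the overall mean for an
#' age group with no observed QoL. Missing age is replaced by the overall
#' mean age; missing sex by the modal sex (ties broken by first-observed
#' category, deterministically). Warns (does not fail) when any field is
#' missing in 5% or more of records. Non-missing values are untouched and the
#' operation is idempotent.
#'
#' @param data Records with (any of) `qol_total`, `age_years`, `sex`.
#' @param fields Fields to impute, a subset of the default.
#' @return The imputed tibble, with an `imputation_log` attribute (named list
#'   of imputation counts) readable via [imputation_log()].
#' @export
impute_missing <- function(data, fields = c("qol_total", "age_years", "sex")) {
  data <- tibble::as_tibble(data)
  fields <- intersect(fields, names(data))
  log <- list()
  for (f in fields) {
    frac <- mean(is.na(data[[f]]))
    if (frac >= 0.05) {
      warning(sprintf("%s is missing in %.1f%% of records (expected < 5%%)",
                      f, 100 * frac))
    }
  }

  if ("age_years" %in% fields) {
    miss <- is.na(data$age_years)
    data$age_years[miss] <- mean(data$age_years[!miss])
    log$age_years <- sum(miss)
  }
  if ("sex" %in% fields) {
    miss <- is.na(data$sex)
    obs <- data$sex[!miss]
    tab <- table(factor(obs, levels = unique(obs)))  # first-observed tie-break
    data$sex[miss] <- names(tab)[which.max(tab)]
    log$sex <- sum(miss)
  }
  if ("qol_total" %in% fields) {
    miss <- is.na(data$qol_total)
    if (any(miss)) {
      grp <- floor(data$age_years)
      means <- tapply(data$qol_total[!miss], grp[!miss], mean)
      overall <- mean(data$qol_total[!miss])
      fill <- unname(means[as.character(grp[miss])])
      fell_back <- is.na(fill)
      fill[fell_back] <- overall
      if (any(fell_back)) log$qol_total_overall_fallback <- sum(fell_back)
      data$qol_total[miss] <- fill
    }
    log$qol_total <- sum(miss)
  }
  attr(data, "imputation_log") <- log
  data
}

#' Read the imputation log left by [impute_missing()]
#' @param data A tibble returned by [impute_missing()].
#' @return Named list of imputation counts per field.
#' @export
imputation_log <- function(data) {
  attr(data, "imputation_log") %||% list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
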