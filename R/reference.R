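#' Published 2021 reference inputs for the worked example
#'
#' The printed summary statistics of the 2021 wave of the four-year
#' preschooler surveillance survey the package's methods are built around:
#' the three per-behaviour ilr pivot regression coefficients of the adjusted
#' QoL model, the arithmetic-mean daily hours of PA, SB and SL, the baseline
#' predicted QoL score of the published substitution table, and the published
#' 15-minute substitution predictions. The raw records are restricted, so
#' these printed values are the only inputs available for reproducing the
#' substitution worked example.
#'
#' @return A list: `beta` (named pivot coefficients), `baseline` (named mean
#'   hours, unclosed — they sum to the reported 19.59 h of reported waking
#'   and sleeping time), `baseline_score` (BS), `n` (2021 sample size), and
#'   `deltas_15min` (tibble `from`, `to`, `published` of the six printed
#'   15-minute cells).
#' @export
reference_2021 <- function() {
  list(
    beta = c(PA = 2.82, SB = -2.61, SL = -0.21),
    baseline = c(PA = 3.83, SB = 4.59, SL = 11.17),
    baseline_score = 79.1,
    n = 1004L,
    deltas_15min = tibble::tribble(
      ~from, ~to,  ~published,
      "SB",  "PA",  0.24,
      "SL",  "PA",  0.14,
      "PA",  "SB", -0.24,
      "SL",  "SB", -0.10,
      "PA",  "SL", -0.14,
      "SB",  "SL",  0.10
    )
  )
}
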