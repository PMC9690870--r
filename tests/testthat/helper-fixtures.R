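# shared fixtures: everything is generated in code, nothing read from disk

# n random strictly positive compositions (rows), closed to kappa
random_comps <- function(n, kappa = 24, labels = c("PA", "SB", "SL")) {
  x <- matrix(exp(stats::rnorm(n * length(labels), 0, 0.6)), n,
              dimnames = list(NULL, labels))
  close_composition(x, kappa)
}

# brute-force variation matrix: explicit double loop over part pairs
brute_variation <- function(x) {
  D <- ncol(x)
  T <- matrix(0, D, D, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(D)) {
    for (j in seq_len(D)) {
      if (i != j) T[i, j] <- stats::var(log(x[, i] / x[, j]))
    }
  }
  T
}

# minimal cleaned survey table around given compositions
toy_survey <- function(x, qol = NULL, year = 2021) {
  n <- nrow(x)
  tibble::tibble(
    id = seq_len(n), year = year,
    age_years = seq(2, 5.5, length.out = n),
    sex = rep(c("girl", "boy"), length.out = n),
    pa_hours = x[, "PA"], sb_hours = x[, "SB"], sl_hours = x[, "SL"],
    qol_total = if (is.null(qol)) stats::runif(n, 50, 100) else qol
  )
}

ref <- reference_2021()
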