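#' Default behaviour part columns
#'
#' The canonical three-part daily composition used throughout the package:
#' physical activity (PA), sedentary behaviour (SB) and sleep (SL), stored in
#' hours per day. The names are the behaviour labels, the values the column
#' names expected in a survey table.
#'
#' @return A named character vector mapping behaviour labels to column names.
#' @export
#' @examples
#' part_cols()
part_cols <- function() {
  c(PA = "pa_hours", SB = "sb_hours", SL = "sl_hours")
}

#' Close a positive vector to a constant total
#'
#' Rescales strictly positive part values so they sum to the closure constant
#' `kappa` (24 h for a daily time-use composition). Only relative information
#' is meaningful in a composition, so closure changes nothing the log-ratio
#' machinery can see.
#'
#' @param x Numeric vector (one composition) or matrix (one composition per
#'   row) of strictly positive values.
#' @param kappa Closure constant, in the units of `x`. Default 24 hours.
#' @return `x` rescaled row-wise to sum to `kappa`.
#' @export
#' @examples
#' close_composition(c(PA = 1, SB = 1, SL = 2))
close_composition <- function(x, kappa = 24) {
  stopifnot(is.numeric(kappa), length(kappa) == 1, kappa > 0)
  if (is.matrix(x)) {
    if (any(!is.finite(x)) || any(x <= 0)) {
      stop("compositions must be strictly positive; ",
           "replace zero durations first (see replace_zeros())", call. = FALSE)
    }
    return(x * (kappa / rowSums(x)))
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("compositions must be strictly positive; ",
         "replace zero durations first (see replace_zeros())", call. = FALSE)
  }
  x * (kappa / sum(x))
}

#' Multiplicative replacement of zero durations
#'
#' Log-ratios are undefined at zero. Zero parts are replaced by a small
#' duration `epsilon` and the non-zero parts are multiplicatively shrunk so the
#' row total is preserved (multiplicative replacement).
#'
#' @param x Numeric vector or matrix of non-negative durations; at least one
#'   positive entry per row.
#' @param epsilon Replacement duration in hours. Default 0.25 h (15 min),
#'   matching the reallocation granularity of the substitution analysis.
#' @return `x` with zeros replaced, totals unchanged.
#' @export
#' @examples
#' replace_zeros(c(0, 4, 20))
replace_zeros <- function(x, epsilon = 0.25) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1, epsilon > 0)
  one <- function(v) {
    if (any(!is.finite(v)) || any(v < 0) || all(v == 0)) {
      stop("invalid record: durations must be non-negative with a positive total",
           call. = FALSE)
    }
    z <- v == 0
    if (!any(z)) return(v)
    total <- sum(v)
    v[!z] <- v[!z] * (total - sum(z) * epsilon) / total
    v[z] <- epsilon
    v
  }
  if (!is.matrix(x)) return(one(x))
  if (any(!is.finite(x)) || any(x < 0) || any(rowSums(x) == 0)) {
    stop("invalid record: durations must be non-negative with a positive total",
         call. = FALSE)
  }
  z <- x == 0
  if (!any(z)) return(x)
  tot <- rowSums(x)
  shrink <- (tot - rowSums(z) * epsilon) / tot
  out <- x * shrink
  out[z] <- epsilon
  out
}

#' Centred log-ratio transform
#'
#' `clr(x)_i = ln(x_i / g(x))` with `g` the geometric mean of the parts.
#' Components sum to zero; the transform is invariant to the closure constant.
#'
#' @param x Strictly positive numeric vector or matrix (rows are
#'   compositions).
#' @return Vector or matrix of clr coordinates (same shape as `x`).
#' @export
clr <- function(x) {
  if (is.matrix(x)) {
    lx <- log(x)
    return(lx - rowMeans(lx))
  }
  lx <- log(x)
  lx - mean(lx)
}

#' Inverse centred log-ratio transform
#'
#' @param z clr coordinates (vector or matrix, rows sum to ~0).
#' @param kappa Closure constant. Default 24.
#' @return Composition(s) closed to `kappa`.
#' @export
clr_inverse <- function(z, kappa = 24) {
  close_composition(exp(z), kappa = kappa)
}

#' Pivot isometric log-ratio basis
#'
#' Builds the orthonormal contrast matrix of the pivot sequential binary
#' partition: the first coordinate contrasts the pivot part against the
#' geometric mean of the remaining parts, the next contrasts the second part
#' against the rest, and so on. For three parts with pivot order
#' `(p1 | p2, p3)` the rows are `(sqrt(2/3), -1/sqrt(6), -1/sqrt(6))` and
#' `(0, 1/sqrt(2), -1/sqrt(2))`.
#'
#' @param labels Part labels in canonical order. Default `names(part_cols())`.
#' @param pivot Label placed first in the pivot order. Default the first label.
#' @return An object of class `ilr_basis`: a list with `labels` (the pivot
#'   order) and `contrast` (the (D-1) x D orthonormal matrix, columns named by
#'   `labels`).
#' @export
#' @examples
#' pivot_basis(c("PA", "SB", "SL"), pivot = "SB")
pivot_basis <- function(labels = names(part_cols()), pivot = labels[1]) {
  stopifnot(length(labels) >= 2, !anyDuplicated(labels), pivot %in% labels)
  ord <- c(pivot, setdiff(labels, pivot))
  D <- length(ord)
  V <- matrix(0, D - 1, D, dimnames = list(NULL, ord))
  for (i in seq_len(D - 1)) {
    r <- D - i
    V[i, i] <- sqrt(r / (r + 1))
    V[i, (i + 1):D] <- -1 / sqrt(r * (r + 1))
  }
  structure(list(labels = ord, contrast = V), class = "ilr_basis")
}

#' @export
print.ilr_basis <- function(x, ...) {
  cat("<ilr_basis> pivot order:", paste(x$labels, collapse = " | "), "\n")
  print(round(x$contrast, 4))
  invisible(x)
}

check_basis <- function(basis, labels) {
  if (!inherits(basis, "ilr_basis")) stop("`basis` must be an ilr_basis", call. = FALSE)
  if (!setequal(basis$labels, labels)) {
    stop("basis labels (", paste(basis$labels, collapse = ", "),
         ") do not match composition labels (", paste(labels, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(basis)
}

#' Isometric log-ratio coordinates
#'
#' `z = V ln(x)` with `V` the basis contrast matrix. Invariant to the closure
#' constant because the rows of `V` sum to zero.
#'
#' @param x Named strictly positive vector, or matrix with column names, whose
#'   names match the basis labels.
#' @param basis An [pivot_basis()] object.
#' @return Numeric vector of length D-1, or an n x (D-1) matrix, with
#'   coordinates named `z1`, `z2`, ...
#' @export
ilr <- function(x, basis = pivot_basis()) {
  if (is.matrix(x)) {
    check_basis(basis, colnames(x))
    z <- log(x[, basis$labels, drop = FALSE]) %*% t(basis$contrast)
    colnames(z) <- paste0("z", seq_len(ncol(z)))
    return(z)
  }
  check_basis(basis, names(x))
  z <- drop(basis$contrast %*% log(x[basis$labels]))
  stats::setNames(z, paste0("z", seq_along(z)))
}

#' Inverse isometric log-ratio transform
#'
#' @param z Coordinate vector (length D-1) or matrix (n x (D-1)).
#' @param basis An [pivot_basis()] object.
#' @param kappa Closure constant. Default 24.
#' @return Composition(s) in the basis label order, closed to `kappa`.
#' @export
ilr_inverse <- function(z, basis = pivot_basis(), kappa = 24) {
  V <- basis$contrast
  if (is.matrix(z)) {
    x <- exp(z %*% V)
    colnames(x) <- basis$labels
    return(close_composition(x, kappa))
  }
  x <- drop(exp(crossprod(V, z)))
  names(x) <- basis$labels
  close_composition(x, kappa)
}

## internal: pull the part columns of a survey table as a closed matrix
comp_matrix <- function(data, parts = part_cols(), kappa = 24, epsilon = NULL) {
  miss <- setdiff(unname(parts), names(data))
  if (length(miss)) {
    stop("missing part columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(data[, unname(parts), drop = FALSE])
  colnames(x) <- names(parts)
  storage.mode(x) <- "double"
  if (!is.null(epsilon)) x <- replace_zeros(x, epsilon)
  close_composition(x, kappa)
}

#' Compositional mean of a sample
#'
#' The centre of a compositional sample: per-part geometric means across rows,
#' closed to `kappa`. Equals the ilr-inverse of the arithmetic mean of the ilr
#' coordinates.
#'
#' @param data Data frame of survey records (or a plain numeric matrix of
#'   compositions with one row per record).
#' @param parts Named character vector mapping behaviour labels to columns.
#' @param kappa Closure constant. Default 24.
#' @return A tibble with one row per part: `part`, `mean_hours`,
#'   `mean_proportion`.
#' @export
comp_mean <- function(data, parts = part_cols(), kappa = 24) {
  x <- if (is.matrix(data)) close_composition(data, kappa) else
    comp_matrix(data, parts, kappa)
  g <- exp(colMeans(log(x)))
  m <- close_composition(g, kappa)
  tibble::tibble(part = names(m), mean_hours = unname(m),
                 mean_proportion = unname(m) / kappa)
}

#' Pairwise log-ratio variation matrix
#'
#' The canonical compositional dispersion summary:
#' `T[i, j] = var(ln(x_i / x_j))` over records (unbiased, n-1 denominator).
#' Entries near zero flag tightly coupled (proportional) behaviours. The
#' matrix is symmetric with a zero diagonal and is invariant to per-record
#' rescaling, hence to closure.
#'
#' @inheritParams comp_mean
#' @param long If `TRUE` return a long tibble (`part_1`, `part_2`,
#'   `variation`); otherwise the D x D named matrix.
#' @return Matrix or tibble of pairwise log-ratio variances.
#' @export
variation_matrix <- function(data, parts = part_cols(), long = FALSE) {
  x <- if (is.matrix(data)) data else comp_matrix(data, parts)
  if (nrow(x) < 2) stop("need at least 2 records to estimate dispersion", call. = FALSE)
  lx <- log(x)
  # T_ij = var(l_i - l_j) = S_ii + S_jj - 2 S_ij with S the covariance of logs
  S <- stats::cov(lx)
  v <- diag(S)
  Tm <- outer(v, v, "+") - 2 * S
  Tm[abs(Tm) < 1e-15] <- 0
  diag(Tm) <- 0
  dimnames(Tm) <- list(colnames(x), colnames(x))
  if (!long) return(Tm)
  out <- as.data.frame(as.table(Tm), stringsAsFactors = FALSE)
  names(out) <- c("part_1", "part_2", "variation")
  tibble::as_tibble(out[out$part_1 != out$part_2, ])
}

#' Ternary (barycentric) plot coordinates
#'
#' Maps each three-part composition to the unit triangle with part 1 at the
#' origin, part 2 at (1, 0) and part 3 at the apex (1/2, sqrt(3)/2):
#' `x = p2 + p3 / 2`, `y = sqrt(3)/2 * p3` with `p` the closed proportions.
#'
#' @inheritParams comp_mean
#' @return A tibble with columns `x`, `y` (and any `id` column carried over).
#' @export
ternary_coordinates <- function(data, parts = part_cols(), kappa = 24) {
  x <- if (is.matrix(data)) close_composition(data, kappa) else
    comp_matrix(data, parts, kappa)
  stopifnot(ncol(x) == 3)
  p <- x / kappa
  out <- tibble::tibble(x = p[, 2] + p[, 3] / 2, y = sqrt(3) / 2 * p[, 3])
  if (is.data.frame(data) && "id" %in% names(data)) {
    out <- tibble::add_column(out, id = data$id, .before = 1)
  }
  out
}

#' Add ilr coordinate columns to a survey table
#'
#' Convenience verb for pipelines: computes the pivot ilr coordinates of the
#' behaviour composition of each record and binds them as columns `z1`, `z2`.
#'
#' @inheritParams comp_mean
#' @param basis An [pivot_basis()] object.
#' @param epsilon If not `NULL`, zero durations are first replaced by this
#'   amount (multiplicative replacement).
#' @return The input data with ilr coordinate columns appended, as a tibble.
#' @export
add_ilr <- function(data, basis = pivot_basis(names(parts)), parts = part_cols(),
                    kappa = 24, epsilon = NULL) {
  x <- comp_matrix(data, parts, kappa, epsilon)
  z <- ilr(x, basis)
  dplyr::bind_cols(tibble::as_tibble(data), tibble::as_tibble(z))
}
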