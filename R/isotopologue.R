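#' Aggregated isotopologue abundance distribution of a molecule
#'
#' Computes the probability that a molecule of the given elemental composition
#' carries a total mass shift of k neutron units (the M+k isotopologue),
#' aggregated by nominal mass shift — the quantity a unit-mass-resolution
#' triple-quadrupole instrument sees. Each element's single-atom isotope
#' distribution is raised to its atom count by repeated polynomial
#' self-convolution, and the per-element polynomials are then convolved across
#' elements. Isotopic fine structure (different elemental substitutions at the
#' same nominal shift) is deliberately summed together.
#'
#' @param counts `element_counts` from [parse_formula()], or a formula string.
#' @param nmax highest mass shift retained (default 12, ample for practical
#'   label counts of 3-9); mass beyond `nmax` is recorded as truncation loss.
#' @param table `isotope_table` of elemental natural abundances.
#' @return Object of class `isotopologue_distribution` with fields:
#'   \describe{
#'     \item{p}{numeric vector of length `nmax + 1`; `p[k + 1]` is the
#'       fraction-of-total abundance of M+k.}
#'     \item{truncation_loss}{total abundance beyond `nmax`.}
#'     \item{formula, nmax, table_name}{provenance of the computation.}
#'   }
#'   `p` plus `truncation_loss` sums to 1.
#' @examples
#' d <- isotopologue_distribution("C25H24N6O2")
#' relative_abundance_percent(d, 5)
#' @export
isotopologue_distribution <- function(counts, nmax = 12L,
                                      table = default_isotope_table()) {
  if (is.character(counts)) counts <- parse_formula(counts, table = table)
  stopifnot(inherits(counts, "element_counts") || (!is.null(names(counts))))
  nmax <- as.integer(nmax)
  if (is.na(nmax) || nmax < 0L) stop("nmax must be >= 0", call. = FALSE)
  n <- unclass(counts)
  if (any(n < 1L)) stop("atom counts must be >= 1", call. = FALSE)

  full <- 1
  for (el in names(n)) {
    full <- poly_conv(full, poly_power(element_shift_vector(el, table), n[[el]]))
  }
  keep <- seq_len(min(length(full), nmax + 1L))
  p <- numeric(nmax + 1L)
  p[keep] <- full[keep]
  loss <- if (length(full) > nmax + 1L) sum(full[-keep]) else 0

  structure(list(p = p,
                 truncation_loss = loss,
                 formula = format_formula(n),
                 nmax = nmax,
                 table_name = attr(table, "name")),
            class = "isotopologue_distribution")
}

# direct (non-FFT) polynomial product; coefficients stay exact to rounding
poly_conv <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# p(x)^n by binary exponentiation
poly_power <- function(p, n) {
  result <- 1
  base <- p
  while (n > 0L) {
    if (n %% 2L == 1L) result <- poly_conv(result, base)
    base <- if (n > 1L) poly_conv(base, base) else base
    n <- n %/% 2L
  }
  result
}

#' Abundances of an isotopologue distribution
#'
#' @param dist `isotopologue_distribution`.
#' @param mode `"total"` for fraction-of-total abundances (sum to 1 with the
#'   truncation loss) or `"mono"` for abundances relative to the monoisotopic
#'   peak (`p[0] = 1`).
#' @return Numeric vector indexed `M+0 .. M+nmax`.
#' @export
abundances <- function(dist, mode = c("total", "mono")) {
  stopifnot(inherits(dist, "isotopologue_distribution"))
  mode <- match.arg(mode)
  if (mode == "total") dist$p else dist$p / dist$p[1]
}

#' Relative isotopologue abundance as an interference percentage
#'
#' Returns `100 * p[shift] / p[0]`: the natural abundance of the M+shift
#' isotopologue relative to the monoisotopic peak, i.e. the isotopic
#' interference that unlabeled drug contributes in the mass channel of drug
#' carrying `shift` heavy-isotope labels. Full precision is returned;
#' [truncate_percent()] applies the 4-decimal display convention.
#'
#' @param dist `isotopologue_distribution`.
#' @param shift integer mass shift in `0..nmax`.
#' @return Percentage (full precision).
#' @examples
#' d <- isotopologue_distribution("C25H24N6O2")
#' truncate_percent(relative_abundance_percent(d, 6))
#' @export
relative_abundance_percent <- function(dist, shift) {
  stopifnot(inherits(dist, "isotopologue_distribution"))
  shift <- as.integer(shift)
  if (is.na(shift) || shift < 0L || shift > dist$nmax) {
    stop("shift must be in 0..", dist$nmax, call. = FALSE)
  }
  100 * dist$p[shift + 1L] / dist$p[1L]
}

#' Truncate a percentage for display
#'
#' Interference percentages are reported truncated (not rounded) to 4 decimal
#' places of percent; all decisions in the package use full precision and the
#' truncation is applied at presentation time only.
#'
#' @param x percentage(s).
#' @param digits decimal places kept (default 4).
#' @return Truncated value(s).
#' @export
truncate_percent <- function(x, digits = 4L) {
  f <- 10^digits
  trunc(x * f) / f
}

#' @export
print.isotopologue_distribution <- function(x, ...) {
  cat("Isotopologue distribution of ", x$formula,
      " (table: ", x$table_name, ")\n", sep = "")
  rel <- 100 * x$p / x$p[1]
  df <- data.frame(shift = seq_along(x$p) - 1L,
                   fraction_of_total = signif(x$p, 6),
                   pct_of_monoisotopic = signif(rel, 6))
  print(df, row.names = FALSE)
  if (x$truncation_loss > 0) {
    cat(sprintf("truncation loss beyond M+%d: %.3g\n", x$nmax,
                x$truncation_loss))
  }
  invisible(x)
}
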