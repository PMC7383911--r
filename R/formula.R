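#' Parse a molecular formula into element counts
#'
#' Accepts Hill-style condensed formulas: a sequence of element symbols, each
#' optionally followed by a positive integer count (`"C25H24N6O2"`, `"CH4"`).
#' Parentheses, hydrates, salts, charges and explicit isotope prefixes are not
#' part of the grammar; callers expand those first. Symbols must exist in the
#' isotope table the counts will be used with.
#'
#' @param text formula string.
#' @param table `isotope_table` defining the allowed element symbols.
#' @return Named integer vector of class `element_counts`
#'   (element symbol -> atom count), in Hill order (C, H, then alphabetical).
#' @examples
#' parse_formula("C25H24N6O2")
#' parse_formula("CH4")
#' @export
parse_formula <- function(text, table = default_isotope_table()) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  text <- trimws(text)
  m <- gregexpr("[A-Z][a-z]?|[0-9]+|.", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]

  known <- unique(table$element)
  counts <- integer(0)
  i <- 1L
  while (i <= length(tokens)) {
    sym <- tokens[i]
    if (!grepl("^[A-Z][a-z]?$", sym)) {
      stop("cannot parse formula '", text, "': unexpected token '", sym, "'",
           call. = FALSE)
    }
    if (!(sym %in% known)) {
      stop("unknown element '", sym, "' in formula '", text, "'", call. = FALSE)
    }
    n <- 1L
    if (i + 1L <= length(tokens) && grepl("^[0-9]+$", tokens[i + 1L])) {
      n <- suppressWarnings(as.integer(tokens[i + 1L]))
      if (is.na(n) || n <= 0L) {
        stop("invalid atom count '", tokens[i + 1L], "' for element '", sym,
             "' in formula '", text, "'", call. = FALSE)
      }
      i <- i + 1L
    }
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
    i <- i + 1L
  }
  structure(counts[hill_order(names(counts))], class = "element_counts")
}

# Hill convention: C first, H second (when C present), remainder alphabetical
hill_order <- function(symbols) {
  if ("C" %in% symbols) {
    rest <- sort(setdiff(symbols, c("C", "H")))
    c("C", intersect("H", symbols), rest)
  } else {
    sort(symbols)
  }
}

#' Format element counts as a canonical Hill-ordered formula string
#'
#' @param counts `element_counts` (or named integer vector).
#' @return Formula string; `parse_formula(format_formula(x))` round-trips.
#' @examples
#' format_formula(parse_formula("H4C"))  # "CH4"
#' @export
format_formula <- function(counts) {
  counts <- unclass(counts)
  stopifnot(!is.null(names(counts)), all(counts >= 1))
  counts <- counts[hill_order(names(counts))]
  paste0(names(counts), ifelse(counts > 1L, counts, ""), collapse = "")
}

#' @export
print.element_counts <- function(x, ...) {
  cat(format_formula(x), "\n")
  print(unclass(x))
  invisible(x)
}
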