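#' Natural isotope abundance tables
#'
#' An isotope table maps each supported element to the natural abundances of
#' its stable isotopes, indexed by integer mass shift (neutron count above the
#' lightest isotope). The default table carries IUPAC representative natural
#' abundances for the elements found in small-molecule drugs. Tables are
#' versioned so every feasibility verdict can be audited against the constants
#' that produced it: interference percentages are sensitive in the last digit
#' to the abundance source.
#'
#' @param df data.frame with columns `element` (symbol), `mass_shift`
#'   (non-negative integer) and `abundance` (fraction in `[0, 1]`).
#' @param name short identifier of the table.
#' @param provenance free-text origin of the constants.
#' @return An object of class `isotope_table`: the validated data.frame with
#'   `name` and `provenance` attributes.
#' @examples
#' tab <- default_isotope_table()
#' subset(tab, element == "C")
#' @export
isotope_table <- function(df, name, provenance) {
  stopifnot(is.data.frame(df))
  required <- c("element", "mass_shift", "abundance")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("isotope table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  df$element <- as.character(df$element)
  df$mass_shift <- as.integer(df$mass_shift)
  df$abundance <- as.numeric(df$abundance)
  if (any(df$mass_shift < 0L)) {
    stop("mass shifts must be non-negative integers", call. = FALSE)
  }
  if (any(df$abundance < 0 | df$abundance > 1)) {
    stop("abundances must be fractions in [0, 1]", call. = FALSE)
  }
  sums <- tapply(df$abundance, df$element, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-9]
  if (length(bad) > 0L) {
    stop("per-element abundances must sum to 1 (off for: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  if (anyDuplicated(df[c("element", "mass_shift")])) {
    stop("duplicate (element, mass_shift) rows in isotope table", call. = FALSE)
  }
  structure(df,
            name = as.character(name)[1],
            provenance = as.character(provenance)[1],
            class = c("isotope_table", "data.frame"))
}

#' @rdname isotope_table
#' @export
default_isotope_table <- function() {
  df <- data.frame(
    element = c("C", "C",
                "H", "H",
                "N", "N",
                "O", "O", "O",
                "S", "S", "S", "S",
                "Cl", "Cl",
                "Br", "Br",
                "F", "P", "I"),
    mass_shift = c(0L, 1L,
                   0L, 1L,
                   0L, 1L,
                   0L, 1L, 2L,
                   0L, 1L, 2L, 4L,
                   0L, 2L,
                   0L, 2L,
                   0L, 0L, 0L),
    abundance = c(0.9893, 0.0107,        # 12C / 13C
                  0.999885, 0.000115,    # 1H / 2H
                  0.99636, 0.00364,      # 14N / 15N
                  0.99757, 0.00038, 0.00205,   # 16O / 17O / 18O
                  0.9499, 0.0075, 0.0425, 0.0001,  # 32S / 33S / 34S / 36S
                  0.7576, 0.2424,        # 35Cl / 37Cl
                  0.5069, 0.4931,        # 79Br / 81Br
                  1, 1, 1)               # monoisotopic F, P, I
  )
  isotope_table(df, name = "iupac-representative",
                provenance = "IUPAC representative natural isotopic abundances")
}

#' Read or write an isotope table as CSV
#'
#' CSV columns: `element`, `mass_shift`, `abundance`. Lines starting with `#`
#' are comments; a `# name:` / `# provenance:` pair, when present, populates
#' the table's version metadata.
#'
#' @param path file path.
#' @param table an `isotope_table` (for writing).
#' @return `read_isotope_table()` returns an `isotope_table`;
#'   `write_isotope_table()` returns `path` invisibly.
#' @export
read_isotope_table <- function(path) {
  if (!file.exists(path)) stop("isotope table file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  pick <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  nm <- pick("name")
  pv <- pick("provenance")
  isotope_table(df,
                name = if (is.na(nm)) basename(path) else nm,
                provenance = if (is.na(pv)) path else pv)
}

#' @rdname read_isotope_table
#' @export
write_isotope_table <- function(table, path) {
  stopifnot(inherits(table, "isotope_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# name: ", attr(table, "name")),
               paste0("# provenance: ", attr(table, "provenance"))), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# abundance vector p[shift+1] for one element; length = max shift + 1
element_shift_vector <- function(element, table) {
  rows <- table[table$element == element, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("element '", element, "' is not in isotope table '",
         attr(table, "name"), "'", call. = FALSE)
  }
  p <- numeric(max(rows$mass_shift) + 1L)
  p[rows$mass_shift + 1L] <- rows$abundance
  p
}

#' @export
print.isotope_table <- function(x, ...) {
  cat("Isotope table '", attr(x, "name"), "' (",
      attr(x, "provenance"), ")\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
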