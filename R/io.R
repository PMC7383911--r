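#' Read a drug parameter table
#'
#' CSV columns (exact names): `drug`, `formula`, `dose_ug`, `vd_f_L`,
#' `t_half_h`, `cmax_ss_ng_ml`, `microdose_ug`. Lines starting with `#` are
#' comments. Rows are validated individually; all row errors are collected
#' and reported with their line positions rather than stopping at the first.
#'
#' @param path CSV file path.
#' @return data.frame of validated rows (zero rows, with a warning, for an
#'   empty file). Convert to parameter objects with `drug_table_to_params()`.
#' @export
read_drug_table <- function(path) {
  if (!file.exists(path)) stop("drug table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("drug", "formula", "dose_ug", "vd_f_L", "t_half_h",
                "cmax_ss_ng_ml", "microdose_ug")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("drug table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  if (nrow(df) == 0L) {
    warning("drug table ", path, " contains no rows", call. = FALSE)
    return(df)
  }
  errors <- character(0)
  numeric_cols <- setdiff(required, c("drug", "formula"))
  for (i in seq_len(nrow(df))) {
    for (col in numeric_cols) {
      v <- suppressWarnings(as.numeric(df[[col]][i]))
      if (is.na(v) || v <= 0) {
        errors <- c(errors, sprintf("row %d (%s): %s is not a positive number (got '%s')",
                                    i, df$drug[i], col, df[[col]][i]))
      }
    }
    ok <- tryCatch({ parse_formula(df$formula[i]); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) errors <- c(errors, sprintf("row %d (%s): %s", i, df$drug[i], ok))
  }
  if (length(errors) > 0L) {
    stop("invalid drug table ", path, ":\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }
  for (col in numeric_cols) df[[col]] <- as.numeric(df[[col]])
  df
}

#' @rdname read_drug_table
#' @param df validated drug table data.frame.
#' @export
drug_table_to_params <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    drug_pk_params(df$drug[i], df$formula[i], df$dose_ug[i], df$vd_f_L[i],
                   df$t_half_h[i], df$cmax_ss_ng_ml[i], df$microdose_ug[i])
  })
}

#' Write a feasibility report
#'
#' Deterministic column order, full-precision values plus a
#' display-truncated interference column, and run metadata (tool version,
#' isotope-table version, thresholds) in `#`-prefixed header comments so the
#' file stays parseable as CSV.
#'
#' @param results data.frame from [assess_drugs()].
#' @param path output CSV path.
#' @param table isotope table used (for the provenance header).
#' @param lloq_threshold_pg_ml,half_lives,criterion thresholds to record.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, table = default_isotope_table(),
                         lloq_threshold_pg_ml = 1, half_lives = 3L,
                         criterion = 0.2) {
  cols <- c("drug", "cmax_micro_ng_ml", "c_lloq_pg_ml",
            "allowed_interference_pct", "allowed_interference_pct_display",
            "min_labels", "feasible_1pg", "feasible_10pg", "microdose_ok")
  stopifnot(is.data.frame(results))
  if (nrow(results) > 0L) {
    missing_cols <- setdiff(cols, names(results))
    if (length(missing_cols) > 0L) {
      stop("results are missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  } else {
    results <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)), cols))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# silmtools ", as.character(utils::packageVersion("silmtools"))),
    paste0("# isotope_table: ", attr(table, "name")),
    sprintf("# thresholds: lloq_threshold_pg_ml=%g half_lives=%g interference_criterion=%g",
            lloq_threshold_pg_ml, half_lives, criterion)
  ), con)
  utils::write.csv(format(results[cols], digits = 15, trim = TRUE,
                          scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write long-format concentration profiles
#'
#' CSV columns: `subject`, `channel` (labeled|unlabeled), `route` (iv|oral),
#' `dose_ug`, `time_h`, `conc_ng_ml`. Times are on the study clock.
#'
#' @param path CSV path.
#' @return data.frame of profile rows.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("subject", "channel", "route", "dose_ug", "time_h", "conc_ng_ml")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("profile table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$channel), c("labeled", "unlabeled"))
  if (length(bad) > 0L) {
    stop("unknown channel value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_profiles
#' @param profiles long-format profile data.frame.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bioavailability per subject from a long-format profile table
#'
#' For each subject the oral profile (time since ingestion = study time) and
#' the IV microdose profile (shifted to time since injection, taken as that
#' channel's first sampling time) are analysed by NCA and combined.
#'
#' @param profiles data.frame from [read_profiles()] or
#'   [simulate_study()]`$profiles`.
#' @param lloq_ng_ml optional assay LLOQ.
#' @return data.frame: subject, F, F_pct, auc_ev, auc_iv, dose_iv_ug,
#'   dose_ev_ug, extrapolated_pct_ev, extrapolated_pct_iv.
#' @export
bioavailability_from_table <- function(profiles, lloq_ng_ml = NULL) {
  rows <- lapply(split(profiles, profiles$subject), function(d) {
    ev <- d[d$route == "oral", , drop = FALSE]
    iv <- d[d$route == "iv", , drop = FALSE]
    if (nrow(ev) < 3L || nrow(iv) < 3L) {
      stop("subject ", d$subject[1], ": need both an oral and an iv profile ",
           "with at least 3 samples", call. = FALSE)
    }
    oral_p <- pk_profile(ev$time_h, ev$conc_ng_ml, channel = ev$channel[1],
                         route = "oral", dose_ug = ev$dose_ug[1])
    t0 <- min(iv$time_h)
    iv_p <- pk_profile(iv$time_h - t0, iv$conc_ng_ml, channel = iv$channel[1],
                       route = "iv", dose_ug = iv$dose_ug[1], t0_h = t0)
    est <- bioavailability_from_profiles(oral_p, iv_p, lloq_ng_ml)
    data.frame(subject = d$subject[1], F = est$F, F_pct = est$F_pct,
               auc_ev = est$auc_ev, auc_iv = est$auc_iv,
               dose_iv_ug = est$dose_iv_ug, dose_ev_ug = est$dose_ev_ug,
               extrapolated_pct_ev = est$nca_oral$extrapolated_pct,
               extrapolated_pct_iv = est$nca_iv$extrapolated_pct)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Path of the packaged worked-example drug table
#'
#' Two rows: the ibrutinib worked example (Vd/F back-computed from its
#' 0.010 ng/mL microdose Cmax) and a back-computed abemaciclib row.
#'
#' @return File path inside the installed package.
#' @export
example_drug_table <- function() {
  system.file("extdata", "example_drugs.csv", package = "silmtools",
              mustWork = TRUE)
}
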