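#' Drug pharmacokinetic parameters for SILM feasibility assessment
#'
#' Bundles the per-drug quantities the feasibility calculation needs. Units
#' are fixed at the interface: doses in micrograms, volumes in litres, plasma
#' concentrations in ng/mL, half-life in hours. The terminal half-life is not
#' used numerically by the LLOQ formula but documents the sampling horizon
#' (3 half-lives after injection).
#'
#' @param drug drug name.
#' @param formula molecular formula of the free base (Hill notation).
#' @param dose_ug therapeutic oral dose (ug).
#' @param vd_f_L apparent steady-state volume of distribution Vd/Fss (L).
#' @param t_half_h terminal elimination half-life (h).
#' @param cmax_ss_ng_ml steady-state Cmax of the oral therapeutic dose (ng/mL).
#' @param microdose_ug intended intravenous microdose (ug, default 100).
#' @return Object of class `drug_pk_params`.
#' @examples
#' drug_pk_params("ibrutinib", "C25H24N6O2", dose_ug = 560000,
#'                vd_f_L = 10000, t_half_h = 6, cmax_ss_ng_ml = 221)
#' @export
drug_pk_params <- function(drug, formula, dose_ug, vd_f_L, t_half_h,
                           cmax_ss_ng_ml, microdose_ug = 100) {
  num <- c(dose_ug = dose_ug, vd_f_L = vd_f_L, t_half_h = t_half_h,
           cmax_ss_ng_ml = cmax_ss_ng_ml, microdose_ug = microdose_ug)
  if (any(!is.finite(num)) || any(num <= 0)) {
    bad <- names(num)[!is.finite(num) | num <= 0]
    stop("drug_pk_params: non-positive or missing value for ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  parse_formula(formula)  # fail fast on malformed formulas
  structure(list(drug = as.character(drug), formula = as.character(formula),
                 dose_ug = dose_ug, vd_f_L = vd_f_L, t_half_h = t_half_h,
                 cmax_ss_ng_ml = cmax_ss_ng_ml, microdose_ug = microdose_ug),
            class = "drug_pk_params")
}

#' Theoretical Cmax of an intravenous microdose bolus
#'
#' The peak plasma concentration after an intravenous bolus is the dose
#' divided by the apparent distribution volume; with the dose in micrograms
#' and the volume in litres the quotient is already in ng/mL
#' (1 ug/L = 1 ng/mL).
#'
#' @param microdose_ug intravenous microdose (ug).
#' @param vd_f_L apparent volume of distribution Vd/Fss (L).
#' @return Cmax of the microdose in ng/mL.
#' @examples
#' cmax_iv_microdose(100, 10000)  # 0.010 ng/mL
#' @export
cmax_iv_microdose <- function(microdose_ug, vd_f_L) {
  check_positive(microdose_ug = microdose_ug, vd_f_L = vd_f_L)
  microdose_ug / vd_f_L
}

#' Required assay LLOQ for an intravenous microdose
#'
#' To extrapolate AUC to infinity reliably, the labeled microdose should stay
#' quantifiable to at least `half_lives` terminal half-lives after injection,
#' where its concentration has fallen to `Cmax * 0.5^half_lives`. That
#' concentration is the required lower limit of quantification of the
#' LC-MS/MS assay:
#' `C_LLOQ = microdose / (Vd/Fss) * 0.5^half_lives`, reported in pg/mL.
#'
#' @inheritParams cmax_iv_microdose
#' @param half_lives number of terminal half-lives the assay must cover
#'   (default 3).
#' @return Required LLOQ in pg/mL.
#' @examples
#' required_lloq(100, 10000)  # 1.25 pg/mL
#' @export
required_lloq <- function(microdose_ug, vd_f_L, half_lives = 3L) {
  check_positive(microdose_ug = microdose_ug, vd_f_L = vd_f_L,
                 half_lives = half_lives)
  cmax_iv_microdose(microdose_ug, vd_f_L) * 0.5^half_lives * 1000
}

#' Maximum isotopic interference allowed by the 20% selectivity criterion
#'
#' Bioanalytical selectivity guidance tolerates interference up to 20% of the
#' analyte LLOQ-level response; applied at the microdose Cmax against the
#' steady-state oral Cmax of unlabeled drug this gives the largest natural
#' isotopologue abundance (as a percentage of the unlabeled signal) that
#' still permits selective quantification of the labeled microdose:
#' `(Cmax_microdose * criterion) / Cmax_ss_oral * 100`.
#'
#' @param cmax_microdose_ng_ml microdose Cmax (ng/mL).
#' @param cmax_ss_ng_ml steady-state oral Cmax (ng/mL); must be in the same
#'   units as `cmax_microdose_ng_ml`.
#' @param criterion interference criterion as a fraction of the microdose
#'   signal (default 0.2).
#' @return Maximum allowed interference in percent.
#' @examples
#' max_allowed_interference(0.010, 221)  # 0.000905 %
#' @export
max_allowed_interference <- function(cmax_microdose_ng_ml, cmax_ss_ng_ml,
                                     criterion = 0.2) {
  check_positive(cmax_microdose_ng_ml = cmax_microdose_ng_ml,
                 cmax_ss_ng_ml = cmax_ss_ng_ml)
  if (!is.finite(criterion) || criterion <= 0 || criterion > 1) {
    stop("criterion must be in (0, 1]", call. = FALSE)
  }
  cmax_microdose_ng_ml * criterion / cmax_ss_ng_ml * 100
}

#' Minimum number of stable isotope labels for selective quantification
#'
#' Finds the smallest label count n >= 1 whose natural-abundance M+n
#' isotopologue interference (relative to the monoisotopic peak, full
#' precision) does not exceed the allowance from
#' [max_allowed_interference()]. The boundary is certified: for n >= 2 the
#' interference at n - 1 is checked to exceed the allowance.
#'
#' @param formula molecular formula (string or `element_counts`).
#' @param cmax_microdose_ng_ml microdose Cmax (ng/mL).
#' @param cmax_ss_ng_ml steady-state oral Cmax (ng/mL).
#' @param criterion selectivity criterion fraction (default 0.2).
#' @param nmax largest label count searched (default 12).
#' @param table `isotope_table`.
#' @return Integer label count, with attributes `allowed_pct` (the
#'   selectivity allowance) and `interference_pct` (full-precision M+1..M+nmax
#'   interferences).
#' @examples
#' min_labels("C25H24N6O2", 0.010, 221)  # 6
#' @export
min_labels <- function(formula, cmax_microdose_ng_ml, cmax_ss_ng_ml,
                       criterion = 0.2, nmax = 12L,
                       table = default_isotope_table()) {
  allowed <- max_allowed_interference(cmax_microdose_ng_ml, cmax_ss_ng_ml,
                                      criterion = criterion)
  dist <- isotopologue_distribution(formula, nmax = nmax, table = table)
  interference <- vapply(seq_len(nmax), function(k)
    relative_abundance_percent(dist, k), numeric(1))
  names(interference) <- paste0("M+", seq_len(nmax))
  ok <- interference <= allowed
  if (!any(ok)) {
    stop("no label count up to ", nmax, " brings interference of ",
         dist$formula, " below the allowed ", signif(allowed, 3),
         "% (insufficient labels within limit)", call. = FALSE)
  }
  n <- which(ok)[1]
  if (n > 1L && interference[n - 1L] <= allowed) {
    stop("internal error: interference not above allowance at n - 1",
         call. = FALSE)  # unreachable for monotone drug-sized patterns
  }
  structure(as.integer(n), allowed_pct = allowed,
            interference_pct = interference)
}

#' Check a dose against the microdose definition
#'
#' A microdose is at most 1/100th of the therapeutic dose and never more
#' than 100 ug.
#'
#' @param microdose_ug proposed intravenous dose (ug).
#' @param therapeutic_dose_ug therapeutic oral dose (ug).
#' @return List with `ok` (logical) and `message` (which bound failed, or
#'   confirmation).
#' @examples
#' microdose_check(100, 560000)$ok   # TRUE
#' microdose_check(100, 5000)$ok     # FALSE: exceeds dose/100
#' @export
microdose_check <- function(microdose_ug, therapeutic_dose_ug) {
  check_positive(microdose_ug = microdose_ug,
                 therapeutic_dose_ug = therapeutic_dose_ug)
  fails <- character(0)
  if (microdose_ug > 100) {
    fails <- c(fails, sprintf("exceeds the 100 ug cap (%g ug)", microdose_ug))
  }
  if (microdose_ug > therapeutic_dose_ug / 100) {
    fails <- c(fails, sprintf(
      "exceeds 1/100th of the therapeutic dose (%g > %g ug)",
      microdose_ug, therapeutic_dose_ug / 100))
  }
  if (length(fails) == 0L) {
    list(ok = TRUE, message = "microdose within both bounds")
  } else {
    list(ok = FALSE, message = paste(fails, collapse = "; "))
  }
}

#' Assess SILM trial feasibility for one drug
#'
#' Composes the microdose Cmax, required LLOQ, selectivity allowance and
#' minimum label count into one verdict. Feasibility is judged against an
#' LLOQ threshold of 1 pg/mL (achievable by current ultrasensitive LC-MS/MS)
#' with an informational 10 pg/mL tier (routinely achievable assays).
#'
#' @param params `drug_pk_params`.
#' @param lloq_threshold_pg_ml feasibility threshold on the required LLOQ
#'   (pg/mL, default 1).
#' @param half_lives terminal half-lives the assay must cover (default 3).
#' @param criterion selectivity criterion fraction (default 0.2).
#' @param nmax largest label count searched (default 12).
#' @param table `isotope_table`.
#' @return Object of class `feasibility_result`: drug, cmax_micro_ng_ml,
#'   c_lloq_pg_ml, allowed_interference_pct, min_labels, interference_pct
#'   (per-label-count table), feasible_1pg / feasible_10pg verdicts (the
#'   first named after the threshold actually used) and microdose_ok.
#' @examples
#' p <- drug_pk_params("ibrutinib", "C25H24N6O2", 560000, 10000, 6, 221)
#' assess_feasibility(p)
#' @export
assess_feasibility <- function(params, lloq_threshold_pg_ml = 1,
                               half_lives = 3L, criterion = 0.2, nmax = 12L,
                               table = default_isotope_table()) {
  stopifnot(inherits(params, "drug_pk_params"))
  cmax_micro <- cmax_iv_microdose(params$microdose_ug, params$vd_f_L)
  c_lloq <- required_lloq(params$microdose_ug, params$vd_f_L,
                          half_lives = half_lives)
  labels <- min_labels(params$formula, cmax_micro, params$cmax_ss_ng_ml,
                       criterion = criterion, nmax = nmax, table = table)
  md <- microdose_check(params$microdose_ug, params$dose_ug)
  structure(list(
    drug = params$drug,
    formula = params$formula,
    cmax_micro_ng_ml = cmax_micro,
    c_lloq_pg_ml = c_lloq,
    allowed_interference_pct = attr(labels, "allowed_pct"),
    min_labels = as.integer(labels),
    interference_pct = attr(labels, "interference_pct"),
    feasible_1pg = c_lloq >= lloq_threshold_pg_ml,
    feasible_10pg = c_lloq >= 10,
    lloq_threshold_pg_ml = lloq_threshold_pg_ml,
    microdose_ok = md$ok,
    microdose_message = md$message,
    t_half_h = params$t_half_h,
    sampling_horizon_h = half_lives * params$t_half_h,
    half_lives = half_lives,
    criterion = criterion,
    table_name = attr(table, "name")
  ), class = "feasibility_result")
}

#' Assess a table of drugs
#'
#' @param drugs list of `drug_pk_params`, or a data.frame as returned by
#'   [read_drug_table()].
#' @param ... passed to [assess_feasibility()].
#' @return data.frame with one row per drug, order preserved: drug,
#'   cmax_micro_ng_ml, c_lloq_pg_ml, allowed_interference_pct,
#'   allowed_interference_pct_display, min_labels, feasible_1pg,
#'   feasible_10pg, microdose_ok.
#' @export
assess_drugs <- function(drugs, ...) {
  if (is.data.frame(drugs)) drugs <- drug_table_to_params(drugs)
  stopifnot(all(vapply(drugs, inherits, logical(1), "drug_pk_params")))
  rows <- lapply(drugs, function(p) {
    r <- assess_feasibility(p, ...)
    data.frame(drug = r$drug,
               cmax_micro_ng_ml = r$cmax_micro_ng_ml,
               c_lloq_pg_ml = r$c_lloq_pg_ml,
               allowed_interference_pct = r$allowed_interference_pct,
               allowed_interference_pct_display =
                 truncate_percent(r$allowed_interference_pct, 6L),
               min_labels = r$min_labels,
               feasible_1pg = r$feasible_1pg,
               feasible_10pg = r$feasible_10pg,
               microdose_ok = r$microdose_ok,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

check_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(nm, " must be a single positive number", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.feasibility_result <- function(x, ...) {
  cat("SILM feasibility:", x$drug, paste0("(", x$formula, ")\n"))
  cat(sprintf("  Cmax of IV microdose : %.4g ng/mL\n", x$cmax_micro_ng_ml))
  cat(sprintf("  required LLOQ (%d t1/2): %.4g pg/mL\n",
              x$half_lives, x$c_lloq_pg_ml))
  cat(sprintf("  allowed interference : %.6f %% (criterion %.0f%%)\n",
              x$allowed_interference_pct, 100 * x$criterion))
  cat(sprintf("  minimum labels       : %d (M+%d interference %.4f %%)\n",
              x$min_labels, x$min_labels,
              truncate_percent(x$interference_pct[x$min_labels])))
  cat(sprintf("  feasible at %g pg/mL : %s; at 10 pg/mL: %s\n",
              x$lloq_threshold_pg_ml, x$feasible_1pg, x$feasible_10pg))
  cat("  microdose check      :", x$microdose_message, "\n")
  invisible(x)
}
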