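# Independent oracles used across the suite.

# Brute-force isotopologue distribution: enumerates every per-atom isotope
# assignment and accumulates probability by total mass shift. Exponential in
# atom count -- keep molecules at <= 8 atoms. Deliberately shares no code
# with isotopologue_distribution().
oracle_distribution <- function(counts, table = default_isotope_table()) {
  atoms <- rep(names(counts), times = unlist(counts))
  choices <- lapply(atoms, function(el) {
    rows <- table[table$element == el, , drop = FALSE]
    lapply(seq_len(nrow(rows)),
           function(i) list(shift = rows$mass_shift[i], ab = rows$abundance[i]))
  })
  max_shift <- sum(vapply(choices, function(ch)
    max(vapply(ch, `[[`, numeric(1), "shift")), numeric(1)))
  p <- numeric(max_shift + 1)
  grid <- expand.grid(lapply(choices, seq_along))
  for (r in seq_len(nrow(grid))) {
    shift <- 0
    prob <- 1
    for (a in seq_along(atoms)) {
      iso <- choices[[a]][[grid[r, a]]]
      shift <- shift + iso$shift
      prob <- prob * iso$ab
    }
    p[shift + 1] <- p[shift + 1] + prob
  }
  p
}

# Closed-form one-compartment AUC_0-inf values.
oracle_oral_auc_inf <- function(design) {
  design$F_true * design$oral_dose_ug / (design$vd_L * design$ke)
}

oracle_iv_auc_inf <- function(design) {
  design$microdose_ug / (design$vd_L * design$ke * design$kie)
}

# Random drug-like CHNO(S) formula string, for property tests.
random_formula <- function() {
  n <- c(C = sample(5:40, 1), H = sample(5:50, 1),
         N = sample(0:6, 1), O = sample(0:4, 1), S = sample(0:1, 1))
  n <- n[n > 0]
  paste0(names(n), n, collapse = "")
}
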