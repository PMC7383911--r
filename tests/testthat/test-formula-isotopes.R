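test_that("formulas parse to exact element counts and round-trip", {
  x <- parse_formula("C25H24N6O2")
  expect_identical(unclass(x), c(C = 25L, H = 24L, N = 6L, O = 2L))
  expect_identical(unclass(parse_formula("CH4")), c(C = 1L, H = 4L))
  expect_identical(unclass(parse_formula("Cl2")), c(Cl = 2L))
  # repeated symbols accumulate; output is canonical Hill order
  expect_identical(format_formula(parse_formula("H3CCH3")), "C2H6")
  expect_identical(format_formula(parse_formula("O2N6H24C25")), "C25H24N6O2")
  for (f in c("C25H24N6O2", "CH4", "C16H15F6N5O", "C2H6S"))
    expect_identical(format_formula(parse_formula(f)), f)
})

test_that("malformed formulas are rejected with informative errors", {
  expect_error(parse_formula("Xx9"), "unknown element 'Xx'")
  expect_error(parse_formula("C25H24Qz2"), "unknown element 'Qz'")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("C0H4"), "count")
  expect_error(parse_formula("C2(H6)"), "unexpected token")
  expect_error(parse_formula("c2h6"), "unexpected token")
})

test_that("single-atom distribution reproduces the element's isotope entry", {
  d <- isotopologue_distribution("C", nmax = 1)
  expect_equal(abundances(d, "total"), c(0.9893, 0.0107))
  expect_equal(abundances(d, "mono")[1], 1)
  expect_equal(d$truncation_loss, 0)
})

test_that("convolution matches the brute-force isotope-assignment oracle", {
  tab <- default_isotope_table()
  fixtures <- list(c(C = 1, H = 4), c(C = 2, H = 6), c(C = 2, H = 3, Cl = 3),
                   c(C = 1, H = 2, O = 2), c(C = 2, H = 3, N = 1, O = 1),
                   c(S = 2, O = 4), c(C = 3, N = 4, H = 1),
                   c(C = 1, H = 3, S = 1, Cl = 1, N = 1, O = 1))
  set.seed(401)
  for (i in 1:4) {  # a few randomized <= 8 atom molecules as well
    els <- sample(c("C", "H", "N", "O", "S", "Cl"), sample(2:4, 1))
    n <- as.integer(stats::rmultinom(1, sample(3:8, 1), rep(1, length(els))))
    names(n) <- els
    fixtures <- c(fixtures, list(n[n > 0]))
  }
  for (counts in fixtures) {
    truth <- oracle_distribution(counts, tab)
    nmax <- length(truth) - 1L
    got <- abundances(isotopologue_distribution(
      structure(as.integer(counts), names = names(counts),
                class = "element_counts"), nmax = nmax, table = tab), "total")
    expect_equal(got, truth, tolerance = 1e-12,
                 label = format_formula(counts))
  }
})

test_that("fraction-of-total abundances account for all probability", {
  set.seed(402)
  for (i in 1:20) {
    f <- random_formula()
    d_full <- isotopologue_distribution(f, nmax = 200)  # beyond any real shift
    expect_lt(abs(sum(abundances(d_full, "total")) - 1), 1e-9)
    d_trunc <- isotopologue_distribution(f, nmax = 3)
    expect_lt(abs(sum(d_trunc$p) + d_trunc$truncation_loss - 1), 1e-9)
    expect_gt(d_trunc$truncation_loss, 0)
  }
})

test_that("interference strictly decreases with label count for drug-sized formulas", {
  # CHNOF(S at low count) drug formulas; chlorine/bromine molecules are
  # excluded because 37Cl/81Br put mass at M+2 ahead of M+1
  fixture_formulas <- c("C25H24N6O2",  # ibrutinib
                        "C27H32F2N8",  # abemaciclib
                        "C29H31N7O",   # imatinib
                        "C18H19N3O3S",
                        "C44H49N9O5")
  for (f in fixture_formulas) {
    d <- isotopologue_distribution(f, nmax = 12)
    rel <- abundances(d, "mono")
    expect_true(all(diff(rel[-1]) < 0), label = f)
  }
})

test_that("adding any atom never increases the monoisotopic fraction", {
  base <- c(C = 12L, H = 15L, N = 2L, O = 1L)
  p0 <- abundances(isotopologue_distribution(
    structure(base, class = "element_counts"), nmax = 30), "total")[1]
  for (el in c("C", "H", "N", "O", "S", "Cl", "Br", "F")) {
    more <- base
    more[el] <- ifelse(el %in% names(more), more[el] + 1L, 1L)
    p0_more <- abundances(isotopologue_distribution(
      structure(more, class = "element_counts"), nmax = 30), "total")[1]
    expect_lte(p0_more, p0 + 1e-15, label = el)
  }
})

test_that("relative abundance reporting follows the mono convention and truncates", {
  d <- isotopologue_distribution("C25H24N6O2")
  expect_equal(relative_abundance_percent(d, 0), 100)
  expect_error(relative_abundance_percent(d, 13), "shift must be in")
  expect_error(relative_abundance_percent(d, -1), "shift must be in")
  # truncation, not rounding
  expect_equal(truncate_percent(0.00299999), 0.0029)
  expect_equal(truncate_percent(0.00017732), 0.0001)
  expect_equal(truncate_percent(123.456789, 2), 123.45)
})

test_that("swappable isotope tables change the computed pattern", {
  tab <- isotope_table(
    data.frame(element = c("C", "C", "H"), mass_shift = c(0L, 1L, 0L),
               abundance = c(0.98, 0.02, 1)),
    name = "toy", provenance = "unit test")
  d <- isotopologue_distribution("CH4", nmax = 1, table = tab)
  expect_equal(abundances(d, "mono")[2], 0.02 / 0.98, tolerance = 1e-12)
  # table validation
  expect_error(isotope_table(data.frame(element = "C", mass_shift = 0,
                                        abundance = 0.9), "bad", "test"),
               "sum to 1")
  expect_error(isotopologue_distribution("CH4O", table = tab),
               "unknown element 'O'")
})
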