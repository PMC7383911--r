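test_that("microdose Cmax is dose over distribution volume in ng/mL", {
  expect_equal(cmax_iv_microdose(100, 10000), 0.010)
  expect_equal(cmax_iv_microdose(100, 100), 1.0)
  expect_equal(cmax_iv_microdose(50, 10000), 0.005)
  expect_error(cmax_iv_microdose(0, 100), "positive")
  expect_error(cmax_iv_microdose(100, -1), "positive")
})

test_that("required LLOQ applies the three-half-life rule in pg/mL", {
  expect_identical(required_lloq(100, 10000), 1.25)
  expect_equal(required_lloq(100, 690), 18.115942, tolerance = 1e-6)
  # scaling laws
  expect_equal(required_lloq(100, 20000), required_lloq(100, 10000) / 2)
  expect_equal(required_lloq(50, 10000), required_lloq(100, 10000) / 2)
  # configurable horizon: n half-lives multiplies by 0.5^n
  expect_equal(required_lloq(100, 10000, half_lives = 1), 5)
  expect_equal(required_lloq(100, 100, half_lives = 2), 250)
})

test_that("selectivity allowance follows the 20% criterion", {
  expect_equal(max_allowed_interference(0.010, 221), 0.010 * 0.2 / 221 * 100)
  expect_equal(max_allowed_interference(1, 1), 20)
  expect_equal(max_allowed_interference(0.010, 442),
               max_allowed_interference(0.010, 221) / 2)
  expect_error(max_allowed_interference(0.01, 221, criterion = 0), "criterion")
  expect_error(max_allowed_interference(-1, 221), "positive")
  # closed-form round trip through the microdose Cmax
  d <- 100; v <- 10000; c <- 221
  expect_equal(max_allowed_interference(cmax_iv_microdose(d, v), c),
               0.2 * d / (v * c) * 100)
})

test_that("minimum label count search certifies its boundary", {
  n <- min_labels("C25H24N6O2", 0.010, 221)
  expect_identical(as.integer(n), 6L)
  intf <- attr(n, "interference_pct")
  allowed <- attr(n, "allowed_pct")
  expect_gt(intf[5], allowed)
  expect_lte(intf[6], allowed)

  # ethane against a 0.5% allowance: M+1 exceeds it, M+2 does not
  truth <- oracle_distribution(c(C = 2, H = 6))
  rel_pct <- 100 * truth / truth[1]
  expect_gt(rel_pct[2], 0.5)
  expect_lte(rel_pct[3], 0.5)
  expect_identical(as.integer(min_labels("C2H6", 1, 40)), 2L)  # allowance 0.5%

  # a 100% allowance is always met by a single label on drug-sized molecules
  expect_identical(as.integer(min_labels("C25H24N6O2", 5, 1)), 1L)
  # unreachable allowance within the search limit errors out
  expect_error(min_labels("C90H100", 1e-6, 1e7, nmax = 6),
               "insufficient labels within limit")
})

test_that("label requirements are monotone in the oral Cmax and scale with microdose", {
  cmax_grid <- c(10, 50, 221, 1000, 5000, 20000)
  n <- vapply(cmax_grid, function(cs)
    as.integer(min_labels("C25H24N6O2", 0.010, cs)), integer(1))
  expect_true(all(diff(n) >= 0))

  # halving the microdose halves the allowance exactly
  a_full <- max_allowed_interference(cmax_iv_microdose(100, 10000), 221)
  a_half <- max_allowed_interference(cmax_iv_microdose(50, 10000), 221)
  expect_equal(a_half, a_full / 2)
})

test_that("randomized minimum-label searches always return a certified boundary", {
  set.seed(403)
  for (i in 1:100) {
    f <- random_formula()
    dist <- isotopologue_distribution(f, nmax = 12)
    intf <- vapply(1:12, function(k) relative_abundance_percent(dist, k),
                   numeric(1))
    # draw an allowance that guarantees a solution within the search limit
    allowed <- exp(stats::runif(1, log(max(intf[12], 1e-12)), log(intf[1])))
    # realize it through the allowance interface: allowed = cmax_micro*0.2/cs*100
    cs <- 0.010 * 0.2 * 100 / allowed
    n <- min_labels(f, 0.010, cs)
    expect_lte(intf[as.integer(n)], attr(n, "allowed_pct"))
    if (n > 1L) expect_gt(intf[as.integer(n) - 1L], attr(n, "allowed_pct"))
    expect_identical(as.integer(n),
                     as.integer(which(intf <= attr(n, "allowed_pct"))[1]))
  }
})

test_that("microdose definition check reports which bound failed", {
  expect_true(microdose_check(100, 560000)$ok)
  r1 <- microdose_check(100, 5000)
  expect_false(r1$ok)
  expect_match(r1$message, "1/100th")
  r2 <- microdose_check(150, 100000)
  expect_false(r2$ok)
  expect_match(r2$message, "100 ug cap")
})

test_that("feasibility assessment composes the worked example end to end", {
  p <- drug_pk_params("ibrutinib", "C25H24N6O2", dose_ug = 560000,
                      vd_f_L = 10000, t_half_h = 6, cmax_ss_ng_ml = 221)
  r <- assess_feasibility(p)
  expect_equal(r$cmax_micro_ng_ml, 0.010)
  expect_identical(r$c_lloq_pg_ml, 1.25)
  expect_equal(r$allowed_interference_pct, 0.010 * 0.2 / 221 * 100)
  expect_identical(r$min_labels, 6L)
  expect_true(r$feasible_1pg)
  expect_false(r$feasible_10pg)
  expect_true(r$microdose_ok)
  expect_equal(r$sampling_horizon_h, 18)

  # a small distribution volume makes both tiers feasible
  p2 <- drug_pk_params("smallvd", "C10H14N2", 10000, 10, 4, 50)
  r2 <- assess_feasibility(p2)
  expect_equal(r2$c_lloq_pg_ml, 1250)
  expect_true(r2$feasible_1pg && r2$feasible_10pg)
})

test_that("batch assessment preserves order and the 10 pg tier implies the 1 pg tier", {
  drugs <- read_drug_table(example_drug_table())
  res <- assess_drugs(drugs)
  expect_identical(res$drug, drugs$drug)
  expect_identical(nrow(res), nrow(drugs))
  expect_true(all(!res$feasible_10pg | res$feasible_1pg))
  expect_identical(res$min_labels[res$drug == "ibrutinib"], 6L)
  expect_identical(res$min_labels[res$drug == "abemaciclib"], 5L)
  expect_equal(res$c_lloq_pg_ml[res$drug == "abemaciclib"], 18.1,
               tolerance = 1e-3)
})

test_that("drug parameter validation rejects bad inputs", {
  expect_error(drug_pk_params("x", "C2H6", -1, 10, 1, 1), "dose_ug")
  expect_error(drug_pk_params("x", "C2H6", 1, 10, 1, NA), "cmax_ss_ng_ml")
  expect_error(drug_pk_params("x", "Xx2", 1, 10, 1, 1), "unknown element")
})
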