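---
title: "Planning stable isotopically labeled microdose bioavailability trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning stable isotopically labeled microdose bioavailability trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silmtools)
```

## The problem

Absolute bioavailability compares systemic exposure after an extravascular
dose with exposure after an intravenous reference:

$$F = \frac{AUC_{ev}}{AUC_{iv}} \cdot \frac{Dose_{iv}}{Dose_{ev}}$$

The stable isotopically labeled microdose (SILM) design obtains the IV
reference from a heavy-isotope-labeled microdose (at most 1/100th of the
therapeutic dose, never more than 100 µg) injected at the oral dose's Tmax
during a single dosing event. LC-MS/MS separates the two species by mass, so
oral and IV exposure are measured in the same subject at the same time,
removing inter-occasion and intra-subject variability. Feasibility for a
specific drug turns on two numbers this package computes: the assay
sensitivity required to follow the microdose, and the number of isotope
labels required to keep the unlabeled drug's natural isotopologues out of
the labeled drug's mass channel.

## Isotopologue abundance patterns

A molecule's isotopologue distribution is obtained by treating each atom's
isotope pattern as a polynomial in the mass-shift variable and multiplying:
each element's single-atom distribution is raised to its atom count (binary
exponentiation of the polynomial) and the per-element results are convolved.
`isotopologue_distribution()` aggregates by **integer nominal mass shift**
(total extra neutron count), not isotopic fine structure, matching what a
unit-mass-resolution triple quadrupole resolves. Convolutions are direct
(no FFT), so coefficients are exact to floating-point rounding; the test
suite checks agreement with a brute-force enumeration of every per-atom
isotope assignment to within 1e-12.

Two normalizations are available: *fraction of total* (sums to 1 together
with the recorded truncation loss beyond `nmax`) and *relative to the
monoisotopic peak* (M+0 = 1). Interference calculations use the latter: the
labeled drug is monitored at M+n, and the competing signal is the unlabeled
drug's natural M+n abundance relative to its M+0, of which the measured
oral Cmax is an excellent proxy.

Numerical conventions:

* The default isotope table uses IUPAC representative natural abundances
  (¹³C 1.07%, ²H 0.0115%, ¹⁵N 0.364%, ¹⁷O 0.038%, ¹⁸O 0.205%, plus S, Cl,
  Br, and monoisotopic F, P, I). Published interference figures are
  sensitive in their last digit to the abundance source, so the table is a
  versioned, swappable asset (`read_isotope_table()`), and every report
  records which table produced it. With this table the ibrutinib M+5
  relative abundance evaluates to 0.003029%; sources quoting ≈0.0029%
  imply a ¹³C abundance nearer 1.064% — a last-digit sensitivity, not a
  methodological difference.
* Reported percentages are **truncated** (not rounded) to 4 decimal places
  of percent at presentation time only (`truncate_percent()`); all
  decisions (label counts, verdicts) use full precision.
* `nmax` defaults to 12, comfortably above practical label counts (3–9).
* The formula grammar is strict Hill-style (no parentheses, adducts,
  charges or explicit isotopes); salts and hydrates must be pre-expanded to
  the species actually monitored.

## Sensitivity: the required LLOQ

A bolus microdose peaks at $C_{max} = Dose_{micro} / (V_d/F_{ss})$ (µg and L
give ng/mL directly). To extrapolate $AUC_{0-\infty}$ reliably the profile
should be quantifiable for 3 terminal half-lives, where the concentration is
$C_{max} \times 0.5^3$; that value, in pg/mL, is the required LLOQ
(`required_lloq()`). The half-life multiplier is exposed (`half_lives`,
default 3) since 3×t½ is a planning ideal rather than a law; the
drug's t½ itself sets the sampling horizon, not the LLOQ value. Verdicts
are issued at a 1 pg/mL threshold (the edge of current ultrasensitive
triple-quadrupole practice) with an informational 10 pg/mL tier (routinely
achievable). LLOQ values are reported in pg/mL throughout — mixing ng/mL
and pg/mL is the single most likely unit slip in this workflow, so units
are fixed at the interface: doses µg, volumes L, Cmax ng/mL, LLOQ pg/mL.

## Selectivity: the minimum label count

Bioanalytical guidance tolerates interference at up to 20% of the analyte
signal at its LLOQ. Applied at the microdose Cmax against the steady-state
oral Cmax:

$$\text{Max. interference \%} = \frac{C_{max,micro} \times 0.2}{C_{max,ss,oral}} \times 100$$

`min_labels()` returns the smallest $n \ge 1$ whose full-precision M+n
relative abundance does not exceed this allowance, and certifies the
boundary ($M+(n-1)$ exceeds it). For CHNO/F drugs the pattern decreases
strictly from M+1 on, so the boundary is unique; chlorine- or
bromine-containing molecules have non-monotone patterns (³⁷Cl, ⁸¹Br sit at
M+2) and the "first satisfying n" rule handles them correctly without the
monotonicity assumption. The search deliberately compares full-precision
values: display truncation must never change a label-count decision.

This whole-molecule calculation can overestimate the requirement relative
to fragment-aware (product-ion) methods, which credit labels retained in
the monitored fragment; fragment-aware interference is out of scope here,
so results are conservative (never too few labels).

## Non-compartmental analysis and F

`auc_0_tlast()` uses the pharmacokinetic-standard linear-up/log-down
trapezoid (logarithmic rule only between two positive, strictly decreasing
samples — exact for mono-exponential decay). `lambda_z()` fits log-linear
regressions over suffix windows of 3–7 points after (and excluding) the
observed Cmax and keeps the window with the highest adjusted R², ties going
to more points — a deterministic, auditable rule. `auc_0_inf()` adds
$C_{last}/\lambda_z$ and flags extrapolation above 20% as a quality
warning. Concentrations below a caller-supplied LLOQ are dropped (never
imputed as zero), except the first post-dose sample, mirroring
bioanalytical reporting practice and linking the analysis to the planning
rule above. In the concomitant design each route is analysed on its own
clock (oral: time since ingestion; IV: time since injection) and F uses
each route's own $AUC_{0-\infty}$.

## The simulator: what it emulates and what it does not

`simulate_study()` generates the concomitant design from one-compartment
kinetics — first-order absorption for the oral dose,
$C(t) = \frac{F D k_a}{V_d (k_a - k_e)} (e^{-k_e t} - e^{-k_a t})$, and
bolus decay for the labeled microdose injected at the oral Tmax. Choices:

* **Noise** is multiplicative lognormal with mean 1 (bioanalytical error is
  proportional), default CV 10%, drawn from a private seeded stream so
  identical designs and seeds give identical output and callers' RNG state
  is untouched.
* **Kinetic isotope effect** is a single clearance multiplier on the
  labeled species (the simplest mechanism for "the label alters
  metabolism"). Analytically the estimated F then equals $F \times KIE$: a
  multiplier above 1 (faster labeled clearance) shrinks $AUC_{iv}$ and
  biases F high; the physically common deuterium effect slows labeled
  clearance (multiplier below 1) and biases F low. The tests verify both
  directions by simulation.
* **Sampling** defaults to 16 points over 7 elimination half-lives,
  quadratically front-loaded; the noiseless recovery checks use 64 points
  so trapezoid discretisation error (linear-up segments during absorption)
  stays below the 2% comparison band.

The simulator does **not** emulate multi-compartment distribution,
enterohepatic recirculation, nonlinear (saturable) clearance between
microdose and therapeutic dose, or between-subject variability. Passing
recovery tests therefore demonstrate correctness of the estimation chain
under linear one-compartment assumptions — not robustness of the SILM
design to nonlinear kinetics, which is precisely the scenario concomitant
dosing is meant to defuse in real trials.

Validation scale used by the test suite: 200 simulated studies at CV 10%
(16-point schedules) for the bias/precision checks, 100 randomized
formula/allowance pairs for the label-count boundary property, brute-force
isotope enumeration up to 8 atoms. True F in recovery checks is 0.46, a
representative mid-range bioavailability for oral kinase inhibitors.

## Worked fixtures

`example_drug_table()` ships two rows. The ibrutinib row is the canonical
worked example (Vd/F of 10,000 L back-computed from its 0.010 ng/mL
theoretical microdose Cmax; oral Cmax,ss 221 ng/mL) and reproduces: allowed
interference 0.000905%, required LLOQ 1.25 pg/mL (1.3 at two significant
figures), minimum 6 labels. The abemaciclib row is a back-computed,
partially synthetic fixture: Vd/F 690 L reproduces an 18.1 pg/mL LLOQ, and
a literature-typical steady-state Cmax of 200 ng/mL yields a 5-label
requirement; it exists to exercise the pipeline on a second realistic drug,
not as a reference dataset.

```{r example}
res <- assess_drugs(read_drug_table(example_drug_table()))
res[, c("drug", "c_lloq_pg_ml", "allowed_interference_pct", "min_labels",
        "feasible_1pg", "feasible_10pg")]
```

## Known limitations

* Whole-molecule (not fragment-aware) interference: label counts are upper
  bounds for MRM assays whose product ions retain labels.
* Aggregation by nominal mass shift assumes unit-mass resolution;
  high-resolution instruments resolving fine structure would see lower
  interference at a given shift.
* The microdose-definition check warns on, but does not model, dose
  nonlinearity.
* Single-subject estimation: the package computes per-subject F and leaves
  cohort statistics to the caller.
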