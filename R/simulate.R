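#' Design of a simulated concomitant SILM study
#'
#' One-compartment kinetics: the oral therapeutic dose follows first-order
#' absorption and elimination; the labeled intravenous microdose is a bolus
#' injected, by default, at the oral Tmax (the trial design's injection
#' time). A kinetic isotope effect is modelled as a single clearance
#' multiplier on the labeled species.
#'
#' @param F_true true absolute bioavailability (fraction).
#' @param vd_L volume of distribution (L).
#' @param ke elimination rate constant (1/h).
#' @param ka first-order absorption rate constant (1/h); must differ from `ke`.
#' @param oral_dose_ug oral therapeutic dose (ug).
#' @param microdose_ug intravenous microdose (ug, default 100).
#' @param t_inject_h injection time of the microdose on the study clock
#'   (default the oral Tmax, `log(ka/ke) / (ka - ke)`).
#' @param sampling_times_h per-channel sampling offsets (h since that
#'   channel's own dose; default 16 points over 7 elimination half-lives,
#'   front-loaded to resolve absorption).
#' @param noise_cv multiplicative lognormal noise CV (fraction, default 0.1).
#' @param kie clearance multiplier for the labeled species (default 1 = no
#'   kinetic isotope effect; values above 1 clear the label faster).
#' @param lloq_ng_ml assay LLOQ used to censor simulated samples (default
#'   `NULL`: no censoring).
#' @param seed integer seed recorded in the output; all randomness in
#'   [simulate_study()] flows from it.
#' @return Object of class `simulation_design`.
#' @examples
#' d <- simulation_design(F_true = 0.46, vd_L = 500, ke = 0.1, ka = 1,
#'                        oral_dose_ug = 500000, seed = 42)
#' @export
simulation_design <- function(F_true, vd_L, ke, ka, oral_dose_ug,
                              microdose_ug = 100, t_inject_h = NULL,
                              sampling_times_h = NULL, noise_cv = 0.1,
                              kie = 1, lloq_ng_ml = NULL, seed = 1L) {
  check_positive(vd_L = vd_L, ke = ke, ka = ka, oral_dose_ug = oral_dose_ug,
                 microdose_ug = microdose_ug, kie = kie)
  if (!is.finite(F_true) || F_true < 0 || F_true > 1) {
    stop("F_true must be a fraction in [0, 1]", call. = FALSE)
  }
  if (ka == ke) stop("degenerate model: ka must differ from ke", call. = FALSE)
  if (!is.finite(noise_cv) || noise_cv < 0) {
    stop("noise_cv must be >= 0", call. = FALSE)
  }
  if (is.null(t_inject_h)) t_inject_h <- oral_tmax(ka, ke)
  if (is.null(sampling_times_h)) {
    sampling_times_h <- default_sampling_times(ke)
  }
  stopifnot(all(diff(sampling_times_h) > 0), sampling_times_h[1] >= 0)
  structure(list(F_true = F_true, vd_L = vd_L, ke = ke, ka = ka,
                 oral_dose_ug = oral_dose_ug, microdose_ug = microdose_ug,
                 t_inject_h = t_inject_h,
                 sampling_times_h = as.numeric(sampling_times_h),
                 noise_cv = noise_cv, kie = kie, lloq_ng_ml = lloq_ng_ml,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Time of the oral concentration maximum
#'
#' For first-order absorption and elimination, `Tmax = log(ka/ke)/(ka - ke)`.
#'
#' @param ka,ke absorption and elimination rate constants (1/h).
#' @return Tmax in hours.
#' @export
oral_tmax <- function(ka, ke) {
  check_positive(ka = ka, ke = ke)
  if (ka == ke) stop("degenerate model: ka must differ from ke", call. = FALSE)
  log(ka / ke) / (ka - ke)
}

# 16 samples over 7 elimination half-lives, quadratically front-loaded
default_sampling_times <- function(ke, n = 16L, n_half_lives = 7) {
  horizon <- n_half_lives * log(2) / ke
  horizon * seq(0, 1, length.out = n)^2
}

#' Noiseless oral concentration-time profile
#'
#' `C(t) = F * D * ka / (Vd * (ka - ke)) * (exp(-ke t) - exp(-ka t))`
#' in ng/mL (dose ug, volume L), on the unlabeled channel.
#'
#' @param design `simulation_design`.
#' @param times_h sampling times since ingestion (default the design's).
#' @return `pk_profile`.
#' @export
simulate_oral <- function(design, times_h = design$sampling_times_h) {
  stopifnot(inherits(design, "simulation_design"))
  with(design, {
    conc <- F_true * oral_dose_ug * ka / (vd_L * (ka - ke)) *
      (exp(-ke * times_h) - exp(-ka * times_h))
    pk_profile(times_h, pmax(conc, 0), channel = "unlabeled", route = "oral",
               dose_ug = oral_dose_ug, t0_h = 0)
  })
}

#' Noiseless labeled IV microdose profile
#'
#' Bolus kinetics on the labeled channel, in time since injection:
#' `C(t) = microdose / Vd * exp(-ke * kie * t)`. The kinetic isotope effect
#' multiplies the elimination rate of the labeled species only.
#'
#' @param design `simulation_design`.
#' @param times_h sampling times since injection (default the design's).
#' @return `pk_profile` with `t0_h` set to the injection time.
#' @export
simulate_iv_microdose <- function(design, times_h = design$sampling_times_h) {
  stopifnot(inherits(design, "simulation_design"))
  with(design, {
    conc <- microdose_ug / vd_L * exp(-ke * kie * times_h)
    pk_profile(times_h, conc, channel = "labeled", route = "iv",
               dose_ug = microdose_ug, t0_h = t_inject_h)
  })
}

#' Simulate a full concomitant SILM study
#'
#' Generates the paired oral-unlabeled and IV-labeled profiles of the
#' concomitant design, applies multiplicative lognormal noise (mean 1, the
#' stated CV) to both channels, censors samples below the design LLOQ and
#' returns the profiles together with a truth record. Identical designs and
#' seeds give identical output.
#'
#' @param design `simulation_design`.
#' @return List with `oral` and `iv` (`pk_profile`s), `profiles` (long-format
#'   data.frame with columns subject, channel, route, dose_ug, time_h,
#'   conc_ng_ml; times on the study clock), and `truth` (all design
#'   parameters plus the seed).
#' @examples
#' d <- simulation_design(0.46, 500, 0.1, 1, 5e5, noise_cv = 0, seed = 7)
#' st <- simulate_study(d)
#' bioavailability_from_profiles(st$oral, st$iv)$F
#' @export
simulate_study <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  oral <- simulate_oral(design)
  iv <- simulate_iv_microdose(design)
  rng <- make_noise_rng(design$seed)
  oral$conc_ng_ml <- oral$conc_ng_ml * rng(length(oral$conc_ng_ml),
                                           design$noise_cv)
  iv$conc_ng_ml <- iv$conc_ng_ml * rng(length(iv$conc_ng_ml),
                                       design$noise_cv)
  if (!is.null(design$lloq_ng_ml)) {
    oral <- apply_lloq(oral, design$lloq_ng_ml)
    iv <- apply_lloq(iv, design$lloq_ng_ml)
  }
  profiles <- rbind(
    data.frame(subject = 1L, channel = "unlabeled", route = "oral",
               dose_ug = design$oral_dose_ug,
               time_h = oral$time_h + oral$t0_h,
               conc_ng_ml = oral$conc_ng_ml),
    data.frame(subject = 1L, channel = "labeled", route = "iv",
               dose_ug = design$microdose_ug,
               time_h = iv$time_h + iv$t0_h,
               conc_ng_ml = iv$conc_ng_ml)
  )
  list(oral = oral, iv = iv, profiles = profiles,
       truth = unclass(design))
}

# lognormal multiplicative noise with mean 1 at the requested CV, drawn from
# a private RNG stream so callers' RNG state is untouched
make_noise_rng <- function(seed) {
  state <- NULL
  function(n, cv) {
    if (cv == 0) return(rep(1, n))
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, globalenv())
    sdlog <- sqrt(log(1 + cv^2))
    out <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    state <<- get(".Random.seed", globalenv())
    out
  }
}
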