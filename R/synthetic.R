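#' @title Synthetic trauma-registry cohort generator
#' @description Generates registry-like cohorts in the canonical schema. A
#'   single latent severity factor couples physiology, labs, injury flags and
#'   the massive-transfusion outcome; marginal means/SDs default to the
#'   published baseline table of the registry extract this package emulates,
#'   and the outcome model intercept is calibrated so the expected MT
#'   prevalence matches its target.
#' @name synthetic-cohort
NULL

# Clip ranges (physiological plausibility). Variables generated on the log
# scale (lactate, INR) are clipped after exponentiation.
.CLIP_RANGES <- list(
  age = c(18, 100), heart_rate_er = c(0, 250), sbp_er = c(30, 300),
  hemoglobin_er = c(2, 20), base_excess_er = c(-30, 20),
  lactate_er = c(0, 30), inr_er = c(0.8, 10), quick_er = c(5, 150),
  iss = c(0, 75)
)

.DEFAULT_MARGINALS <- list(
  age            = c(mean = 45.7, sd = 19.3),
  heart_rate_er  = c(mean = 89.7, sd = 20),
  sbp_er         = c(mean = 125.3, sd = 28.6),
  hemoglobin_er  = c(mean = 11.8, sd = 2.6),
  base_excess_er = c(mean = -2.6, sd = 4.3),
  lactate_er     = c(mean = 3.1, sd = 5.2),
  inr_er         = c(mean = 1.2, sd = 0.5),
  quick_er       = c(mean = 81.2, sd = 21.1),
  iss            = c(mean = 24.3, sd = 13.2)
)

# Signed loading of each variable on the latent severity factor.
.DEFAULT_LOADINGS <- c(
  age = 0, heart_rate_er = 0.5, sbp_er = -0.5, hemoglobin_er = -0.5,
  base_excess_er = -0.5, lactate_er = 0.5, inr_er = 0.5, quick_er = -0.5,
  iss = 0.5
)

.DEFAULT_FLAG_PREVALENCES <- c(
  pelvis_displaced = 0.10,  # pelvis AIS >= 4
  femur_fracture   = 0.06,  # femur AIS >= 3
  fast_positive    = 0.15,
  ct_free_fluid    = 0.10
)

.INELIGIBLE_RULES <- c("age", "primary", "icu", "prbc", "hemostatics")

#' Specification of a synthetic cohort
#'
#' Bundles and validates every generator parameter. Defaults reproduce the
#' published cohort structure this package emulates: baseline marginal
#' means/SDs, 73.4% male, 95% blunt mechanism and a 5.6% massive-transfusion
#' prevalence.
#'
#' @param n Number of eligible patients to generate (>= 1).
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   cohort.
#' @param marginals Named list of `c(mean, sd)` per continuous variable;
#'   entries override the defaults.
#' @param male_fraction,blunt_fraction Fractions in `[0, 1]`.
#' @param severity_loadings Named signed loadings in `[-1, 1]`; entries
#'   override the defaults (heart rate, lactate, INR, ISS load positively;
#'   blood pressure, haemoglobin, base excess, Quick negatively).
#' @param flag_prevalences Named prevalences for `pelvis_displaced`
#'   (AIS >= 4), `femur_fracture` (AIS >= 3), `fast_positive`,
#'   `ct_free_fluid`; severity-linked via a unit-slope logistic.
#' @param p_gcs_le8 Target prevalence of severe neurological impairment
#'   (GCS <= 8), severity-linked.
#' @param outcome_beta Slope of latent severity in the outcome logit (> 0
#'   couples the outcome to severity; 0 decouples it).
#' @param target_prevalence Massive-transfusion prevalence target in (0, 1).
#' @param missingness_rate Per-field missingness probability in `[0, 1)`
#'   applied to score-relevant fields.
#' @param ineligible_counts Named integer counts of appended
#'   filter-violating records, names among
#'   `age`, `primary`, `icu`, `prbc`, `hemostatics`.
#' @return Object of class `mt_cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n = 5000, seed = 1L, marginals = list(),
                        male_fraction = 0.734, blunt_fraction = 0.95,
                        severity_loadings = c(), flag_prevalences = c(),
                        p_gcs_le8 = 0.2, outcome_beta = 2.0,
                        target_prevalence = 0.056, missingness_rate = 0,
                        ineligible_counts = c()) {
  fail <- function(field, why) {
    stop(sprintf("invalid cohort spec: field '%s' %s", field, why), call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != round(n))
    fail("n", "must be a positive integer")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    fail("seed", "must be an integer")
  marg <- .DEFAULT_MARGINALS
  for (nm in names(marginals)) {
    if (!nm %in% names(marg)) fail("marginals", paste0("has unknown variable '", nm, "'"))
    m <- marginals[[nm]]
    if (length(m) != 2 || any(is.na(m)) || m[2] <= 0)
      fail("marginals", paste0("entry '", nm, "' must be c(mean, sd) with sd > 0"))
    marg[[nm]] <- c(mean = unname(m[1]), sd = unname(m[2]))
  }
  for (f in c("male_fraction", "blunt_fraction", "target_prevalence",
              "missingness_rate", "p_gcs_le8")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      fail(f, "must be a fraction in [0, 1]")
  }
  if (missingness_rate >= 1) fail("missingness_rate", "must be below 1")
  if (target_prevalence <= 0 || target_prevalence >= 1)
    fail("target_prevalence", "must be strictly inside (0, 1)")
  loadings <- .DEFAULT_LOADINGS
  for (nm in names(severity_loadings)) {
    if (!nm %in% names(loadings))
      fail("severity_loadings", paste0("has unknown variable '", nm, "'"))
    v <- severity_loadings[[nm]]
    if (!is.numeric(v) || is.na(v) || abs(v) > 1)
      fail("severity_loadings", paste0("entry '", nm, "' must be in [-1, 1]"))
    loadings[[nm]] <- v
  }
  prev <- .DEFAULT_FLAG_PREVALENCES
  for (nm in names(flag_prevalences)) {
    if (!nm %in% names(prev))
      fail("flag_prevalences", paste0("has unknown flag '", nm, "'"))
    v <- flag_prevalences[[nm]]
    if (!is.numeric(v) || is.na(v) || v <= 0 || v >= 1)
      fail("flag_prevalences", paste0("entry '", nm, "' must be in (0, 1)"))
    prev[[nm]] <- v
  }
  if (!is.numeric(outcome_beta) || length(outcome_beta) != 1 ||
      is.na(outcome_beta) || outcome_beta < 0)
    fail("outcome_beta", "must be a nonnegative number")
  inel <- stats::setNames(integer(length(.INELIGIBLE_RULES)), .INELIGIBLE_RULES)
  for (nm in names(ineligible_counts)) {
    if (!nm %in% .INELIGIBLE_RULES)
      fail("ineligible_counts", paste0("has unknown rule '", nm, "'"))
    v <- ineligible_counts[[nm]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v != round(v))
      fail("ineligible_counts", paste0("entry '", nm, "' must be a nonnegative integer"))
    inel[[nm]] <- as.integer(v)
  }
  structure(list(
    n = as.integer(n), seed = as.integer(seed), marginals = marg,
    male_fraction = male_fraction, blunt_fraction = blunt_fraction,
    severity_loadings = loadings, flag_prevalences = prev,
    p_gcs_le8 = p_gcs_le8, outcome_beta = outcome_beta,
    target_prevalence = target_prevalence,
    missingness_rate = missingness_rate, ineligible_counts = inel),
    class = "mt_cohort_spec")
}

#' @export
print.mt_cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec: n =", x$n, ", seed =", x$seed,
      ", target MT prevalence =", x$target_prevalence, "\n")
  invisible(x)
}

# mean of N(m, s) clamped to [lo, hi]
.clamped_normal_mean <- function(m, s, lo, hi) {
  a <- (lo - m) / s; b <- (hi - m) / s
  lo * stats::pnorm(a) + hi * (1 - stats::pnorm(b)) +
    m * (stats::pnorm(b) - stats::pnorm(a)) +
    s * (stats::dnorm(a) - stats::dnorm(b))
}

# location shift so the clamped mean hits the target mean
.clip_adjusted_mu <- function(target_mean, s, lo, hi) {
  f <- function(m) .clamped_normal_mean(m, s, lo, hi) - target_mean
  stats::uniroot(f, lower = target_mean - 3 * s, upper = target_mean + 3 * s,
                 tol = 1e-10)$root
}

# first two moments of exp(mu + s Z) clamped to [lo, hi]
.clamped_lognormal_moments <- function(mu, s, lo, hi) {
  A <- if (lo > 0) (log(lo) - mu) / s else -Inf
  B <- (log(hi) - mu) / s
  p_lo <- stats::pnorm(A); p_hi <- 1 - stats::pnorm(B)
  m1 <- lo * p_lo + hi * p_hi +
    exp(mu + s^2 / 2) * (stats::pnorm(B - s) - stats::pnorm(A - s))
  m2 <- lo^2 * p_lo + hi^2 * p_hi +
    exp(2 * mu + 2 * s^2) * (stats::pnorm(B - 2 * s) - stats::pnorm(A - 2 * s))
  c(mean = m1, sd = sqrt(max(0, m2 - m1^2)))
}

# lognormal parameters whose CLAMPED distribution matches (mean, sd);
# clamping a heavy upper tail otherwise deflates the sd well below target
.clipped_lognormal_params <- function(target_mean, target_sd, lo, hi) {
  # naive (unclipped) moment match as the starting point
  s2 <- log(1 + (target_sd / target_mean)^2)
  start <- c(log(target_mean) - s2 / 2, log(sqrt(s2)))
  obj <- function(par) {
    mom <- .clamped_lognormal_moments(par[1], exp(par[2]), lo, hi)
    ((mom[1] - target_mean) / target_mean)^2 + ((mom[2] - target_sd) / target_sd)^2
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  c(mu = unname(fit$par[1]), sigma = exp(unname(fit$par[2])))
}

# E[plogis(alpha + beta * S)], S standard normal
.expected_logistic <- function(alpha, beta) {
  if (beta == 0) return(stats::plogis(alpha))
  stats::integrate(function(s) stats::plogis(alpha + beta * s) * stats::dnorm(s),
                   -Inf, Inf, rel.tol = 1e-10)$value
}

# bisection for the intercept giving a target marginal probability
.calibrate_logit_intercept <- function(target, beta, tolerance = 1e-6) {
  if (!is.finite(target) || target <= 0 || target >= 1) {
    stop("target prevalence must be strictly inside (0, 1)", call. = FALSE)
  }
  if (beta == 0) return(stats::qlogis(target))
  lo <- -20; hi <- 20
  repeat {
    mid <- (lo + hi) / 2
    p <- .expected_logistic(mid, beta)
    if (abs(p - target) <= tolerance || (hi - lo) < 1e-12) return(mid)
    if (p < target) lo <- mid else hi <- mid
  }
}

#' Calibrate the outcome-model intercept
#'
#' Finds, by bisection, the intercept `alpha` such that the expected
#' massive-transfusion prevalence `E[plogis(alpha + beta * S)]` under a
#' standard-normal latent severity `S` (evaluated by quadrature) matches the
#' spec's target. With `beta = 0` the closed form `qlogis(target)` is
#' returned.
#'
#' @param spec An `mt_cohort_spec` (uses its `target_prevalence` and
#'   `outcome_beta`).
#' @param tolerance Absolute tolerance on the expected prevalence.
#' @return The calibrated intercept.
#' @export
calibrate_intercept <- function(spec, tolerance = 1e-6) {
  stopifnot(inherits(spec, "mt_cohort_spec"), tolerance > 0)
  .calibrate_logit_intercept(spec$target_prevalence, spec$outcome_beta,
                             tolerance)
}

#' Generate a synthetic trauma cohort
#'
#' Draws `n` eligible patients: a standard-normal latent severity per
#' patient; continuous variables as `mu + sd * (rho * s + sqrt(1 - rho^2) * e)`
#' clamped to physiological ranges (with the location shifted so the clamped
#' mean still hits its target); lactate and INR on the log scale with the
#' clamped distribution moment-matched to the target mean/SD; GCS and injury
#' flags severity-linked and anchored at their prevalences; penetrating
#' mechanism and male sex independent of severity; the MT outcome from a
#' calibrated logistic in severity, with pRBC counts constructed to agree
#' with the outcome (>= 10 units iff MT). Optional missingness and
#' filter-violating records are then injected.
#'
#' @param spec An `mt_cohort_spec`.
#' @param keep_latent Add a `latent_severity` column (not part of the CSV
#'   schema) for diagnostics.
#' @return Cohort `data.frame` in the canonical schema; identical spec and
#'   seed give a bit-identical result.
#' @export
generate_cohort <- function(spec, keep_latent = FALSE) {
  stopifnot(inherits(spec, "mt_cohort_spec"))
  n <- spec$n
  set.seed(spec$seed)
  s <- stats::rnorm(n)

  draw_normal <- function(var) {
    m <- spec$marginals[[var]]; rho <- spec$severity_loadings[[var]]
    clip <- .CLIP_RANGES[[var]]
    mu <- .clip_adjusted_mu(m["mean"], m["sd"], clip[1], clip[2])
    z <- rho * s + sqrt(1 - rho^2) * stats::rnorm(n)
    pmin(pmax(mu + m["sd"] * z, clip[1]), clip[2])
  }
  draw_lognormal <- function(var) {
    m <- spec$marginals[[var]]; rho <- spec$severity_loadings[[var]]
    clip <- .CLIP_RANGES[[var]]
    par <- .clipped_lognormal_params(m["mean"], m["sd"], clip[1], clip[2])
    z <- rho * s + sqrt(1 - rho^2) * stats::rnorm(n)
    pmin(pmax(exp(par["mu"] + par["sigma"] * z), clip[1]), clip[2])
  }
  severity_flag <- function(prevalence, slope = 1) {
    alpha <- .calibrate_logit_intercept(prevalence, slope, 1e-8)
    stats::runif(n) < stats::plogis(alpha + slope * s)
  }

  age <- as.integer(round(draw_normal("age")))
  hr <- round(draw_normal("heart_rate_er"))
  sbp <- round(draw_normal("sbp_er"))
  hb <- round(draw_normal("hemoglobin_er"), 1)
  be <- round(draw_normal("base_excess_er"), 1)
  quick <- round(draw_normal("quick_er"))
  iss <- as.integer(round(draw_normal("iss")))
  lactate <- round(draw_lognormal("lactate_er"), 1)
  inr <- round(draw_lognormal("inr_er"), 2)

  sex <- ifelse(stats::runif(n) < spec$male_fraction, "male", "female")
  mechanism <- ifelse(stats::runif(n) < spec$blunt_fraction, "blunt", "penetrating")

  gcs_severe <- severity_flag(spec$p_gcs_le8)
  gcs <- integer(n)
  n_sev <- sum(gcs_severe)
  if (n_sev > 0) {
    gcs[gcs_severe] <- sample(3:8, n_sev, replace = TRUE,
                              prob = c(3, 2, 1.5, 1.2, 1, 1))
  }
  if (n_sev < n) {
    gcs[!gcs_severe] <- sample(9:15, n - n_sev, replace = TRUE,
                               prob = c(1, 1, 1, 2, 3, 5, 8))
  }

  pelvis_displaced <- severity_flag(spec$flag_prevalences[["pelvis_displaced"]])
  pelvis_ais <- integer(n)
  pelvis_ais[pelvis_displaced] <-
    ifelse(stats::runif(sum(pelvis_displaced)) < 0.6, 5L, 4L)
  minor <- !pelvis_displaced
  pelvis_ais[minor] <- sample(0:3, sum(minor), replace = TRUE,
                              prob = c(0.85, 0.06, 0.05, 0.04))
  femur_flag <- severity_flag(spec$flag_prevalences[["femur_fracture"]])
  femur_ais <- integer(n)
  femur_ais[femur_flag] <- ifelse(stats::runif(sum(femur_flag)) < 0.7, 3L, 4L)
  femur_ais[!femur_flag] <- sample(0:2, sum(!femur_flag), replace = TRUE,
                                   prob = c(0.9, 0.06, 0.04))
  fast_positive <- severity_flag(spec$flag_prevalences[["fast_positive"]])
  ct_free_fluid <- severity_flag(spec$flag_prevalences[["ct_free_fluid"]])

  alpha <- .calibrate_logit_intercept(spec$target_prevalence,
                                      spec$outcome_beta, 1e-8)
  mt <- stats::runif(n) < stats::plogis(alpha + spec$outcome_beta * s)
  prbc <- integer(n)
  prbc[mt] <- 10L + stats::rpois(sum(mt), 4)
  prbc[!mt] <- pmin(stats::rgeom(sum(!mt), 0.6), 9L)

  cohort <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = age, sex = sex, mechanism = mechanism,
    primary_admission = TRUE, survived_to_icu = TRUE,
    heart_rate_er = hr, sbp_er = sbp, hemoglobin_er = hb,
    base_excess_er = be, lactate_er = lactate, inr_er = inr,
    quick_er = quick, gcs = gcs, fast_positive = fast_positive,
    ct_free_fluid = ct_free_fluid, pelvis_ais = pelvis_ais,
    femur_ais = femur_ais, prbc_units_er_to_icu = prbc,
    hemostatic_agents = FALSE, iss = iss,
    stringsAsFactors = FALSE)

  if (spec$missingness_rate > 0) {
    cohort <- inject_missingness(cohort, spec$missingness_rate,
                                 seed = spec$seed + 1L)
  }
  if (sum(spec$ineligible_counts) > 0) {
    cohort <- inject_ineligible(cohort, spec$ineligible_counts,
                                seed = spec$seed + 2L)
  }
  if (keep_latent) cohort$latent_severity <- c(s, rep(NA_real_,
                                                      nrow(cohort) - n))
  cohort
}

#' Inject missingness into score-relevant fields
#'
#' Sets each score-relevant field independently to missing with probability
#' `rate`; deterministic given `seed`. Supports testing of the complete-case
#' eligibility filter.
#'
#' @param records Cohort `data.frame`.
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The records with missing values injected.
#' @export
inject_missingness <- function(records, rate, seed = 1L) {
  stopifnot(is.data.frame(records), rate >= 0, rate < 1)
  if (rate == 0 || nrow(records) == 0) return(records)
  fields <- score_required_fields()
  withr_seed(seed, {
    for (f in fields) {
      hit <- stats::runif(nrow(records)) < rate
      records[[f]][hit] <- NA
    }
  })
  records
}

#' Append filter-violating records
#'
#' Appends synthetic records that each violate exactly one eligibility rule
#' (under-age, not primary-admitted, died before ICU, missing pRBC count,
#' hemostatic agents given) and are otherwise clean, so that
#' [apply_eligibility_filters()] recovers the injected counts.
#'
#' @param records Cohort `data.frame`.
#' @param counts Named counts, names among `age`, `primary`, `icu`, `prbc`,
#'   `hemostatics`.
#' @param seed Integer seed (used for the violators' covariate draws).
#' @return The records with violators appended.
#' @export
inject_ineligible <- function(records, counts, seed = 1L) {
  stopifnot(is.data.frame(records))
  full <- stats::setNames(integer(length(.INELIGIBLE_RULES)), .INELIGIBLE_RULES)
  for (nm in names(counts)) {
    if (!nm %in% .INELIGIBLE_RULES) stop("unknown rule: ", nm, call. = FALSE)
    full[[nm]] <- as.integer(counts[[nm]])
  }
  total <- sum(full)
  if (total == 0) return(records)
  template <- function(id) data.frame(
    patient_id = id, age = 40L, sex = "male", mechanism = "blunt",
    primary_admission = TRUE, survived_to_icu = TRUE,
    heart_rate_er = 90, sbp_er = 125, hemoglobin_er = 11.8,
    base_excess_er = -2.6, lactate_er = 1.9, inr_er = 1.1, quick_er = 84,
    gcs = 15L, fast_positive = FALSE, ct_free_fluid = FALSE,
    pelvis_ais = 0L, femur_ais = 0L, prbc_units_er_to_icu = 0L,
    hemostatic_agents = FALSE, iss = 20L, stringsAsFactors = FALSE)
  rows <- withr_seed(seed, {
    out <- list(); k <- 0
    for (rule in .INELIGIBLE_RULES) {
      for (i in seq_len(full[[rule]])) {
        k <- k + 1
        r <- template(sprintf("INEL_%s_%03d", rule, i))
        switch(rule,
          age = { r$age <- sample(1:17, 1) },
          primary = { r$primary_admission <- FALSE },
          icu = { r$survived_to_icu <- FALSE },
          prbc = { r$prbc_units_er_to_icu <- NA_integer_ },
          hemostatics = { r$hemostatic_agents <- TRUE })
        out[[k]] <- r
      }
    }
    out
  })
  extra <- do.call(rbind, rows)
  if (!is.null(records$latent_severity)) extra$latent_severity <- NA_real_
  rbind(records, extra[names(records)])
}
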