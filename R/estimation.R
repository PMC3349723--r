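## Parameter estimation: back-calculation of baseline (risk-class-specific)
## rates from population-level rates and relative risks, additive
## decomposition of total mortality, and net transition probabilities.
##
## The central identity is
##   population rate(a,s) = baseline rate(a,s) * E[RR | a,s],
## where the expectation is over the risk-factor distribution at (a,s).
## The baseline rate is the rate in a (possibly hypothetical) class with
## relative risk 1.

#' Expected relative risk over the risk-factor distribution
#'
#' For categorical factors this is the prevalence-weighted mean of the
#' class relative risks; the duration-dependent class contributes its
#' duration-distribution-weighted RR.  For continuous factors it is
#' `E[RR^(X - x0)]` under the declared (normal or log-normal) exposure
#' distribution, evaluated by Gauss--Legendre quadrature on a range
#' truncated at 6 standard deviations.
#'
#' @param rf A [risk_factor_spec()].
#' @param rr An [rr_spec()].
#' @param age,sex Optional single age and sex; if omitted the full
#'   [age_sex_table()] is returned.
#' @return A single number, or an `age_sex_table` when `age`/`sex` are
#'   omitted.
#' @export
expected_rr <- function(rf, rr, age = NULL, sex = NULL) {
  tab <- if (rf$kind == "continuous") {
    expected_rr_continuous(rf, rr)
  } else {
    eff <- eff_class_rr(rf, rr)
    v <- matrix(0, AGE_MAX + 1L, 2L)
    for (k in seq_len(n_classes(rf))) v <- v + rf$prevalence[, , k] * eff[k]
    age_sex_table(v)
  }
  if (is.null(age)) tab else ast_at(tab, age, sex)
}

## Class-level relative risks with the duration class collapsed to its
## duration-distribution-weighted mean (used for estimation, where only the
## class marginal matters).
eff_class_rr <- function(rf, rr) {
  K <- n_classes(rf)
  eff <- rr$per_class
  if (is.null(eff)) eff <- rep(1, K)
  if (rf$kind == "duration" && !is.null(rr$duration_table)) {
    w <- rf$duration_distribution
    tab <- rr$duration_table
    idx <- pmin(seq_along(w) - 1L, length(tab) - 1L) + 1L
    eff[rf$duration_category] <- sum(w * tab[idx])
  }
  eff
}

expected_rr_continuous <- function(rf, rr, n_nodes = 96L) {
  if (is.null(rr$per_unit)) return(age_sex_table(1))
  log_rr <- log(rr$per_unit)
  gl <- pracma::gaussLegendre(n_nodes, -6, 6)
  mu <- unclass(rf$prevalence$mean)
  sd <- unclass(rf$prevalence$sd)
  x0 <- rf$reference_value
  out <- matrix(NA_real_, AGE_MAX + 1L, 2L)
  phi <- stats::dnorm(gl$x)
  mass <- sum(gl$w * phi)   # truncated normal mass on +-6 sd
  for (s in 1:2) for (a in seq_len(AGE_MAX + 1L)) {
    if (rf$distribution == "normal") {
      x <- mu[a, s] + sd[a, s] * gl$x
    } else {
      if (mu[a, s] <= 0) stop("log-normal exposure requires mean > 0")
      sigma2 <- log(1 + sd[a, s]^2 / mu[a, s]^2)
      lmu <- log(mu[a, s]) - sigma2 / 2
      x <- exp(lmu + sqrt(sigma2) * gl$x)
    }
    out[a, s] <- sum(gl$w * phi * exp(log_rr * (x - x0))) / mass
  }
  age_sex_table(out)
}

#' Baseline rate from a population-level rate
#'
#' The baseline rate (the rate in a risk-factor class with relative risk 1)
#' is the population rate divided by the expected relative risk; the same
#' operation applies to disease incidence and to other-cause mortality.
#'
#' @param pop_rate Population-level rate [age_sex_table()].
#' @param rf A [risk_factor_spec()].
#' @param rr The [rr_spec()] linking the factor to this rate.
#' @return An `age_sex_table` of baseline rates.
#' @export
baseline_rate <- function(pop_rate, rf, rr) {
  e <- expected_rr(rf, rr)
  if (any(unclass(e) <= 0)) stop("expected relative risk must be > 0")
  age_sex_table(unclass(pop_rate) / unclass(e))
}

#' Additive decomposition of total mortality
#'
#' Other-cause mortality is total mortality minus the mortality attributable
#' to the modelled diseases: for each disease, prevalent non-cured cases
#' contribute their excess mortality and incident cases contribute the
#' acutely fatal fraction.
#'
#' @param total Total mortality hazard [age_sex_table()].
#' @param diseases List of [disease_spec()]s.
#' @return An `age_sex_table` of other-cause mortality; an error naming the
#'   first offending (age, sex) cell if the decomposition turns negative.
#' @export
decompose_other_cause_mortality <- function(total, diseases) {
  ocm <- unclass(total)
  for (d in diseases) {
    ocm <- ocm -
      unclass(d$prevalence) * (1 - d$cured_fraction) * unclass(d$excess_mortality) -
      unclass(d$incidence) * d$acutely_fatal_fraction
  }
  bad <- which(ocm < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "inconsistent inputs: negative other-cause mortality at age %d, sex %s (%.6g)",
      bad[1, 1] - 1L, SEXES[bad[1, 2]], ocm[bad[1, , drop = FALSE]]))
  }
  age_sex_table(ocm)
}

#' Risk-class-specific disease prevalence
#'
#' Population-level disease prevalence is distributed over risk-factor
#' classes proportionally to the class relative risks on incidence, so that
#' the prevalence-weighted mean over classes reproduces the population
#' value.
#'
#' @param disease A [disease_spec()].
#' @param rf A [risk_factor_spec()] (categorical or duration kind).
#' @return Array `[age, sex, category]` of within-class disease prevalence.
#' @export
class_specific_prevalence <- function(disease, rf) {
  if (rf$kind == "continuous")
    stop("class_specific_prevalence applies to categorical/duration factors")
  K <- n_classes(rf)
  eff <- eff_class_rr(rf, rr_inc_for(rf, disease$name))
  denom <- matrix(0, AGE_MAX + 1L, 2L)
  for (k in seq_len(K)) denom <- denom + rf$prevalence[, , k] * eff[k]
  out <- array(NA_real_, c(AGE_MAX + 1L, 2L, K),
               dimnames = list(age = 0:AGE_MAX, sex = SEXES,
                               category = rf$categories))
  base <- unclass(disease$prevalence) / denom
  for (k in seq_len(K)) out[, , k] <- base * eff[k]
  if (any(out > 1 + 1e-12)) {
    bad <- which(out > 1 + 1e-12, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "inconsistent inputs: class-specific prevalence of %s exceeds 1 at age %d, sex %s, class %s",
      disease$name, bad[1] - 1L, SEXES[bad[2]], rf$categories[bad[3]]))
  }
  out
}

#' Net transition probabilities
#'
#' Estimates, for every age and sex, the annual transition matrix over
#' risk-factor categories that maps the prevalence at age a exactly onto
#' the prevalence at age a+1, with flow only between adjacent (ordered)
#' categories and, across any category boundary, in one direction only
#' (minimal net flow).  Used to hold the age-specific risk-factor
#' prevalence constant over calendar time, ignoring cohort effects.
#'
#' @param rf A [risk_factor_spec()] of categorical or duration kind.
#' @return A [transition_model()] in explicit mode.
#' @export
net_transitions <- function(rf) {
  if (rf$kind == "continuous")
    stop("net transitions apply to categorical/duration factors")
  K <- n_classes(rf)
  M <- array(0, c(AGE_MAX + 1L, 2L, K, K))
  for (s in 1:2) {
    for (a in 0:AGE_MAX) {
      Tm <- diag(K)
      if (a < AGE_MAX && K > 1L) {
        p0 <- rf$prevalence[a + 1L, s, ]
        p1 <- rf$prevalence[a + 2L, s, ]
        flow <- cumsum(p0 - p1)[seq_len(K - 1L)]
        for (k in seq_len(K - 1L)) {
          f <- flow[k]
          if (f > 1e-15) {
            if (p0[k] <= 0) stop(sprintf(
              "net transitions infeasible at age %d, sex %s: flow out of empty class %s",
              a, SEXES[s], rf$categories[k]))
            Tm[k, k + 1L] <- f / p0[k]
          } else if (f < -1e-15) {
            if (p0[k + 1L] <= 0) stop(sprintf(
              "net transitions infeasible at age %d, sex %s: flow out of empty class %s",
              a, SEXES[s], rf$categories[k + 1L]))
            Tm[k + 1L, k] <- -f / p0[k + 1L]
          }
        }
        diag(Tm) <- 0
        stay <- 1 - rowSums(Tm)
        if (any(stay < -1e-9)) stop(sprintf(
          "net transitions infeasible at age %d, sex %s: required outflow exceeds class occupancy",
          a, SEXES[s]))
        diag(Tm) <- pmax(stay, 0)
      }
      M[a + 1L, s, , ] <- Tm
    }
  }
  transition_model("explicit", M)
}

## Expand any transition mode into explicit matrices.
resolve_transitions <- function(inputs) {
  tr <- inputs$transitions
  rf <- inputs$risk_factor
  switch(tr$mode,
         explicit = tr,
         zero = identity_transitions(n_classes(rf)),
         net = net_transitions(rf))
}

#' Estimate all baseline quantities for a simulation
#'
#' Runs the estimation module: decomposes total mortality into
#' disease-attributable and other-cause mortality, back-calculates baseline
#' other-cause mortality and per-disease baseline incidence, and allocates
#' disease prevalence over risk-factor classes.
#'
#' @param inputs A [sim_inputs()] bundle.
#' @return An object of class `baseline_rates`: a list with elements
#'   `other_cause_mortality` (population level), `baseline_other_cause_mortality`,
#'   `baseline_incidence` (named list per disease) and `class_prevalence`
#'   (named list of `[age, sex, category]` arrays; `NULL` entries for a
#'   continuous factor, where allocation is by individual exposure).
#' @export
estimate_baselines <- function(inputs) {
  rf <- inputs$risk_factor
  ocm <- decompose_other_cause_mortality(inputs$population$total_mortality,
                                         inputs$diseases)
  bocm <- baseline_rate(ocm, rf, rf$rr_mortality)
  binc <- lapply(inputs$diseases, function(d)
    baseline_rate(d$incidence, rf, rr_inc_for(rf, d$name)))
  cprev <- if (rf$kind == "continuous") {
    stats::setNames(vector("list", length(inputs$diseases)),
                    names(inputs$diseases))
  } else {
    lapply(inputs$diseases, function(d) class_specific_prevalence(d, rf))
  }
  structure(list(other_cause_mortality = ocm,
                 baseline_other_cause_mortality = bocm,
                 baseline_incidence = binc,
                 class_prevalence = cprev),
            class = "baseline_rates")
}
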