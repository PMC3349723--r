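## Seeded generators of internally consistent synthetic input sets.  Total
## mortality is constructed as other-cause mortality plus the
## disease-attributable terms, so the additive decomposition is exact by
## construction and the engine's first-year mortality closes on the input.

#' Parameters of the synthetic toy dataset
#'
#' Defaults describe a small but epidemiologically plausible population:
#' three ordered exposure classes with moderately harmful relative risks,
#' two chronic diseases in separate clusters (one causally linked to the
#' exposure, one unrelated), Gompertz-like other-cause mortality, constant
#' newborn inflow, and age-constant exposure prevalence (so net transitions
#' reduce to identity) unless an age gradient is requested.
#'
#' @param n_classes 2 or 3 risk-factor classes.
#' @param n_diseases 0--2 diseases.
#' @param rr_inc List of per-class RR vectors on incidence, one per
#'   disease.
#' @param rr_mort Per-class RR vector on other-cause mortality.
#' @param inc_base Base incidence hazards, one per disease.
#' @param em_base Excess-mortality hazards, one per disease.
#' @param cured,fatal Cured and acutely fatal fractions, one per disease.
#' @param same_cluster Put both diseases in one cluster.
#' @param intermediate_rr RR of disease 1 on disease 2's incidence
#'   (requires `same_cluster`); `NULL` for none.
#' @param prevalence_gradient Give exposure prevalence an age gradient
#'   (exercises non-trivial net transitions).
#' @param start_count Population count per single year of age (0--95) and
#'   sex at the start.
#' @param newborns Newborn count per simulation year (both sexes).
#' @param horizon,n_biographies,seed Simulation controls.
#' @return A list of class `toy_params`.
#' @export
toy_params <- function(n_classes = 3L, n_diseases = 2L,
                       rr_inc = NULL, rr_mort = NULL,
                       inc_base = c(0.010, 0.006), em_base = c(0.02, 0.015),
                       cured = c(0, 0), fatal = c(0, 0),
                       same_cluster = FALSE, intermediate_rr = NULL,
                       prevalence_gradient = FALSE,
                       start_count = 100, newborns = 200,
                       horizon = 10L, n_biographies = 300L, seed = 1L) {
  stopifnot(n_classes %in% 2:3, n_diseases %in% 0:2)
  if (is.null(rr_mort))
    rr_mort <- c(1, 1.3, 1.8)[seq_len(n_classes)]
  if (is.null(rr_inc)) {
    rr_inc <- list(c(1, 1.5, 2)[seq_len(n_classes)], rep(1, n_classes))
  }
  structure(list(n_classes = as.integer(n_classes),
                 n_diseases = as.integer(n_diseases),
                 rr_inc = rr_inc, rr_mort = rr_mort,
                 inc_base = inc_base, em_base = em_base,
                 cured = cured, fatal = fatal,
                 same_cluster = same_cluster,
                 intermediate_rr = intermediate_rr,
                 prevalence_gradient = prevalence_gradient,
                 start_count = start_count, newborns = newborns,
                 horizon = as.integer(horizon),
                 n_biographies = as.integer(n_biographies),
                 seed = as.integer(seed)),
            class = "toy_params")
}

toy_prevalence_array <- function(K, gradient) {
  base <- switch(K - 1L, c(0.7, 0.3), c(0.5, 0.3, 0.2))
  arr <- array(rep(base, each = (AGE_MAX + 1L) * 2L),
               c(AGE_MAX + 1L, 2L, K),
               dimnames = list(age = 0:AGE_MAX, sex = SEXES, category = NULL))
  if (gradient) {
    ages <- 0:AGE_MAX
    p1 <- 0.6 - 0.3 * pmin(ages, 95) / 95
    rest <- 1 - p1
    share <- base[-1L] / sum(base[-1L])
    for (s in 1:2) {
      arr[, s, 1L] <- p1
      for (k in 2:K) arr[, s, k] <- rest * share[k - 1L]
    }
  }
  arr
}

#' Generate a consistent synthetic input set
#'
#' Builds other-cause mortality and the disease tables first, then total
#' mortality as their additive sum, so [decompose_other_cause_mortality()]
#' recovers the constructed other-cause mortality exactly.  Deterministic
#' given the parameters (the seed only drives the simulation itself).
#'
#' @param params A [toy_params()] list.
#' @return A [sim_inputs()] bundle that passes [validate_inputs()].
#' @export
make_toy_dataset <- function(params = toy_params()) {
  p <- params
  K <- p$n_classes
  classes <- c("low", "mid", "high")[seq_len(K)]
  prev <- toy_prevalence_array(K, p$prevalence_gradient)
  dimnames(prev)[[3]] <- classes

  ocm <- age_sex_table(function(a) 5e-4 * exp(0.065 * pmin(a, 100)))
  diseases <- list()
  dnames <- c("cardio", "lungdis")[seq_len(p$n_diseases)]
  for (d in seq_len(p$n_diseases)) {
    inc <- age_sex_table(function(a) p$inc_base[d] * (0.25 + 1.5 * pmin(a, 95) / 95))
    dprev <- age_sex_table(function(a) 0.01 + (0.06 + 0.02 * d) * pmin(a, 95) / 95)
    em <- age_sex_table(p$em_base[d])
    irr <- list()
    if (!is.null(p$intermediate_rr) && d == 1L && p$n_diseases == 2L &&
        p$same_cluster)
      irr <- stats::setNames(list(p$intermediate_rr), dnames[2L])
    diseases[[dnames[d]]] <- disease_spec(
      name = dnames[d],
      cluster = if (p$same_cluster) "cluster1" else paste0("cluster", d),
      incidence = inc, prevalence = dprev, excess_mortality = em,
      cured_fraction = p$cured[d], acutely_fatal_fraction = p$fatal[d],
      intermediate_rr = irr)
  }

  total <- unclass(ocm)
  for (d in diseases) {
    total <- total +
      unclass(d$prevalence) * (1 - d$cured_fraction) * unclass(d$excess_mortality) +
      unclass(d$incidence) * d$acutely_fatal_fraction
  }

  rr_incidence <- list()
  for (d in seq_len(p$n_diseases))
    rr_incidence[[dnames[d]]] <- rr_spec(per_class = p$rr_inc[[d]])
  rf <- risk_factor_spec("categorical", categories = classes,
                         prevalence = prev, rr_incidence = rr_incidence,
                         rr_mortality = rr_spec(per_class = p$rr_mort))

  pop <- population_spec(
    start_counts = age_sex_table(function(a) ifelse(a <= 95, p$start_count, 0)),
    newborns = rep(p$newborns, p$horizon),
    newborn_sex_ratio = 0.5,
    total_mortality = age_sex_table(total))

  inputs <- sim_inputs(population = pop, risk_factor = rf,
                       transitions = transition_model("net"),
                       diseases = diseases,
                       horizon = p$horizon, n_biographies = p$n_biographies,
                       seed = p$seed)
  attr(inputs, "constructed_ocm") <- ocm
  inputs
}

#' Input sets with analytically known outputs
#'
#' Small configurations whose outcomes have closed forms, used to validate
#' the pipeline end to end.
#'
#' @param which One of:
#'   * `"constant_hazard"`: single class, no disease, annual death
#'     probability 1/2 at every age, so life expectancy is 1.5 years;
#'   * `"single_disease"`: one disease with constant incidence hazard 0.1,
#'     no excess or other-cause mortality, so disease occupancy after t
#'     years is `1 - exp(-0.1 t)`;
#'   * `"two_cluster"`: two diseases in independent clusters with hazards
#'     0.1 and 0.05, so the jointly disease-free share after t years is
#'     `exp(-0.15 t)`;
#'   * `"two_state_protective"`: two classes whose only effect is a
#'     mortality RR of (1, 3); moving everyone into class 1 must lower
#'     deaths;
#'   * `"stationary"`: constant exposure prevalence (net transitions reduce
#'     to identity), constant mortality hazard 0.01 with the matching
#'     stationary age structure, constant newborn inflow, and a disease
#'     whose input prevalence follows the model's own incidence recursion,
#'     so period measures are constant over time.
#' @param horizon,n_biographies Overrides of the per-case defaults.
#' @return List with `inputs` (a [sim_inputs()]) and `expected` (named list
#'   of closed-form values).
#' @export
make_closed_form_case <- function(which = c("constant_hazard", "single_disease",
                                            "two_cluster", "two_state_protective",
                                            "stationary"),
                                  horizon = NULL, n_biographies = NULL) {
  which <- match.arg(which)
  one_class <- function() risk_factor_spec(
    "categorical", categories = "all",
    prevalence = array(1, c(AGE_MAX + 1L, 2L, 1L)))
  flat_pop <- function(total_mortality, count = 100) population_spec(
    start_counts = age_sex_table(function(a) ifelse(a <= 95, count, 0)),
    newborns = rep(count, 50), newborn_sex_ratio = 0.5,
    total_mortality = total_mortality)

  if (which == "constant_hazard") {
    q <- 0.5
    inputs <- sim_inputs(
      population = flat_pop(age_sex_table(-log(1 - q))),
      risk_factor = one_class(), transitions = transition_model("zero"),
      diseases = list(),
      horizon = if (is.null(horizon)) 12L else horizon,
      n_biographies = if (is.null(n_biographies)) 20L else n_biographies,
      seed = 7L)
    return(list(inputs = inputs,
                expected = list(period_le = 1.5, cohort_le = 1.5,
                                annual_death_probability = q)))
  }

  if (which %in% c("single_disease", "two_cluster")) {
    lam <- if (which == "single_disease") 0.1 else c(0.1, 0.05)
    diseases <- list()
    for (d in seq_along(lam)) {
      nm <- paste0("disease", d)
      diseases[[nm]] <- disease_spec(
        name = nm, cluster = paste0("cluster", d),
        incidence = age_sex_table(lam[d]),
        prevalence = age_sex_table(0),
        excess_mortality = age_sex_table(0))
    }
    inputs <- sim_inputs(
      population = flat_pop(age_sex_table(0)),
      risk_factor = one_class(), transitions = transition_model("zero"),
      diseases = diseases,
      horizon = if (is.null(horizon)) 5L else horizon,
      n_biographies = if (is.null(n_biographies)) 20L else n_biographies,
      seed = 7L)
    expected <- if (which == "single_disease") {
      list(occupancy_at = function(t) 1 - exp(-0.1 * t))
    } else {
      list(none_at = function(t) exp(-sum(lam) * t))
    }
    return(list(inputs = inputs, expected = expected))
  }

  if (which == "two_state_protective") {
    prev <- array(NA_real_, c(AGE_MAX + 1L, 2L, 2L))
    prev[, , 1L] <- 0.5; prev[, , 2L] <- 0.5
    rf <- risk_factor_spec("categorical", categories = c("safe", "exposed"),
                           prevalence = prev,
                           rr_mortality = rr_spec(per_class = c(1, 3)))
    erc <- 0.5 * 1 + 0.5 * 3
    inputs <- sim_inputs(
      population = flat_pop(age_sex_table(0.02)),
      risk_factor = rf, transitions = transition_model("zero"),
      diseases = list(),
      horizon = if (is.null(horizon)) 10L else horizon,
      n_biographies = if (is.null(n_biographies)) 400L else n_biographies,
      seed = 7L)
    return(list(inputs = inputs,
                expected = list(baseline_ocm = 0.02 / erc)))
  }

  ## stationary
  m <- 0.01
  lam <- 0.02
  pi_d <- numeric(AGE_MAX + 1L)
  for (a in seq_len(AGE_MAX)) {
    pi_d[a + 1L] <- pi_d[a] + (1 - pi_d[a]) * (1 - exp(-lam))
  }
  prev <- array(NA_real_, c(AGE_MAX + 1L, 2L, 2L))
  prev[, , 1L] <- 0.6; prev[, , 2L] <- 0.4
  rf <- risk_factor_spec("categorical", categories = c("a", "b"),
                         prevalence = prev)
  disease <- disease_spec("cond", cluster = "c1",
                          incidence = age_sex_table(lam),
                          prevalence = age_sex_table(cbind(pi_d, pi_d)),
                          excess_mortality = age_sex_table(0))
  ## stationarity: newborn inflow per sex must equal the age-0 start count
  pop <- population_spec(
    start_counts = age_sex_table(function(a) ifelse(a <= 95, 100 * exp(-m * a), 0)),
    newborns = rep(200, 50), newborn_sex_ratio = 0.5,
    total_mortality = age_sex_table(m))
  inputs <- sim_inputs(population = pop, risk_factor = rf,
                       transitions = transition_model("net"),
                       diseases = list(cond = disease),
                       horizon = if (is.null(horizon)) 20L else horizon,
                       n_biographies = if (is.null(n_biographies)) 100L else n_biographies,
                       seed = 7L)
  list(inputs = inputs,
       expected = list(mortality_hazard = m, disease_prevalence_by_age = pi_d))
}
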