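## Input specification objects: risk factor, transitions, diseases,
## population, and the bundle that drives a simulation.

#' Relative-risk specification
#'
#' Describes how a relative risk depends on risk-factor exposure.  For a
#' categorical factor supply one RR per category; for a duration-dependent
#' factor additionally supply a table of RRs by whole years spent in the
#' duration class; for a continuous factor supply the RR per unit of
#' exposure above the reference value.
#'
#' @param per_class Numeric vector, one RR (> 0) per category.
#' @param duration_table Numeric vector of RRs by years in the duration
#'   class (index 1 = duration 0); used instead of `per_class` for the
#'   duration class.
#' @param per_unit Single RR per exposure unit (continuous factors).
#' @return An object of class `rr_spec`.
#' @export
rr_spec <- function(per_class = NULL, duration_table = NULL, per_unit = NULL) {
  structure(list(per_class = per_class, duration_table = duration_table,
                 per_unit = per_unit), class = "rr_spec")
}

rr_null <- function(n_class) rr_spec(per_class = rep(1, n_class))

## RR for one individual hazard key (class + years in duration class).
rr_value <- function(rr, class, duration = 0L, rf = NULL) {
  if (!is.null(rr$duration_table) && !is.null(rf) &&
      identical(class, rf$duration_category)) {
    tab <- rr$duration_table
    return(tab[min(duration, length(tab) - 1L) + 1L])
  }
  rr$per_class[class]
}

#' Risk-factor specification
#'
#' Defines the single risk factor of a model: categorical (up to ten
#' classes), duration-dependent (one of the classes carries a
#' duration-dependent relative risk), or continuous (normal or log-normal
#' exposure distribution).
#'
#' @param kind `"categorical"`, `"duration"` or `"continuous"`.
#' @param categories Character vector of 1--10 class labels
#'   (categorical/duration kinds).
#' @param prevalence For categorical/duration kinds: an array
#'   `[age, sex, category]` of class proportions summing to 1 over
#'   categories at every age/sex.  For continuous: a list with
#'   `age_sex_table` elements `mean` and `sd`.
#' @param rr_incidence Named list, one [rr_spec()] per disease name.
#' @param rr_mortality An [rr_spec()] acting on other-cause mortality.
#' @param duration_category Index of the duration-dependent class.
#' @param duration_max Cap (years) on the duration clock (default 20).
#' @param duration_distribution Proportions over durations `0:duration_max`
#'   used for individuals already in the duration class at baseline;
#'   default: all mass at duration 0.
#' @param distribution `"normal"` or `"lognormal"` (continuous kind).
#' @param reference_value Exposure level at which RR = 1 (continuous kind).
#' @param check Validate invariants (default `TRUE`).
#' @return An object of class `risk_factor_spec`.
#' @export
risk_factor_spec <- function(kind = c("categorical", "duration", "continuous"),
                             categories = NULL, prevalence = NULL,
                             rr_incidence = list(), rr_mortality = NULL,
                             duration_category = NULL, duration_max = 20L,
                             duration_distribution = NULL,
                             distribution = c("normal", "lognormal"),
                             reference_value = 0, check = TRUE) {
  kind <- match.arg(kind)
  distribution <- match.arg(distribution)
  if (kind != "continuous") {
    if (is.null(categories)) stop("categories required for kind ", kind)
    K <- length(categories)
    if (check && (K < 1L || K > 10L))
      stop("number of categories must be between 1 and 10")
    if (kind == "duration") {
      if (is.null(duration_category)) duration_category <- K
      if (is.null(duration_distribution)) {
        duration_distribution <- c(1, rep(0, duration_max))
      }
    }
    if (check && !is.null(prevalence)) {
      sums <- apply(prevalence, c(1, 2), sum)
      bad <- which(abs(sums - 1) > 1e-9, arr.ind = TRUE)
      if (nrow(bad)) {
        stop(sprintf(
          "risk-factor prevalence must sum to 1 over categories; off at age %s, sex %s (sum %.6f)",
          bad[1, 1] - 1L, SEXES[bad[1, 2]], sums[bad[1, , drop = FALSE]]))
      }
      if (any(prevalence < 0)) stop("risk-factor prevalence must be >= 0")
    }
  } else {
    if (is.null(prevalence) || !all(c("mean", "sd") %in% names(prevalence)))
      stop("continuous risk factor needs prevalence = list(mean = , sd = )")
    if (check && any(unclass(prevalence$sd) <= 0))
      stop("continuous risk factor: sd must be > 0")
    categories <- "exposure"
  }
  if (is.null(rr_mortality)) rr_mortality <-
    if (kind == "continuous") rr_spec(per_unit = 1) else rr_null(length(categories))
  if (check) {
    for (rr in c(rr_incidence, list(rr_mortality))) {
      vals <- c(rr$per_class, rr$duration_table, rr$per_unit)
      if (any(vals <= 0)) stop("all relative risks must be > 0")
    }
  }
  structure(list(kind = kind, categories = categories,
                 prevalence = prevalence,
                 rr_incidence = rr_incidence, rr_mortality = rr_mortality,
                 duration_category = duration_category,
                 duration_max = as.integer(duration_max),
                 duration_distribution = duration_distribution,
                 distribution = distribution,
                 reference_value = reference_value),
            class = "risk_factor_spec")
}

n_classes <- function(rf) length(rf$categories)

rr_inc_for <- function(rf, disease_name) {
  rr <- rf$rr_incidence[[disease_name]]
  if (is.null(rr)) {
    rr <- if (rf$kind == "continuous") rr_spec(per_unit = 1)
          else rr_null(n_classes(rf))
  }
  rr
}

#' Risk-factor transition model
#'
#' @param mode `"zero"` (state never changes), `"net"` (net transition
#'   probabilities are estimated from the prevalence, see
#'   [net_transitions()]), or `"explicit"`.
#' @param matrices For explicit mode: array `[age, sex, from, to]` of annual
#'   transition probabilities (rows sum to 1).
#' @return An object of class `transition_model`.
#' @export
transition_model <- function(mode = c("zero", "net", "explicit"),
                             matrices = NULL) {
  mode <- match.arg(mode)
  if (mode == "explicit" && is.null(matrices))
    stop("explicit transition model needs matrices")
  structure(list(mode = mode, matrices = matrices),
            class = "transition_model")
}

identity_transitions <- function(K) {
  m <- array(0, c(AGE_MAX + 1L, 2L, K, K))
  for (k in seq_len(K)) m[, , k, k] <- 1
  transition_model("explicit", m)
}

#' Chronic-disease specification
#'
#' All epidemiological inputs are population-level (by age and sex); the
#' estimation module back-calculates risk-class-specific values from the
#' relative risks.  Excess mortality applies to prevalent non-cured cases;
#' the acutely fatal fraction of incident cases dies immediately.
#'
#' @param name Disease label.
#' @param cluster Cluster label; diseases in the same cluster may be linked
#'   through intermediate-disease relative risks, clusters are independent.
#' @param incidence,prevalence,excess_mortality [age_sex_table()]s:
#'   incidence and excess-mortality annual hazard rates, prevalence a
#'   proportion.
#' @param cured_fraction Proportion of cases with zero excess mortality.
#' @param acutely_fatal_fraction Proportion of incident cases dying
#'   immediately.
#' @param intermediate_rr Named list `other disease -> RR` multiplying this
#'   disease's incidence when the named (same-cluster) disease is present.
#' @return An object of class `disease_spec`.
#' @export
disease_spec <- function(name, cluster = name,
                         incidence, prevalence, excess_mortality,
                         cured_fraction = 0, acutely_fatal_fraction = 0,
                         intermediate_rr = list()) {
  structure(list(name = name, cluster = cluster,
                 incidence = incidence, prevalence = prevalence,
                 excess_mortality = excess_mortality,
                 cured_fraction = cured_fraction,
                 acutely_fatal_fraction = acutely_fatal_fraction,
                 intermediate_rr = intermediate_rr),
            class = "disease_spec")
}

#' Closed-population specification
#'
#' @param start_counts [age_sex_table()] of population counts at the start
#'   of the simulation (ages 0--95; ages above 95 are ignored and treated
#'   as zero).
#' @param newborns Numeric vector of newborn counts, one per future
#'   simulation year (recycled if shorter than the horizon).
#' @param newborn_sex_ratio Proportion female among newborns.
#' @param total_mortality [age_sex_table()] of all-cause mortality hazard
#'   rates.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(start_counts, newborns, newborn_sex_ratio = 0.5,
                            total_mortality) {
  sc <- unclass(start_counts)
  sc[97:(AGE_MAX + 1L), ] <- 0
  structure(list(start_counts = age_sex_table(sc), newborns = newborns,
                 newborn_sex_ratio = newborn_sex_ratio,
                 total_mortality = total_mortality),
            class = "population_spec")
}

#' Bundle of all simulation inputs
#'
#' @param population A [population_spec()].
#' @param risk_factor A [risk_factor_spec()].
#' @param transitions A [transition_model()] (default: net transitions).
#' @param diseases List of [disease_spec()]s.
#' @param horizon Number of simulated years (>= 1).
#' @param n_biographies Simulated individuals per cohort and sex.
#' @param seed Master integer seed.
#' @return An object of class `sim_inputs`.
#' @export
sim_inputs <- function(population, risk_factor,
                       transitions = transition_model("net"),
                       diseases = list(), horizon = 10L,
                       n_biographies = 500L, seed = 1L) {
  stopifnot(horizon >= 1L, n_biographies >= 1L)
  names(diseases) <- vapply(diseases, `[[`, "", "name")
  structure(list(population = population, risk_factor = risk_factor,
                 transitions = transitions, diseases = diseases,
                 horizon = as.integer(horizon),
                 n_biographies = as.integer(n_biographies),
                 seed = as.integer(seed),
                 reference_prevalence = NULL),
            class = "sim_inputs")
}

#' @export
print.sim_inputs <- function(x, ...) {
  rf <- x$risk_factor
  cat("<sim_inputs>\n")
  cat("  risk factor: ", rf$kind,
      if (rf$kind != "continuous")
        paste0(" (", length(rf$categories), " classes: ",
               paste(rf$categories, collapse = ", "), ")")
      else paste0(" (", rf$distribution, ")"), "\n", sep = "")
  cat("  diseases:    ", if (length(x$diseases))
        paste(names(x$diseases), collapse = ", ") else "(none)", "\n", sep = "")
  cat("  transitions: ", x$transitions$mode, "\n", sep = "")
  cat("  horizon:     ", x$horizon, " years; ", x$n_biographies,
      " biographies/cohort/sex; seed ", x$seed, "\n", sep = "")
  invisible(x)
}
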