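## Scenario layer: reference versus intervention runs and their comparison.
##
## A scenario may replace the initial risk-factor prevalence with a
## counterfactual (a one-time, sustained intervention: applied to the
## starting population and to every newborn cohort), override the
## transition model, and/or be targeted at part of the population (an age
## window and/or one sex).  All scenarios run with common random numbers
## derived from the same master seed, so a null intervention reproduces
## the reference exactly.

#' Scenario specification
#'
#' @param name Scenario label.
#' @param counterfactual_prevalence Optional replacement risk-factor
#'   prevalence: array `[age, sex, category]` (or a probability vector over
#'   categories, recycled over the whole grid) applied at year 0 and to
#'   entering newborn cohorts inside the target window.
#' @param transition_override Optional [transition_model()] applied inside
#'   the target window (`"zero"` or explicit mode).
#' @param target List with any of `min_age`, `max_age`, `sexes` restricting
#'   who is affected (defaults: 0, 95, both sexes).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, counterfactual_prevalence = NULL,
                          transition_override = NULL, target = list()) {
  tg <- list(min_age = 0L, max_age = 95L, sexes = SEXES)
  tg[names(target)] <- target
  if (tg$min_age < 0 || tg$max_age > 95 || tg$min_age > tg$max_age)
    stop("invalid target age window")
  if (!all(tg$sexes %in% SEXES)) stop("invalid target sexes")
  structure(list(name = name,
                 counterfactual_prevalence = counterfactual_prevalence,
                 transition_override = transition_override, target = tg),
            class = "scenario_spec")
}

expand_counterfactual <- function(cf, K) {
  if (is.array(cf) && length(dim(cf)) == 3L) return(cf)
  if (is.numeric(cf) && length(cf) == K) {
    out <- array(rep(cf, each = (AGE_MAX + 1L) * 2L), c(AGE_MAX + 1L, 2L, K))
    return(out)
  }
  stop("counterfactual prevalence must be a [age, sex, category] array or a category probability vector")
}

#' Apply a scenario to the simulation inputs
#'
#' Returns a modified input bundle: inside the target window the initial
#' prevalence is replaced by the counterfactual and/or the transitions are
#' overridden; outside the window nothing changes.  The original prevalence
#' is retained as the reference for coupling initial disease burden across
#' scenarios.
#'
#' @param inputs A [sim_inputs()] bundle.
#' @param spec A [scenario_spec()].
#' @return A modified `sim_inputs` object.
#' @export
apply_scenario <- function(inputs, spec) {
  out <- inputs
  rf <- inputs$risk_factor
  tg <- spec$target
  ages_idx <- (tg$min_age:tg$max_age) + 1L
  sex_idx <- sex_index(tg$sexes)
  if (!is.null(spec$counterfactual_prevalence)) {
    if (rf$kind == "continuous")
      stop("counterfactual prevalence applies to categorical/duration factors")
    cf <- expand_counterfactual(spec$counterfactual_prevalence, n_classes(rf))
    sums <- apply(cf, c(1, 2), sum)
    if (any(abs(sums[ages_idx, sex_idx] - 1) > 1e-9))
      stop("counterfactual prevalence rows must sum to 1")
    ## a window reaching the last input age (95) also covers the internal
    ## 96-105 extension, mirroring how input tables are held constant there
    if (tg$max_age == 95L) {
      for (a in 97:(AGE_MAX + 1L)) cf[a, , ] <- cf[96L, , ]
      ages_idx <- c(ages_idx, 97:(AGE_MAX + 1L))
    }
    prev <- rf$prevalence
    prev[ages_idx, sex_idx, ] <- cf[ages_idx, sex_idx, ]
    out$reference_prevalence <- rf$prevalence
    out$risk_factor$prevalence <- prev
  }
  if (!is.null(spec$transition_override)) {
    base <- resolve_transitions(inputs)
    ov <- spec$transition_override
    ovm <- switch(ov$mode,
                  explicit = ov$matrices,
                  zero = identity_transitions(n_classes(rf))$matrices,
                  stop("transition override must be explicit or zero mode"))
    M <- base$matrices
    M[ages_idx, sex_idx, , ] <- ovm[ages_idx, sex_idx, , ]
    out$transitions <- transition_model("explicit", M)
  }
  out
}

## Full pipeline for one (already scenario-modified) input bundle:
## estimation -> biographies -> cohort life tables -> aggregation.
## Baselines are estimated from the supplied epidemiological inputs (which
## scenarios never alter); scenarios only change exposure dynamics.
simulate_population <- function(inputs, baselines = NULL) {
  if (is.null(baselines)) baselines <- estimate_baselines(inputs)
  trans <- resolve_transitions(inputs)
  pop <- inputs$population
  horizon <- inputs$horizon
  nb <- rep_len(pop$newborns, horizon)
  lifetables <- list()
  counts <- numeric(0)
  for (s in 1:2) {
    pre <- if (inputs$risk_factor$kind != "continuous")
      precompute_updates(inputs, baselines, SEXES[s]) else NULL
    add <- function(entry_age, entry_year, N) {
      bset <- simulate_biographies(inputs, entry_age, SEXES[s],
                                   entry_year = entry_year,
                                   transitions = trans)
      lt <- build_cohort_lifetable(bset, baselines, inputs, precomputed = pre)
      lifetables[[length(lifetables) + 1L]] <<- lt
      counts[length(counts) + 1L] <<- N
    }
    for (e in 0:95) {
      N <- ast_at(pop$start_counts, e, s)
      if (N > 0) add(e, 0L, N)
    }
    ratio <- if (s == 1L) pop$newborn_sex_ratio else 1 - pop$newborn_sex_ratio
    for (u in seq_len(horizon)) {
      N <- nb[u] * ratio
      if (N > 0) add(0L, u, N)
    }
  }
  meta <- list(categories = inputs$risk_factor$categories,
               newborn_sex_ratio = pop$newborn_sex_ratio)
  aggregate_cohorts(lifetables, counts, horizon, meta = meta)
}

#' Run reference and intervention scenarios
#'
#' The main entry point of the engine.  Runs the full pipeline (parameter
#' estimation, risk-factor biographies, disease life tables, aggregation)
#' once per scenario, with common random numbers across scenarios.  The
#' first scenario is the reference.
#'
#' @param inputs A [sim_inputs()] bundle.
#' @param scenarios List of [scenario_spec()]s; defaults to a single
#'   reference scenario.
#' @return An object of class `hia_run`: named list of `output_frame`s
#'   (`$frames`), the scenario specs and the inputs.  Methods: `print`,
#'   `summary`, `plot`.
#' @examples
#' \donttest{
#' inp <- make_toy_dataset(toy_params(horizon = 5, n_biographies = 100))
#' run <- run_hia(inp, list(scenario_spec("reference"),
#'                          scenario_spec("all_low",
#'                            counterfactual_prevalence = c(1, 0, 0))))
#' summary(run)
#' }
#' @export
run_hia <- function(inputs, scenarios = list(scenario_spec("reference"))) {
  if (!length(scenarios)) stop("at least one scenario (the reference) is required")
  baselines <- estimate_baselines(inputs)
  frames <- list()
  for (sc in scenarios) {
    inp_s <- apply_scenario(inputs, sc)
    frames[[sc$name]] <- simulate_population(inp_s, baselines = baselines)
  }
  structure(list(frames = frames, scenarios = scenarios, inputs = inputs,
                 baselines = baselines),
            class = "hia_run")
}

#' @export
print.hia_run <- function(x, ...) {
  cat("<hia_run> ", length(x$frames), " scenario(s): ",
      paste(names(x$frames), collapse = ", "), "\n", sep = "")
  h <- x$inputs$horizon
  for (nm in names(x$frames)) {
    ps <- population_size(x$frames[[nm]])
    cat(sprintf("  %-12s population %s -> %s over %d years\n", nm,
                format(round(ps[1]), big.mark = ","),
                format(round(ps[h + 1]), big.mark = ","), h))
  }
  invisible(x)
}

#' @export
summary.hia_run <- function(object, year = NULL, ...) {
  h <- object$inputs$horizon
  if (is.null(year)) year <- h
  rows <- lapply(names(object$frames), function(nm) {
    fr <- object$frames[[nm]]
    ps <- population_size(fr)
    data.frame(scenario = nm,
               population_y0 = ps[1],
               population_yT = ps[h + 1],
               cumulative_deaths = sum(deaths_per_year(fr)[seq_len(h)]),
               period_le_female = period_life_expectancy(fr, year, "female"),
               period_le_male = period_life_expectancy(fr, year, "male"))
  })
  out <- do.call(rbind, rows)
  dis <- object$frames[[1]]$meta$disease_names
  for (d in dis) {
    out[[paste0("cases_", d)]] <-
      vapply(names(object$frames),
             function(nm) disease_count(object$frames[[nm]], d)[year + 1L],
             numeric(1))
  }
  attr(out, "year") <- year
  class(out) <- c("summary.hia_run", "data.frame")
  out
}

#' @export
print.summary.hia_run <- function(x, ...) {
  cat("Scenario summary (year ", attr(x, "year"), "):\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
plot.hia_run <- function(x, what = c("population", "deaths"), ...) {
  what <- match.arg(what)
  h <- x$inputs$horizon
  ys <- sapply(x$frames, function(fr)
    if (what == "population") population_size(fr) else deaths_per_year(fr))
  graphics::matplot(0:h, ys, type = "l", lty = 1, lwd = 2,
                    xlab = "simulation year",
                    ylab = if (what == "population") "population size"
                           else "deaths per year", ...)
  graphics::legend("topleft", legend = names(x$frames), lty = 1, lwd = 2,
                   col = seq_along(x$frames), bty = "n")
  invisible(x)
}

#' Compare an intervention scenario with the reference
#'
#' Per-year and cumulative differences (intervention minus reference) for
#' deaths, prevalent disease cases, population size and period life
#' expectancy.
#'
#' @param ref,intervention `output_frame`s from the same population and
#'   horizon (e.g. two elements of an [run_hia()] result's `$frames`).
#' @return An object of class `hia_comparison` with a per-year data frame
#'   (`$by_year`) and summary elements (`$cumulative_excess_deaths`,
#'   `$le_diff` at the final year by sex).
#' @export
compare_scenarios <- function(ref, intervention) {
  h <- ref$meta$horizon
  if (!identical(h, intervention$meta$horizon))
    stop("scenarios have different horizons")
  if (!identical(ref$meta$disease_names, intervention$meta$disease_names))
    stop("scenarios have different disease sets")
  by_year <- data.frame(
    year = 0:h,
    deaths_ref = deaths_per_year(ref),
    deaths_int = deaths_per_year(intervention),
    population_diff = population_size(intervention) - population_size(ref))
  by_year$deaths_diff <- by_year$deaths_int - by_year$deaths_ref
  for (d in ref$meta$disease_names) {
    by_year[[paste0("cases_diff_", d)]] <-
      disease_count(intervention, d) - disease_count(ref, d)
  }
  le_diff <- vapply(c("female", "male", "combined"), function(sx)
    period_life_expectancy(intervention, h, sx) -
      period_life_expectancy(ref, h, sx), numeric(1))
  structure(list(by_year = by_year,
                 cumulative_excess_deaths = sum(by_year$deaths_diff[seq_len(h)]),
                 le_diff = le_diff),
            class = "hia_comparison")
}

#' @export
print.hia_comparison <- function(x, ...) {
  h <- max(x$by_year$year)
  cat("<hia_comparison> intervention minus reference over ", h, " years\n",
      sep = "")
  cat(sprintf("  cumulative excess deaths: %.1f\n", x$cumulative_excess_deaths))
  cat(sprintf("  period LE difference at year %d: female %+.3f, male %+.3f\n",
              h, x$le_diff[["female"]], x$le_diff[["male"]]))
  dcols <- grep("^cases_diff_", names(x$by_year), value = TRUE)
  for (cn in dcols) {
    cat(sprintf("  %s at year %d: %+.1f\n",
                sub("^cases_diff_", "excess cases of ", cn), h,
                x$by_year[[cn]][h + 1L]))
  }
  invisible(x)
}
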