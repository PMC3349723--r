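## Assembly of cohort life tables into population-level results and the
## summary measures computed from them: period (cross-sectional) and cohort
## (longitudinal) life expectancy, disease-free life expectancy and
## expected years lived with each disease.
##
## Life-table conventions: deaths receive a half-year person-year credit
## (a_x = 0.5) and the table is closed at age 105: survivors die at exact
## age 105, contributing no person-years beyond it (so zero mortality below
## 105 gives a life expectancy at birth of exactly 105 years).

#' Aggregate cohort life tables into a population output frame
#'
#' Weighted sums of the per-capita cohort life tables with the cohort start
#' counts; period year t collects each cohort at age entry_age + (t -
#' entry_year).  The population is closed (no migration).
#'
#' @param lifetables List of `cohort_lifetable` objects, one per (cohort,
#'   sex), including newborn cohorts entering each simulation year.
#' @param counts Numeric vector of cohort start counts, parallel to
#'   `lifetables`.
#' @param horizon Number of simulated years.
#' @param meta Optional list carried through (risk-factor categories,
#'   disease names).
#' @return An object of class `output_frame` with elements `period`
#'   (arrays `alive`, `deaths`, `disease`, `disease_free` indexed
#'   `[year 0..horizon, age 0..105, sex, class(, disease)]`), `cohorts`
#'   (the cohort tables plus counts) and `meta`.
#' @export
aggregate_cohorts <- function(lifetables, counts, horizon, meta = list()) {
  stopifnot(length(lifetables) == length(counts))
  K <- lifetables[[1L]]$K
  dnames <- lifetables[[1L]]$disease_names
  D <- length(dnames)
  TT <- horizon + 1L
  dn <- list(year = 0:horizon, age = 0:AGE_MAX, sex = SEXES, class = NULL)
  alive <- array(0, c(TT, AGE_MAX + 1L, 2L, K))
  deaths <- array(0, c(TT, AGE_MAX + 1L, 2L, K))
  disease <- array(0, c(TT, AGE_MAX + 1L, 2L, K, max(D, 1L)))
  disease_free <- array(0, c(TT, AGE_MAX + 1L, 2L, K))
  for (i in seq_along(lifetables)) {
    lt <- lifetables[[i]]
    N <- counts[i]
    if (N <= 0) next
    s <- sex_index(lt$sex)
    for (t in max(lt$entry_year, 0L):horizon) {
      a <- lt$entry_age + (t - lt$entry_year)
      if (a > AGE_MAX) break
      j <- a - lt$entry_age + 1L
      alive[t + 1L, a + 1L, s, ] <- alive[t + 1L, a + 1L, s, ] + N * lt$alive[j, ]
      deaths[t + 1L, a + 1L, s, ] <- deaths[t + 1L, a + 1L, s, ] + N * lt$deaths[j, ]
      disease_free[t + 1L, a + 1L, s, ] <-
        disease_free[t + 1L, a + 1L, s, ] + N * lt$disease_free[j, ]
      if (D) disease[t + 1L, a + 1L, s, , ] <-
        disease[t + 1L, a + 1L, s, , ] + N * lt$disease[j, , ]
    }
  }
  structure(list(
    period = list(alive = alive, deaths = deaths, disease = disease,
                  disease_free = disease_free),
    cohorts = list(tables = lifetables, counts = counts),
    meta = c(meta, list(horizon = horizon, K = K, disease_names = dnames))),
    class = "output_frame")
}

#' @export
print.output_frame <- function(x, ...) {
  h <- x$meta$horizon
  cat("<output_frame> ", h, " simulated years, ",
      length(x$cohorts$tables), " cohort life tables\n", sep = "")
  cat("  population: ", format(round(sum(x$period$alive[1L, , , ])), big.mark = ","),
      " at year 0; ", format(round(sum(x$period$alive[h + 1L, , , ])), big.mark = ","),
      " at year ", h, "\n", sep = "")
  invisible(x)
}

## Period age-specific death probabilities for one year/sex; classes are
## summed.  Ages with no population carry the last populated age's value
## forward (and the terminal age is closed with q = 1).
period_qx <- function(frame, year, s) {
  al <- apply(frame$period$alive[year + 1L, , s, , drop = FALSE], 2, sum)
  de <- apply(frame$period$deaths[year + 1L, , s, , drop = FALSE], 2, sum)
  q <- rep(NA_real_, AGE_MAX + 1L)
  pop <- al > 0
  q[pop] <- de[pop] / al[pop]
  if (!any(pop)) stop("no population in year ", year)
  last <- NA_real_
  for (a in seq_len(AGE_MAX + 1L)) {
    if (is.na(q[a])) q[a] <- last else last <- q[a]
  }
  if (is.na(q[1L])) q[seq_len(which(pop)[1L] - 1L)] <- q[which(pop)[1L]]
  q[AGE_MAX + 1L] <- 1
  pmin(pmax(q, 0), 1)
}

life_table_from_qx <- function(q) {
  lx <- cumprod(c(1, 1 - q[-length(q)]))
  dx <- lx * q
  Lx <- lx - 0.5 * dx
  Lx[length(Lx)] <- 0   # survivors die at exact age 105
  list(lx = lx, dx = dx, Lx = Lx)
}

#' Period life expectancy
#'
#' Standard period life table at birth from one simulation year's
#' age-specific mortality probabilities, with half-year credit for deaths
#' and closure at age 105.
#'
#' @param frame An `output_frame`.
#' @param year Simulation year (0 to horizon).
#' @param sex `"female"`, `"male"` or `"combined"` (weighted by the newborn
#'   sex ratio, if available in the frame's meta).
#' @return Life expectancy at birth, in years.
#' @export
period_life_expectancy <- function(frame, year, sex = "combined") {
  if (year < 0 || year > frame$meta$horizon)
    stop("year outside the simulated horizon")
  if (sex == "combined") {
    w <- frame$meta$newborn_sex_ratio
    if (is.null(w)) w <- 0.5
    return(w * period_life_expectancy(frame, year, "female") +
           (1 - w) * period_life_expectancy(frame, year, "male"))
  }
  q <- period_qx(frame, year, sex_index(sex))
  sum(life_table_from_qx(q)$Lx)
}

find_cohort <- function(frame, entry_year, entry_age, sex) {
  for (i in seq_along(frame$cohorts$tables)) {
    lt <- frame$cohorts$tables[[i]]
    if (lt$entry_year == entry_year && lt$entry_age == entry_age &&
        lt$sex == sex) return(lt)
  }
  stop("no cohort entering year ", entry_year, " at age ", entry_age,
       " (", sex, ")")
}

#' Cohort life expectancy
#'
#' Expected years lived from the entry age, integrated along one simulated
#' cohort's life table (followed to age 105), with half-year credit for
#' deaths.
#'
#' @param frame An `output_frame`.
#' @param entry_year,entry_age Identify the cohort (entry_year 0 for
#'   cohorts alive at the start).
#' @param sex `"female"` or `"male"`.
#' @return Expected years lived from entry.
#' @export
cohort_life_expectancy <- function(frame, entry_year = 0L, entry_age = 0L,
                                   sex = "female") {
  lt <- find_cohort(frame, entry_year, entry_age, sex)
  trapezoid_years(rowSums(lt$alive))
}

## Person-years under a_x = 0.5 with terminal death at exact age 105:
## trapezoidal integration of the occupancy curve over the followed ages.
trapezoid_years <- function(z) sum(z) - 0.5 * z[1L] - 0.5 * z[length(z)]

#' Disease-free life expectancy and expected years with disease
#'
#' Period variant: Sullivan weighting of the period prevalence with the
#' period life table's person-years.  Cohort variant: direct trapezoidal
#' integration of the cohort's occupancy.
#'
#' @param frame An `output_frame`.
#' @param year Simulation year for the period variant (default 1).
#' @param cohort Optional list `list(entry_year=, entry_age=)` selecting
#'   the cohort variant instead.
#' @param sex `"female"` or `"male"`.
#' @return List with `life_expectancy`, `disease_free_le` and `years_with`
#'   (named vector, one entry per disease).
#' @export
health_expectancies <- function(frame, year = 1L, cohort = NULL,
                                sex = "female") {
  dnames <- frame$meta$disease_names
  D <- length(dnames)
  if (is.null(cohort)) {
    s <- sex_index(sex)
    q <- period_qx(frame, year, s)
    ltab <- life_table_from_qx(q)
    al <- apply(frame$period$alive[year + 1L, , s, , drop = FALSE], 2, sum)
    dfr <- apply(frame$period$disease_free[year + 1L, , s, , drop = FALSE], 2, sum)
    pop <- al > 0
    pfree <- rep(NA_real_, AGE_MAX + 1L)
    pfree[pop] <- dfr[pop] / al[pop]
    pfree <- fill_forward(pfree)
    le <- sum(ltab$Lx)
    dfle <- sum(ltab$Lx * pfree)
    yw <- stats::setNames(numeric(D), dnames)
    for (d in seq_len(D)) {
      dc <- apply(frame$period$disease[year + 1L, , s, , d, drop = FALSE], 2, sum)
      pd <- rep(NA_real_, AGE_MAX + 1L)
      pd[pop] <- dc[pop] / al[pop]
      yw[d] <- sum(ltab$Lx * fill_forward(pd))
    }
  } else {
    lt <- find_cohort(frame, cohort$entry_year, cohort$entry_age, sex)
    le <- trapezoid_years(rowSums(lt$alive))
    dfle <- trapezoid_years(rowSums(lt$disease_free))
    yw <- stats::setNames(numeric(D), dnames)
    for (d in seq_len(D))
      yw[d] <- trapezoid_years(rowSums(lt$disease[, , d, drop = FALSE]))
  }
  list(life_expectancy = le, disease_free_le = dfle, years_with = yw)
}

fill_forward <- function(x) {
  last <- NA_real_
  for (i in seq_along(x)) {
    if (is.na(x[i])) x[i] <- last else last <- x[i]
  }
  if (is.na(x[1L])) {
    first <- which(!is.na(x))[1L]
    if (!is.na(first)) x[seq_len(first - 1L)] <- x[first]
  }
  x[is.na(x)] <- 0
  x
}

#' Per-year population summaries of an output frame
#'
#' `population_size()`: total alive population per simulation year.
#' `disease_count()`: prevalent cases of one disease per year.
#' `deaths_per_year()`: deaths during each year t -> t+1.
#'
#' @param frame An `output_frame`.
#' @param disease Disease name.
#' @return Numeric vector over simulation years 0..horizon.
#' @export
population_size <- function(frame) {
  vapply(0:frame$meta$horizon,
         function(t) sum(frame$period$alive[t + 1L, , , ]), numeric(1))
}

#' @rdname population_size
#' @export
disease_count <- function(frame, disease) {
  d <- match(disease, frame$meta$disease_names)
  if (is.na(d)) stop("unknown disease: ", disease)
  vapply(0:frame$meta$horizon,
         function(t) sum(frame$period$disease[t + 1L, , , , d]), numeric(1))
}

#' @rdname population_size
#' @export
deaths_per_year <- function(frame) {
  vapply(0:frame$meta$horizon,
         function(t) sum(frame$period$deaths[t + 1L, , , ]), numeric(1))
}
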