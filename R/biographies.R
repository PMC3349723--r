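## Stochastic micro-simulation of individual risk-factor trajectories
## ("biographies").  One RNG stream per (cohort, sex), derived from the
## master seed by a fixed integer hash, so that scenario comparisons are
## common-random-number paired: a null intervention reproduces the
## reference bitwise.

stream_seed <- function(master, entry_year, entry_age, sex_idx) {
  h <- (as.double(master %% 1048576L) * 1664525 +
        as.double(entry_year) * 7919 +
        as.double(entry_age) * 101 + as.double(sex_idx)) %% 2147483646
  as.integer(h) + 1L
}

## Inverse-CDF categorical draw; shared uniforms keep scenarios coupled.
draw_categorical <- function(u, p) {
  findInterval(u, cumsum(p)[-length(p)]) + 1L
}

#' Sample initial risk-factor states
#'
#' Draws `n` states from a categorical prevalence vector by inverse-CDF
#' sampling; deterministic given the seed.
#'
#' @param prevalence Probability vector over categories.
#' @param n Number of draws (> 0).
#' @param seed Integer seed.
#' @return Integer vector of category indices.
#' @export
sample_initial_states <- function(prevalence, n, seed) {
  if (n <= 0) stop("n must be positive")
  set.seed(seed)
  draw_categorical(stats::runif(n), prevalence)
}

exposure_quantile <- function(rf, u, age, sex) {
  m <- ast_at(rf$prevalence$mean, age, sex)
  s <- ast_at(rf$prevalence$sd, age, sex)
  if (rf$distribution == "normal") {
    stats::qnorm(u, m, s)
  } else {
    sigma2 <- log(1 + s^2 / m^2)
    stats::qlnorm(u, log(m) - sigma2 / 2, sqrt(sigma2))
  }
}

#' Simulate risk-factor biographies for one cohort
#'
#' Each individual's state at age a+1 is drawn from row state(a) of the
#' (age- and sex-specific) transition matrix; the duration clock of the
#' duration-dependent class increments while in the class and resets to 0
#' on entry.  Continuous exposures use rank preservation: a quantile rank
#' drawn once at entry, evaluated against the age-specific distribution at
#' every age.  Identical trajectories are merged with summed weights.
#'
#' @param inputs A [sim_inputs()] bundle.
#' @param entry_age Age of the cohort at entry (0--95).
#' @param sex `"female"` or `"male"`.
#' @param entry_year Simulation year the cohort enters (0 for cohorts alive
#'   at the start, >= 1 for newborn cohorts).
#' @param transitions Optional resolved explicit [transition_model()]
#'   (computed from `inputs` if omitted).
#' @param n Number of simulated individuals (default
#'   `inputs$n_biographies`).
#' @return An object of class `biography_set`: merged trajectories
#'   (`states` matrix, one row per distinct trajectory, one column per age
#'   `entry_age:105`), `weight` (summing to `n`), entry metadata, and for
#'   duration/continuous kinds the duration clocks / exposure values.
#' @export
simulate_biographies <- function(inputs, entry_age, sex, entry_year = 0L,
                                 transitions = NULL, n = NULL) {
  rf <- inputs$risk_factor
  if (is.null(n)) n <- inputs$n_biographies
  s <- sex_index(sex)
  ages <- entry_age:AGE_MAX
  L <- length(ages)
  set.seed(stream_seed(inputs$seed, entry_year, entry_age, s))
  u0 <- stats::runif(n)

  if (rf$kind == "continuous") {
    values <- vapply(ages, function(a) exposure_quantile(rf, u0, a, s),
                     numeric(n))
    values <- matrix(values, nrow = n)
    out <- list(entry_age = as.integer(entry_age), entry_year = as.integer(entry_year),
                sex = SEXES[s], ages = ages, n = n,
                states = matrix(1L, n, L), weight = rep(1, n),
                durations = NULL, values = values, ref_states = rep(1L, n))
    class(out) <- "biography_set"
    return(out)
  }

  K <- n_classes(rf)
  prev_entry <- rf$prevalence[entry_age + 1L, s, ]
  init <- draw_categorical(u0, prev_entry)
  ref_init <- if (!is.null(inputs$reference_prevalence)) {
    draw_categorical(u0, inputs$reference_prevalence[entry_age + 1L, s, ])
  } else init

  dur0 <- integer(n)
  if (rf$kind == "duration") {
    in_dc <- init == rf$duration_category
    if (any(in_dc)) {
      w <- rf$duration_distribution
      dur0[in_dc] <- sample.int(length(w), sum(in_dc), replace = TRUE,
                                prob = w) - 1L
    }
  }

  Tm <- if (is.null(transitions)) resolve_transitions(inputs) else transitions
  M <- Tm$matrices
  st <- matrix(0L, n, L)
  st[, 1L] <- init
  for (j in seq_len(L - 1L)) {
    a <- ages[j]
    u <- stats::runif(n)
    cur <- st[, j]
    nxt <- cur
    for (k in unique(cur)) {
      idx <- which(cur == k)
      nxt[idx] <- draw_categorical(u[idx], M[a + 1L, s, k, ])
    }
    st[, j + 1L] <- nxt
  }

  durations <- NULL
  if (rf$kind == "duration") {
    dc <- rf$duration_category
    durations <- matrix(0L, n, L)
    durations[, 1L] <- ifelse(st[, 1L] == dc, dur0, 0L)
    for (j in seq_len(L - 1L)) {
      durations[, j + 1L] <- ifelse(
        st[, j + 1L] == dc,
        ifelse(st[, j] == dc, durations[, j] + 1L, 0L), 0L)
    }
    durations <- pmin(durations, rf$duration_max)
  }

  ## lossless merge of identical trajectories
  keycols <- c(list(ref_init, dur0), lapply(seq_len(L), function(j) st[, j]))
  key <- do.call(paste, c(keycols, sep = ","))
  first <- !duplicated(key)
  idx_map <- match(key, key[first])
  weight <- as.numeric(tabulate(idx_map, nbins = sum(first)))
  out <- list(entry_age = as.integer(entry_age),
              entry_year = as.integer(entry_year),
              sex = SEXES[s], ages = ages, n = n,
              states = st[first, , drop = FALSE], weight = weight,
              durations = if (!is.null(durations)) durations[first, , drop = FALSE],
              values = NULL, ref_states = ref_init[first])
  class(out) <- "biography_set"
  out
}

#' @export
print.biography_set <- function(x, ...) {
  cat("<biography_set> cohort entering year ", x$entry_year, " at age ",
      x$entry_age, ", sex ", x$sex, "\n  ", x$n, " individuals in ",
      nrow(x$states), " distinct trajectories over ages ",
      min(x$ages), "-", max(x$ages), "\n", sep = "")
  invisible(x)
}

## Weighted class occupancy of a biography set at a given age.
occupancy_at <- function(bset, age, K) {
  j <- match(age, bset$ages)
  w <- tapply(bset$weight, factor(bset$states[, j], levels = seq_len(K)), sum)
  w[is.na(w)] <- 0
  as.numeric(w) / sum(bset$weight)
}
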