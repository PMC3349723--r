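## Deterministic disease life tables.
##
## For each risk-factor biography the joint disease-state occupancy of every
## disease cluster is evolved in annual steps.  Within a year, dynamics are
## competing constant hazards: from a state with total exit hazard
## H = mu + sum(lambda_d) the staying probability is exp(-H) and the exit
## mass is allocated proportionally to the hazards; mass moving through the
## incidence of disease d is split into an immediately-dying fraction
## (acutely fatal) and the remainder, which enters the state with d added.
## At most one incidence event happens per year.  Clusters are independent:
## overall survival multiplies the common other-cause survival with each
## cluster's disease-death survival, so the total mortality hazard is
## additive across clusters plus other-cause mortality.

#' Joint state space of a disease cluster
#'
#' Enumerates all subsets of the cluster's member diseases; state 1 is
#' "none".
#'
#' @param diseases List of [disease_spec()]s belonging to one cluster.
#' @return An object of class `cluster_state_space` with elements `names`
#'   (disease names), `n_states` (`2^k`) and `present` (logical
#'   `n_states x k` membership matrix).
#' @export
cluster_state_space <- function(diseases) {
  nm <- vapply(diseases, `[[`, "", "name")
  k <- length(nm)
  S <- bitwShiftL(1L, k)
  present <- matrix(FALSE, S, max(k, 1L))
  for (d in seq_len(k))
    present[, d] <- bitwAnd(seq_len(S) - 1L, bitwShiftL(1L, d - 1L)) > 0L
  colnames(present) <- if (k) nm else NULL
  structure(list(names = nm, n_states = S, present = present[, seq_len(k), drop = FALSE]),
            class = "cluster_state_space")
}

state_index <- function(space, present_names) {
  bits <- match(present_names, space$names)
  if (anyNA(bits)) stop("unknown disease in state: ",
                        paste(present_names[is.na(bits)], collapse = ", "))
  sum(bitwShiftL(1L, bits - 1L)) + 1L
}

## RR matrix of intermediate-disease links within a cluster:
## inter[source, target] multiplies the incidence of `target` while
## `source` is present.
intermediate_matrix <- function(diseases) {
  nm <- vapply(diseases, `[[`, "", "name")
  k <- length(nm)
  m <- matrix(1, k, k, dimnames = list(source = nm, target = nm))
  for (d in diseases) {
    for (tgt in names(d$intermediate_rr)) {
      if (tgt %in% nm) m[d$name, tgt] <- d$intermediate_rr[[tgt]]
    }
  }
  m
}

#' Hazards leaving one joint disease state
#'
#' For a given age, sex and risk-factor class, returns (i) the incidence
#' hazard of every absent disease -- baseline incidence times the
#' risk-factor RR times the RRs of any present intermediate diseases -- and
#' (ii) the mortality hazard: baseline other-cause mortality times the
#' risk-factor RR on mortality, plus the excess mortality (scaled by one
#' minus the cured fraction) of every present disease.
#'
#' @param state Character vector of present disease names (empty = healthy).
#' @param age,sex Age (0--105) and sex.
#' @param risk_class Risk-factor class index (or exposure value for a
#'   continuous factor).
#' @param baselines A `baseline_rates` object from [estimate_baselines()].
#' @param diseases List of [disease_spec()]s forming one cluster.
#' @param rf The [risk_factor_spec()].
#' @param duration Years in the duration class (duration kind only).
#' @return List with elements `incidence` (named vector over absent
#'   diseases) and `mortality` (single hazard).
#' @export
state_hazards <- function(state, age, sex, risk_class, baselines, diseases,
                          rf, duration = 0L) {
  nm <- vapply(diseases, `[[`, "", "name")
  inter <- intermediate_matrix(diseases)
  absent <- setdiff(nm, state)
  lam <- vapply(absent, function(d) {
    ast_at(baselines$baseline_incidence[[d]], age, sex) *
      rf_rr_multiplier(rf, rr_inc_for(rf, d), risk_class, duration) *
      prod(inter[state, d])
  }, numeric(1))
  mu <- ast_at(baselines$baseline_other_cause_mortality, age, sex) *
    rf_rr_multiplier(rf, rf$rr_mortality, risk_class, duration)
  for (d in diseases) {
    if (d$name %in% state)
      mu <- mu + (1 - d$cured_fraction) * ast_at(d$excess_mortality, age, sex)
  }
  list(incidence = lam, mortality = mu)
}

## RR multiplier for one individual: class RR, duration-dependent RR, or
## RR^(x - x0) for a continuous exposure value.
rf_rr_multiplier <- function(rf, rr, risk_class, duration = 0L) {
  if (rf$kind == "continuous") {
    if (is.null(rr$per_unit)) 1 else rr$per_unit^(risk_class - rf$reference_value)
  } else {
    rr_value(rr, risk_class, duration, rf)
  }
}

## One-year update matrix for a cluster: alive flows M (S x S) and death
## vector dvec, from per-state incidence hazards, disease mortality and the
## acutely fatal fractions.  `lam_base[d]` is the incidence hazard of d
## before intermediate-disease multipliers; `extra_mu` is added to every
## state's mortality hazard (0 in the engine, where other-cause mortality
## is applied as a separate multiplicative survival factor).
cluster_update_matrix <- function(space, lam_base, inter, em, cured, fatal,
                                  extra_mu = 0) {
  S <- space$n_states
  k <- length(space$names)
  M <- matrix(0, S, S)
  dvec <- numeric(S)
  for (i in seq_len(S)) {
    pres <- space$present[i, ]
    mu <- extra_mu + sum((1 - cured[pres]) * em[pres])
    lam <- numeric(k)
    for (d in seq_len(k)) {
      if (!pres[d])
        lam[d] <- lam_base[d] * prod(inter[pres, d])
    }
    H <- mu + sum(lam)
    if (H <= 0) {
      M[i, i] <- 1
      next
    }
    exit <- -expm1(-H)
    M[i, i] <- exp(-H)
    dvec[i] <- mu / H * exit
    for (d in seq_len(k)) {
      if (lam[d] > 0) {
        move <- lam[d] / H * exit
        j <- i + bitwShiftL(1L, d - 1L)
        M[i, j] <- M[i, j] + move * (1 - fatal[d])
        dvec[i] <- dvec[i] + move * fatal[d]
      }
    }
  }
  list(M = M, dvec = dvec)
}

#' One-year competing-hazards update of a cluster occupancy
#'
#' Applies the within-year scheme to an occupancy distribution over a
#' cluster's joint states: staying probability `exp(-H)` for total exit
#' hazard `H`, exit mass allocated proportionally to the individual
#' hazards, at most one incidence event per year, acutely fatal fractions
#' dying immediately.
#'
#' @param occupancy Probability vector over the joint states (sums to 1).
#' @param hazards List, one element per state, each a list with `incidence`
#'   (named hazard vector over absent diseases) and `mortality` (single
#'   hazard), as returned by [state_hazards()].
#' @param space The [cluster_state_space()].
#' @param fatal Named vector of acutely fatal fractions per disease
#'   (default 0).
#' @return List with `occupancy` (next distribution conditional on being
#'   alive) and `deaths` (probability mass dying within the year).
#' @export
annual_update <- function(occupancy, hazards, space, fatal = NULL) {
  if (abs(sum(occupancy) - 1) > 1e-9)
    stop("occupancy must sum to 1")
  k <- length(space$names)
  if (is.null(fatal)) fatal <- stats::setNames(rep(0, k), space$names)
  S <- space$n_states
  M <- matrix(0, S, S)
  dvec <- numeric(S)
  for (i in seq_len(S)) {
    lam <- hazards[[i]]$incidence
    mu <- hazards[[i]]$mortality
    H <- mu + sum(lam)
    if (H <= 0) { M[i, i] <- 1; next }
    exit <- -expm1(-H)
    M[i, i] <- exp(-H)
    dvec[i] <- mu / H * exit
    for (d in names(lam)) {
      if (lam[[d]] > 0) {
        move <- lam[[d]] / H * exit
        j <- i + bitwShiftL(1L, match(d, space$names) - 1L)
        M[i, j] <- M[i, j] + move * (1 - fatal[[d]])
        dvec[i] <- dvec[i] + move * fatal[[d]]
      }
    }
  }
  q <- as.numeric(occupancy %*% M)
  deaths <- sum(occupancy * dvec)
  alive <- 1 - deaths
  list(occupancy = if (alive > 0) q / alive else q, deaths = deaths)
}

## ---- engine internals -----------------------------------------------------

## Hazard keys: trajectories sharing a key share the same one-year update.
## Categorical: key = class.  Duration kind: the duration class is expanded
## by years-in-class (capped).
hazard_keys <- function(rf) {
  K <- n_classes(rf)
  if (rf$kind == "duration") {
    cap <- rf$duration_max
    keys <- data.frame(class = c(seq_len(K), rep(rf$duration_category, cap)),
                       duration = c(rep(0L, K), seq_len(cap)))
  } else {
    keys <- data.frame(class = seq_len(K), duration = 0L)
  }
  keys
}

key_of <- function(rf, class, duration) {
  K <- n_classes(rf)
  if (rf$kind == "duration") {
    ifelse(class == rf$duration_category & duration > 0L,
           K + pmin(duration, rf$duration_max), class)
  } else class
}

## Precompute, for one sex, the per-(age, key) cluster update matrices and
## other-cause survival factors.  Layout: list over clusters, each a list
## over ages 0..104, each a list over keys of list(M, dvec); plus
## ocm_factor[age, key].
precompute_updates <- function(inputs, baselines, sex) {
  rf <- inputs$risk_factor
  s <- sex_index(sex)
  keys <- hazard_keys(rf)
  nk <- nrow(keys)
  clusters <- split(inputs$diseases,
                    vapply(inputs$diseases, `[[`, "", "cluster"))
  cl_info <- lapply(clusters, function(ds) {
    list(diseases = ds, space = cluster_state_space(ds),
         inter = intermediate_matrix(ds),
         cured = vapply(ds, `[[`, 0, "cured_fraction"),
         fatal = vapply(ds, `[[`, 0, "acutely_fatal_fraction"))
  })
  bocm <- unclass(baselines$baseline_other_cause_mortality)
  ocm_factor <- matrix(NA_real_, AGE_MAX + 1L, nk)
  for (g in seq_len(nk)) {
    rrm <- rr_value(rf$rr_mortality, keys$class[g], keys$duration[g], rf)
    ocm_factor[, g] <- exp(-bocm[, s] * rrm)
  }
  upd <- lapply(cl_info, function(ci) {
    ds <- ci$diseases
    lapply(0:(AGE_MAX - 1L), function(a) {
      em_a <- vapply(ds, function(d) ast_at(d$excess_mortality, a, s), 0)
      lapply(seq_len(nk), function(g) {
        lam <- vapply(ds, function(d) {
          ast_at(baselines$baseline_incidence[[d$name]], a, s) *
            rr_value(rr_inc_for(rf, d$name), keys$class[g], keys$duration[g], rf)
        }, numeric(1))
        cluster_update_matrix(ci$space, lam, ci$inter, em_a, ci$cured, ci$fatal)
      })
    })
  })
  list(keys = keys, clusters = cl_info, updates = upd, ocm_factor = ocm_factor)
}

#' Build the disease life table of one cohort
#'
#' Evolves, for every distinct trajectory of a [simulate_biographies()]
#' set, the joint disease-state occupancy of each cluster and the survival
#' probability through annual steps from the entry age to the terminal age
#' 105 (where the life table is closed).  Disease occupancy at entry is
#' initialised from the risk-class-specific disease prevalence, with
#' independence between diseases of a cluster at baseline.
#'
#' @param biographies A `biography_set`.
#' @param baselines A `baseline_rates` object.
#' @param inputs The [sim_inputs()] bundle.
#' @param precomputed Optional result of the internal update precomputation
#'   for this sex (reused across cohorts by [run_hia()]).
#' @return An object of class `cohort_lifetable`: per-capita arrays over
#'   ages `entry_age:105` -- `alive` and `deaths` (`L x K`, by risk class),
#'   `disease` (`L x K x D` prevalent share) and `disease_free` (`L x K`).
#' @export
build_cohort_lifetable <- function(biographies, baselines, inputs,
                                   precomputed = NULL) {
  rf <- inputs$risk_factor
  bset <- biographies
  s <- sex_index(bset$sex)
  ages <- bset$ages
  L <- length(ages)
  m <- nrow(bset$states)
  w <- bset$weight / bset$n
  K <- n_classes(rf)
  dnames <- names(inputs$diseases)
  D <- length(dnames)

  continuous <- rf$kind == "continuous"
  if (!continuous && is.null(precomputed))
    precomputed <- precompute_updates(inputs, baselines, bset$sex)
  cl_info <- if (continuous) {
    clusters <- split(inputs$diseases,
                      vapply(inputs$diseases, `[[`, "", "cluster"))
    lapply(clusters, function(ds)
      list(diseases = ds, space = cluster_state_space(ds),
           inter = intermediate_matrix(ds),
           cured = vapply(ds, `[[`, 0, "cured_fraction"),
           fatal = vapply(ds, `[[`, 0, "acutely_fatal_fraction")))
  } else precomputed$clusters
  nC <- length(cl_info)

  ## initial occupancy per cluster: product of within-class marginals
  Q <- vector("list", nC)
  erc <- if (continuous && D)
    lapply(dnames, function(d)
      expected_rr(rf, rr_inc_for(rf, d))) else NULL
  if (!is.null(erc)) names(erc) <- dnames
  a0 <- ages[1L]
  for (ci in seq_len(nC)) {
    space <- cl_info[[ci]]$space
    Si <- space$n_states
    q <- matrix(0, m, Si)
    marg <- sapply(cl_info[[ci]]$diseases, function(d) {
      if (continuous) {
        x0 <- bset$values[, 1L]
        rr <- rr_inc_for(rf, d$name)
        mult <- if (is.null(rr$per_unit)) rep(1, m)
                else rr$per_unit^(x0 - rf$reference_value)
        pv <- ast_at(d$prevalence, a0, s) * mult / ast_at(erc[[d$name]], a0, s)
        pmin(pv, 1)
      } else {
        baselines$class_prevalence[[d$name]][a0 + 1L, s, bset$ref_states]
      }
    })
    marg <- matrix(marg, nrow = m)
    for (st in seq_len(Si)) {
      pres <- space$present[st, ]
      pcol <- rep(1, m)
      for (d in seq_along(pres))
        pcol <- pcol * (if (pres[d]) marg[, d] else 1 - marg[, d])
      q[, st] <- pcol
    }
    Q[[ci]] <- q
  }
  Surv <- rep(1, m)

  alive <- matrix(0, L, K)
  deaths <- matrix(0, L, K)
  disease <- array(0, c(L, K, max(D, 1L)))
  disease_free <- matrix(0, L, K)

  bocm <- unclass(baselines$baseline_other_cause_mortality)

  for (j in seq_len(L)) {
    a <- ages[j]
    cls <- bset$states[, j]
    dur <- if (!is.null(bset$durations)) bset$durations[, j] else rep(0L, m)

    ## record
    dfree <- rep(1, m)
    margs <- if (D) matrix(0, m, D, dimnames = list(NULL, dnames)) else NULL
    for (ci in seq_len(nC)) {
      space <- cl_info[[ci]]$space
      dfree <- dfree * Q[[ci]][, 1L]
      for (d in seq_along(space$names))
        margs[, space$names[d]] <-
          Q[[ci]][, space$present[, d], drop = FALSE] |> rowSums()
    }
    wS <- w * Surv
    for (k in unique(cls)) {
      idx <- which(cls == k)
      alive[j, k] <- sum(wS[idx])
      disease_free[j, k] <- sum(wS[idx] * dfree[idx])
      if (D) for (d in seq_len(D))
        disease[j, k, d] <- sum(wS[idx] * margs[idx, d])
    }

    if (a == AGE_MAX) {            # terminal closure: everyone dies at 105
      deaths[j, ] <- alive[j, ]
      break
    }

    ## update to age a + 1
    Snew <- Surv
    if (continuous) {
      xa <- bset$values[, j]
      rrm <- if (is.null(rf$rr_mortality$per_unit)) rep(1, m)
             else rf$rr_mortality$per_unit^(xa - rf$reference_value)
      for (i in seq_len(m)) {
        f <- exp(-bocm[a + 1L, s] * rrm[i])
        for (ci in seq_len(nC)) {
          dsl <- cl_info[[ci]]$diseases
          lam <- vapply(dsl, function(d) {
            rr <- rr_inc_for(rf, d$name)
            mult <- if (is.null(rr$per_unit)) 1
                    else rr$per_unit^(xa[i] - rf$reference_value)
            ast_at(baselines$baseline_incidence[[d$name]], a, s) * mult
          }, numeric(1))
          em_a <- vapply(dsl, function(d) ast_at(d$excess_mortality, a, s), 0)
          um <- cluster_update_matrix(cl_info[[ci]]$space, lam,
                                      cl_info[[ci]]$inter, em_a,
                                      cl_info[[ci]]$cured, cl_info[[ci]]$fatal)
          q <- as.numeric(Q[[ci]][i, ] %*% um$M)
          dmass <- sum(Q[[ci]][i, ] * um$dvec)
          fc <- 1 - dmass
          Q[[ci]][i, ] <- if (fc > 0) q / fc else q
          f <- f * fc
        }
        Snew[i] <- Surv[i] * f
      }
    } else {
      gkey <- key_of(rf, cls, dur)
      for (g in unique(gkey)) {
        idx <- which(gkey == g)
        f <- rep(precomputed$ocm_factor[a + 1L, g], length(idx))
        for (ci in seq_len(nC)) {
          um <- precomputed$updates[[ci]][[a + 1L]][[g]]
          Qi <- Q[[ci]][idx, , drop = FALSE]
          qn <- Qi %*% um$M
          dmass <- as.numeric(Qi %*% um$dvec)
          fc <- 1 - dmass
          ok <- fc > 0
          qn[ok, ] <- qn[ok, , drop = FALSE] / fc[ok]
          Q[[ci]][idx, ] <- qn
          f <- f * fc
        }
        Snew[idx] <- Surv[idx] * f
      }
    }
    dying <- w * (Surv - Snew)
    for (k in unique(cls)) {
      idx <- which(cls == k)
      deaths[j, k] <- sum(dying[idx])
    }
    Surv <- Snew
  }

  structure(list(entry_age = bset$entry_age, entry_year = bset$entry_year,
                 sex = bset$sex, ages = ages, n = bset$n, K = K,
                 disease_names = dnames, alive = alive, deaths = deaths,
                 disease = if (D) disease else array(0, c(L, K, 0L)),
                 disease_free = disease_free),
            class = "cohort_lifetable")
}

#' @export
print.cohort_lifetable <- function(x, ...) {
  cat("<cohort_lifetable> cohort entering year ", x$entry_year, " at age ",
      x$entry_age, ", sex ", x$sex, "\n", sep = "")
  surv <- rowSums(x$alive)
  show <- unique(round(seq(1, length(x$ages), length.out = 6)))
  cat("  survival: ",
      paste(sprintf("age %d: %.3f", x$ages[show], surv[show]), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
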