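make_two_disease_cluster <- function(em = c(0.05, 0.02), cured = c(0.2, 0),
                                     inter = NULL) {
  d1 <- disease_spec("diab", cluster = "c1",
                     incidence = age_sex_table(0.01),
                     prevalence = age_sex_table(0.05),
                     excess_mortality = age_sex_table(em[1]),
                     cured_fraction = cured[1],
                     intermediate_rr = if (!is.null(inter)) list(ihd = inter) else list())
  d2 <- disease_spec("ihd", cluster = "c1",
                     incidence = age_sex_table(0.02),
                     prevalence = age_sex_table(0.04),
                     excess_mortality = age_sex_table(em[2]),
                     cured_fraction = cured[2])
  list(diab = d1, ihd = d2)
}

test_that("state hazards follow the baseline-times-RR formulas", {
  ds <- make_two_disease_cluster(inter = 2)
  rf <- two_class_rf(p1 = 0.5)
  inp <- sim_inputs(
    population = population_spec(age_sex_table(10), newborns = 0,
                                 total_mortality = age_sex_table(0.05)),
    risk_factor = rf, diseases = ds, horizon = 1, n_biographies = 10)
  b <- estimate_baselines(inp)

  # healthy state, all RR = 1: hazards are the baselines
  hz <- state_hazards(character(0), 50, "female", 1, b, ds, rf)
  expect_equal(hz$incidence[["diab"]],
               ast_at(b$baseline_incidence$diab, 50, "female"))
  expect_equal(hz$mortality,
               ast_at(b$baseline_other_cause_mortality, 50, "female"))

  # intermediate disease doubles the linked incidence, all else equal
  hz_d <- state_hazards("diab", 50, "female", 1, b, ds, rf)
  expect_equal(hz_d$incidence[["ihd"]], 2 * hz$incidence[["ihd"]])

  # diseased mortality: baseline OCM + (1 - cured) * excess
  expect_equal(hz_d$mortality,
               hz$mortality + (1 - 0.2) * 0.05)
})

test_that("diseased mortality equals OCM plus cure-scaled excess in a hand case", {
  d <- disease_spec("d", incidence = age_sex_table(0.001),
                    prevalence = age_sex_table(0.02),
                    excess_mortality = age_sex_table(0.05),
                    cured_fraction = 0.2)
  rf <- one_class_rf()
  inp <- sim_inputs(
    population = population_spec(age_sex_table(10), newborns = 0,
                                 total_mortality = age_sex_table(0.01 + 0.02 * 0.8 * 0.05)),
    risk_factor = rf, diseases = list(d = d), horizon = 1, n_biographies = 5)
  b <- estimate_baselines(inp)
  hz <- state_hazards("d", 0, "male", 1, b, list(d = d), rf)
  expect_equal(hz$mortality, 0.01 + 0.8 * 0.05, tolerance = 1e-12)
})

test_that("annual update reproduces competing-exponential closed forms", {
  space <- cluster_state_space(list(disease_spec(
    "d", incidence = age_sex_table(0), prevalence = age_sex_table(0),
    excess_mortality = age_sex_table(0))))
  hz <- function(lam, mu) list(
    list(incidence = c(d = lam), mortality = mu),  # healthy
    list(incidence = stats::setNames(numeric(0), character(0)), mortality = mu))

  # H = 0: occupancy unchanged
  up0 <- annual_update(c(1, 0), hz(0, 0), space)
  expect_equal(up0$occupancy, c(1, 0))
  expect_equal(up0$deaths, 0)

  # pure incidence: P(gain disease) = 1 - exp(-0.1)
  up1 <- annual_update(c(1, 0), hz(0.1, 0), space)
  expect_equal(up1$occupancy[2], 1 - exp(-0.1), tolerance = 1e-12)

  # equal competing hazards: each outcome gets half the exit mass
  up2 <- annual_update(c(1, 0), list(
    list(incidence = c(d = 0.1), mortality = 0.1),
    list(incidence = stats::setNames(numeric(0), character(0)), mortality = 0)),
    space)
  half_exit <- 0.5 * (1 - exp(-0.2))
  expect_equal(up2$deaths, half_exit, tolerance = 1e-12)
  expect_equal(up2$occupancy[2] * (1 - up2$deaths), half_exit, tolerance = 1e-12)

  expect_error(annual_update(c(0.7, 0.1), hz(0.1, 0), space), "sum to 1")
})

test_that("annual update matches a 1000-substep Euler integration", {
  ds <- make_two_disease_cluster(em = c(0.15, 0.1), cured = c(0.1, 0), inter = 2)
  space <- cluster_state_space(ds)
  fatal <- c(diab = 0.15, ihd = 0)
  set.seed(42)
  for (rep in 1:10) {
    # keep every state's total exit hazard at or below 0.5
    lam_base <- stats::runif(2, 0, 0.12)
    mu_ocm <- stats::runif(1, 0, 0.1)
    hazards <- lapply(seq_len(space$n_states), function(i) {
      pres <- space$present[i, ]
      lam <- numeric(0)
      if (!pres[1]) lam <- c(lam, diab = lam_base[1])
      if (!pres[2]) lam <- c(lam, ihd = lam_base[2] * if (pres[1]) 2 else 1)
      mu <- mu_ocm + sum(c(0.9 * 0.15, 0.1)[pres])
      list(incidence = lam, mortality = mu)
    })
    occ <- as.numeric(stats::rmultinom(1, 20, rep(1, 4))) / 20
    got <- annual_update(occ, hazards, space, fatal = fatal)
    ref <- euler_update(occ, hazards, space, fatal = fatal, nstep = 1000L)
    expect_lt(max(abs(got$occupancy - ref$occupancy)), 1e-4)
    expect_lt(abs(got$deaths - ref$deaths), 1e-4)
  }
})

test_that("cohort life tables reproduce single-disease and independence closed forms", {
  cf <- make_closed_form_case("single_disease")
  inp <- cf$inputs
  b <- estimate_baselines(inp)
  bs <- simulate_biographies(inp, 0, "female")
  lt <- build_cohort_lifetable(bs, b, inp)
  # no mortality: everyone alive until the terminal age
  expect_equal(rowSums(lt$alive)[1:105], rep(1, 105), tolerance = 1e-12)
  # P(disease by age t) = 1 - exp(-0.1 t)
  for (t in c(1, 5, 20)) {
    expect_equal(sum(lt$disease[t + 1, , 1]), cf$expected$occupancy_at(t),
                 tolerance = 1e-9)
  }

  cf2 <- make_closed_form_case("two_cluster")
  inp2 <- cf2$inputs
  lt2 <- build_cohort_lifetable(simulate_biographies(inp2, 0, "female"),
                                estimate_baselines(inp2), inp2)
  # independent clusters: disease-free share is the product of the clusters
  for (t in c(1, 5, 30)) {
    expect_equal(sum(lt2$disease_free[t + 1, ]), cf2$expected$none_at(t),
                 tolerance = 1e-9)
  }
})

test_that("with no diseases survival is the exponential of cumulated OCM", {
  rf <- two_class_rf(p1 = 0.5, rr_mort = c(1, 3))
  m <- 0.02
  inp <- sim_inputs(
    population = population_spec(age_sex_table(10), newborns = 0,
                                 total_mortality = age_sex_table(m)),
    risk_factor = rf, transitions = transition_model("zero"),
    horizon = 3, n_biographies = 400, seed = 5)
  b <- estimate_baselines(inp)
  bs <- simulate_biographies(inp, 40, "male")
  lt <- build_cohort_lifetable(bs, b, inp)
  # oracle: closed-form exponential survival from the drawn class shares
  p <- hiasim:::occupancy_at(bs, 40, 2)
  bm <- m / (0.5 * 1 + 0.5 * 3)
  for (t in c(1, 10, 40)) {
    expected <- p[1] * exp(-bm * t) + p[2] * exp(-3 * bm * t)
    expect_equal(sum(lt$alive[t + 1, ]), expected, tolerance = 1e-10)
  }
})

test_that("mass is conserved and survival is monotone", {
  inp <- make_toy_dataset(toy_params(n_biographies = 150, same_cluster = TRUE,
                                     intermediate_rr = 2,
                                     cured = c(0.2, 0), fatal = c(0.1, 0)))
  b <- estimate_baselines(inp)
  for (entry in c(0L, 60L)) {
    bs <- simulate_biographies(inp, entry, "female")
    lt <- build_cohort_lifetable(bs, b, inp)
    S <- rowSums(lt$alive)
    cum_deaths <- cumsum(rowSums(lt$deaths))
    L <- length(S)
    # alive + cumulative deaths = 1 at every age
    expect_lt(max(abs(S[2:L] + cum_deaths[1:(L - 1)] - 1)), 1e-9)
    expect_true(all(diff(S) <= 1e-12))
    expect_equal(S[1], 1, tolerance = 1e-12)
    # terminal closure at 105
    expect_equal(sum(lt$deaths[L, ]), S[L], tolerance = 1e-12)
    # disease occupancy within [0, alive]
    expect_true(all(lt$disease >= -1e-12))
    expect_true(all(lt$disease_free >= -1e-12))
    expect_true(all(rowSums(lt$disease_free) <= S + 1e-9))
  }
})

test_that("without cure the update never flows out of a disease state", {
  ds <- make_two_disease_cluster(cured = c(0, 0))
  space <- cluster_state_space(ds)
  um <- hiasim:::cluster_update_matrix(space, lam_base = c(0.1, 0.2),
                                       inter = hiasim:::intermediate_matrix(ds),
                                       em = c(0.05, 0.02), cured = c(0, 0),
                                       fatal = c(0, 0))
  for (i in seq_len(space$n_states)) {
    for (j in seq_len(space$n_states)) {
      lost <- space$present[i, ] & !space$present[j, ]
      if (any(lost)) expect_equal(um$M[i, j], 0)
    }
  }
  # and with em = 0 the aggregated disease share is non-decreasing
  cf <- make_closed_form_case("single_disease")
  lt <- build_cohort_lifetable(simulate_biographies(cf$inputs, 0, "male"),
                               estimate_baselines(cf$inputs), cf$inputs)
  expect_true(all(diff(apply(lt$disease, 1, sum)) >= -1e-12))
})

test_that("acutely fatal incidence removes the fatal fraction immediately", {
  d <- disease_spec("d", incidence = age_sex_table(0.1),
                    prevalence = age_sex_table(0),
                    excess_mortality = age_sex_table(0),
                    acutely_fatal_fraction = 0.5)
  inp <- sim_inputs(
    population = population_spec(age_sex_table(10), newborns = 0,
                                 total_mortality = age_sex_table(0.05)),
    risk_factor = one_class_rf(), transitions = transition_model("zero"),
    diseases = list(d = d), horizon = 1, n_biographies = 5)
  b <- estimate_baselines(inp)
  lt <- build_cohort_lifetable(simulate_biographies(inp, 0, "female"), b, inp)
  # year-1 deaths: competing OCM and fatal half of incidence
  lam <- 0.1; mu <- 0.05 - 0.1 * 0.5  # input total minus attributable = OCM
  H <- lam + mu
  exit <- 1 - exp(-H)
  expected_deaths <- exit * (mu / H) + exit * (lam / H) * 0.5
  expect_equal(sum(lt$deaths[1, ]), expected_deaths, tolerance = 1e-10)
})

test_that("continuous exposures drive individual hazards through RR^(x - x0)", {
  rf <- risk_factor_spec("continuous",
                         prevalence = list(mean = age_sex_table(1),
                                           sd = age_sex_table(0.5)),
                         distribution = "normal", reference_value = 1,
                         rr_mortality = rr_spec(per_unit = 2))
  inp <- sim_inputs(
    population = population_spec(age_sex_table(10), newborns = 0,
                                 total_mortality = age_sex_table(0.02)),
    risk_factor = rf, transitions = transition_model("zero"),
    horizon = 1, n_biographies = 50, seed = 3)
  b <- estimate_baselines(inp)
  bs <- simulate_biographies(inp, 50, "female")
  lt <- build_cohort_lifetable(bs, b, inp)
  bm <- ast_at(b$baseline_other_cause_mortality, 50, "female")
  expected <- mean(exp(-bm * 2^(bs$values[, 1] - 1)))
  expect_equal(sum(lt$alive[2, ]), expected, tolerance = 1e-10)
})
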