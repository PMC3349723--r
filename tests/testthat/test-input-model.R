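test_that("age/sex tables extend beyond the last supplied age and reject bad grids", {
  df <- expand.grid(age = 0:95, sex = c("female", "male"),
                    stringsAsFactors = FALSE)
  df$value <- 0.01 + df$age / 1000
  tab <- as_age_sex_table(df)
  expect_equal(ast_at(tab, 50, "male"), 0.06)
  # constant extension above age 95
  expect_equal(ast_at(tab, 105, "female"), ast_at(tab, 95, "female"))

  expect_error(as_age_sex_table(df[-10, ]), "missing cell")
  expect_error(as_age_sex_table(rbind(df, df[1, ])), "duplicate")
  df2 <- df
  df2$sex[1] <- "other"
  expect_error(as_age_sex_table(df2), "unknown sex")
  expect_error(as_age_sex_table(df[df$age < 90, ]), "up to 95")
})

test_that("a degenerate configuration (one class, no diseases) loads and runs", {
  inp <- sim_inputs(
    population = population_spec(age_sex_table(10), newborns = 10,
                                 total_mortality = age_sex_table(0.01)),
    risk_factor = one_class_rf(),
    transitions = transition_model("zero"),
    diseases = list(), horizon = 2, n_biographies = 5)
  expect_length(inp$diseases, 0)
  expect_true(is_valid(inp))
})

test_that("risk-factor prevalence that does not sum to 1 is rejected with location", {
  prev <- array(0.45, c(106, 2, 2))  # sums to 0.9 everywhere
  expect_error(
    risk_factor_spec("categorical", categories = c("a", "b"), prevalence = prev),
    "sum to 1.*age 0.*female")
})

test_that("a written input set reloads with identical values", {
  dir <- withr::local_tempdir()
  inp <- make_toy_dataset(toy_params(prevalence_gradient = TRUE,
                                     same_cluster = TRUE,
                                     intermediate_rr = 1.5,
                                     cured = c(0.2, 0), fatal = c(0.1, 0)))
  scen <- list(scenario_spec("reference"),
               scenario_spec("all_low", counterfactual_prevalence = c(1, 0, 0),
                             target = list(min_age = 10, max_age = 60,
                                           sexes = "male")))
  cfg <- write_inputs(inp, dir, scenarios = scen)
  re <- load_inputs(cfg)
  expect_equal(unclass(re$population$total_mortality),
               unclass(inp$population$total_mortality), tolerance = 1e-12)
  expect_equal(re$risk_factor$prevalence, inp$risk_factor$prevalence,
               tolerance = 1e-12)
  expect_equal(re$risk_factor$rr_mortality$per_class,
               inp$risk_factor$rr_mortality$per_class)
  expect_equal(names(re$diseases), names(inp$diseases))
  for (d in names(inp$diseases)) {
    expect_equal(unclass(re$diseases[[d]]$incidence),
                 unclass(inp$diseases[[d]]$incidence), tolerance = 1e-12)
    expect_equal(re$diseases[[d]]$cured_fraction, inp$diseases[[d]]$cured_fraction)
    expect_equal(re$diseases[[d]]$intermediate_rr, inp$diseases[[d]]$intermediate_rr)
  }
  expect_equal(re$horizon, inp$horizon)
  expect_equal(re$seed, inp$seed)
  sc2 <- attr(re, "scenarios")
  expect_length(sc2, 2)
  expect_equal(sc2[[2]]$target$sexes, "male")
  expect_equal(sc2[[2]]$counterfactual_prevalence[30, 2, ],
               c(low = 1, mid = 0, high = 0))
})

test_that("load_inputs reports missing files and malformed tables by name", {
  dir <- withr::local_tempdir()
  inp <- make_toy_dataset(toy_params(n_diseases = 0))
  cfg <- write_inputs(inp, dir)
  file.remove(file.path(dir, "total_mortality.csv"))
  expect_error(load_inputs(cfg), "total_mortality.csv")
  expect_error(load_inputs(file.path(dir, "nope.yaml")), "missing config")
})

test_that("validate_inputs flags injected violations with their location", {
  inp <- make_toy_dataset(toy_params())
  expect_length(validate_inputs(inp)$violations, 0)

  # negative other-cause mortality forced by an oversized excess mortality
  bad <- inp
  bad$population$total_mortality <- age_sex_table(0.01)
  bad$diseases$cardio$prevalence <- age_sex_table(0.6)
  bad$diseases$cardio$excess_mortality <- age_sex_table(0.02)
  v <- validate_inputs(bad)
  expect_true(any(grepl("negative other-cause mortality", v$violations)))

  # transition matrix row not summing to 1
  bad <- inp
  M <- identity_transitions(3)$matrices
  M[41, 1, 2, 3] <- 0.2   # row 'mid' now sums to 1.2 at age 40, female
  bad$transitions <- transition_model("explicit", M)
  v <- validate_inputs(bad)
  expect_true(any(grepl("row does not sum to 1 at age 40, sex female, from class mid",
                        v$violations)))

  # property-style mutations: row-sum, negativity, missing cell
  mutations <- list(
    function(x) { x$risk_factor$prevalence[13, 1, 1] <- x$risk_factor$prevalence[13, 1, 1] + 0.05; x },
    function(x) { x$diseases$cardio$incidence[5, 2] <- -0.01; x },
    function(x) { x$population$total_mortality[70, 1] <- NA; x },
    function(x) { x$diseases$lungdis$prevalence[20, 2] <- 1.4; x },
    function(x) { x$population$newborn_sex_ratio <- 1.2; x },
    function(x) { x$diseases$cardio$intermediate_rr <- list(lungdis = 2); x }  # cross-cluster
  )
  for (mut in mutations) {
    v <- validate_inputs(mut(inp))
    expect_gt(length(v$violations), 0)
  }

  # cycle among intermediate links (same cluster both ways)
  cyc <- make_toy_dataset(toy_params(same_cluster = TRUE))
  cyc$diseases$cardio$intermediate_rr <- list(lungdis = 2)
  cyc$diseases$lungdis$intermediate_rr <- list(cardio = 2)
  v <- validate_inputs(cyc)
  expect_true(any(grepl("cycle", v$violations)))
})

test_that("results written to disk reload with identical values", {
  inp <- make_toy_dataset(toy_params(horizon = 2, n_biographies = 60,
                                     start_count = 50))
  run <- run_hia(inp)
  fr <- run$frames$reference
  dir <- withr::local_tempdir()
  write_output(fr, dir)
  back <- read_output(dir)

  # year-0 alive reproduces the starting population exactly
  al0 <- back$period_alive[back$period_alive$year == 0, ]
  by_age <- tapply(al0$value, list(al0$age, al0$sex), sum)
  for (a in c(0, 40, 95)) {
    expect_equal(by_age[as.character(a), "female"],
                 ast_at(inp$population$start_counts, a, "female"))
  }
  expect_equal(sum(al0$value), sum(unclass(inp$population$start_counts)))

  # round-trip: every written value matches the in-memory array
  classes <- fr$meta$categories
  al <- back$period_alive
  idx <- cbind(al$year + 1L, al$age + 1L, match(al$sex, c("female", "male")),
               match(al$risk_class, classes))
  expect_lt(max(abs(fr$period$alive[idx] - al$value)), 1e-12)
  # zero-omission: all unwritten cells are zero
  tmp <- fr$period$alive
  tmp[idx] <- 0
  expect_equal(sum(tmp != 0), 0)

  dis <- back$period_disease_prevalence
  idx5 <- cbind(dis$year + 1L, dis$age + 1L, match(dis$sex, c("female", "male")),
                match(dis$risk_class, classes),
                match(dis$disease, fr$meta$disease_names))
  expect_lt(max(abs(fr$period$disease[idx5] - dis$value)), 1e-12)
  expect_true(all(c("measure", "year", "sex", "value") %in% names(back$summary)))
})
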