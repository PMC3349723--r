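test_that("expected relative risk averages class RRs by prevalence", {
  rf <- two_class_rf(p1 = 0.5)
  rr <- rr_spec(per_class = c(1, 2))
  expect_equal(expected_rr(rf, rr, age = 30, sex = "female"), 1.5)
  # single category: identity
  expect_equal(expected_rr(one_class_rf(), rr_spec(per_class = 3.7),
                           age = 0, sex = "male"), 3.7)
})

test_that("continuous expected RR matches the log-normal moment closed form", {
  # X - x0 ~ N(0, 1), RR per unit = e  =>  E[RR^(X-x0)] = exp(1/2)
  rf <- risk_factor_spec("continuous",
                         prevalence = list(mean = age_sex_table(0),
                                           sd = age_sex_table(1)),
                         distribution = "normal", reference_value = 0)
  got <- expected_rr(rf, rr_spec(per_unit = exp(1)), age = 40, sex = "female")
  expect_equal(got, exp(0.5), tolerance = 1e-6)

  # general normal closed form: exp(b*(m - x0) + b^2 s^2 / 2), b = log RR
  rf2 <- risk_factor_spec("continuous",
                          prevalence = list(mean = age_sex_table(24),
                                            sd = age_sex_table(3)),
                          distribution = "normal", reference_value = 22)
  b <- log(1.08)
  expect_equal(expected_rr(rf2, rr_spec(per_unit = 1.08), age = 50, sex = "male"),
               exp(b * 2 + b^2 * 9 / 2), tolerance = 1e-6)
})

test_that("baseline rates invert the RR-weighted average", {
  rf <- two_class_rf(p1 = 0.5)
  rr <- rr_spec(per_class = c(1, 2))
  b <- baseline_rate(age_sex_table(0.03), rf, rr)
  expect_equal(ast_at(b, 10, "female"), 0.02)
  # all RR = 1: baseline equals the population rate exactly
  pop <- age_sex_table(function(a) 0.001 * (1 + a))
  expect_equal(unclass(baseline_rate(pop, rf, rr_spec(per_class = c(1, 1)))),
               unclass(pop))
})

test_that("reconstruction identities hold to 1e-12 on random valid inputs", {
  set.seed(301)
  for (rep in 1:20) {
    K <- sample(2:6, 1)
    prev <- random_prevalence_array(K)
    rf <- risk_factor_spec("categorical", categories = paste0("c", 1:K),
                           prevalence = prev)
    rrv <- stats::runif(K, 0.3, 4)
    rr <- rr_spec(per_class = rrv)
    pop_rate <- age_sex_table(matrix(stats::runif(106 * 2, 0.001, 0.1), 106, 2))
    b <- unclass(baseline_rate(pop_rate, rf, rr))
    recon <- matrix(0, 106, 2)
    for (k in 1:K) recon <- recon + prev[, , k] * rrv[k] * b
    expect_lt(max(abs(recon - unclass(pop_rate))), 1e-12)

    d <- disease_spec("d", incidence = pop_rate,
                      prevalence = age_sex_table(matrix(stats::runif(212, 0, 0.15), 106, 2)),
                      excess_mortality = age_sex_table(0.01))
    rf2 <- risk_factor_spec("categorical", categories = paste0("c", 1:K),
                            prevalence = prev,
                            rr_incidence = stats::setNames(list(rr), "d"))
    cp <- class_specific_prevalence(d, rf2)
    wmean <- matrix(0, 106, 2)
    for (k in 1:K) wmean <- wmean + prev[, , k] * cp[, , k]
    expect_lt(max(abs(wmean - unclass(d$prevalence))), 1e-12)
  }
})

test_that("class-specific prevalence splits proportionally to incidence RRs", {
  rf <- two_class_rf(p1 = 0.5, rr_inc = c(1, 2), diseases = "d")
  d <- disease_spec("d", incidence = age_sex_table(0.01),
                    prevalence = age_sex_table(0.06),
                    excess_mortality = age_sex_table(0))
  cp <- class_specific_prevalence(d, rf)
  expect_equal(unname(cp[31, 1, ]), c(0.04, 0.08))
  # all RR = 1: every class carries the population prevalence
  rf1 <- two_class_rf(p1 = 0.3)
  cp1 <- class_specific_prevalence(d, rf1)
  expect_true(all(abs(cp1 - 0.06) < 1e-12))
  # impossible allocation (class value > 1) is an inconsistency error
  d2 <- disease_spec("d", incidence = age_sex_table(0.01),
                     prevalence = age_sex_table(0.8),
                     excess_mortality = age_sex_table(0))
  expect_error(class_specific_prevalence(d2, rf), "exceeds 1")
})

test_that("mortality decomposition follows the additive model", {
  d <- disease_spec("d", incidence = age_sex_table(0.001),
                    prevalence = age_sex_table(0.1),
                    excess_mortality = age_sex_table(0.02))
  ocm <- decompose_other_cause_mortality(age_sex_table(0.01), list(d))
  expect_equal(ast_at(ocm, 50, "female"), 0.008)
  # empty disease list: other-cause mortality equals total mortality
  tot <- age_sex_table(function(a) 0.002 + a / 1e4)
  expect_equal(unclass(decompose_other_cause_mortality(tot, list())),
               unclass(tot))
  # cured and acutely fatal terms
  d2 <- disease_spec("d", incidence = age_sex_table(0.01),
                     prevalence = age_sex_table(0.1),
                     excess_mortality = age_sex_table(0.02),
                     cured_fraction = 0.5, acutely_fatal_fraction = 0.2)
  expect_equal(ast_at(decompose_other_cause_mortality(age_sex_table(0.01), list(d2)),
                      0, "male"),
               0.01 - 0.1 * 0.5 * 0.02 - 0.01 * 0.2)
  # inconsistent inputs are refused with the offending cell named
  d3 <- disease_spec("d", incidence = age_sex_table(0),
                     prevalence = age_sex_table(0.6),
                     excess_mortality = age_sex_table(0.02))
  expect_error(decompose_other_cause_mortality(age_sex_table(0.01), list(d3)),
               "age 0, sex female")
})

test_that("net transitions solve the adjacent-flow balance equations", {
  # constant prevalence: identity matrices
  rf <- two_class_rf(p1 = 0.6)
  tm <- net_transitions(rf)
  expect_equal(tm$matrices[50, 1, , ], diag(2))

  # hand-solved 2-class case: p(a) = (0.6, 0.4) -> p(a+1) = (0.5, 0.5)
  prev <- array(NA_real_, c(106, 2, 2))
  for (a in 0:105) {
    p1 <- max(0.6 - 0.1 * a, 0.1)
    prev[a + 1, , ] <- rep(c(p1, 1 - p1), each = 2)
  }
  rf2 <- risk_factor_spec("categorical", categories = c("a", "b"),
                          prevalence = prev)
  Tm <- net_transitions(rf2)$matrices[1, 1, , ]
  expect_equal(Tm[1, 2], 0.1 / 0.6, tolerance = 1e-12)
  expect_equal(Tm[2, 1], 0)

  # hand-solved 3-class case via cumulative flows
  prev3 <- array(NA_real_, c(106, 2, 3))
  prev3[1, , ] <- rep(c(0.5, 0.3, 0.2), each = 2)
  for (a in 1:105) prev3[a + 1, , ] <- rep(c(0.4, 0.35, 0.25), each = 2)
  rf3 <- risk_factor_spec("categorical", categories = c("a", "b", "c"),
                          prevalence = prev3)
  Tm3 <- net_transitions(rf3)$matrices[1, 1, , ]
  expect_equal(Tm3[1, 2], 0.2, tolerance = 1e-12)
  expect_equal(Tm3[2, 3], 0.05 / 0.3, tolerance = 1e-12)
  expect_equal(Tm3[2, 1], 0)
  expect_equal(Tm3[3, 2], 0)
  expect_equal(drop(prev3[1, 1, ] %*% Tm3), prev3[2, 1, ], tolerance = 1e-12)
})

test_that("net transitions reproduce the prevalence along any age span", {
  set.seed(99)
  for (rep in 1:10) {
    K <- sample(2:5, 1)
    prev <- random_smooth_prevalence(K)
    rf <- risk_factor_spec("categorical", categories = paste0("c", 1:K),
                           prevalence = prev)
    M <- net_transitions(rf)$matrices
    for (s in 1:2) {
      p <- prev[1, s, ]
      for (a in 0:40) {
        Tm <- M[a + 1, s, , ]
        expect_true(all(Tm >= 0), info = "rows are probability vectors")
        expect_lt(max(abs(rowSums(Tm) - 1)), 1e-12)
        p <- drop(p %*% Tm)
        expect_lt(max(abs(p - prev[a + 2, s, ])), 1e-12)
      }
    }
  }
})
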