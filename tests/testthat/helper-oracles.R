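# Independent oracles and shared mini-fixtures for the suite.

# Forward-Euler integration of the within-year dynamics (competing constant
# hazards, at most one incidence event per year, acutely fatal split):
# mass leaving a state accrues in destination/death buckets and does not
# flow again within the year.  Independent of the analytic allocation used
# by annual_update().
euler_update <- function(occ, hazards, space, fatal = NULL, nstep = 1000L) {
  S <- space$n_states
  k <- length(space$names)
  if (is.null(fatal)) fatal <- stats::setNames(rep(0, k), space$names)
  lam <- matrix(0, S, max(k, 1L))
  mu <- numeric(S)
  for (i in seq_len(S)) {
    l <- hazards[[i]]$incidence
    mu[i] <- hazards[[i]]$mortality
    for (d in names(l)) lam[i, match(d, space$names)] <- l[[d]]
  }
  H <- mu + rowSums(lam)
  h <- 1 / nstep
  stay <- occ
  arrive <- numeric(S)
  dead <- 0
  for (step in seq_len(nstep)) {
    dead <- dead + sum(stay * mu) * h
    for (i in seq_len(S)) {
      for (d in seq_len(k)) {
        if (lam[i, d] > 0) {
          mv <- stay[i] * lam[i, d] * h
          dead <- dead + mv * fatal[[space$names[d]]]
          j <- i + bitwShiftL(1L, d - 1L)
          arrive[j] <- arrive[j] + mv * (1 - fatal[[space$names[d]]])
        }
      }
    }
    stay <- stay * (1 - H * h)
  }
  q <- stay + arrive
  list(occupancy = q / (1 - dead), deaths = dead)
}

# Single-class risk factor (no exposure heterogeneity).
one_class_rf <- function() {
  risk_factor_spec("categorical", categories = "all",
                   prevalence = array(1, c(106, 2, 1)))
}

# Two-class risk factor with age-constant prevalence p1.
two_class_rf <- function(p1 = 0.5, rr_mort = c(1, 1), rr_inc = NULL,
                         diseases = character(0)) {
  prev <- array(NA_real_, c(106, 2, 2))
  prev[, , 1] <- p1
  prev[, , 2] <- 1 - p1
  rri <- list()
  for (d in diseases) rri[[d]] <- rr_spec(per_class = rr_inc)
  risk_factor_spec("categorical", categories = c("c1", "c2"),
                   prevalence = prev, rr_incidence = rri,
                   rr_mortality = rr_spec(per_class = rr_mort))
}

# Random valid simplex prevalence array (independent cells).
random_prevalence_array <- function(K) {
  raw <- array(stats::runif(106 * 2 * K, 0.05, 1), c(106, 2, K))
  sw <- apply(raw, c(1, 2), sum)
  for (k in seq_len(K)) raw[, , k] <- raw[, , k] / sw
  raw
}

# Random simplex prevalence varying smoothly with age (a linear blend of
# two random endpoints), so year-to-year net flows are small and the
# adjacent-flow transition construction is feasible.
random_smooth_prevalence <- function(K) {
  out <- array(NA_real_, c(106, 2, K))
  for (s in 1:2) {
    p0 <- stats::runif(K, 0.1, 1); p0 <- p0 / sum(p0)
    p1 <- stats::runif(K, 0.1, 1); p1 <- p1 / sum(p1)
    w <- (0:105) / 105
    for (k in seq_len(K)) out[, s, k] <- (1 - w) * p0[k] + w * p1[k]
  }
  out
}

expect_simplex <- function(p, tol = 1e-9) {
  expect_true(all(p >= -tol))
  expect_lt(abs(sum(p) - 1), tol)
}
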