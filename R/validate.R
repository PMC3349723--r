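## Full validation of a simulation input bundle.  Unlike the constructors
## (which fail fast on structurally impossible values), validate_inputs
## never throws: it returns a report listing every violated invariant and
## consistency problem, so mutually inconsistent epidemiological inputs are
## surfaced before a long simulation run.

check_table <- function(report, tab, what, lower = 0, upper = Inf) {
  v <- unclass(tab)
  if (anyNA(v)) {
    bad <- which(is.na(v), arr.ind = TRUE)[1L, ]
    report <- c(report, sprintf("%s: missing cell at age %d, sex %s",
                                what, bad[1] - 1L, SEXES[bad[2]]))
    v[is.na(v)] <- lower
  }
  if (any(v < lower)) {
    bad <- which(v < lower, arr.ind = TRUE)[1L, ]
    report <- c(report, sprintf("%s: value below %g at age %d, sex %s",
                                what, lower, bad[1] - 1L, SEXES[bad[2]]))
  }
  if (any(v > upper)) {
    bad <- which(v > upper, arr.ind = TRUE)[1L, ]
    report <- c(report, sprintf("%s: value above %g at age %d, sex %s",
                                what, upper, bad[1] - 1L, SEXES[bad[2]]))
  }
  report
}

detect_cycle <- function(adj) {
  ## adj: logical matrix, adj[i, j] = edge i -> j
  nm <- rownames(adj)
  remaining <- rep(TRUE, nrow(adj))
  repeat {
    if (!any(remaining)) return(NULL)
    indeg <- colSums(adj[remaining, remaining, drop = FALSE])
    src <- which(indeg == 0)
    if (!length(src)) return(nm[remaining])
    keep <- which(remaining)[-src]
    remaining[] <- FALSE
    remaining[keep] <- TRUE
  }
}

#' Validate a simulation input bundle
#'
#' Checks every structural invariant (complete age/sex grids,
#' non-negativity, probability bounds, prevalence simplexes, transition
#' row sums, intermediate-disease links acyclic and within-cluster) and
#' the mutual consistency of the epidemiological inputs, in particular
#' that total mortality minus the disease-attributable mortality is
#' non-negative at every age and sex.
#'
#' @param inputs A [sim_inputs()] bundle.
#' @return An object of class `validation_report` with elements
#'   `violations` and `warnings` (character vectors); empty `violations`
#'   means the inputs are usable.
#' @export
validate_inputs <- function(inputs) {
  rep_ <- character(0)
  warn <- character(0)
  rf <- inputs$risk_factor
  pop <- inputs$population

  ## population
  rep_ <- check_table(rep_, pop$start_counts, "start_counts")
  rep_ <- check_table(rep_, pop$total_mortality, "total_mortality")
  if (pop$newborn_sex_ratio < 0 || pop$newborn_sex_ratio > 1)
    rep_ <- c(rep_, "newborn_sex_ratio outside [0, 1]")
  if (any(pop$newborns < 0)) rep_ <- c(rep_, "negative newborn count")
  if (inputs$horizon < 1) rep_ <- c(rep_, "horizon must be >= 1")
  if (inputs$n_biographies < 1) rep_ <- c(rep_, "n_biographies must be >= 1")

  ## risk factor
  if (rf$kind == "continuous") {
    rep_ <- check_table(rep_, rf$prevalence$mean, "exposure mean",
                        lower = -Inf)
    if (any(unclass(rf$prevalence$sd) <= 0, na.rm = TRUE))
      rep_ <- c(rep_, "continuous risk factor: sd must be > 0")
  } else {
    K <- n_classes(rf)
    if (K < 1 || K > 10)
      rep_ <- c(rep_, "number of risk-factor categories must be 1..10")
    if (anyNA(rf$prevalence)) {
      bad <- which(is.na(rf$prevalence), arr.ind = TRUE)[1L, ]
      rep_ <- c(rep_, sprintf(
        "risk-factor prevalence: missing cell at age %d, sex %s, class %s",
        bad[1] - 1L, SEXES[bad[2]], rf$categories[bad[3]]))
    } else {
      if (any(rf$prevalence < 0))
        rep_ <- c(rep_, "risk-factor prevalence: negative value")
      sums <- apply(rf$prevalence, c(1, 2), sum)
      off <- which(abs(sums - 1) > 1e-9, arr.ind = TRUE)
      if (nrow(off))
        rep_ <- c(rep_, sprintf(
          "risk-factor prevalence does not sum to 1 at age %d, sex %s (sum %.6f)",
          off[1, 1] - 1L, SEXES[off[1, 2]], sums[off[1, , drop = FALSE]]))
    }
    for (nm in names(rf$rr_incidence)) {
      rr <- rf$rr_incidence[[nm]]
      if (any(c(rr$per_class, rr$duration_table) <= 0))
        rep_ <- c(rep_, sprintf("relative risks on %s incidence must be > 0", nm))
    }
    if (any(c(rf$rr_mortality$per_class, rf$rr_mortality$duration_table) <= 0))
      rep_ <- c(rep_, "relative risks on mortality must be > 0")
  }

  ## transitions
  tr <- inputs$transitions
  if (tr$mode == "explicit") {
    M <- tr$matrices
    if (any(M < -1e-12) || any(M > 1 + 1e-12))
      rep_ <- c(rep_, "transition probabilities outside [0, 1]")
    rs <- apply(M, c(1, 2, 3), sum)
    off <- which(abs(rs - 1) > 1e-9, arr.ind = TRUE)
    if (nrow(off))
      rep_ <- c(rep_, sprintf(
        "transition matrix row does not sum to 1 at age %d, sex %s, from class %s (sum %.6f)",
        off[1, 1] - 1L, SEXES[off[1, 2]], rf$categories[off[1, 3]],
        rs[off[1, , drop = FALSE]]))
  }

  ## diseases
  dnames <- names(inputs$diseases)
  for (d in inputs$diseases) {
    rep_ <- check_table(rep_, d$incidence, paste0(d$name, " incidence"))
    rep_ <- check_table(rep_, d$prevalence, paste0(d$name, " prevalence"),
                        upper = 1)
    rep_ <- check_table(rep_, d$excess_mortality,
                        paste0(d$name, " excess mortality"))
    if (d$cured_fraction < 0 || d$cured_fraction > 1)
      rep_ <- c(rep_, paste0(d$name, ": cured_fraction outside [0, 1]"))
    if (d$acutely_fatal_fraction < 0 || d$acutely_fatal_fraction > 1)
      rep_ <- c(rep_, paste0(d$name, ": acutely_fatal_fraction outside [0, 1]"))
    for (tgt in names(d$intermediate_rr)) {
      if (!tgt %in% dnames) {
        rep_ <- c(rep_, sprintf("%s: intermediate link to unknown disease %s",
                                d$name, tgt))
      } else if (inputs$diseases[[tgt]]$cluster != d$cluster) {
        rep_ <- c(rep_, sprintf(
          "%s: intermediate link to %s crosses clusters (%s vs %s)",
          d$name, tgt, d$cluster, inputs$diseases[[tgt]]$cluster))
      }
      if (d$intermediate_rr[[tgt]] <= 0)
        rep_ <- c(rep_, sprintf("%s -> %s: intermediate RR must be > 0",
                                d$name, tgt))
    }
  }
  if (length(dnames) > 1L) {
    adj <- matrix(FALSE, length(dnames), length(dnames),
                  dimnames = list(dnames, dnames))
    for (d in inputs$diseases)
      for (tgt in intersect(names(d$intermediate_rr), dnames))
        adj[d$name, tgt] <- TRUE
    cyc <- detect_cycle(adj)
    if (!is.null(cyc))
      rep_ <- c(rep_, paste0("cycle among intermediate-disease links: ",
                             paste(cyc, collapse = ", ")))
  }

  ## consistency: additive mortality decomposition must stay non-negative
  ocm_ok <- tryCatch({
    decompose_other_cause_mortality(pop$total_mortality, inputs$diseases)
    TRUE
  }, error = function(e) {
    rep_ <<- c(rep_, paste0("negative other-cause mortality: ",
                            conditionMessage(e)))
    FALSE
  })
  if (ocm_ok && rf$kind != "continuous" && length(inputs$diseases)) {
    for (d in inputs$diseases) {
      tryCatch(class_specific_prevalence(d, rf), error = function(e)
        rep_ <<- c(rep_, conditionMessage(e)))
    }
  }

  structure(list(violations = rep_, warnings = warn),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (!length(x$violations)) {
    cat("inputs valid: no violations\n")
  } else {
    cat(length(x$violations), "violation(s):\n")
    for (v in x$violations) cat("  - ", v, "\n", sep = "")
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' @rdname validate_inputs
#' @export
is_valid <- function(inputs) length(validate_inputs(inputs)$violations) == 0L
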