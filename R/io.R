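## File interface: one YAML config file referencing delimited CSV tables
## (header `age,sex,value` or `age,sex,category,value`, UTF-8, age
## ascending), and delimited result files with deterministic ordering.

read_input_table <- function(dir, file, what = file) {
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("missing input file: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed table ", path, ": ",
                                          conditionMessage(e)))
  if (!is.numeric(df$value))
    stop(what, " (", path, "): 'value' column must be numeric")
  df
}

parse_rr <- function(x, categories, what) {
  if (is.null(x)) return(NULL)
  if (is.list(x) && !is.null(x$per_unit)) return(rr_spec(per_unit = x$per_unit))
  if (is.list(x) && (!is.null(x$per_class) || !is.null(x$duration_table))) {
    pc <- x$per_class
    if (!is.null(pc)) pc <- unlist(pc)[categories]
    return(rr_spec(per_class = as.numeric(pc),
                   duration_table = as.numeric(unlist(x$duration_table))))
  }
  v <- unlist(x)
  if (is.null(names(v))) {
    if (length(v) == 1L) return(rr_spec(per_unit = as.numeric(v)))
    stop(what, ": relative risks must be named by category")
  }
  miss <- setdiff(categories, names(v))
  if (length(miss)) stop(what, ": missing RR for category ",
                         paste(miss, collapse = ", "))
  rr_spec(per_class = as.numeric(v[categories]))
}

#' Load simulation inputs from a config file
#'
#' Reads a YAML configuration (keys: `population`, `risk_factor`,
#' `transitions`, `diseases`, `scenarios`, `horizon`, `n_biographies`,
#' `seed`) whose table entries name CSV files relative to the config's
#' directory.  Input tables must cover ages 0--95; values above the last
#' supplied age are held constant up to the internal terminal age 105.
#'
#' @param config_path Path to the YAML config file.
#' @return A [sim_inputs()] bundle; any scenario definitions from the
#'   config are attached as `attr(, "scenarios")` (a list of
#'   [scenario_spec()]s).
#' @export
load_inputs <- function(config_path) {
  if (!file.exists(config_path)) stop("missing config file: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  dir <- dirname(config_path)

  ## population
  pc <- cfg$population
  if (is.null(pc)) stop(config_path, ": missing 'population' section")
  start <- as_age_sex_table(read_input_table(dir, pc$start_counts),
                            what = pc$start_counts)
  tm <- as_age_sex_table(read_input_table(dir, pc$total_mortality),
                         what = pc$total_mortality)
  newborns <- if (is.character(pc$newborns)) {
    nb <- utils::read.csv(file.path(dir, pc$newborns))
    nb$value[order(nb$year)]
  } else as.numeric(pc$newborns)
  pop <- population_spec(start, newborns,
                         newborn_sex_ratio = pc$newborn_sex_ratio %||% 0.5,
                         total_mortality = tm)

  ## risk factor
  rc <- cfg$risk_factor
  if (is.null(rc)) stop(config_path, ": missing 'risk_factor' section")
  kind <- rc$kind %||% "categorical"
  if (kind == "continuous") {
    prev <- list(mean = as_age_sex_table(read_input_table(dir, rc$mean),
                                         what = rc$mean),
                 sd = as_age_sex_table(read_input_table(dir, rc$sd),
                                       what = rc$sd))
    categories <- NULL
  } else {
    categories <- as.character(unlist(rc$categories))
    prev <- as_category_table(read_input_table(dir, rc$prevalence),
                              categories, what = rc$prevalence)
  }
  diseases <- list()
  rr_incidence <- list()
  for (dc in cfg$diseases %||% list()) {
    d <- disease_spec(
      name = dc$name, cluster = dc$cluster %||% dc$name,
      incidence = as_age_sex_table(read_input_table(dir, dc$incidence),
                                   what = dc$incidence),
      prevalence = as_age_sex_table(read_input_table(dir, dc$prevalence),
                                    what = dc$prevalence),
      excess_mortality = as_age_sex_table(
        read_input_table(dir, dc$excess_mortality), what = dc$excess_mortality),
      cured_fraction = dc$cured_fraction %||% 0,
      acutely_fatal_fraction = dc$acutely_fatal_fraction %||% 0,
      intermediate_rr = lapply(dc$rr_from_diseases %||% list(), as.numeric))
    diseases[[dc$name]] <- d
    rr <- parse_rr(dc$rr_from_risk_factor, categories,
                   paste0(dc$name, " rr_from_risk_factor"))
    if (!is.null(rr)) rr_incidence[[dc$name]] <- rr
  }
  rf <- risk_factor_spec(
    kind = kind, categories = categories, prevalence = prev,
    rr_incidence = rr_incidence,
    rr_mortality = parse_rr(rc$rr_mortality, categories, "rr_mortality"),
    duration_category = if (!is.null(rc$duration_category))
      match(rc$duration_category, categories),
    duration_max = rc$duration_max %||% 20L,
    duration_distribution = if (!is.null(rc$duration_distribution))
      as.numeric(unlist(rc$duration_distribution)),
    distribution = rc$distribution %||% "normal",
    reference_value = rc$reference_value %||% 0)

  ## transitions
  tc <- cfg$transitions %||% list(mode = "net")
  trans <- if ((tc$mode %||% "net") == "explicit") {
    df <- read_input_table(dir, tc$file)
    K <- length(categories)
    M <- array(NA_real_, c(AGE_MAX + 1L, 2L, K, K))
    df$sex <- tolower(df$sex)
    fi <- match(df$from, categories); ti <- match(df$to, categories)
    if (anyNA(fi) || anyNA(ti))
      stop(tc$file, ": unknown category label in from/to")
    M[cbind(df$age + 1L, sex_index(df$sex), fi, ti)] <- df$value
    M[is.na(M)] <- 0
    for (a in 97:(AGE_MAX + 1L)) {
      blank <- apply(M[a, , , , drop = FALSE], 2, sum) == 0
      if (any(blank)) M[a, blank, , ] <- M[96L, blank, , ]
    }
    transition_model("explicit", M)
  } else transition_model(tc$mode %||% "net")

  inputs <- sim_inputs(population = pop, risk_factor = rf,
                       transitions = trans, diseases = diseases,
                       horizon = cfg$horizon %||% 10L,
                       n_biographies = cfg$n_biographies %||% 500L,
                       seed = cfg$seed %||% 1L)
  scen <- lapply(cfg$scenarios %||% list(), function(sc) {
    cf <- if (!is.null(sc$counterfactual_prevalence)) {
      as_category_table(read_input_table(dir, sc$counterfactual_prevalence),
                        categories, what = sc$counterfactual_prevalence)
    }
    ov <- if (!is.null(sc$transition_override))
      transition_model(sc$transition_override)
    scenario_spec(sc$name, counterfactual_prevalence = cf,
                  transition_override = ov,
                  target = sc$target %||% list())
  })
  attr(inputs, "scenarios") <- scen
  inputs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulation input bundle to disk
#'
#' The inverse of [load_inputs()]: writes a YAML config plus one CSV per
#' table into `dir`.  `load_inputs(file.path(dir, "config.yaml"))` returns
#' a bundle with identical values.
#'
#' @param inputs A [sim_inputs()] bundle.
#' @param dir Output directory (created if needed).
#' @param scenarios Optional list of [scenario_spec()]s to include.
#' @return The config path, invisibly.
#' @export
write_inputs <- function(inputs, dir, scenarios = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtab <- function(tab, file) {
    utils::write.csv(ast_to_df(tab), file.path(dir, file), row.names = FALSE)
    file
  }
  wcat <- function(arr, file) {
    utils::write.csv(category_table_to_df(arr), file.path(dir, file),
                     row.names = FALSE)
    file
  }
  rf <- inputs$risk_factor
  pop <- inputs$population
  rr_out <- function(rr) {
    if (!is.null(rr$per_unit)) list(per_unit = rr$per_unit)
    else if (!is.null(rr$duration_table))
      list(per_class = as.list(stats::setNames(rr$per_class, rf$categories)),
           duration_table = rr$duration_table)
    else as.list(stats::setNames(rr$per_class, rf$categories))
  }
  cfg <- list(
    horizon = inputs$horizon, n_biographies = inputs$n_biographies,
    seed = inputs$seed,
    population = list(
      start_counts = wtab(pop$start_counts, "start_counts.csv"),
      total_mortality = wtab(pop$total_mortality, "total_mortality.csv"),
      newborns = as.numeric(pop$newborns),
      newborn_sex_ratio = pop$newborn_sex_ratio),
    risk_factor = if (rf$kind == "continuous") list(
      kind = rf$kind, distribution = rf$distribution,
      reference_value = rf$reference_value,
      mean = wtab(rf$prevalence$mean, "exposure_mean.csv"),
      sd = wtab(rf$prevalence$sd, "exposure_sd.csv"),
      rr_mortality = rr_out(rf$rr_mortality)
    ) else c(list(
      kind = rf$kind, categories = as.list(rf$categories),
      prevalence = wcat(rf$prevalence, "rf_prevalence.csv"),
      rr_mortality = rr_out(rf$rr_mortality)),
      if (rf$kind == "duration") list(
        duration_category = rf$categories[rf$duration_category],
        duration_max = rf$duration_max,
        duration_distribution = rf$duration_distribution)),
    transitions = if (inputs$transitions$mode == "explicit") {
      K <- n_classes(rf)
      grid <- expand.grid(age = 0:AGE_MAX, sex = SEXES,
                          from = rf$categories, to = rf$categories,
                          stringsAsFactors = FALSE)
      grid$value <- inputs$transitions$matrices[cbind(
        grid$age + 1L, sex_index(grid$sex),
        match(grid$from, rf$categories), match(grid$to, rf$categories))]
      grid <- grid[grid$value != 0, ]
      grid <- grid[order(grid$age, grid$sex, grid$from, grid$to), ]
      utils::write.csv(grid, file.path(dir, "transitions.csv"),
                       row.names = FALSE)
      list(mode = "explicit", file = "transitions.csv")
    } else list(mode = inputs$transitions$mode),
    diseases = lapply(inputs$diseases, function(d) c(list(
      name = d$name, cluster = d$cluster,
      incidence = wtab(d$incidence, paste0(d$name, "_incidence.csv")),
      prevalence = wtab(d$prevalence, paste0(d$name, "_prevalence.csv")),
      excess_mortality = wtab(d$excess_mortality,
                              paste0(d$name, "_excess_mortality.csv")),
      cured_fraction = d$cured_fraction,
      acutely_fatal_fraction = d$acutely_fatal_fraction),
      if (!is.null(rf$rr_incidence[[d$name]]))
        list(rr_from_risk_factor = rr_out(rf$rr_incidence[[d$name]])),
      if (length(d$intermediate_rr))
        list(rr_from_diseases = d$intermediate_rr))),
    scenarios = lapply(scenarios %||% list(), function(sc) c(
      list(name = sc$name),
      if (!is.null(sc$counterfactual_prevalence)) list(
        counterfactual_prevalence = wcat(
          expand_counterfactual(sc$counterfactual_prevalence, n_classes(rf)) |>
            (\(a) { dimnames(a)[[3]] <- rf$categories; a })(),
          paste0("cf_", gsub("[^a-z0-9]", "_", tolower(sc$name)), ".csv"))),
      if (!is.null(sc$transition_override))
        list(transition_override = sc$transition_override$mode),
      list(target = sc$target)))
  )
  cfg$diseases <- unname(cfg$diseases)
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write simulation results to delimited files
#'
#' One CSV per measure with columns `year, age, sex, risk_class, disease,
#' value` (rows with value 0 omitted; deterministic column order and row
#' sort), plus `summary.csv` with the life-expectancy measures per year and
#' sex.
#'
#' @param frame An `output_frame`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_output <- function(frame, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  classes <- frame$meta$categories %||% as.character(seq_len(frame$meta$K))
  h <- frame$meta$horizon
  long4 <- function(arr, disease = "all") {
    g <- expand.grid(year = 0:h, age = 0:AGE_MAX, sex = SEXES,
                     risk_class = classes, stringsAsFactors = FALSE)
    g$disease <- disease
    g$value <- as.vector(arr)
    g <- g[g$value != 0, c("year", "age", "sex", "risk_class", "disease", "value")]
    g[order(g$year, g$age, g$sex, g$risk_class, g$disease), ]
  }
  files <- character(0)
  wr <- function(df, file) {
    utils::write.csv(df, file.path(out_dir, file), row.names = FALSE)
    files <<- c(files, file)
  }
  wr(long4(frame$period$alive), "period_alive.csv")
  wr(long4(frame$period$deaths), "period_deaths.csv")
  wr(long4(frame$period$disease_free), "period_disease_free.csv")
  dnames <- frame$meta$disease_names
  dis <- do.call(rbind, lapply(seq_along(dnames), function(d)
    long4(frame$period$disease[, , , , d], disease = dnames[d])))
  if (is.null(dis))
    dis <- long4(frame$period$alive * 0)
  wr(dis, "period_disease_prevalence.csv")

  ## summary: life-expectancy measures per year and sex
  rows <- list()
  for (t in 0:h) for (sx in SEXES) {
    he <- health_expectancies(frame, year = t, sex = sx)
    rows[[length(rows) + 1L]] <- data.frame(
      measure = c("period_le", "disease_free_le",
                  if (length(dnames)) paste0("years_with_", dnames)),
      year = t, sex = sx,
      value = c(he$life_expectancy, he$disease_free_le,
                if (length(dnames)) unname(he$years_with)))
  }
  wr(do.call(rbind, rows), "summary.csv")
  invisible(files)
}

#' Read back result files written by [write_output()]
#'
#' @param out_dir Directory written by [write_output()].
#' @return Named list of data frames, one per file.
#' @export
read_output <- function(out_dir) {
  fs <- list.files(out_dir, pattern = "\\.csv$")
  out <- lapply(fs, function(f)
    utils::read.csv(file.path(out_dir, f), stringsAsFactors = FALSE))
  names(out) <- sub("\\.csv$", "", fs)
  out
}
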