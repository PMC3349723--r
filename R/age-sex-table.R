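## Age/sex grid conventions used throughout the engine.
##
## Every rate, probability, proportion or count is carried on a common grid:
## integer single-year ages 0..105 by sex (female, male).  Input tables are
## required up to age 95; values for ages 96..105 are held constant at the
## last supplied age so cohorts can be followed to the terminal age 105,
## where the life table is closed (everyone dies).

AGE_MAX <- 105L
SEXES <- c("female", "male")

#' Age-by-sex table
#'
#' The universal carrier for age- and sex-specific quantities: a numeric
#' matrix with one row per integer age 0--105 and one column per sex
#' (`"female"`, `"male"`).
#'
#' @param x Either a single number (recycled over the whole grid), a
#'   function of `age` (applied to ages 0--105, same values for both
#'   sexes), or a 106 x 2 numeric matrix.
#' @return An object of class `age_sex_table`: a 106 x 2 numeric matrix
#'   with dimnames `age` (0--105) and `sex`.
#' @examples
#' age_sex_table(0.01)
#' age_sex_table(function(age) 1e-4 * exp(0.08 * age))
#' @export
age_sex_table <- function(x) {
  n <- AGE_MAX + 1L
  if (is.function(x)) {
    v <- x(0:AGE_MAX)
    m <- cbind(v, v)
  } else if (length(x) == 1L) {
    m <- matrix(as.numeric(x), n, 2L)
  } else if (is.matrix(x)) {
    stopifnot(nrow(x) == n, ncol(x) == 2L)
    m <- x
  } else if (length(x) == n) {
    m <- cbind(as.numeric(x), as.numeric(x))
  } else {
    stop("cannot interpret 'x' as an age/sex table")
  }
  dimnames(m) <- list(age = 0:AGE_MAX, sex = SEXES)
  storage.mode(m) <- "double"
  class(m) <- c("age_sex_table", "matrix", "array")
  m
}

#' @export
print.age_sex_table <- function(x, ...) {
  cat("<age_sex_table> ages 0-", AGE_MAX, ", sexes female/male\n", sep = "")
  sub <- unclass(x)[as.character(c(0, 25, 50, 75, 95, 105)), , drop = FALSE]
  print(sub, ...)
  invisible(x)
}

is_age_sex_table <- function(x) inherits(x, "age_sex_table")

## Subsetting an age_sex_table drops the class on purpose (plain matrix
## semantics); look-ups use ast_at().
ast_at <- function(tab, age, sex) {
  unclass(tab)[age + 1L, sex_index(sex)]
}

sex_index <- function(sex) {
  if (is.numeric(sex)) return(as.integer(sex))
  i <- match(sex, SEXES)
  if (anyNA(i)) stop("unknown sex label: ", paste(sex[is.na(i)], collapse = ", "))
  i
}

#' Convert a long data frame to an age/sex table
#'
#' Expects columns `age`, `sex`, `value` covering ages 0 up to at least
#' `min_age_required` for both sexes; ages above the last supplied age are
#' held constant at that age's value.
#'
#' @param df Data frame with columns `age`, `sex`, `value`.
#' @param what Label used in error messages (e.g. a file name).
#' @param min_age_required Largest age that must be present (default 95).
#' @return An `age_sex_table`.
#' @export
as_age_sex_table <- function(df, what = "table", min_age_required = 95L) {
  need <- c("age", "sex", "value")
  if (!all(need %in% names(df)))
    stop(what, ": columns must include ", paste(need, collapse = ", "))
  df$sex <- tolower(as.character(df$sex))
  bad <- setdiff(unique(df$sex), SEXES)
  if (length(bad))
    stop(what, ": unknown sex label(s): ", paste(bad, collapse = ", "))
  key <- paste(df$age, df$sex)
  if (anyDuplicated(key))
    stop(what, ": duplicate (age,sex) cell at ", key[duplicated(key)][1L])
  m <- matrix(NA_real_, AGE_MAX + 1L, 2L)
  m[cbind(df$age + 1L, sex_index(df$sex))] <- df$value
  for (s in 1:2) {
    col <- m[, s]
    amax <- max(which(!is.na(col))) - 1L
    if (amax < min_age_required)
      stop(what, ": ages must be supplied up to ", min_age_required,
           " (sex ", SEXES[s], " stops at ", amax, ")")
    miss <- which(is.na(col[seq_len(amax + 1L)]))
    if (length(miss))
      stop(what, ": missing cell at age ", miss[1L] - 1L, ", sex ", SEXES[s])
    if (amax < AGE_MAX) col[(amax + 2L):(AGE_MAX + 1L)] <- col[amax + 1L]
    m[, s] <- col
  }
  age_sex_table(m)
}

## Long-format data frame view (full internal grid).
ast_to_df <- function(tab) {
  data.frame(
    age = rep(0:AGE_MAX, times = 2L),
    sex = rep(SEXES, each = AGE_MAX + 1L),
    value = as.vector(unclass(tab))
  )
}

## Category-valued table: array [age 0..105, sex, category], long columns
## age, sex, category, value.
as_category_table <- function(df, categories, what = "table",
                              min_age_required = 95L) {
  need <- c("age", "sex", "category", "value")
  if (!all(need %in% names(df)))
    stop(what, ": columns must include ", paste(need, collapse = ", "))
  df$category <- as.character(df$category)
  bad <- setdiff(unique(df$category), categories)
  if (length(bad))
    stop(what, ": unknown category label(s): ", paste(bad, collapse = ", "))
  out <- array(NA_real_, c(AGE_MAX + 1L, 2L, length(categories)),
               dimnames = list(age = 0:AGE_MAX, sex = SEXES,
                               category = categories))
  for (k in seq_along(categories)) {
    sub <- df[df$category == categories[k], c("age", "sex", "value")]
    out[, , k] <- unclass(as_age_sex_table(sub,
      what = paste0(what, " [", categories[k], "]"),
      min_age_required = min_age_required))
  }
  out
}

category_table_to_df <- function(arr) {
  categories <- dimnames(arr)[[3]]
  do.call(rbind, lapply(seq_along(categories), function(k) {
    d <- ast_to_df(age_sex_table(arr[, , k]))
    d$category <- categories[k]
    d[, c("age", "sex", "category", "value")]
  }))
}
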