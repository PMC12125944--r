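#' Life tables for ages 45 to 90
#'
#' An age- and sex-indexed table of annual mortality probabilities covering
#' the model horizon (entry at 45, termination at 90). Mortality is applied
#' as a step function: the annual probability for the current year of age is
#' converted to a per-cycle (monthly) probability and held constant until the
#' next birthday.
#'
#' @param age Integer vector of contiguous ages, must cover 45..90.
#' @param q_annual Annual death probabilities in `[0, 1]`, same length.
#' @param sex One of `"general"`, `"male"`, `"female"`.
#' @return An object of class `life_table` (a data.frame with columns
#'   `age`, `sex`, `q_annual`).
#' @export
life_table <- function(age, q_annual, sex = c("general", "male", "female")) {
  sex <- match.arg(sex)
  age <- as.integer(age)
  ord <- order(age)
  age <- age[ord]; q_annual <- q_annual[ord]
  if (anyDuplicated(age)) stop("duplicate ages in life table", call. = FALSE)
  if (!identical(age, 45:90))
    stop("life table must cover contiguous ages 45..90", call. = FALSE)
  if (any(!is.finite(q_annual)) || any(q_annual < 0) || any(q_annual > 1))
    stop("annual mortality probabilities must lie in [0, 1]", call. = FALSE)
  structure(data.frame(age = age, sex = sex, q_annual = q_annual),
            class = c("life_table", "data.frame"))
}

#' Convert an annual to a monthly mortality probability
#'
#' Constant hazard within the year: `1 - (1 - q)^(1/12)`, so that twelve
#' successive monthly applications compound back to the annual probability.
#'
#' @param q_annual Annual probability in `[0, 1]` (vectorised).
#' @return Monthly probability in `[0, 1]`.
#' @export
annual_to_monthly_prob <- function(q_annual) {
  if (any(!is.finite(q_annual)) || any(q_annual < 0) || any(q_annual > 1))
    stop("q_annual must lie in [0, 1]", call. = FALSE)
  1 - (1 - q_annual)^(1 / 12)
}

#' Monthly mortality at an age in months
#'
#' Looks up the annual probability for `floor(age_months / 12)` and converts
#' it to a monthly probability; constant within each year of age.
#'
#' @param table A [life_table()].
#' @param age_months Age in months, 540..1080 (vectorised).
#' @return Monthly death probability.
#' @export
mortality_at <- function(table, age_months) {
  stopifnot(inherits(table, "life_table"))
  if (any(age_months < 540) || any(age_months > 1080))
    stop("age_months outside the table's 45-90 year range", call. = FALSE)
  yr <- pmin(age_months %/% 12L, 90L)  # month 1080 uses the age-90 row
  annual_to_monthly_prob(table$q_annual[match(yr, table$age)])
}

#' Read a life table from CSV
#'
#' Expects header `age,sex,q_annual` with one row per age 45..90 and a single
#' sex level.
#'
#' @param path CSV path.
#' @return A [life_table()].
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "sex", "q_annual")
  if (!all(need %in% names(df)))
    stop("life table CSV must have columns age, sex, q_annual", call. = FALSE)
  bad <- which(!is.finite(df$q_annual) | df$q_annual < 0 | df$q_annual > 1)
  if (length(bad))
    stop("invalid q_annual at line ", bad[1L] + 1L, " of ", path, call. = FALSE)
  sexes <- unique(df$sex)
  if (length(sexes) != 1L)
    stop("life table CSV must contain a single sex level, found: ",
         paste(sexes, collapse = ", "), call. = FALSE)
  miss <- setdiff(45:90, df$age)
  if (length(miss))
    stop("life table missing age(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  life_table(df$age, df$q_annual, sex = sexes)
}

#' Write a life table to CSV
#'
#' @param table A [life_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(table, path) {
  stopifnot(inherits(table, "life_table"))
  utils::write.csv(as.data.frame(table)[, c("age", "sex", "q_annual")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Cumulative probability of surviving each of the 540 monthly cycles from
# age 45, given a life table. Element t is survival to the end of cycle t.
monthly_survival_curve <- function(table, cycles = 540L,
                                   start_age_months = 540L) {
  m <- mortality_at(table, start_age_months + seq_len(cycles) - 1L)
  cumprod(1 - m)
}
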