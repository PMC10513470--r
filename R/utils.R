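# Internal helpers shared across modules.

# Age grid: single years 0..99 plus an open 100+ accumulator, and the two
# sexes every schedule is disaggregated by.
.ages <- 0:100
.n_ages <- 101L
.sexes <- c("male", "female")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (commercial "half-up" rounding), unlike [base::round()] which rounds
#' half to even. Used for all printed report percentages and counts.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(2.5)        # 3, where round(2.5) gives 2
#' round_half_up(6.6661, 1)  # 6.7
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small guard against representation error just below an exact .5
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Build an age x sex matrix (101 x 2, dimnames age/sex) from a long data
# frame with columns age, sex and `value_col`.
.df_to_age_sex_matrix <- function(df, value_col) {
  need <- c("age", "sex", value_col)
  if (!all(need %in% names(df))) {
    stopf("expected columns %s", paste(need, collapse = ", "))
  }
  m <- matrix(NA_real_, .n_ages, 2L, dimnames = list(age = .ages, sex = .sexes))
  age_i <- match(df$age, .ages)
  sex_i <- match(df$sex, .sexes)
  if (anyNA(age_i) || anyNA(sex_i)) {
    stopf("ages must be 0..100 and sex one of %s", paste(.sexes, collapse = "/"))
  }
  m[cbind(age_i, sex_i)] <- df[[value_col]]
  if (anyNA(m)) stopf("'%s' must be defined for every (age, sex) cell", value_col)
  m
}

.check_age_sex_matrix <- function(m, what) {
  if (!is.matrix(m) || nrow(m) != .n_ages || ncol(m) != 2L) {
    stopf("'%s' must be a %d x 2 (age x sex) matrix", what, .n_ages)
  }
  if (is.null(dimnames(m))) {
    dimnames(m) <- list(age = .ages, sex = .sexes)
  }
  if (anyNA(m) || any(!is.finite(m))) stopf("'%s' contains missing values", what)
  m
}
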