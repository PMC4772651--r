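#' Observation-weighted age-specific fertility
#'
#' Estimates the expected number of daughters per female per year in each
#' age class. For each female, observed live births in a class are
#' multiplied by her observation fraction for that class; these products
#' are summed over females and divided by the sum of the fractions (the
#' weight sum `N_m`). Because newborns of both sexes — including those that
#' died before sexing — enter the numerator, the total is halved under an
#' assumed 50:50 birth sex ratio to give daughters per female.
#'
#' @param fc a `fertility_counts` object from [tabulate_fertility()].
#' @return A list with `m` (daughters per female per year; 0 where no
#'   female-years were observed) and `N_m` (the weight-sum sample sizes).
#' @export
age_specific_fertility <- function(fc) {
  ws <- fc$weight_sum
  m <- ifelse(ws > 0, (fc$weighted_births / ws) / 2, 0)
  m[ws <= 0] <- 0
  list(m = as.numeric(m), N_m = as.numeric(ws))
}

#' Birth sex ratio with exact binomial confidence interval
#'
#' Proportion female among offspring born into the study whose sex was
#' determined; offspring of unknown sex are excluded. The confidence
#' interval is the exact (Clopper–Pearson) binomial interval, which remains
#' valid at the small sample sizes typical of field studies.
#'
#' @param records a [census_records] object.
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `sex_ratio_summary` with `n_sexed`,
#'   `prop_female`, `ci_low`, `ci_high`, `conf_level`.
#' @export
sex_ratio <- function(records, conf_level = 0.95) {
  sexed <- records$births$offspring_sex[records$births$offspring_sex %in% c("F", "M")]
  n <- length(sexed)
  if (n == 0L) stop_invalid("no sexed offspring: sex ratio is undefined")
  nf <- sum(sexed == "F")
  ci <- stats::binom.test(nf, n, conf.level = conf_level)$conf.int
  structure(list(n_sexed = n, prop_female = nf / n,
                 ci_low = ci[1], ci_high = ci[2], conf_level = conf_level),
            class = "sex_ratio_summary")
}

#' @export
print.sex_ratio_summary <- function(x, ...) {
  cat(sprintf("Birth sex ratio: %.3f female (n = %d sexed; %d%% CI %.3f-%.3f)\n",
              x$prop_female, x$n_sexed, round(100 * x$conf_level),
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Offspring sex by mother's age
#'
#' Weighted per-age probabilities of producing a son or a daughter: the
#' weighted number of sexed sons (daughters) divided by the weighted number
#' of mothers. Offspring that died before their sex could be determined are
#' necessarily excluded here (though not from the fertility schedule).
#'
#' @param fc a `fertility_counts` object.
#' @return data.frame with columns `age`, `p_son`, `p_daughter`,
#'   `n_mothers`, one row per age class with a positive weight sum.
#' @export
offspring_sex_by_mother_age <- function(fc) {
  keep <- fc$weight_sum > 0
  data.frame(
    age = (seq_len(fc$n_classes) - 1L)[keep],
    p_son = fc$weighted_sons[keep] / fc$weight_sum[keep],
    p_daughter = fc$weighted_daughters[keep] / fc$weight_sum[keep],
    n_mothers = fc$n_mothers[keep]
  )
}

#' Age at first reproduction
#'
#' For every female with at least one observed birth, her age at first
#' reproduction is the youngest age class in which she gave birth. The
#' median and quartiles use linear interpolation of order statistics
#' (`stats::quantile` type 7).
#'
#' @param records a [census_records] object.
#' @param known_age_only if `TRUE`, restrict to females of exactly known
#'   age (born into the study, `entry_age == 0`), excluding females whose
#'   ages were estimated at entry.
#' @return An object of class `afr_distribution` with the per-female ages,
#'   their `median`, and quartiles `q1`, `q3`.
#' @export
age_first_reproduction <- function(records, known_age_only = FALSE) {
  b <- records$births
  if (known_age_only) {
    ind <- records$individuals
    known <- ind$id[ind$entry_age == 0L]
    b <- b[b$mother_id %in% known, , drop = FALSE]
  }
  if (!nrow(b)) stop_invalid("no reproducing females: age at first ",
                             "reproduction is undefined")
  afr <- tapply(b$mother_age, b$mother_id, min)
  ages <- as.numeric(afr)
  structure(list(ages = ages,
                 n = length(ages),
                 median = pct(ages, 0.5),
                 q1 = pct(ages, 0.25),
                 q3 = pct(ages, 0.75)),
            class = "afr_distribution")
}

#' @export
print.afr_distribution <- function(x, ...) {
  cat(sprintf("Age at first reproduction: median %.1f (IQR %.1f-%.1f, n = %d females)\n",
              x$median, x$q1, x$q3, x$n))
  invisible(x)
}
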