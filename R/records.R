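#' Individual-based census records
#'
#' Container for one monitoring study's individual histories, held in a
#' relational layout: one row per individual, one row per observed birth
#' event, and one row per female-by-age observation fraction.
#'
#' @param individuals data.frame with columns `id` (unique identifier),
#'   `sex` (`"F"`, `"M"` or `"unknown"`), `entry_age` (integer age class at
#'   first contact; 0 means born into the study), `exit_age` (integer age
#'   class at last contact), and `fate` (one of `"death"`,
#'   `"permanent_disappearance"`, `"censored"`).
#' @param births data.frame with columns `mother_id`, `mother_age` (the
#'   mother's age class when the birth was observed) and `offspring_sex`
#'   (`"F"`, `"M"` or `"unknown"`). May have zero rows.
#' @param obs data.frame with columns `id`, `age`, `fraction`: the fraction
#'   of age interval `age` during which the (female) individual was under
#'   intensive fertility observation. Any female-by-age combination absent
#'   from this table has fraction 1 (full observation). May have zero rows.
#'
#' @details Age classes are half-open one-year intervals `[x, x + 1)`
#'   indexed by the integer `x`, with class 0 the first year of life.
#'   An individual with `entry_age = e` and `exit_age = x` was at risk in
#'   classes `e, ..., x` and met its fate during class `x`.
#'
#' @return An object of class `census_records`.
#' @export
census_records <- function(individuals,
                           births = data.frame(mother_id = integer(),
                                               mother_age = integer(),
                                               offspring_sex = character()),
                           obs = data.frame(id = integer(),
                                            age = integer(),
                                            fraction = double())) {
  need <- c("id", "sex", "entry_age", "exit_age", "fate")
  if (!is.data.frame(individuals) || !all(need %in% names(individuals))) {
    stop_invalid("`individuals` must be a data.frame with columns ",
                 paste(need, collapse = ", "))
  }
  individuals <- as.data.frame(individuals)[need]
  births <- as.data.frame(births)[c("mother_id", "mother_age", "offspring_sex")]
  obs <- as.data.frame(obs)[c("id", "age", "fraction")]
  rownames(individuals) <- rownames(births) <- rownames(obs) <- NULL

  if (anyDuplicated(individuals$id)) {
    stop_invalid("duplicated individual ids")
  }
  if (!all(individuals$sex %in% c("F", "M", "unknown"))) {
    stop_invalid("`sex` must be one of \"F\", \"M\", \"unknown\"")
  }
  if (!all(individuals$fate %in% c("death", "permanent_disappearance", "censored"))) {
    stop_invalid("`fate` must be one of \"death\", \"permanent_disappearance\", \"censored\"")
  }
  check_nonneg(individuals$entry_age, "entry_age", integerish = TRUE)
  check_nonneg(individuals$exit_age, "exit_age", integerish = TRUE)
  bad <- individuals$exit_age < individuals$entry_age
  if (any(bad)) {
    stop_invalid("exit_age < entry_age for id(s): ",
                 paste(utils::head(individuals$id[bad], 5), collapse = ", "))
  }

  if (nrow(births)) {
    i <- match(births$mother_id, individuals$id)
    if (anyNA(i)) stop_invalid("birth event with unknown mother_id")
    if (!all(individuals$sex[i] == "F")) {
      stop_invalid("birth events are only allowed for female individuals")
    }
    check_nonneg(births$mother_age, "mother_age", integerish = TRUE)
    outside <- births$mother_age < individuals$entry_age[i] |
      births$mother_age > individuals$exit_age[i]
    if (any(outside)) {
      stop_invalid("birth event outside the mother's [entry_age, exit_age] ",
                   "for mother id(s): ",
                   paste(utils::head(unique(births$mother_id[outside]), 5),
                         collapse = ", "))
    }
    if (!all(births$offspring_sex %in% c("F", "M", "unknown"))) {
      stop_invalid("`offspring_sex` must be one of \"F\", \"M\", \"unknown\"")
    }
  }

  if (nrow(obs)) {
    i <- match(obs$id, individuals$id)
    if (anyNA(i)) stop_invalid("observation fraction for unknown id")
    check_prob(obs$fraction, "fraction")
    check_nonneg(obs$age, "obs age", integerish = TRUE)
  }

  structure(list(individuals = individuals, births = births, obs = obs),
            class = "census_records")
}

#' @export
print.census_records <- function(x, ...) {
  n <- nrow(x$individuals)
  tab <- table(factor(x$individuals$sex, levels = c("F", "M", "unknown")))
  cat("Census records:", n, "individuals",
      sprintf("(%d F, %d M, %d unknown)", tab[["F"]], tab[["M"]], tab[["unknown"]]),
      "\n")
  cat("  ", nrow(x$births), "observed birth events;",
      nrow(x$obs), "non-default observation fractions\n")
  cat("  fates:", paste(names(table(x$individuals$fate)),
                        table(x$individuals$fate), collapse = ", "), "\n")
  invisible(x)
}

# look up observation-fraction weights for (id, age) pairs; default 1
obs_weight <- function(records, id, age) {
  w <- rep(1, length(id))
  if (nrow(records$obs)) {
    key <- paste(id, age)
    i <- match(key, paste(records$obs$id, records$obs$age))
    hit <- !is.na(i)
    w[hit] <- records$obs$fraction[i[hit]]
  }
  w
}
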