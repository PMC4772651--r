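#' Configuration for the census-study simulator
#'
#' Assembles and validates the parameters of a simulated individual-based
#' monitoring study with known demographic truth.
#'
#' @param true_q numeric vector of per-age-class death probabilities, one
#'   entry per age class `0..max_age`.
#' @param true_m numeric vector of expected daughters per female per year,
#'   same length as `true_q`. Total birth counts are Poisson with mean
#'   `2 * true_m[x]` per female-year (sons plus daughters under the assumed
#'   birth sex ratio).
#' @param n_births number of newborns founding the study population in
#'   study year 0.
#' @param sex_ratio_female probability that a newborn is female (default 0.5).
#' @param n_immigrants number of immigrants entering the population at ages
#'   drawn from `immigrant_age_probs`, in uniformly chosen study years.
#' @param immigrant_age_probs numeric vector of categorical weights over
#'   entry age classes `0..max_age` (required when `n_immigrants > 0`;
#'   normalised internally).
#' @param annual_censor_prob per-year probability that a live individual is
#'   right-censored (known emigration or other end of observation).
#' @param annual_disappear_prob per-year probability of permanent
#'   disappearance with ambiguous fate. Either a single value or a named
#'   vector `c(F = , M = )` to mimic sex-biased dispersal.
#' @param obs_fraction_law distribution of the per-female, per-age-class
#'   fertility-observation fraction: `NULL` (full observation, fraction 1),
#'   or a list with `dist = "fixed"` (`value`), `dist = "uniform"`
#'   (`min`, `max`) or `dist = "beta"` (`shape1`, `shape2`).
#' @param unsexed_infant_prob probability that an offspring dying in its
#'   first age class is recorded with unknown sex (it died before its sex
#'   could be determined).
#' @param max_age oldest age class; survivors of class `max_age` are
#'   right-censored there. Defaults to `length(true_q) - 1`.
#' @param study_years length of the study window in years (default
#'   `max_age + 1`, so the founding cohort can be followed over its whole
#'   lifespan). Individuals alive when the study ends are right-censored.
#' @param seed integer seed; simulations are fully reproducible given the
#'   configuration.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_population()], [true_life_table()], [reference_schedule()]
#' @export
sim_config <- function(true_q, true_m, n_births,
                       sex_ratio_female = 0.5,
                       n_immigrants = 0L,
                       immigrant_age_probs = NULL,
                       annual_censor_prob = 0,
                       annual_disappear_prob = 0,
                       obs_fraction_law = NULL,
                       unsexed_infant_prob = 0,
                       max_age = length(true_q) - 1L,
                       study_years = max_age + 1L,
                       seed = 1L) {
  max_age <- check_scalar_count(max_age, "max_age", min = 0L)
  check_prob(true_q, "true_q", len = max_age + 1L)
  check_nonneg(true_m, "true_m", len = max_age + 1L)
  check_prob(sex_ratio_female, "sex_ratio_female", len = 1L)
  n_births <- check_scalar_count(n_births, "n_births", min = 1L)
  n_immigrants <- check_scalar_count(n_immigrants, "n_immigrants", min = 0L)
  check_prob(annual_censor_prob, "annual_censor_prob", len = 1L)
  check_prob(unsexed_infant_prob, "unsexed_infant_prob", len = 1L)
  study_years <- check_scalar_count(study_years, "study_years", min = 1L)
  seed <- check_scalar_count(seed, "seed", min = 0L)

  if (length(annual_disappear_prob) == 1L && is.null(names(annual_disappear_prob))) {
    annual_disappear_prob <- c(F = unname(annual_disappear_prob),
                               M = unname(annual_disappear_prob))
  }
  if (!all(c("F", "M") %in% names(annual_disappear_prob))) {
    stop_invalid("`annual_disappear_prob` must be a single value or named c(F = , M = )")
  }
  annual_disappear_prob <- annual_disappear_prob[c("F", "M")]
  check_prob(annual_disappear_prob, "annual_disappear_prob")

  if (n_immigrants > 0L) {
    if (is.null(immigrant_age_probs)) {
      stop_invalid("`immigrant_age_probs` is required when n_immigrants > 0")
    }
    check_nonneg(immigrant_age_probs, "immigrant_age_probs")
    if (length(immigrant_age_probs) > max_age + 1L || sum(immigrant_age_probs) <= 0) {
      stop_invalid("`immigrant_age_probs` must have positive mass on ages 0..max_age")
    }
    immigrant_age_probs <- immigrant_age_probs / sum(immigrant_age_probs)
  }

  if (!is.null(obs_fraction_law)) {
    if (!is.list(obs_fraction_law) ||
        !obs_fraction_law$dist %in% c("fixed", "uniform", "beta")) {
      stop_invalid("`obs_fraction_law` must be NULL or a list with dist in ",
                   "\"fixed\", \"uniform\", \"beta\"")
    }
    if (obs_fraction_law$dist == "fixed") {
      check_prob(obs_fraction_law$value, "obs_fraction_law$value", len = 1L)
    }
    if (obs_fraction_law$dist == "uniform") {
      check_prob(c(obs_fraction_law$min, obs_fraction_law$max),
                 "obs_fraction_law min/max", len = 2L)
      if (obs_fraction_law$min > obs_fraction_law$max) {
        stop_invalid("obs_fraction_law: min > max")
      }
    }
    if (obs_fraction_law$dist == "beta") {
      check_nonneg(c(obs_fraction_law$shape1, obs_fraction_law$shape2),
                   "obs_fraction_law shapes", len = 2L)
    }
  }

  structure(list(
    true_q = as.numeric(true_q),
    true_m = as.numeric(true_m),
    n_births = n_births,
    sex_ratio_female = sex_ratio_female,
    n_immigrants = n_immigrants,
    immigrant_age_probs = immigrant_age_probs,
    annual_censor_prob = annual_censor_prob,
    annual_disappear_prob = annual_disappear_prob,
    obs_fraction_law = obs_fraction_law,
    unsexed_infant_prob = unsexed_infant_prob,
    max_age = max_age,
    study_years = study_years,
    seed = seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$max_age + 1, "age classes,",
      x$n_births, "founding births,", x$n_immigrants, "immigrants,",
      x$study_years, "study years, seed", x$seed, "\n")
  invisible(x)
}

draw_obs <- function(law, n) {
  if (is.null(law)) return(rep(1, n))
  switch(law$dist,
         fixed = rep(law$value, n),
         uniform = stats::runif(n, law$min, law$max),
         beta = stats::rbeta(n, law$shape1, law$shape2))
}

#' Simulate an individual-based census study
#'
#' Generates individual histories from a known demographic schedule by
#' stepping a population through a fixed study window of calendar years.
#' Each year every individual of age class `x` faces, in order, a death
#' hazard `true_q[x]`, a permanent-disappearance hazard, and a censoring
#' hazard; survivors of the oldest class are right-censored. Every female
#' present in an age class draws a Poisson number of newborns with mean
#' `2 * true_m[x]`; observed births (after thinning by her observation
#' fraction for that class) become new individual records that are
#' themselves followed — so daughters born early in the study reproduce
#' within it, as in a real monitored population.
#'
#' Individuals still alive at the end of the study window are
#' right-censored. Because events are resolved at whole age-class
#' granularity, an end-of-study censoring falls exactly on a class
#' boundary; to honour the half-interval assumption used by the actuarial
#' mortality estimator, each such individual is recorded (with equal
#' probability) either as censored in its last fully observed class or as
#' censored on entry to the next class with observation fraction 0.
#'
#' @param config a [sim_config()] object.
#' @return A [census_records] object. Deterministic given `config`
#'   (including its `seed`).
#' @examples
#' sched <- reference_schedule()
#' cfg <- sim_config(true_q = sched$q, true_m = sched$m,
#'                   n_births = 200, seed = 42)
#' simulate_population(cfg)
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, unclass(config))
  }
  set.seed(config$seed)
  A <- config$max_age
  Tw <- config$study_years
  q <- config$true_q
  m2 <- 2 * config$true_m
  pdis <- config$annual_disappear_prob
  pc <- config$annual_censor_prob
  law <- config$obs_fraction_law

  # individual state (parallel vectors; id == position)
  sex <- character(0)
  byear <- integer(0)   # calendar year of birth (entry year - entry age)
  entry <- integer(0)
  exit <- integer(0)
  fate <- character(0)
  alive <- logical(0)
  last_proc <- integer(0)

  # birth-event log (child kept internally to allow later sex masking)
  b_mother <- integer(0); b_age <- integer(0); b_child <- integer(0)
  # observation-fraction log
  o_id <- integer(0); o_age <- integer(0); o_frac <- double(0)

  add_individuals <- function(n, sexes, byr, ent) {
    start <- length(sex)
    sex <<- c(sex, sexes)
    byear <<- c(byear, rep_len(byr, n))
    entry <<- c(entry, rep_len(ent, n))
    exit <<- c(exit, rep(NA_integer_, n))
    fate <<- c(fate, rep(NA_character_, n))
    alive <<- c(alive, rep(TRUE, n))
    last_proc <<- c(last_proc, rep(-1L, n))
    start + seq_len(n)
  }

  # founders: newborn cohort in study year 0
  n0 <- config$n_births
  add_individuals(n0,
                  ifelse(stats::runif(n0) < config$sex_ratio_female, "F", "M"),
                  byr = 0L, ent = 0L)
  # immigrants: entry ages from the stated categorical law, uniform entry years
  if (config$n_immigrants > 0L) {
    ni <- config$n_immigrants
    ia <- sample.int(length(config$immigrant_age_probs), ni, replace = TRUE,
                     prob = config$immigrant_age_probs) - 1L
    iy <- sample.int(Tw, ni, replace = TRUE) - 1L
    add_individuals(ni,
                    ifelse(stats::runif(ni) < config$sex_ratio_female, "F", "M"),
                    byr = iy - ia, ent = ia)
    # store entry ages individually (add_individuals recycles)
    entry[(n0 + 1L):(n0 + ni)] <- ia
    byear[(n0 + 1L):(n0 + ni)] <- iy - ia
  }

  for (t in 0:(Tw - 1L)) {
    repeat {
      idx <- which(alive & last_proc < t & (byear + entry) <= t)
      if (!length(idx)) break
      last_proc[idx] <- t
      age <- t - byear[idx]
      n <- length(idx)

      # yearly hazards, fixed order: death -> disappearance -> censoring
      die <- stats::runif(n) < q[age + 1L]
      dis <- !die & stats::runif(n) < pdis[sex[idx]]
      cen <- !die & !dis & stats::runif(n) < pc
      cap <- !die & !dis & !cen & age == A   # oldest class: survivors censored
      gone <- die | dis | cen | cap
      exit[idx[gone]] <- age[gone]
      fate[idx[die]] <- "death"
      fate[idx[dis]] <- "permanent_disappearance"
      fate[idx[cen | cap]] <- "censored"
      alive[idx[gone]] <- FALSE

      # births: every female present in the class this year draws offspring
      isf <- sex[idx] == "F"
      if (any(isf)) {
        fem <- idx[isf]
        fage <- age[isf]
        frac <- draw_obs(law, length(fem))
        if (!is.null(law)) {
          o_id <- c(o_id, fem); o_age <- c(o_age, fage); o_frac <- c(o_frac, frac)
        }
        nb <- stats::rpois(length(fem), m2[fage + 1L])
        kb <- if (is.null(law)) nb else stats::rbinom(length(fem), nb, frac)
        tot <- sum(kb)
        if (tot > 0L) {
          moms <- rep(fem, kb)
          mage <- rep(fage, kb)
          csex <- ifelse(stats::runif(tot) < config$sex_ratio_female, "F", "M")
          kids <- add_individuals(tot, csex, byr = t, ent = 0L)
          b_mother <- c(b_mother, moms)
          b_age <- c(b_age, mage)
          b_child <- c(b_child, kids)
        }
      }
    }
  }

  # end of study: boundary censoring with the half-interval split
  rem <- which(alive)
  if (length(rem)) {
    lastc <- Tw - 1L - byear[rem]          # last fully observed class
    heads <- stats::runif(length(rem)) < 0.5
    exit[rem] <- ifelse(heads, lastc, lastc + 1L)
    fate[rem] <- "censored"
    alive[rem] <- FALSE
    tails_f <- rem[!heads & sex[rem] == "F"]
    if (length(tails_f)) {
      o_id <- c(o_id, tails_f)
      o_age <- c(o_age, (Tw - byear[tails_f]))
      o_frac <- c(o_frac, rep(0, length(tails_f)))
    }
  }

  # infants that died before their sex could be determined
  if (config$unsexed_infant_prob > 0 && length(b_child)) {
    died0 <- b_child[exit[b_child] == 0L & fate[b_child] == "death"]
    if (length(died0)) {
      mask <- died0[stats::runif(length(died0)) < config$unsexed_infant_prob]
      sex[mask] <- "unknown"
    }
  }

  individuals <- data.frame(
    id = seq_along(sex), sex = sex,
    entry_age = entry, exit_age = exit, fate = fate,
    stringsAsFactors = FALSE
  )
  births <- data.frame(
    mother_id = b_mother, mother_age = b_age,
    offspring_sex = sex[b_child],
    stringsAsFactors = FALSE
  )
  obs <- data.frame(id = o_id, age = o_age, fraction = o_frac)
  census_records(individuals, births, obs)
}

#' Ground-truth life table of a simulation configuration
#'
#' Converts a simulator configuration into the life table implied by its
#' mortality and fertility schedules, for use as the known truth in
#' parameter-recovery and coverage experiments.
#'
#' @param config a [sim_config()] object.
#' @return A [life_table] object with `q = true_q`, `m = true_m`,
#'   survivorship from the product-of-survival identity, and
#'   `omega = max_age`.
#' @export
true_life_table <- function(config) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, unclass(config))
  }
  A <- config$max_age
  l <- survivorship(config$true_q)[seq_len(A + 1L)]
  new_life_table(q = config$true_q, l = l, m = config$true_m,
                 omega = A, sex = "F")
}
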