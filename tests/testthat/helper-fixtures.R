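# shared fixture builders: tiny hand-made record sets, random life tables
# and random count tables used across the suite

make_records <- function(individuals, births = NULL, obs = NULL) {
  if (is.null(births)) {
    births <- data.frame(mother_id = integer(), mother_age = integer(),
                         offspring_sex = character())
  }
  if (is.null(obs)) {
    obs <- data.frame(id = integer(), age = integer(), fraction = double())
  }
  census_records(individuals, births, obs)
}

one_individual <- function(id = 1L, sex = "F", entry = 0L, exit = 3L,
                           fate = "death") {
  data.frame(id = id, sex = sex, entry_age = entry, exit_age = exit,
             fate = fate)
}

# a random life table with fertility, valid for Leslie analysis:
# q in (0, 0.9] with a fatal final class, m positive at some ages
random_life_table <- function(n_classes = 10L) {
  q <- c(stats::runif(n_classes - 1L, 0.02, 0.5), 1)
  l <- survivorship(q)[seq_len(n_classes)]
  m <- stats::runif(n_classes, 0, 0.8) * (stats::runif(n_classes) < 0.7)
  if (all(m == 0)) m[n_classes] <- 0.5
  new_life_table(q = q, l = l, m = m, omega = n_classes - 1L, sex = "F")
}

# random cohort of individuals entering at age 0 with no censoring: each
# dies in some class; returns the records and the death-age vector
random_uncensored_cohort <- function(n = 50L, n_classes = 6L) {
  death_age <- sample.int(n_classes, n, replace = TRUE) - 1L
  rec <- make_records(data.frame(
    id = seq_len(n), sex = "F", entry_age = 0L, exit_age = death_age,
    fate = "death"))
  list(records = rec, death_age = death_age)
}

default_sim_config <- function(n_births = 500, seed = 42, ...) {
  s <- reference_schedule()
  sim_config(true_q = s$q, true_m = s$m, n_births = n_births, seed = seed, ...)
}
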