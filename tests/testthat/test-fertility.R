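test_that("fertility halves the all-offspring rate", {
  fc <- structure(list(weighted_births = c(0, 1.5), weight_sum = c(2, 1.5),
                       weighted_sons = c(0, 0.5), weighted_daughters = c(0, 1),
                       n_mothers = c(2, 2), n_classes = 2L),
                  class = "fertility_counts")
  fert <- age_specific_fertility(fc)
  expect_equal(fert$m, c(0, 0.5))
  expect_equal(fert$N_m, c(2, 1.5))
  # halving holds identically for arbitrary inputs
  set.seed(4)
  for (rep in 1:20) {
    ws <- stats::runif(6, 0.5, 10)
    wb <- stats::runif(6, 0, 20)
    fc2 <- structure(list(weighted_births = wb, weight_sum = ws,
                          weighted_sons = wb / 2, weighted_daughters = wb / 2,
                          n_mothers = ceiling(ws), n_classes = 6L),
                     class = "fertility_counts")
    expect_equal(age_specific_fertility(fc2)$m, (wb / ws) / 2)
  }
})

test_that("classes with no observed female-years get zero fertility", {
  fc <- structure(list(weighted_births = c(0, 0, 2), weight_sum = c(0, 4, 4),
                       weighted_sons = c(0, 0, 1), weighted_daughters = c(0, 0, 1),
                       n_mothers = c(0, 4, 4), n_classes = 3L),
                  class = "fertility_counts")
  expect_equal(age_specific_fertility(fc)$m, c(0, 0, 0.25))
})

test_that("constant weights give the unweighted estimator", {
  ind <- data.frame(id = 1:4, sex = "F", entry_age = 0L, exit_age = 3L,
                    fate = "censored")
  births <- data.frame(mother_id = c(1L, 1L, 2L, 3L), mother_age = c(2L, 3L, 2L, 3L),
                       offspring_sex = c("F", "M", "F", "F"))
  for (k in c(0.25, 1)) {
    obs <- expand.grid(id = 1:4, age = 0:3)
    obs$fraction <- k
    fc <- tabulate_fertility(make_records(ind, births, obs))
    expect_equal(age_specific_fertility(fc)$m, c(0, 0, 2 / 4, 2 / 4) / 2)
  }
})

test_that("sex ratio uses exact binomial intervals on sexed offspring only", {
  ind <- data.frame(id = 1L, sex = "F", entry_age = 0L, exit_age = 5L,
                    fate = "censored")
  births <- data.frame(mother_id = rep(1L, 100),
                       mother_age = rep(3L, 100),
                       offspring_sex = c(rep("F", 50), rep("M", 50)))
  sr <- sex_ratio(make_records(ind, births))
  expect_equal(sr$prop_female, 0.5)
  expect_equal(sr$n_sexed, 100)
  expect_equal(sr$ci_low, 1 - sr$ci_high, tolerance = 1e-10)
  expect_equal(c(sr$ci_low, sr$ci_high),
               as.numeric(stats::binom.test(50, 100)$conf.int))

  births0 <- data.frame(mother_id = rep(1L, 12), mother_age = rep(3L, 12),
                        offspring_sex = c(rep("M", 10), rep("unknown", 2)))
  sr0 <- sex_ratio(make_records(ind, births0))
  expect_equal(sr0$prop_female, 0)
  expect_equal(sr0$ci_low, 0)
  expect_equal(sr0$n_sexed, 10)

  bu <- data.frame(mother_id = 1L, mother_age = 3L, offspring_sex = "unknown")
  expect_error(sex_ratio(make_records(ind, bu)), "undefined")
})

test_that("sex-ratio interval covers the truth at the nominal rate", {
  hits <- 0L
  for (i in 1:60) {
    rec <- simulate_population(default_sim_config(n_births = 700, seed = 400 + i))
    sr <- sex_ratio(rec)
    expect_gt(sr$n_sexed, 500)
    hits <- hits + (sr$ci_low <= 0.5 && 0.5 <= sr$ci_high)
  }
  expect_gte(hits, 54)  # >= 90% empirical coverage
})

test_that("offspring sex by mother age divides weighted counts by weight sums", {
  fc <- structure(list(weighted_births = c(0, 2.5), weight_sum = c(0, 2),
                       weighted_sons = c(0, 1), weighted_daughters = c(0, 1),
                       n_mothers = c(0, 3), n_classes = 2L),
                  class = "fertility_counts")
  tab <- offspring_sex_by_mother_age(fc)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$p_son, 0.5)
  expect_equal(tab$p_daughter, 0.5)

  rec <- simulate_population(default_sim_config(n_births = 600, seed = 13,
                                                unsexed_infant_prob = 0.3))
  fc2 <- tabulate_fertility(rec)
  tab2 <- offspring_sex_by_mother_age(fc2)
  all_rate <- (fc2$weighted_births / fc2$weight_sum)[fc2$weight_sum > 0]
  expect_true(all(tab2$p_son + tab2$p_daughter <= all_rate + 1e-9))
})

test_that("age at first reproduction is the minimum birth age per female", {
  ind <- rbind(one_individual(1L, "F", 0L, 8L, "censored"),
               one_individual(2L, "F", 0L, 8L, "censored"))
  births <- data.frame(mother_id = c(1L, 1L, 2L), mother_age = c(5L, 7L, 6L),
                       offspring_sex = rep("F", 3))
  afr <- age_first_reproduction(make_records(ind, births))
  expect_equal(sort(afr$ages), c(5, 6))
  expect_equal(afr$median, 5.5)
  # invariant to additional later births
  births2 <- rbind(births, data.frame(mother_id = 2L, mother_age = 8L,
                                      offspring_sex = "M"))
  expect_equal(age_first_reproduction(make_records(ind, births2))$median, 5.5)

  expect_error(age_first_reproduction(make_records(ind)), "undefined")
})

test_that("simulated first reproduction respects the maturity age", {
  s <- reference_schedule()
  maturity <- min(which(s$m > 0)) - 1L
  rec <- simulate_population(default_sim_config(n_births = 500, seed = 14))
  afr <- age_first_reproduction(rec)
  expect_gte(min(afr$ages), maturity)
  # the known-age filter keeps a subset
  afr_known <- age_first_reproduction(rec, known_age_only = TRUE)
  expect_lte(afr_known$n, afr$n)
})
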