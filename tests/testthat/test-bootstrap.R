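# a small but fully specified female life table for bootstrap tests
boot_table <- function(scale = 1) {
  q <- c(0.3, 0.2, 1)
  new_life_table(q = q, l = survivorship(q)[1:3], m = c(0, 0.6, 0.4),
                 N_q = c(50, 30, 20) * scale, N_m = c(40, 28, 15) * scale,
                 omega = 2L, sex = "F")
}

test_that("mortality resampling has binomial moments on ceiled denominators", {
  set.seed(201)
  n_draw <- 10000
  q_hat <- c(0.3, 0.05)
  N_q <- c(19.2, 40)   # ceils to 20 and 40
  draws <- t(replicate(n_draw, sample_mortality(q_hat, N_q)))
  # every draw is a multiple of 1/ceil(N_q)
  expect_true(all(abs(draws[, 1] * 20 - round(draws[, 1] * 20)) < 1e-12))
  expect_true(all(abs(draws[, 2] * 40 - round(draws[, 2] * 40)) < 1e-12))
  for (j in 1:2) {
    n <- ceiling(N_q)[j]
    mu <- q_hat[j]
    v <- mu * (1 - mu) / n
    expect_lt(abs(mean(draws[, j]) - mu), 4 * sqrt(v / n_draw))
    expect_lt(abs(stats::var(draws[, j]) - v), 0.2 * v)
  }
  # deterministic endpoints and NA propagation
  expect_equal(sample_mortality(c(0, 1), c(10, 10)), c(0, 1))
  expect_equal(sample_mortality(c(NA, 0.5), c(10, 0)), c(NA_real_, NA_real_))
  expect_error(sample_mortality(1.2, 10), "\\[0, 1\\]")
})

test_that("fertility resampling has Poisson moments on ceiled denominators", {
  set.seed(202)
  n_draw <- 10000
  m_hat <- c(0.4, 0)
  N_m <- c(24.1, 10)   # ceils to 25 and 10
  draws <- t(replicate(n_draw, sample_fertility(m_hat, N_m)))
  expect_true(all(draws[, 2] == 0))
  expect_true(all(abs(draws[, 1] * 25 - round(draws[, 1] * 25)) < 1e-12))
  mu <- m_hat[1]
  v <- mu / 25          # Var(Pois(25 * m) / 25)
  expect_lt(abs(mean(draws[, 1]) - mu), 4 * sqrt(v / n_draw))
  expect_lt(abs(stats::var(draws[, 1]) - v), 0.2 * v)
  # zero weight sum gives zero fertility, not NA
  expect_equal(sample_fertility(c(0.5, 0.5), c(0, 4))[1], 0)
  expect_error(sample_fertility(-0.1, 5), "non-negative")
})

test_that("the envelope stores every replicate and its own percentiles", {
  env <- bootstrap_ci(boot_table(), n_reps = 200, seed = 7)
  expect_s3_class(env, "bootstrap_envelope")
  expect_equal(env$n_reps, 200L)
  expect_length(env$replicates$R0, 200)
  expect_length(env$replicates$lambda, 200)
  for (nm in c("l", "m", "w", "v", "e")) {
    expect_equal(dim(env$replicates[[nm]]), c(200L, 3L))
  }
  # reported limits are the type-7 percentiles of the stored replicates
  expect_equal(env$estimates$statistic, c("R0", "G", "lambda"))
  expect_equal(env$estimates$lower[1],
               unname(stats::quantile(env$replicates$R0, 0.025, type = 7)))
  expect_equal(env$estimates$upper[3],
               unname(stats::quantile(env$replicates$lambda, 0.975, type = 7,
                                      na.rm = TRUE)))
  le <- env$ages$l
  expect_equal(le$lower,
               apply(env$replicates$l, 2, stats::quantile, 0.025, type = 7,
                     na.rm = TRUE),
               ignore_attr = TRUE)
  # point estimates pass through unchanged
  point <- demographic_summary(boot_table())
  expect_equal(env$estimates$estimate,
               c(point$R0, point$G, point$lambda))
  expect_equal(env$ages$e$estimate, point$e)
  # intervals bracket sensibly
  expect_true(all(env$estimates$lower <= env$estimates$upper))
})

test_that("the bootstrap stream is reproducible from the seed", {
  e1 <- bootstrap_ci(boot_table(), n_reps = 50, seed = 99)
  e2 <- bootstrap_ci(boot_table(), n_reps = 50, seed = 99)
  expect_identical(e1, e2)
  e3 <- bootstrap_ci(boot_table(), n_reps = 50, seed = 100)
  expect_false(identical(e1$replicates$R0, e3$replicates$R0))
})

test_that("deterministic rates give zero-width envelopes", {
  lt <- new_life_table(q = c(0, 1), l = c(1, 1), m = c(0.5, 0.2),
                       N_q = c(10, 10), N_m = c(0, 8),
                       omega = 1L, sex = "F")
  suppressMessages(env <- bootstrap_ci(lt, n_reps = 100, seed = 1))
  # q in {0, 1} resamples to itself, so l is fixed across replicates
  expect_equal(env$ages$l$lower, env$ages$l$upper)
  expect_equal(env$ages$l$lower, lt$l)
  # the class with zero weight sum keeps m = 0.5 . 0? no: weight 0 -> m* = 0
  expect_true(all(env$replicates$m[, 1] == 0))
})

test_that("replicates with zero R0 are excluded from G and lambda", {
  lt <- new_life_table(q = c(0.5, 1), l = c(1, 0.5), m = c(0, 0.1),
                       N_q = c(30, 15), N_m = c(20, 2),
                       omega = 1L, sex = "F")
  # n = 2 females, m = 0.1: P(Pois(0.2) = 0) ~ 0.82, so degenerate
  # replicates are plentiful
  expect_message(env <- bootstrap_ci(lt, n_reps = 300, seed = 5),
                 "excluded")
  expect_gt(env$n_degenerate, 0)
  expect_equal(env$n_degenerate, sum(env$replicates$R0 == 0))
  expect_equal(env$n_degenerate, sum(is.na(env$replicates$G)))
  expect_equal(env$n_degenerate, sum(is.na(env$replicates$lambda)))
  # life expectancy is defined for every replicate regardless
  expect_false(anyNA(env$replicates$e))
  expect_false(anyNA(env$estimates$lower))
})

test_that("intervals shrink when the sample sizes grow tenfold", {
  suppressMessages({
    small <- bootstrap_ci(boot_table(1), n_reps = 400, seed = 3)
    big <- bootstrap_ci(boot_table(10), n_reps = 400, seed = 3)
  })
  width <- function(env, i) env$estimates$upper[i] - env$estimates$lower[i]
  for (i in 1:3) expect_lt(width(big, i), width(small, i))
  # roughly the sqrt(10) scaling expected of a parametric bootstrap
  expect_lt(width(big, 3), width(small, 3) / 2)
})

test_that("bootstrap input validation", {
  lt_no_m <- new_life_table(q = c(0.5, 1), l = c(1, 0.5), omega = 1L, sex = "F")
  expect_error(bootstrap_ci(lt_no_m), "N_q and N_m")
  expect_error(bootstrap_ci(boot_table(), n_reps = 0), ">= 1")
})
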