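micro_table <- function() {
  new_life_table(q = c(0.5, 0.5), l = c(1, 0.5), m = c(0, 2),
                 omega = 1L, sex = "F")
}

test_that("the two-class worked example has its closed-form statistics", {
  lt <- micro_table()
  expect_equal(net_reproductive_rate(lt), 1)
  expect_equal(generation_time(lt), 1)
  A <- build_leslie(lt)
  expect_equal(A, matrix(c(0, 0.5, 2, 0), 2, 2))
  eig <- eigen_analysis(A)
  expect_equal(eig$lambda, 1)
  expect_equal(eig$w, c(2 / 3, 1 / 3))
  expect_equal(eig$v, c(1, 2))
  expect_equal(life_expectancy(A), c(1.5, 1))
})

test_that("degenerate fertility edge cases behave", {
  lt0 <- new_life_table(q = c(0.5, 0.5), l = c(1, 0.5), m = c(0, 0),
                        omega = 1L, sex = "F")
  expect_equal(net_reproductive_rate(lt0), 0)
  expect_error(generation_time(lt0), "undefined")
  expect_equal(build_leslie(lt0)[1, ], c(0, 0))
  expect_error(eigen_analysis(build_leslie(lt0)), "no positive fertility")

  # reproduction only at birth: a 1x1 block with lambda = m0
  lt1 <- new_life_table(q = 1, l = 1, m = 1.5, omega = 0L, sex = "F")
  expect_equal(eigen_analysis(build_leslie(lt1))$lambda, 1.5)

  # reproduction concentrated at one age: G is that age
  lta <- new_life_table(q = c(0.2, 0.2, 1), l = c(1, 0.8, 0.64),
                        m = c(0, 0, 0.9), omega = 2L, sex = "F")
  expect_equal(generation_time(lta), 2)
})

test_that("R0 equals the dominant eigenvalue of the next-generation matrix", {
  set.seed(55)
  for (rep in 1:30) {
    lt <- random_life_table(10L)
    A <- build_leslie(lt)
    U <- A; U[1, ] <- 0
    Fm <- matrix(0, nrow(A), ncol(A)); Fm[1, ] <- A[1, ]
    ngm <- Fm %*% solve(diag(nrow(A)) - U)
    expect_equal(net_reproductive_rate(lt), max(Re(eigen(ngm)$values)),
                 tolerance = 1e-10)
  }
})

test_that("G equals the lx*mx-weighted mean age computed by brute force", {
  set.seed(56)
  for (rep in 1:30) {
    lt <- random_life_table(8L)
    w <- lt$l * lt$m
    expect_equal(generation_time(lt),
                 stats::weighted.mean(0:lt$omega, w), tolerance = 1e-12)
  }
})

test_that("subdiagonal products round-trip the survivorship", {
  set.seed(57)
  for (rep in 1:30) {
    lt <- random_life_table(9L)
    A <- build_leslie(lt)
    sub <- A[cbind(2:nrow(A), 1:(nrow(A) - 1))]
    expect_true(all(sub >= 0 & sub <= 1))
    expect_equal(c(1, cumprod(sub)), lt$l, tolerance = 1e-12)
    off <- A; off[1, ] <- 0; off[cbind(2:nrow(A), 1:(nrow(A) - 1))] <- 0
    expect_true(all(off == 0))
  }
  # survivorship hitting zero before the truncation age leaves a survival
  # ratio undefined
  bad <- new_life_table(q = c(1, 0, 1), l = c(1, 0, 0), m = c(0, 0, 1),
                        omega = 2L, sex = "F")
  expect_error(build_leslie(bad), "zero")
})

test_that("the dominant eigenpair satisfies the Euler-Lotka identity", {
  set.seed(58)
  for (rep in 1:100) {
    lt <- random_life_table(sample(4:12, 1))
    eig <- eigen_analysis(build_leslie(lt))
    x <- 0:lt$omega
    resid <- abs(sum(lt$m * lt$l * eig$lambda^(-(x + 1))) - 1)
    expect_lt(resid, 1e-9)
  }
})

test_that("right and left eigenvectors verify their defining equations", {
  set.seed(59)
  for (rep in 1:25) {
    lt <- random_life_table(10L)
    A <- build_leslie(lt)
    eig <- eigen_analysis(A)
    expect_lt(max(abs(A %*% eig$w - eig$lambda * eig$w)), 1e-9)
    expect_lt(max(abs(t(eig$v) %*% A - eig$lambda * t(eig$v))), 1e-9)
    expect_equal(sum(eig$w), 1)
    expect_equal(eig$v[1], 1)
    expect_true(all(eig$w >= -1e-12))
  }
})

test_that("R0 and lambda sit on the same side of 1", {
  set.seed(61)
  base <- random_life_table(8L)
  # scale fertility so that R0 is exactly 1, then perturb both ways
  for (scale in c(1, 0.7, 1.4)) {
    m1 <- base$m / net_reproductive_rate(base) * scale
    lt <- new_life_table(q = base$q, l = base$l, m = m1, omega = base$omega,
                         sex = "F")
    lam <- eigen_analysis(build_leslie(lt))$lambda
    R0 <- net_reproductive_rate(lt)
    expect_equal(R0, scale, tolerance = 1e-12)
    if (scale == 1) expect_equal(lam, 1, tolerance = 1e-10)
    if (scale < 1) expect_lt(lam, 1)
    if (scale > 1) expect_gt(lam, 1)
  }
})

test_that("fundamental-matrix life expectancy equals the survivorship sums", {
  expect_equal(life_expectancy(matrix(c(0, 0.5, 0, 0), 2, 2)), c(1.5, 1))
  expect_equal(life_expectancy(matrix(0, 3, 3)), rep(1, 3))
  set.seed(60)
  for (rep in 1:50) {
    lt <- random_life_table(sample(4:12, 1))
    e <- life_expectancy(build_leslie(lt))
    direct <- vapply(0:lt$omega, function(x) {
      sum(lt$l[(x + 1):(lt$omega + 1)]) / lt$l[x + 1]
    }, 0)
    expect_equal(e, direct, tolerance = 1e-10)
    expect_true(all(e >= 1))
  }
})

test_that("reproductive value is unimodal, peaking at or after first reproduction", {
  s <- reference_schedule()
  lt <- new_life_table(q = s$q, l = survivorship(s$q)[1:10], m = s$m,
                       omega = 9L, sex = "F")
  v <- eigen_analysis(build_leslie(lt))$v
  peak <- which.max(v)
  expect_gte(peak, min(which(s$m > 0)))
  expect_true(all(diff(v[1:peak]) > 0))
  expect_true(all(diff(v[peak:length(v)]) < 0))
  expect_equal(v[1], 1)
})

test_that("survival to the median age at first reproduction is a lookup", {
  lt <- new_life_table(q = c(0.2, 0.25, 1), l = c(1, 0.8, 0.6),
                       m = c(0, 0.2, 0.4), omega = 2L, sex = "F")
  expect_equal(survival_to_median_afr(lt, 2), 0.6)
  expect_equal(survival_to_median_afr(lt, 0), 1)
  expect_equal(survival_to_median_afr(lt, 1.5), 0.8)              # floored
  expect_equal(survival_to_median_afr(lt, 1.5, interpolate = TRUE), 0.7)
  expect_error(survival_to_median_afr(lt, 5), "beyond")

  cfg <- default_sim_config(n_births = 1500, seed = 15)
  rec <- simulate_population(cfg)
  counts <- tabulate_counts(rec, "F")
  ltF <- add_fertility(estimate_life_table(counts),
                       tabulate_fertility(rec, n_classes = counts$n_classes))
  afr <- age_first_reproduction(rec)
  sm <- survival_to_median_afr(ltF, afr)
  # the estimate should sit near the generating schedule's survivorship
  # evaluated at the same (estimated) median age
  sm_true <- survival_to_median_afr(true_life_table(cfg), afr)
  expect_lt(abs(sm - sm_true), 0.05)
})
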