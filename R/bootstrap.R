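#' Sample one plausible mortality schedule
#'
#' Parametric resampling of age-specific mortality: for each age class the
#' adjusted at-risk number is rounded up to the next integer `n`, a
#' binomial number of deaths is drawn with probability equal to the point
#' estimate, and the sampled death count divided by `n` gives one plausible
#' mortality value.
#'
#' @param q_hat point estimates of `q` per age class (in `[0, 1]`; `NA`
#'   entries are propagated).
#' @param N_q adjusted at-risk sample sizes (may be fractional; rounded up).
#' @return Numeric vector of resampled `q` values (`NA` where `n = 0`).
#'   Uses R's global random number stream; seed at the caller
#'   (see [bootstrap_ci()]).
#' @export
sample_mortality <- function(q_hat, N_q) {
  check_nonneg(N_q, "N_q", len = length(q_hat))
  if (any(q_hat < 0 | q_hat > 1, na.rm = TRUE)) {
    stop_invalid("`q_hat` must be in [0, 1]")
  }
  n <- ceiling(N_q)
  out <- rep(NA_real_, length(q_hat))
  ok <- !is.na(q_hat) & n > 0
  out[ok] <- stats::rbinom(sum(ok), n[ok], q_hat[ok]) / n[ok]
  out
}

#' Sample one plausible fertility schedule
#'
#' Parametric resampling of age-specific fertility: the weight sum is
#' rounded up to the next integer `n` (the effective number of females
#' observed at that age), the total number of daughters across those
#' females is drawn as a sum of `n` i.i.d. Poisson counts with mean equal
#' to the point estimate (drawn as a single Poisson with mean `n * m_hat`,
#' which is the same distribution), and the total divided by `n` gives one
#' plausible fertility value.
#'
#' @param m_hat point estimates of `m` per age class (non-negative).
#' @param N_m fertility weight sums (may be fractional; rounded up).
#' @return Numeric vector of resampled `m` values (0 where `n = 0`).
#' @export
sample_fertility <- function(m_hat, N_m) {
  check_nonneg(m_hat, "m_hat")
  check_nonneg(N_m, "N_m", len = length(m_hat))
  n <- ceiling(N_m)
  out <- numeric(length(m_hat))
  ok <- n > 0 & m_hat > 0
  if (any(ok)) {
    out[ok] <- stats::rpois(sum(ok), n[ok] * m_hat[ok]) / n[ok]
  }
  out
}

#' Parametric-bootstrap confidence intervals for life-history statistics
#'
#' Resamples the mortality and fertility schedules of a completed female
#' life table ([sample_mortality()], [sample_fertility()]), recomputes
#' survivorship and every downstream statistic for each replicate, and
#' reports the 2.5th and 97.5th percentiles of the bootstrap distributions
#' as confidence limits. The truncation age is held fixed across
#' replicates. Replicates with a resampled `R0` of zero leave the
#' generation time (and the eigenstructure) undefined; they are excluded
#' from those statistics' percentile sets and their number is reported.
#'
#' Within each replicate, draws are ordered age-ascending with mortality
#' before fertility, so runs are reproducible given the seed.
#'
#' @param lt a [life_table] with fertility and both sample-size vectors
#'   (`N_q`, `N_m`).
#' @param n_reps number of bootstrap replicates (default 4999).
#' @param seed integer seed for the replicate stream.
#' @param conf_level confidence level (default 0.95, i.e. the 2.5th and
#'   97.5th percentiles).
#' @return An object of class `bootstrap_envelope`: scalar intervals for
#'   `R0`, `G` and `lambda`, per-age envelopes for `l`, `m`, `w`, `v` and
#'   `e`, the stored replicate values, `n_reps`, `seed`, and the count of
#'   degenerate replicates excluded from `G`.
#' @export
bootstrap_ci <- function(lt, n_reps = 4999L, seed = 1L, conf_level = 0.95) {
  n_reps <- check_scalar_count(n_reps, "n_reps", min = 1L)
  seed <- check_scalar_count(seed, "seed", min = 0L)
  if (is.null(lt$m) || is.null(lt$N_m) || is.null(lt$N_q)) {
    stop_invalid("bootstrap needs a life table with m, N_q and N_m")
  }
  len <- lt$omega + 1L
  x <- 0:lt$omega

  set.seed(seed)
  R0_r <- G_r <- lam_r <- numeric(n_reps)
  l_r <- m_r <- w_r <- v_r <- e_r <- matrix(NA_real_, n_reps, len)

  for (r in seq_len(n_reps)) {
    q_s <- sample_mortality(lt$q, lt$N_q)
    m_s <- sample_fertility(lt$m, lt$N_m)
    q_s[is.na(q_s)] <- lt$q[is.na(q_s)]  # classes with n = 0 keep the point value
    l_s <- c(1, cumprod(1 - q_s))[seq_len(len)]
    R0 <- sum(l_s * m_s)
    R0_r[r] <- R0
    G_r[r] <- if (R0 > 0) sum(x * l_s * m_s) / R0 else NA_real_
    l_r[r, ] <- l_s
    m_r[r, ] <- m_s

    A <- leslie_from_rates(1 - q_s[-len], m_s)
    e_r[r, ] <- life_expectancy(A)
    if (R0 > 0) {
      eig <- eigen_analysis(A)
      lam_r[r] <- eig$lambda
      w_r[r, ] <- eig$w
      v_r[r, ] <- eig$v
    } else {
      lam_r[r] <- NA_real_
    }
  }

  n_degenerate <- sum(is.na(G_r))
  if (n_degenerate > 0) {
    message(n_degenerate, " replicate(s) with R0 = 0 excluded from G, ",
            "lambda, w and v percentiles")
  }

  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  point <- demographic_summary(lt)
  scalar <- function(est, reps) {
    qq <- pct(reps, probs)
    c(estimate = est, lower = qq[1], upper = qq[2])
  }
  estimates <- rbind(
    R0 = scalar(point$R0, R0_r),
    G = scalar(point$G, G_r),
    lambda = scalar(point$lambda, lam_r)
  )
  estimates <- data.frame(statistic = rownames(estimates), estimates,
                          row.names = NULL)

  age_env <- function(est, reps) {
    data.frame(age = x, estimate = est,
               lower = apply(reps, 2, pct, probs = probs[1]),
               upper = apply(reps, 2, pct, probs = probs[2]))
  }
  ages <- list(
    l = age_env(lt$l, l_r),
    m = age_env(lt$m, m_r),
    w = age_env(point$w, w_r),
    v = age_env(point$v, v_r),
    e = age_env(point$e, e_r)
  )

  structure(list(
    estimates = estimates,
    ages = ages,
    replicates = list(R0 = R0_r, G = G_r, lambda = lam_r,
                      l = l_r, m = m_r, w = w_r, v = v_r, e = e_r),
    n_reps = n_reps, seed = seed, conf_level = conf_level,
    n_degenerate = n_degenerate
  ), class = "bootstrap_envelope")
}

#' @export
print.bootstrap_envelope <- function(x, ...) {
  cat("Parametric bootstrap envelope:", x$n_reps, "replicates, seed",
      x$seed, "\n")
  print(x$estimates, digits = 4)
  if (x$n_degenerate > 0) {
    cat("  (", x$n_degenerate, " degenerate replicate(s) excluded from G)\n",
        sep = "")
  }
  invisible(x)
}
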