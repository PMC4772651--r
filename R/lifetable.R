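#' Life-table object
#'
#' Low-level constructor for a truncated life table: age classes `0..omega`
#' with mortality `q`, survivorship `l` (with `l[1] = 1` and
#' `l[x+1] = l[x] * (1 - q[x])`), optional fertility `m` and the sample
#' sizes behind them (`N_q`: censoring-adjusted at-risk numbers; `N_m`:
#' fertility weight sums). Most users build one with
#' [estimate_life_table()] rather than directly.
#'
#' @param q,l numeric vectors of length `omega + 1`.
#' @param m optional daughter-fertility vector of the same length.
#' @param N_q,N_m,N,c,dp optional sample-size / count vectors of the same
#'   length (`N`, `c`, `dp` are carried through from the source counts for
#'   reporting).
#' @param omega integer truncation age (last age class in the table).
#' @param sex `"F"` or `"M"`.
#' @return An object of class `life_table`.
#' @export
new_life_table <- function(q, l, m = NULL, N_q = NULL, N_m = NULL,
                           N = NULL, c = NULL, dp = NULL,
                           omega = length(q) - 1L, sex = "F") {
  omega <- check_scalar_count(omega, "omega", min = 0L)
  len <- omega + 1L
  check_prob(q, "q", len = len)
  check_prob(l, "l", len = len)
  if (abs(l[1] - 1) > 1e-12) stop_invalid("l[0] must equal 1")
  if (len > 1L) {
    rec <- l[-1] - l[-len] * (1 - q[-len])
    if (any(abs(rec) > 1e-8)) {
      stop_invalid("l does not satisfy l[x+1] = l[x] * (1 - q[x])")
    }
    if (any(diff(l) > 1e-12)) stop_invalid("l must be non-increasing")
  }
  if (!is.null(m)) check_nonneg(m, "m", len = len)
  for (nm in c("N_q", "N_m", "N", "c", "dp")) {
    v <- get(nm)
    if (!is.null(v)) check_nonneg(v, nm, len = len)
  }
  if (!sex %in% c("F", "M")) stop_invalid("`sex` must be \"F\" or \"M\"")
  structure(list(q = as.numeric(q), l = as.numeric(l),
                 m = if (is.null(m)) NULL else as.numeric(m),
                 N_q = N_q, N_m = N_m, N = N, c = c, dp = dp,
                 omega = omega, sex = sex),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat("Life table (sex ", x$sex, "), ages 0..", x$omega,
      if (is.null(x$m)) ", survival only" else ", with fertility", "\n", sep = "")
  print(utils::head(as.data.frame(x), 12))
  if (x$omega + 1L > 12L) cat("  ... (", x$omega + 1L, " classes)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.life_table <- function(x, ...) {
  out <- data.frame(x = 0:x$omega)
  for (nm in c("N", "c", "dp", "N_q")) {
    if (!is.null(x[[nm]])) out[[nm]] <- x[[nm]]
  }
  out$q <- x$q
  out$l <- x$l
  if (!is.null(x$m)) {
    out$m <- x$m
    if (!is.null(x$N_m)) out$N_m <- x$N_m
  }
  out
}

#' Actuarial age-specific mortality
#'
#' Estimates the per-age-class probability of death under right-censoring
#' with the actuarial method: half of the individuals censored within a
#' class are subtracted from its at-risk number (censoring is assumed to
#' fall half before and half after the interval midpoint), giving the
#' adjusted sample size `N_q[x] = N[x] - c[x] / 2` and the estimate
#' `q[x] = dp[x] / N_q[x]`, where `dp` pools deaths with permanent
#' disappearances so that mortality is not underestimated.
#'
#' @param counts an [age_class_counts] object.
#' @param disappearances how to treat permanent disappearances: `"deaths"`
#'   (default: pooled into the mortality numerator) or `"censored"`
#'   (treated as right-censored, which can greatly underestimate mortality
#'   for a heavily dispersing sex; a caution is issued).
#' @return A list with `q` (estimates, `NA` where no one is at risk) and
#'   `N_q` (adjusted sample sizes). Ratios above 1 (possible under heavy
#'   within-class censoring) are clamped to 1 with a warning.
#' @export
actuarial_mortality <- function(counts, disappearances = c("deaths", "censored")) {
  disappearances <- match.arg(disappearances)
  dd <- counts$dp
  cc <- counts$c
  if (disappearances == "censored") {
    warning("treating permanent disappearances as censored can greatly ",
            "underestimate mortality for a dispersing sex")
    dd <- counts$d
    cc <- counts$c + counts$p
  }
  N_q <- counts$N - cc / 2
  if (any(dd > 0 & N_q <= 0)) {
    stop_invalid("deaths observed with non-positive adjusted sample size in ",
                 "age class ", which(dd > 0 & N_q <= 0)[1] - 1L)
  }
  q <- ifelse(N_q > 0, dd / N_q, NA_real_)
  if (any(q > 1, na.rm = TRUE)) {
    warning("q > 1 after censoring adjustment in age class(es) ",
            paste(which(q > 1) - 1L, collapse = ", "), "; clamped to 1")
    q <- pmin(q, 1)
  }
  list(q = q, N_q = N_q)
}

#' Survivorship from age-specific mortality
#'
#' Computes the probability of surviving from birth to the start of each
#' age class: `l[0] = 1`, `l[x] = prod(1 - q[i], i < x)`.
#'
#' @param q numeric vector of mortality probabilities; entries must be in
#'   `[0, 1]`. If `q` contains `NA` (inestimable classes), the product
#'   stops at the first one — the table simply ends there.
#' @return Numeric survivorship vector of length `length(q) + 1` (or up to
#'   the first undefined entry).
#' @examples
#' survivorship(c(0.5, 0.5))  # 1, 0.5, 0.25
#' @export
survivorship <- function(q) {
  if (anyNA(q)) q <- q[seq_len(which(is.na(q))[1] - 1L)]
  if (length(q)) check_prob(q, "q")
  c(1, cumprod(1 - q))
}

#' Truncate mortality and survivorship at the last observed death
#'
#' Where the oldest individuals are still alive (right-censored), the last
#' estimable age class is the last one with an observed death (or
#' disappearance pooled as death); survivorship beyond it is unknown. The
#' table is also cut where survivorship reaches zero.
#'
#' @param counts an [age_class_counts] object.
#' @param q,l optional precomputed estimates from [actuarial_mortality()]
#'   and [survivorship()]; recomputed if missing.
#' @param disappearances passed to [actuarial_mortality()] when `q` is
#'   recomputed.
#' @return A [life_table] (without fertility; see [add_fertility()]).
#' @export
truncate_at_last_death <- function(counts, q = NULL, l = NULL,
                                   disappearances = "deaths") {
  cens <- identical(disappearances, "censored")
  if (is.null(q)) {
    est <- actuarial_mortality(counts, disappearances = disappearances)
    q <- est$q
    N_q <- est$N_q
  } else {
    N_q <- counts$N - (if (cens) counts$c + counts$p else counts$c) / 2
  }
  if (is.null(l)) l <- survivorship(q)

  dd <- if (cens) counts$d else counts$dp
  n_est <- length(l) - 1L          # classes with a defined q estimate
  death_ages <- which(dd[seq_len(n_est)] > 0) - 1L
  if (!length(death_ages)) {
    stop_invalid("no observed deaths: the life table is empty")
  }
  omega <- max(death_ages)
  zero <- which(l == 0) - 1L
  if (length(zero)) omega <- min(omega, zero[1])
  keep <- seq_len(omega + 1L)

  new_life_table(q = q[keep], l = l[keep], N_q = N_q[keep],
                 N = counts$N[keep], c = counts$c[keep], dp = counts$dp[keep],
                 omega = omega, sex = counts$sex)
}

#' Estimate a life table from age-class counts
#'
#' Convenience wrapper: [actuarial_mortality()], then [survivorship()],
#' then [truncate_at_last_death()].
#'
#' @inheritParams truncate_at_last_death
#' @inheritParams actuarial_mortality
#' @return A [life_table].
#' @export
estimate_life_table <- function(counts, disappearances = c("deaths", "censored")) {
  disappearances <- match.arg(disappearances)
  est <- actuarial_mortality(counts, disappearances = disappearances)
  l <- survivorship(est$q)
  truncate_at_last_death(counts, q = est$q, l = l,
                         disappearances = disappearances)
}

#' Attach a fertility schedule to a life table
#'
#' Computes the observation-weighted daughter-fertility schedule from
#' [fertility counts][tabulate_fertility] and stores it (with its weight
#' sums `N_m`) on the life table, truncated to the table's age range.
#'
#' @param lt a [life_table].
#' @param fc a `fertility_counts` object covering at least ages
#'   `0..lt$omega`.
#' @return The life table with `m` and `N_m` filled in.
#' @export
add_fertility <- function(lt, fc) {
  fert <- age_specific_fertility(fc)
  len <- lt$omega + 1L
  if (length(fert$m) < len) {
    stop_invalid("fertility counts cover fewer age classes than the life table")
  }
  lt$m <- fert$m[seq_len(len)]
  lt$N_m <- fert$N_m[seq_len(len)]
  lt
}
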