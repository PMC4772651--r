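#' Per-age-class census counts
#'
#' Holds one sex's per-age-class vectors of entries (`t`, with `t[1]` =
#' births into class 0), deaths (`d`), permanent disappearances (`p`) and
#' censored individuals (`c`), together with the pooled mortality numerator
#' `dp = d + p` and the at-risk vector `N` from [at_risk()].
#'
#' @param sex `"F"` or `"M"`.
#' @param t,d,p,c non-negative integer vectors of equal length (one entry
#'   per age class, starting at class 0).
#' @return An object of class `age_class_counts`.
#' @export
age_class_counts <- function(sex, t, d, p, c) {
  if (!sex %in% c("F", "M")) stop_invalid("`sex` must be \"F\" or \"M\"")
  n <- length(t)
  check_nonneg(t, "t", len = n, integerish = TRUE)
  check_nonneg(d, "d", len = n, integerish = TRUE)
  check_nonneg(p, "p", len = n, integerish = TRUE)
  check_nonneg(c, "c", len = n, integerish = TRUE)
  out <- structure(list(sex = sex, t = as.numeric(t), d = as.numeric(d),
                        p = as.numeric(p), c = as.numeric(c),
                        dp = as.numeric(d + p), N = NULL, n_classes = n),
                   class = "age_class_counts")
  out$N <- at_risk(out)
  bad <- out$N < out$d + out$p + out$c
  if (any(bad)) {
    stop_invalid("inconsistent counts: exits exceed the at-risk number in age ",
                 "class ", which(bad)[1] - 1L)
  }
  out
}

#' @export
print.age_class_counts <- function(x, ...) {
  cat("Age-class counts (sex ", x$sex, "): ", x$n_classes, " classes, ",
      sum(x$t), " individuals (", sum(x$d), " deaths, ", sum(x$p),
      " disappearances, ", sum(x$c), " censored)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.age_class_counts <- function(x, ...) {
  data.frame(age = seq_len(x$n_classes) - 1L, entries = x$t, deaths = x$d,
             disappearances = x$p, censored = x$c, dp = x$dp, N = x$N)
}

#' Tabulate individual records into age-class counts
#'
#' Reduces individual histories to one sex's per-age-class count vectors:
#' each individual adds one entry at its entry age and exactly one exit
#' (death, permanent disappearance, or censoring) at its exit age.
#'
#' @param records a [census_records] object.
#' @param sex `"F"` or `"M"`; individuals of unknown sex are excluded with a
#'   warning.
#' @param truncate_age optional integer: individuals exiting beyond this age
#'   are converted to censored at `truncate_age`, and the table ends there
#'   (used e.g. where older immigrants have unreliable ages). Individuals
#'   entering above `truncate_age` are dropped.
#' @param n_classes optional number of age classes; defaults to
#'   `max(exit_age) + 1` over the retained records.
#' @return An [age_class_counts] object.
#' @export
tabulate_counts <- function(records, sex = c("F", "M"), truncate_age = NULL,
                            n_classes = NULL) {
  sex <- match.arg(sex)
  ind <- records$individuals
  n_unknown <- sum(ind$sex == "unknown")
  if (n_unknown > 0) {
    warning(n_unknown, " individual(s) of unknown sex excluded from tabulation")
  }
  ind <- ind[ind$sex == sex, , drop = FALSE]

  if (!is.null(truncate_age)) {
    truncate_age <- check_scalar_count(truncate_age, "truncate_age", min = 0L)
    late <- ind$entry_age > truncate_age
    if (any(late)) {
      warning(sum(late), " individual(s) entering beyond truncate_age dropped")
      ind <- ind[!late, , drop = FALSE]
    }
    over <- ind$exit_age > truncate_age
    ind$exit_age[over] <- truncate_age
    ind$fate[over] <- "censored"
    if (is.null(n_classes)) n_classes <- truncate_age + 1L
  }
  if (is.null(n_classes)) {
    n_classes <- if (nrow(ind)) max(ind$exit_age) + 1L else 0L
  }
  if (n_classes < 1L) stop_invalid("no records to tabulate for sex ", sex)

  tab <- function(ages) tabulate(ages + 1L, nbins = n_classes)
  age_class_counts(
    sex = sex,
    t = tab(ind$entry_age),
    d = tab(ind$exit_age[ind$fate == "death"]),
    p = tab(ind$exit_age[ind$fate == "permanent_disappearance"]),
    c = tab(ind$exit_age[ind$fate == "censored"])
  )
}

#' At-risk numbers from age-class counts
#'
#' The number of individuals alive at the start of each age class, obtained
#' by carrying entries forward and removing exits:
#' `N[0] = t[0]`; `N[x] = N[x-1] - dp[x-1] - c[x-1] + t[x]`.
#' This equals a direct count of individuals with
#' `entry_age <= x <= exit_age`.
#'
#' @param counts an [age_class_counts] object (or a bare list with `t`,
#'   `dp`, `c`).
#' @return Numeric vector of at-risk numbers per age class. A negative
#'   value (inconsistent counts) is an error naming the offending class.
#' @export
at_risk <- function(counts) {
  n <- length(counts$t)
  N <- numeric(n)
  N[1] <- counts$t[1]
  for (x in seq_len(n - 1L)) {
    N[x + 1L] <- N[x] - counts$dp[x] - counts$c[x] + counts$t[x + 1L]
  }
  if (any(N < 0)) {
    stop_invalid("inconsistent counts: negative at-risk number in age class ",
                 which(N < 0)[1] - 1L)
  }
  N
}

#' Observation-weighted fertility counts
#'
#' Per-age-class accumulators for the fertility estimator: each female
#' alive in class `x` contributes her observation fraction for that class
#' to `weight_sum[x]`, and her observed newborns at `x` (of any sex,
#' including those that died before sexing) times that fraction to
#' `weighted_births[x]`. Sexed offspring are accumulated separately in
#' `weighted_sons` / `weighted_daughters`.
#'
#' @param records a [census_records] object (female records are used).
#' @param n_classes optional number of age classes; defaults to
#'   `max(exit_age) + 1` over females.
#' @return An object of class `fertility_counts` with numeric vectors
#'   `weighted_births`, `weight_sum`, `weighted_sons`,
#'   `weighted_daughters`, integer `n_mothers`, and `n_classes`.
#' @export
tabulate_fertility <- function(records, n_classes = NULL) {
  fem <- records$individuals[records$individuals$sex == "F", , drop = FALSE]
  if (is.null(n_classes)) {
    n_classes <- if (nrow(fem)) max(fem$exit_age) + 1L else 0L
  }
  if (n_classes < 1L) stop_invalid("no female records to tabulate")

  # one row per female-by-occupied-age cell
  span <- fem$exit_age - fem$entry_age + 1L
  fid <- rep(fem$id, span)
  fage <- unlist(mapply(seq.int, fem$entry_age, fem$exit_age,
                        SIMPLIFY = FALSE), use.names = FALSE)
  keep <- fage < n_classes
  fid <- fid[keep]; fage <- fage[keep]
  w <- obs_weight(records, fid, fage)

  key <- paste(fid, fage)
  b <- records$births
  tally <- function(sel) {
    if (!any(sel)) return(numeric(length(key)))
    tb <- table(paste(b$mother_id[sel], b$mother_age[sel]))
    out <- as.numeric(tb[key])
    out[is.na(out)] <- 0
    out
  }
  nb_all <- tally(rep(TRUE, nrow(b)))
  nb_son <- tally(b$offspring_sex == "M")
  nb_dau <- tally(b$offspring_sex == "F")

  agg <- function(vals) {
    out <- numeric(n_classes)
    s <- rowsum(vals, fage)
    out[as.integer(rownames(s)) + 1L] <- s[, 1]
    out
  }

  structure(list(
    weighted_births = agg(w * nb_all),
    weight_sum = agg(w),
    weighted_sons = agg(w * nb_son),
    weighted_daughters = agg(w * nb_dau),
    n_mothers = agg(rep(1, length(fage))),
    n_classes = n_classes
  ), class = "fertility_counts")
}

#' @export
print.fertility_counts <- function(x, ...) {
  cat("Fertility counts:", x$n_classes, "age classes,",
      round(sum(x$weighted_births), 2), "weighted births over",
      round(sum(x$weight_sum), 2), "weighted female-years\n")
  invisible(x)
}

#' @export
as.data.frame.fertility_counts <- function(x, ...) {
  data.frame(age = seq_len(x$n_classes) - 1L,
             weighted_births = x$weighted_births,
             weight_sum = x$weight_sum,
             weighted_sons = x$weighted_sons,
             weighted_daughters = x$weighted_daughters,
             n_mothers = x$n_mothers)
}
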