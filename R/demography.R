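#' Net reproductive rate
#'
#' Lifetime expected number of daughters per newborn female:
#' `R0 = sum(l[x] * m[x])` over the table's age range.
#'
#' @param lt a [life_table] with fertility attached (see [add_fertility()]).
#' @return The net reproductive rate, a non-negative number.
#' @export
net_reproductive_rate <- function(lt) {
  if (is.null(lt$m)) stop_invalid("life table has no fertility schedule")
  sum(lt$l * lt$m)
}

#' Generation time
#'
#' Mean age of mothers at daughter production:
#' `G = sum(x * l[x] * m[x]) / R0`.
#'
#' @param lt a [life_table] with fertility.
#' @return Generation time in years. Undefined (an error) when `R0 = 0`.
#' @export
generation_time <- function(lt) {
  R0 <- net_reproductive_rate(lt)
  if (R0 <= 0) stop_invalid("generation time is undefined when R0 = 0")
  x <- 0:lt$omega
  sum(x * lt$l * lt$m) / R0
}

#' Build a Leslie matrix from a life table
#'
#' Places the fertilities `m[x]` in the first row and the survival ratios
#' `l[x+1] / l[x]` on the subdiagonal (column `x`), with zeros elsewhere,
#' giving the age-structured projection matrix of dimension `omega + 1`.
#'
#' @param lt a [life_table] with fertility.
#' @return A square numeric matrix.
#' @export
build_leslie <- function(lt) {
  if (is.null(lt$m)) stop_invalid("life table has no fertility schedule")
  n <- lt$omega + 1L
  if (n > 1L && any(lt$l[seq_len(n - 1L)] == 0)) {
    stop_invalid("survivorship is zero before the truncation age (class ",
                 which(lt$l == 0)[1] - 1L, "): survival ratios are undefined")
  }
  A <- matrix(0, n, n)
  A[1, ] <- lt$m
  if (n > 1L) {
    A[cbind(2:n, 1:(n - 1L))] <- lt$l[-1] / lt$l[-n]
  }
  A
}

# Leslie matrix directly from per-class survival probabilities (1 - q) and
# fertilities; used by the bootstrap, where a resampled q of 1 mid-table
# would make survivorship ratios 0/0.
leslie_from_rates <- function(s, m) {
  n <- length(m)
  A <- matrix(0, n, n)
  A[1, ] <- m
  if (n > 1L) A[cbind(2:n, 1:(n - 1L))] <- s
  A
}

#' Dominant eigenstructure of a Leslie matrix
#'
#' Extracts the asymptotic population growth rate (dominant eigenvalue),
#' the stable age distribution (dominant right eigenvector, scaled to sum
#' to 1), and the reproductive values (dominant left eigenvector, scaled so
#' the value at birth is 1). The dominant eigenvalue of a non-negative
#' Leslie matrix with at least one positive fertility is real and positive
#' (Perron–Frobenius); a numerically complex result beyond tolerance, or an
#' eigenpair that fails to satisfy `A w = lambda w` to 1e-8, is an error
#' rather than being silently accepted.
#'
#' @param A square non-negative matrix (see [build_leslie()]).
#' @return list with `lambda`, `w`, `v`.
#' @export
eigen_analysis <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A) || any(A < 0)) {
    stop_invalid("`A` must be a square non-negative matrix")
  }
  if (all(A[1, ] <= 0)) {
    stop_invalid("no positive fertility: growth rate is degenerate")
  }
  pick_dominant <- function(e) {
    mod <- Mod(e$values)
    cand <- which(mod >= max(mod) * (1 - 1e-9))
    cand[which.max(Re(e$values[cand]))]
  }
  er <- eigen(A)
  i <- pick_dominant(er)
  lam_c <- er$values[i]
  if (abs(Im(lam_c)) > 1e-9 * max(1, abs(Re(lam_c))) || Re(lam_c) <= 0) {
    stop_invalid("dominant eigenvalue is not real positive: degenerate matrix")
  }
  lambda <- Re(lam_c)

  w <- er$vectors[, i]
  if (max(abs(Im(w))) > 1e-9 * max(abs(w), 1)) {
    stop_invalid("dominant right eigenvector has a non-negligible imaginary part")
  }
  w <- Re(w)
  w <- w / sum(w)

  el <- eigen(t(A))
  j <- which.min(Mod(el$values - lam_c))
  v <- el$vectors[, j]
  if (max(abs(Im(v))) > 1e-9 * max(abs(v), 1)) {
    stop_invalid("dominant left eigenvector has a non-negligible imaginary part")
  }
  v <- Re(v)
  if (abs(v[1]) < 1e-12) stop_invalid("reproductive value at birth is zero")
  v <- v / v[1]

  resid <- max(abs(A %*% w - lambda * w))
  if (resid > 1e-8 * max(1, lambda)) {
    stop_invalid("eigen decomposition did not converge (residual ", resid, ")")
  }
  list(lambda = lambda, w = as.numeric(w), v = as.numeric(v))
}

#' Life expectancy at each age from the fundamental matrix
#'
#' Zeroes the fertility row of the Leslie matrix to obtain the
#' survival-only matrix `U`, then sums each column of the fundamental
#' matrix `(I - U)^{-1}`. Entry `x` is the expected number of whole age
#' intervals an individual alive at the start of class `x` still has ahead
#' of it, counting the current interval — so every entry is at least 1.
#'
#' @param A a Leslie matrix (see [build_leslie()]).
#' @return Numeric vector of life expectancies per age class.
#' @export
life_expectancy <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop_invalid("`A` must be a square matrix")
  }
  U <- A
  U[1, ] <- 0
  Fund <- tryCatch(solve(diag(nrow(A)) - U),
                   error = function(e) {
                     stop_invalid("I - U is singular (terminal survival of 1?): ",
                                  conditionMessage(e))
                   })
  colSums(Fund)
}

#' Survival from birth to the median age at first reproduction
#'
#' Looks up the survivorship at the median age at which females first
#' reproduced: the fraction of newborns that live long enough to start
#' reproducing.
#'
#' @param lt a [life_table].
#' @param afr an [afr_distribution][age_first_reproduction] object, or a
#'   single numeric median age.
#' @param interpolate if `FALSE` (default) the median is floored to an
#'   integer age class and the survivorship looked up directly; if `TRUE`,
#'   survivorship is linearly interpolated at a non-integer median.
#' @return Survival probability in `[0, 1]`.
#' @export
survival_to_median_afr <- function(lt, afr, interpolate = FALSE) {
  med <- if (inherits(afr, "afr_distribution")) afr$median else afr
  if (!is.numeric(med) || length(med) != 1L || is.na(med) || med < 0) {
    stop_invalid("median age at first reproduction must be a single ",
                 "non-negative number")
  }
  if (med > lt$omega) {
    stop_invalid("median age at first reproduction (", med,
                 ") lies beyond the life table (omega = ", lt$omega, ")")
  }
  if (interpolate) {
    lo <- floor(med); hi <- ceiling(med)
    if (lo == hi) return(lt$l[lo + 1L])
    lt$l[lo + 1L] + (med - lo) * (lt$l[hi + 1L] - lt$l[lo + 1L])
  } else {
    lt$l[floor(med) + 1L]
  }
}

#' Demographic summary of a female life table
#'
#' Computes the standard scalar and per-age population statistics from a
#' completed female life table: net reproductive rate `R0`, generation time
#' `G`, asymptotic growth rate `lambda`, stable age distribution `w`,
#' reproductive values `v`, life expectancies `e`, and (when an age at
#' first reproduction is supplied) the fraction of newborns surviving to
#' the median age at first reproduction.
#'
#' @param lt a [life_table] with fertility.
#' @param afr optional [afr_distribution][age_first_reproduction] or
#'   numeric median age.
#' @param interpolate_afr passed to [survival_to_median_afr()].
#' @return An object of class `demographic_summary`.
#' @export
demographic_summary <- function(lt, afr = NULL, interpolate_afr = FALSE) {
  R0 <- net_reproductive_rate(lt)
  G <- if (R0 > 0) generation_time(lt) else {
    warning("R0 = 0: generation time undefined")
    NA_real_
  }
  A <- build_leslie(lt)
  eig <- eigen_analysis(A)
  e <- life_expectancy(A)
  stm <- if (!is.null(afr)) {
    survival_to_median_afr(lt, afr, interpolate = interpolate_afr)
  } else NA_real_
  structure(list(R0 = R0, G = G, lambda = eig$lambda,
                 w = eig$w, v = eig$v, e = e,
                 surv_to_median_afr = stm,
                 omega = lt$omega),
            class = "demographic_summary")
}

#' @export
print.demographic_summary <- function(x, ...) {
  cat("Demographic summary (ages 0..", x$omega, ")\n", sep = "")
  cat(sprintf("  R0     = %.4f daughters/female\n", x$R0))
  cat(sprintf("  G      = %.4f years\n", x$G))
  cat(sprintf("  lambda = %.4f\n", x$lambda))
  cat(sprintf("  e[0]   = %.4f years\n", x$e[1]))
  if (!is.na(x$surv_to_median_afr)) {
    cat(sprintf("  survival to median AFR = %.4f\n", x$surv_to_median_afr))
  }
  invisible(x)
}
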