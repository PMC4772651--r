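#' Reference demographic schedule
#'
#' A ten-class (ages 0--9) mortality and daughter-fertility schedule used as
#' the package's standard ground truth for simulation experiments. The shape
#' is typical of a medium-sized, long-lived social mammal: elevated
#' first-year mortality, low prime-age adult mortality rising with
#' senescence, a hard maximum lifespan (the final age class is always
#' fatal, so a closed cohort yields a complete life table), reproductive
#' maturity in age class 3, and a mid-life fertility plateau followed by a
#' gradual decline.
#'
#' @return A list with components `q` (per-class probability of death) and
#'   `m` (expected daughters per female per year), each of length 10.
#' @examples
#' sched <- reference_schedule()
#' survivorship(sched$q)
#' @export
reference_schedule <- function() {
  list(
    q = c(0.20, 0.10, 0.07, 0.05, 0.05, 0.06, 0.08, 0.12, 0.20, 1.00),
    m = c(0.00, 0.00, 0.00, 0.10, 0.30, 0.45, 0.45, 0.40, 0.30, 0.20)
  )
}
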