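# Internal validation helpers. Validation failures signal a condition of
# class "lifetab_validation_error" so callers (and the CLI) can distinguish
# bad input from computation failures.

stop_invalid <- function(...) {
  msg <- paste0(...)
  cond <- structure(
    class = c("lifetab_validation_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

check_prob <- function(x, name, len = NULL) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_invalid("`", name, "` must be numeric in [0, 1] with no missing values")
  }
  if (!is.null(len) && length(x) != len) {
    stop_invalid("`", name, "` must have length ", len, ", got ", length(x))
  }
  invisible(x)
}

check_nonneg <- function(x, name, len = NULL, integerish = FALSE) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop_invalid("`", name, "` must be non-negative with no missing values")
  }
  if (integerish && any(x != floor(x))) {
    stop_invalid("`", name, "` must contain whole numbers")
  }
  if (!is.null(len) && length(x) != len) {
    stop_invalid("`", name, "` must have length ", len, ", got ", length(x))
  }
  invisible(x)
}

check_scalar_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    stop_invalid("`", name, "` must be a single integer >= ", min)
  }
  invisible(as.integer(x))
}

# quantile convention used throughout the package: order statistics with
# linear interpolation (stats::quantile type 7)
pct <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, na.rm = TRUE, names = FALSE)
}
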