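# Readers and writers for the package's delimited-text formats, plus the
# end-to-end pipeline driver. All formats are plain tab-separated text with
# a header row; lines starting with "#" carry metadata (sex, seed, ...).

fate_tokens <- c(death = "death", permanent_disappearance = "permanent_disappearance",
                 censored = "censored")

encode_pairs <- function(a, b) {
  if (!length(a)) return("")
  paste(paste(a, b, sep = ":"), collapse = ";")
}

decode_pairs <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(list(a = character(0), b = character(0)))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop_invalid("malformed pair encoding: ", s)
  list(a = vapply(parts, `[`, "", 1L), b = vapply(parts, `[`, "", 2L))
}

#' Write census records to a delimited text file
#'
#' One row per individual with tab-separated columns `id`, `sex`,
#' `entry_age`, `exit_age`, `fate`, `births`, `obs_fraction`. Birth events
#' are serialised as `age:sex` pairs joined by `;` (e.g. `4:F;6:M`), and
#' non-default observation fractions as `age:fraction` pairs; empty fields
#' mean no births / full observation.
#'
#' @param records a [census_records] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  ind <- records$individuals
  b <- records$births
  o <- records$obs
  enc_b <- rep("", nrow(ind))
  if (nrow(b)) {
    sx <- c(F = "F", M = "M", unknown = "U")[b$offspring_sex]
    sp <- split(seq_len(nrow(b)), factor(b$mother_id, levels = ind$id))
    has <- lengths(sp) > 0
    enc_b[has] <- vapply(sp[has], function(i) {
      ord <- i[order(b$mother_age[i])]
      encode_pairs(b$mother_age[ord], sx[ord])
    }, "")
  }
  enc_o <- rep("", nrow(ind))
  if (nrow(o)) {
    sp <- split(seq_len(nrow(o)), factor(o$id, levels = ind$id))
    has <- lengths(sp) > 0
    enc_o[has] <- vapply(sp[has], function(i) {
      ord <- i[order(o$age[i])]
      encode_pairs(o$age[ord], sprintf("%.17g", o$fraction[ord]))
    }, "")
  }
  out <- data.frame(id = ind$id, sex = ind$sex, entry_age = ind$entry_age,
                    exit_age = ind$exit_age, fate = ind$fate,
                    births = enc_b, obs_fraction = enc_o)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read census records from a delimited text file
#'
#' Parses the layout written by [write_records()], validating every row.
#' All malformed rows are collected and reported together with their line
#' numbers.
#'
#' @param path input file path.
#' @return A [census_records] object.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("integer", "character", "integer",
                                          "integer", "character", "character",
                                          "character"),
                           na.strings = NULL, quote = "", comment.char = "#")
  need <- c("id", "sex", "entry_age", "exit_age", "fate", "births", "obs_fraction")
  if (!all(need %in% names(raw))) {
    stop_invalid("records file must have columns: ", paste(need, collapse = ", "))
  }
  errs <- character(0)
  note <- function(i, msg) errs <<- c(errs, paste0("line ", i + 1L, ": ", msg))

  b_m <- integer(0); b_a <- integer(0); b_s <- character(0)
  o_i <- integer(0); o_a <- integer(0); o_f <- double(0)
  for (i in seq_len(nrow(raw))) {
    if (!raw$sex[i] %in% c("F", "M", "unknown")) note(i, "unknown sex token")
    if (!raw$fate[i] %in% fate_tokens) note(i, "unknown fate token")
    if (is.na(raw$entry_age[i]) || is.na(raw$exit_age[i]) ||
        raw$exit_age[i] < raw$entry_age[i]) {
      note(i, "exit_age < entry_age or missing ages")
    }
    pb <- tryCatch(decode_pairs(raw$births[i]), error = function(e) NULL)
    if (is.null(pb)) {
      note(i, "malformed births field")
    } else if (length(pb$a)) {
      sx <- c(F = "F", M = "M", U = "unknown")[pb$b]
      if (anyNA(sx)) note(i, "unknown offspring sex token")
      b_m <- c(b_m, rep(raw$id[i], length(pb$a)))
      b_a <- c(b_a, as.integer(pb$a))
      b_s <- c(b_s, unname(sx))
    }
    po <- tryCatch(decode_pairs(raw$obs_fraction[i]), error = function(e) NULL)
    if (is.null(po)) {
      note(i, "malformed obs_fraction field")
    } else if (length(po$a)) {
      fr <- as.numeric(po$b)
      if (anyNA(fr) || any(fr < 0 | fr > 1)) note(i, "observation fraction outside [0, 1]")
      o_i <- c(o_i, rep(raw$id[i], length(po$a)))
      o_a <- c(o_a, as.integer(po$a))
      o_f <- c(o_f, fr)
    }
  }
  if (length(errs)) {
    stop_invalid("invalid records in ", path, ":\n  ",
                 paste(utils::head(errs, 10), collapse = "\n  "),
                 if (length(errs) > 10) paste0("\n  ... and ", length(errs) - 10, " more"))
  }
  census_records(
    individuals = raw[c("id", "sex", "entry_age", "exit_age", "fate")],
    births = data.frame(mother_id = b_m, mother_age = b_a, offspring_sex = b_s),
    obs = data.frame(id = o_i, age = o_a, fraction = o_f)
  )
}

counts_canonical <- c("age", "entries", "deaths", "disappearances", "censored")
fertility_canonical <- c("weight_sum", "weighted_births", "weighted_sons",
                         "weighted_daughters", "n_mothers")

#' Write age-class count tables
#'
#' Emits a pre-binned count table in the deposited-life-table layout: one
#' row per one-year age class with columns `age`, `entries`, `deaths`,
#' `disappearances`, `censored`, plus — when fertility counts are supplied
#' for a female table — `weight_sum`, `weighted_births`, `weighted_sons`,
#' `weighted_daughters` and `n_mothers`. The sex is recorded on a `# sex:`
#' comment line.
#'
#' @param counts an [age_class_counts] object.
#' @param path output file path.
#' @param fertility optional `fertility_counts` with the same number of
#'   classes (female tables only).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, fertility = NULL) {
  df <- data.frame(age = seq_len(counts$n_classes) - 1L,
                   entries = counts$t, deaths = counts$d,
                   disappearances = counts$p, censored = counts$c)
  if (!is.null(fertility)) {
    if (fertility$n_classes != counts$n_classes) {
      stop_invalid("fertility counts and age-class counts differ in length")
    }
    df$weight_sum <- fertility$weight_sum
    df$weighted_births <- fertility$weighted_births
    df$weighted_sons <- fertility$weighted_sons
    df$weighted_daughters <- fertility$weighted_daughters
    df$n_mothers <- fertility$n_mothers
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# sex: ", counts$sex), con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read age-class count tables
#'
#' Parses the layout written by [write_counts()] (and, via `header_map`,
#' tables with alternative column headers, such as downloaded deposit
#' tables whose exact header strings differ).
#'
#' @param path input file path.
#' @param sex `"F"` or `"M"`; defaults to the `# sex:` comment in the file,
#'   or `"F"` when absent.
#' @param header_map optional named character vector mapping the file's
#'   headers to the canonical names (`c(Entries = "entries", ...)`).
#' @param strict if `TRUE`, an inconsistent at-risk recurrence (more exits
#'   than individuals present) is an error; by default the
#'   [age_class_counts] constructor raises it anyway because the at-risk
#'   numbers are recomputed.
#' @return A list with `counts` (an [age_class_counts]) and `fertility`
#'   (a `fertility_counts`, or `NULL` when the file has no fertility
#'   columns).
#' @export
read_counts <- function(path, sex = NULL, header_map = NULL, strict = TRUE) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  first <- readLines(path, n = 5L)
  sexline <- grep("^# *sex:", first, value = TRUE)
  if (is.null(sex)) {
    sex <- if (length(sexline)) trimws(sub("^# *sex:", "", sexline[1])) else "F"
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE)
  if (!is.null(header_map)) {
    hit <- names(df) %in% names(header_map)
    names(df)[hit] <- header_map[names(df)[hit]]
  }
  if (!all(counts_canonical %in% names(df))) {
    stop_invalid("counts file must have columns ",
                 paste(counts_canonical, collapse = ", "),
                 " (use `header_map` for other dialects)")
  }
  df <- df[order(df$age), , drop = FALSE]
  if (!identical(as.integer(df$age), seq_len(nrow(df)) - 1L)) {
    stop_invalid("age column must run 0, 1, 2, ... with no gaps")
  }
  counts <- age_class_counts(sex = sex, t = df$entries, d = df$deaths,
                             p = df$disappearances, c = df$censored)
  fert <- NULL
  if (all(fertility_canonical %in% names(df))) {
    check_nonneg(df$weight_sum, "weight_sum")
    check_nonneg(df$weighted_births, "weighted_births")
    fert <- structure(list(
      weighted_births = as.numeric(df$weighted_births),
      weight_sum = as.numeric(df$weight_sum),
      weighted_sons = as.numeric(df$weighted_sons),
      weighted_daughters = as.numeric(df$weighted_daughters),
      n_mothers = as.numeric(df$n_mothers),
      n_classes = nrow(df)
    ), class = "fertility_counts")
  }
  list(counts = counts, fertility = fert)
}

#' Write a life table as delimited text
#'
#' One row per age class with columns `x`, `N`, `c`, `dp`, `N_q`, `q`, `l`
#' (plus `m` and `N_m` for female tables with fertility); count columns are
#' included when the table was estimated from counts.
#'
#' @param lt a [life_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  df <- as.data.frame(lt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# sex: ", lt$sex), con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a life table written by [write_life_table()]
#'
#' @param path input file path.
#' @return A [life_table].
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  first <- readLines(path, n = 2L)
  sexline <- grep("^# *sex:", first, value = TRUE)
  sex <- if (length(sexline)) trimws(sub("^# *sex:", "", sexline[1])) else "F"
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  if (!all(c("x", "q", "l") %in% names(df))) {
    stop_invalid("life-table file must have columns x, q, l")
  }
  df <- df[order(df$x), , drop = FALSE]
  grab <- function(nm) if (nm %in% names(df)) df[[nm]] else NULL
  new_life_table(q = df$q, l = df$l, m = grab("m"),
                 N_q = grab("N_q"), N_m = grab("N_m"), N = grab("N"),
                 c = grab("c"), dp = grab("dp"),
                 omega = nrow(df) - 1L, sex = sex)
}

#' Write a Leslie matrix as delimited text
#'
#' Dense tab-separated matrix, one row per line, with age-class column
#' headers.
#'
#' @param A a Leslie matrix (see [build_leslie()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_leslie <- function(A, path) {
  colnames(A) <- paste0("age_", seq_len(ncol(A)) - 1L)
  utils::write.table(format(A, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a bootstrap envelope as delimited text
#'
#' Long format keyed by statistic and age class (`NA` age for the scalar
#' statistics), with the seed and replicate count recorded in the header.
#'
#' @param env a [bootstrap_envelope][bootstrap_ci].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(env, path) {
  scal <- data.frame(statistic = env$estimates$statistic, age = NA_integer_,
                     estimate = env$estimates$estimate,
                     lower = env$estimates$lower, upper = env$estimates$upper)
  per_age <- do.call(rbind, lapply(names(env$ages), function(nm) {
    cbind(statistic = nm, env$ages[[nm]])
  }))
  out <- rbind(scal, per_age[c("statistic", "age", "estimate", "lower", "upper")])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# n_reps: ", env$n_reps),
               paste0("# seed: ", env$seed),
               paste0("# conf_level: ", env$conf_level)), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
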