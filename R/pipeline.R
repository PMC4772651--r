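#' Pipeline run configuration
#'
#' Builds and validates the configuration of an end-to-end analysis run.
#' Exactly one input mode must be active: `simulate` (a [sim_config()] or a
#' bare list of its arguments), `records_path` (an individual-records file),
#' or `counts_path` (a pre-binned count table in the layout of
#' [write_counts()]; female and/or male, as a named list or single path).
#'
#' @param simulate optional [sim_config()] (or argument list) to generate
#'   the records.
#' @param records_path optional path to a records file ([read_records()]).
#' @param counts_path optional path(s) to count tables; a single path or a
#'   named list/vector with elements `F` and/or `M`.
#' @param sex which pipelines to run: `"F"`, `"M"` or `"both"`. Male runs
#'   stop after survivorship (no fertility, demography or bootstrap).
#' @param truncate_age optional truncation age for the male table (for
#'   example where older immigrant males have unreliable ages); applied to
#'   male tabulation only.
#' @param disappearances disappearance policy for mortality estimation:
#'   `"deaths"` (default) or `"censored"` (see [actuarial_mortality()]).
#' @param n_reps bootstrap replicates (default 4999).
#' @param seed seed for the bootstrap stream (the simulator uses the seed
#'   inside its own config).
#' @param known_age_afr_only restrict age-at-first-reproduction summaries to
#'   known-age females (see [age_first_reproduction()]).
#' @param out_dir output directory (created if needed).
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulate = NULL, records_path = NULL, counts_path = NULL,
                       sex = c("both", "F", "M"), truncate_age = NULL,
                       disappearances = c("deaths", "censored"),
                       n_reps = 4999L, seed = 1L,
                       known_age_afr_only = FALSE, out_dir = ".") {
  sex <- match.arg(sex)
  disappearances <- match.arg(disappearances)
  modes <- c(!is.null(simulate), !is.null(records_path), !is.null(counts_path))
  if (sum(modes) != 1L) {
    stop_invalid("exactly one of `simulate`, `records_path`, `counts_path` ",
                 "must be given")
  }
  if (!is.null(simulate) && !inherits(simulate, "sim_config")) {
    simulate <- do.call(sim_config, simulate)
  }
  if (!is.null(counts_path)) {
    counts_path <- as.list(counts_path)
    if (is.null(names(counts_path)) && length(counts_path) == 1L) {
      names(counts_path) <- if (sex == "M") "M" else "F"
    }
    if (!all(names(counts_path) %in% c("F", "M"))) {
      stop_invalid("`counts_path` must be named with elements F and/or M")
    }
  }
  n_reps <- check_scalar_count(n_reps, "n_reps", min = 1L)
  seed <- check_scalar_count(seed, "seed", min = 0L)
  structure(list(simulate = simulate, records_path = records_path,
                 counts_path = counts_path, sex = sex,
                 truncate_age = truncate_age,
                 disappearances = disappearances,
                 n_reps = n_reps, seed = seed,
                 known_age_afr_only = isTRUE(known_age_afr_only),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Flat key/value file mirroring the arguments of [run_config()]; the
#' `simulate` key holds the arguments of [sim_config()] as a nested map.
#' The format is chosen by file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path configuration file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = ,
                yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                stop_invalid("config must be .yaml, .yml or .json"))
  if (!is.null(cfg$simulate) && !is.null(cfg$simulate$obs_fraction_law)) {
    cfg$simulate$obs_fraction_law <- as.list(cfg$simulate$obs_fraction_law)
  }
  do.call(run_config, cfg)
}

pipeline_stage <- function(name, expr) {
  message("[", name, "] ...")
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full demographic pipeline
#'
#' Executes (as configured) simulate -> tabulate -> survival -> fertility ->
#' demography -> bootstrap, writing every product as delimited text (plus a
#' JSON summary) under `config$out_dir` and logging each stage. Male
#' pipelines stop after survivorship.
#'
#' @param config a [run_config()] object (or a path understood by
#'   [read_run_config()]).
#' @return Invisibly, a list with the computed objects (`records`, `counts`,
#'   `fertility`, `life_tables`, `leslie`, `summary`, `afr`, `sex_ratio`,
#'   `bootstrap`) and the written `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) {
    stop_invalid("`config` must be a run_config or a path to one")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  res <- list()

  records <- NULL
  counts <- list()
  fert <- NULL

  if (!is.null(config$simulate)) {
    records <- pipeline_stage("simulate", simulate_population(config$simulate))
    files["records"] <- write_records(records, out("records.tsv"))
    message("  ", nrow(records$individuals), " individuals (seed ",
            config$simulate$seed, ")")
  } else if (!is.null(config$records_path)) {
    records <- pipeline_stage("read_records", read_records(config$records_path))
  }

  want <- if (config$sex == "both") c("F", "M") else config$sex
  if (!is.null(records)) {
    for (s in want) {
      counts[[s]] <- pipeline_stage(paste0("tabulate_", s), {
        tabulate_counts(records, sex = s,
                        truncate_age = if (s == "M") config$truncate_age else NULL)
      })
    }
    if ("F" %in% want) {
      fert <- pipeline_stage("tabulate_fertility",
                             tabulate_fertility(records,
                                                n_classes = counts$F$n_classes))
    }
  } else {
    for (s in intersect(want, names(config$counts_path))) {
      got <- pipeline_stage(paste0("read_counts_", s),
                            read_counts(config$counts_path[[s]], sex = s))
      counts[[s]] <- got$counts
      if (s == "F") fert <- got$fertility
    }
    if (!length(counts)) stop_invalid("no count tables match the requested sex")
  }
  for (s in names(counts)) {
    f <- if (s == "F" && !is.null(fert)) fert else NULL
    files[paste0("counts_", s)] <-
      write_counts(counts[[s]], out(paste0("counts_", s, ".tsv")), fertility = f)
  }

  lts <- list()
  for (s in names(counts)) {
    lts[[s]] <- pipeline_stage(paste0("life_table_", s), {
      estimate_life_table(counts[[s]], disappearances = config$disappearances)
    })
  }

  summary_obj <- afr <- sr <- env <- leslie <- NULL
  if ("F" %in% names(lts)) {
    if (is.null(fert)) {
      message("[fertility] no fertility information: female run stops at survivorship")
    } else {
      lts$F <- pipeline_stage("fertility", add_fertility(lts$F, fert))
      if (!is.null(records)) {
        sr <- tryCatch(sex_ratio(records), error = function(e) NULL)
        afr <- tryCatch(
          age_first_reproduction(records,
                                 known_age_only = config$known_age_afr_only),
          error = function(e) NULL)
      }
      summary_obj <- pipeline_stage("demography",
                                    demographic_summary(lts$F, afr = afr))
      leslie <- build_leslie(lts$F)
      files["leslie"] <- write_leslie(leslie, out("leslie.tsv"))
      env <- pipeline_stage("bootstrap",
                            bootstrap_ci(lts$F, n_reps = config$n_reps,
                                         seed = config$seed))
      files["bootstrap"] <- write_envelope(env, out("bootstrap.tsv"))
      message("  ", config$n_reps, " replicates, seed ", config$seed)
    }
  }
  for (s in names(lts)) {
    files[paste0("life_table_", s)] <-
      write_life_table(lts[[s]], out(paste0("life_table_", s, ".tsv")))
  }

  summ <- list(
    sexes = names(lts),
    n_individuals = if (!is.null(records)) nrow(records$individuals) else NA,
    omega = lapply(lts, `[[`, "omega"),
    seed = config$seed,
    n_reps = if (!is.null(env)) env$n_reps else NA
  )
  if (!is.null(summary_obj)) {
    summ$R0 <- summary_obj$R0
    summ$generation_time <- summary_obj$G
    summ$lambda <- summary_obj$lambda
    summ$life_expectancy_at_birth <- summary_obj$e[1]
    summ$surv_to_median_afr <- summary_obj$surv_to_median_afr
  }
  if (!is.null(afr)) summ$median_afr <- afr$median
  if (!is.null(sr)) {
    summ$prop_female <- sr$prop_female
    summ$n_sexed <- sr$n_sexed
  }
  if (!is.null(env)) {
    summ$ci <- stats::setNames(
      lapply(seq_len(nrow(env$estimates)),
             function(i) list(lower = env$estimates$lower[i],
                              upper = env$estimates$upper[i])),
      env$estimates$statistic)
  }
  files["summary"] <- out("summary.json")
  jsonlite::write_json(summ, files["summary"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  message("[done] outputs in ", config$out_dir)

  invisible(list(records = records, counts = counts, fertility = fert,
                 life_tables = lts, leslie = leslie, summary = summary_obj,
                 afr = afr, sex_ratio = sr, bootstrap = env, files = files))
}
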