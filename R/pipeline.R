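# End-to-end driver: simulate -> clean -> analyze -> detect, with a YAML
# config, per-stage seeds and a reproducibility manifest.  Identical
# config + seeds give byte-identical TSV/JSON outputs.

#' Run the analysis pipeline
#'
#' Executes the stages requested in `config`, writing every product to
#' `out_dir` together with a manifest (`manifest.json`) holding the config
#' snapshot, the seeds, MD5 checksums of all inputs and outputs, the
#' package version and per-stage row counts.  Recognized config blocks:
#'
#' * `simulate_survey`: arguments for [survey_sim_config()], or
#'   `cohort_emulator: true` (+ `seed`) for [simulate_cohort_emulator()];
#'   writes `survey.csv`.
#' * `survey`: `input` (CSV path; defaults to the simulated survey),
#'   `min_age`, `max_uninformative`, `questions` (sex-comparison family),
#'   `age_question`, `n_perm`, `seed`; writes `cleaning_report.json`,
#'   `prevalences.tsv`, `sex_tests.tsv`, `parents.json` and, when
#'   `age_question` is set, `age_tests.tsv`.
#' * `simulate_airflow`: arguments for [trace_sim_config()] (`events` as a
#'   list of `[onset_s, relative_volume_change]` pairs); writes
#'   `trace.csv` and `true_events.json`.
#' * `sniff`: `input` (trace CSV; defaults to the simulated trace),
#'   `baseline_window`, `vol_threshold`, `sd_threshold`, `sd_method`;
#'   writes `sniff_events.tsv` and `sniff_summary.json`.
#'
#' Unknown block names, and a stage given both an `input` and a simulated
#' product, raise a config error.
#'
#' @param config a named list, or the path to a YAML file with one block
#'   per stage.
#' @param out_dir output directory (created if absent).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_config(sprintf("no such config: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a list or a YAML path")
  known <- c("simulate_survey", "survey", "simulate_airflow", "sniff")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop_config(sprintf("unknown stage(s) in config: %s",
                        paste(unknown, collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "sniffself",
                   version = as.character(utils::packageVersion("sniffself")),
                   config = config, stages = list(),
                   inputs = list(), outputs = list())
  paths <- character(0)
  survey_path <- NULL
  trace_path <- NULL

  if (!is.null(config$simulate_survey)) {
    blk <- config$simulate_survey
    tab <- if (isTRUE(blk$cohort_emulator)) {
      simulate_cohort_emulator(seed = blk$seed)
    } else {
      blk$cohort_emulator <- NULL
      simulate_survey(do.call(survey_sim_config, blk))
    }
    survey_path <- file.path(out_dir, "survey.csv")
    write_survey(tab, survey_path)
    paths <- c(paths, survey_path)
    manifest$stages$simulate_survey <- list(n_respondents = nrow(tab),
                                            seed = blk$seed)
  }

  if (!is.null(config$survey)) {
    blk <- config$survey
    if (!is.null(blk$input) && !is.null(config$simulate_survey)) {
      stop_config("survey stage given both an input file and a simulate block")
    }
    input <- blk$input %||% survey_path
    if (is.null(input)) stop_config("survey stage has no input")
    manifest$inputs$survey <- unname(tools::md5sum(input))
    tab <- read_survey(input)
    cleaned <- clean_survey(tab,
                            min_age = blk$min_age %||% 18,
                            max_uninformative = blk$max_uninformative %||% 5)
    jsonlite::write_json(unclass(cleaned$report),
                         file.path(out_dir, "cleaning_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    prev <- question_prevalences(cleaned$table)
    write_tsv(prev, file.path(out_dir, "prevalences.tsv"))
    fam <- blk$questions %||% paste0("q", 1:10)
    sex <- sex_comparison_family(cleaned$table, questions = fam,
                                 n_perm = blk$n_perm %||% 10000,
                                 seed = blk$seed)
    write_tsv(sex, file.path(out_dir, "sex_tests.tsv"))
    par <- parent_phase_summary(cleaned$table)
    par$age_freq <- as.list(par$age_freq)
    jsonlite::write_json(par, file.path(out_dir, "parents.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, file.path(out_dir, c("cleaning_report.json",
                                           "prevalences.tsv",
                                           "sex_tests.tsv", "parents.json")))
    if (!is.null(blk$age_question)) {
      grid <- age_comparison_grid(cleaned$table, blk$age_question,
                                  n_perm = blk$n_perm %||% 10000,
                                  seed = child_seed(blk$seed, 99))
      write_tsv(grid, file.path(out_dir, "age_tests.tsv"))
      paths <- c(paths, file.path(out_dir, "age_tests.tsv"))
    }
    manifest$stages$survey <- list(n_raw = cleaned$report$n_raw,
                                   n_retained = cleaned$report$n_retained,
                                   n_sex_tests = nrow(sex),
                                   seed = blk$seed)
  }

  if (!is.null(config$simulate_airflow)) {
    blk <- config$simulate_airflow
    if (!is.null(blk$events)) {
      ev <- blk$events
      if (!is.data.frame(ev)) {
        ev <- do.call(rbind, lapply(ev, function(e) {
          data.frame(onset_s = e[[1]], relative_volume_change = e[[2]])
        }))
      }
      blk$events <- ev
    }
    sim <- simulate_airflow(do.call(trace_sim_config, blk))
    trace_path <- file.path(out_dir, "trace.csv")
    write_trace(sim$trace, trace_path)
    jsonlite::write_json(sim$events, file.path(out_dir, "true_events.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    paths <- c(paths, trace_path, file.path(out_dir, "true_events.json"))
    manifest$stages$simulate_airflow <- list(n_samples = length(sim$trace$flow),
                                             n_events = nrow(sim$events),
                                             seed = blk$seed)
  }

  if (!is.null(config$sniff)) {
    blk <- config$sniff
    if (!is.null(blk$input) && !is.null(config$simulate_airflow)) {
      stop_config("sniff stage given both an input file and a simulate block")
    }
    input <- blk$input %||% trace_path
    if (is.null(input)) stop_config("sniff stage has no input")
    manifest$inputs$sniff <- unname(tools::md5sum(input))
    trace <- read_trace(input)
    events <- detect_sniffs(
      trace,
      baseline_window = unlist(blk$baseline_window),
      thresholds = list(vol = blk$vol_threshold %||% 0.15,
                        sd = blk$sd_threshold %||% 0.35),
      sd_method = blk$sd_method %||% "rolling")
    write_tsv(events, file.path(out_dir, "sniff_events.tsv"))
    jsonlite::write_json(list(n_events = nrow(events),
                              n_increase = sum(events$direction == "increase"),
                              n_decrease = sum(events$direction == "decrease")),
                         file.path(out_dir, "sniff_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, file.path(out_dir, c("sniff_events.tsv",
                                           "sniff_summary.json")))
    manifest$stages$sniff <- list(n_events = nrow(events))
  }

  if (!length(manifest$stages)) stop_config("config requests no stages")
  manifest$outputs <- as.list(tools::md5sum(paths))
  names(manifest$outputs) <- basename(paths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
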