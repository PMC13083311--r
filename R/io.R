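# Trial CSV dialect: comma-separated, UTF-8, header required, columns
# participant, condition, congruency, rt_ms, accuracy. Internal tibbles use
# `rt`; the `_ms` suffix documents the unit on disk.

.conditions <- c("FA", "OM", "C")
.congruencies <- c("congruent", "incongruent")

#' Write trials to CSV
#'
#' @param trials trial tibble (`participant`, `condition`, `congruency`,
#'   `rt`, `accuracy`; unresponded trials are dropped before writing).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  if ("responded" %in% names(trials)) {
    trials <- trials[trials$responded %in% TRUE, , drop = FALSE]
  }
  out <- tibble::tibble(participant = trials$participant,
                        condition = trials$condition,
                        congruency = trials$congruency,
                        rt_ms = trials$rt,
                        accuracy = trials$accuracy)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and validate a trial CSV
#'
#' Rejects files whose header does not match the documented dialect, and
#' rows with non-positive or missing RT, unknown condition or congruency
#' labels, or accuracy outside \{0, 1\} — reporting the offending file line
#' numbers (the header is line 1).
#'
#' @param path CSV file with columns `participant`, `condition`,
#'   `congruency`, `rt_ms`, `accuracy`.
#' @return A validated trial tibble with columns `participant`,
#'   `condition`, `congruency`, `rt`, `accuracy`, `responded` (always
#'   `TRUE`: the file format only carries responded trials).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  required <- c("participant", "condition", "congruency", "rt_ms",
                "accuracy")
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  missing <- setdiff(required, trimws(header))
  if (length(missing)) {
    stop("malformed trial file: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           participant = readr::col_character(),
                           condition = readr::col_character(),
                           congruency = readr::col_character(),
                           rt_ms = readr::col_double(),
                           accuracy = readr::col_double()))
  line <- seq_len(nrow(raw)) + 1L
  problems <- character(0)
  bad_rt <- which(is.na(raw$rt_ms) | raw$rt_ms <= 0)
  if (length(bad_rt)) {
    problems <- c(problems, paste0("non-positive or missing rt_ms on line(s) ",
                                   paste(line[bad_rt], collapse = ", ")))
  }
  bad_cond <- which(!raw$condition %in% .conditions)
  if (length(bad_cond)) {
    problems <- c(problems, paste0("unknown condition label on line(s) ",
                                   paste(line[bad_cond], collapse = ", ")))
  }
  bad_congr <- which(!raw$congruency %in% .congruencies)
  if (length(bad_congr)) {
    problems <- c(problems, paste0("unknown congruency label on line(s) ",
                                   paste(line[bad_congr], collapse = ", ")))
  }
  bad_acc <- which(!raw$accuracy %in% c(0, 1))
  if (length(bad_acc)) {
    problems <- c(problems, paste0("accuracy outside {0,1} on line(s) ",
                                   paste(line[bad_acc], collapse = ", ")))
  }
  if (length(problems)) {
    stop("malformed trial file '", path, "':\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  tibble::tibble(participant = raw$participant, condition = raw$condition,
                 congruency = raw$congruency, rt = raw$rt_ms,
                 accuracy = as.integer(raw$accuracy), responded = TRUE)
}

#' Pipeline configuration
#'
#' Flat key-value configuration driving [run_pipeline()]; serialisable to
#' YAML with [write_pipeline_config()]. Defaults equal the desk profile on
#' a small generated study.
#'
#' @param profile fitting profile, `"desk"` or `"study"`.
#' @param seed master seed for the run.
#' @param input_trials path to a trial CSV, or `NULL` to generate a
#'   synthetic study.
#' @param n_participants,trials_per_condition generator design (used when
#'   `input_trials` is `NULL`).
#' @param noise_stage run the observation-noise stage.
#' @param allow_long must be `TRUE` to run the `"study"` profile, which
#'   takes hours.
#' @param ... overrides passed to [fit_control()] (e.g. `n_starts`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = "desk", seed = 1L,
                            input_trials = NULL, n_participants = 8L,
                            trials_per_condition = 128L, noise_stage = TRUE,
                            allow_long = FALSE, ...) {
  structure(list(profile = profile, seed = as.integer(seed),
                 input_trials = input_trials,
                 n_participants = as.integer(n_participants),
                 trials_per_condition = as.integer(trials_per_condition),
                 noise_stage = isTRUE(noise_stage),
                 allow_long = isTRUE(allow_long),
                 control_overrides = list(...)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  flat <- config[names(config) != "control_overrides"]
  flat <- c(flat, config$control_overrides)
  flat <- flat[!vapply(flat, is.null, logical(1))]
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  flat <- yaml::read_yaml(path)
  known <- c("profile", "seed", "input_trials", "n_participants",
             "trials_per_condition", "noise_stage", "allow_long")
  args <- flat[intersect(names(flat), known)]
  extra <- flat[setdiff(names(flat), known)]
  do.call(pipeline_config, c(args, extra))
}

#' Run the full analysis pipeline
#'
#' Generate (or read) trials, run the hierarchical fit, compute
#' goodness-of-fit statistics, and run the condition analyses; write every
#' artifact plus a run manifest to `out_dir`. A rerun with the same
#' configuration and seed reproduces the estimates exactly.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the fitted `ssp_hierarchical`, the
#'   analysis tables, and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (config$profile == "study" && !config$allow_long) {
    stop("the 'study' profile runs thousands of multistart optimisations ",
         "and takes hours; set allow_long = TRUE to proceed",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  control <- do.call(fit_control,
                     c(list(profile = config$profile),
                       config$control_overrides))
  config_sim <- sim_config()
  seeds <- derive_seeds(config$seed, 2L)

  if (is.null(config$input_trials)) {
    message("stage generate: synthetic study, seed ", seeds[1])
    study <- generate_study(
      study_design(n_participants = config$n_participants,
                   trials_per_condition = config$trials_per_condition),
      config_sim, seed = seeds[1])
    trials <- study$trials
    readr::write_csv(study$truth, file.path(out_dir, "truth.csv"))
    write_trials(trials, file.path(out_dir, "trials.csv"))
  } else {
    message("stage read: ", config$input_trials)
    trials <- read_trials(config$input_trials)
  }

  message("stage fit: hierarchical estimation (profile ", config$profile,
          ", seed ", seeds[2], ")")
  fit <- fit_hierarchical(trials, control = control, config = config_sim,
                          seed = seeds[2], noise_stage = config$noise_stage)

  pop_row <- tibble::tibble(level = "population",
                            tibble::as_tibble(as.list(fit$population)))
  readr::write_csv(pop_row, file.path(out_dir, "population.csv"))
  readr::write_csv(
    tibble::tibble(condition = rownames(fit$condition_deltas),
                   tibble::as_tibble(as.data.frame(fit$condition_deltas))),
    file.path(out_dir, "condition_deltas.csv"))
  readr::write_csv(
    tibble::tibble(participant = rownames(fit$participant_deltas),
                   tibble::as_tibble(as.data.frame(fit$participant_deltas))),
    file.path(out_dir, "participant_deltas.csv"))
  readr::write_csv(fit$within_transformed,
                   file.path(out_dir, "within_transformed.csv"))
  if (!is.null(fit$observation_estimates)) {
    readr::write_csv(fit$observation_estimates,
                     file.path(out_dir, "observation_estimates.csv"))
  }

  message("stage analyze: condition effects")
  est <- estimates_long(fit, "within_transformed")
  anova_tab <- condition_anova_all(est, "within_transformed")
  readr::write_csv(anova_tab[, setdiff(names(anova_tab), "reports")],
                   file.path(out_dir, "condition_anova.csv"))
  ratio <- fit$within_transformed
  ratio_ok <- ratio$r_d > 0
  ratio_tab <- tibble::tibble(participant = ratio$participant[ratio_ok],
                              condition = ratio$condition[ratio_ok],
                              value = convergence_ratio(
                                ratio$sd_a0[ratio_ok], ratio$r_d[ratio_ok]))
  readr::write_csv(ratio_tab, file.path(out_dir, "convergence_ratio.csv"))

  manifest <- list(
    package = "sspflanker",
    version = as.character(packageVersion("sspflanker")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    profile = config$profile,
    seed = config$seed,
    stage_seeds = list(generate = seeds[1], fit = seeds[2]),
    control = control[c("n_starts", "n_sim_congruent", "n_sim_incongruent",
                        "maxit", "reltol", "floor_mult")],
    design = list(n_participants = config$n_participants,
                  trials_per_condition = config$trials_per_condition),
    input_trials = config$input_trials,
    gof = fit$gof,
    out_dir = out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(fit = fit, anova = anova_tab, ratio = ratio_tab,
                 manifest = manifest, out_dir = out_dir))
}
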