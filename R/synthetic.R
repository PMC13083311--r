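#' Condition parameter profiles for the synthetic study
#'
#' Per-condition SSP parameter means used as the generating values of the
#' synthetic-study module: initial spotlight width `sd_a0` of 0.42 (FA),
#' 4.63 (OM), 4.43 (C); shrink rate `r_d` of 0.001 (FA), 0.105 (OM),
#' 0.081 (C); nondecision mean of 271.2 (FA), 285.0 (OM), 273.0 (C) ms and
#' nondecision SD of 17.65 (FA), 31.42 (OM), 18.64 (C) ms. Perceptual input
#' (0.6) and boundary (60) are common to all three conditions, since no
#' condition differences arise on those parameters.
#'
#' @return A tibble with a `condition` column and the six parameter columns.
#' @export
default_condition_profiles <- function() {
  tibble::tibble(
    condition = c("FA", "OM", "C"),
    sd_a0 = c(0.42, 4.63, 4.43),
    r_d = c(0.001, 0.105, 0.081),
    p_input = c(0.6, 0.6, 0.6),
    boundary = c(60, 60, 60),
    ndt_mean = c(271.2, 285.0, 273.0),
    ndt_sd = c(17.65, 31.42, 18.64)
  )
}

# Lower clip applied to composed generating parameters, so every simulated
# observer has a valid, strictly positive parameter vector.
.gen_floor <- c(0.001, 1e-4, 0.01, 1, 1, 0.1)

#' Synthetic study design
#'
#' Defaults mirror the study structure: 29 participants, three
#' within-subject conditions (FA, OM, C), 512 trials per condition evenly
#' divided between congruent and incongruent. Between-participant
#' variability is a per-parameter SD applied as a zero-mean truncated-normal
#' baseline offset shared across a participant's three conditions; the
#' default SDs are half the start-distribution SDs.
#'
#' @param n_participants number of simulated participants.
#' @param trials_per_condition trials per participant-by-condition cell
#'   (half congruent).
#' @param condition_profiles tibble of per-condition generating parameters;
#'   see [default_condition_profiles()].
#' @param participant_sd per-parameter between-participant SDs.
#' @param truncation participant offsets are truncated at
#'   `truncation * participant_sd`.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_participants = 29L, trials_per_condition = 512L,
                         condition_profiles = default_condition_profiles(),
                         participant_sd = c(0.6, 0.025, 0.15, 15, 30, 10),
                         truncation = 2.5) {
  if (n_participants < 1L) stop("need at least one participant",
                                call. = FALSE)
  if (trials_per_condition < 2L || trials_per_condition %% 2L != 0L) {
    stop("trials_per_condition must be a positive even count", call. = FALSE)
  }
  structure(list(n_participants = as.integer(n_participants),
                 trials_per_condition = as.integer(trials_per_condition),
                 condition_profiles = condition_profiles,
                 participant_sd = as_param_vector(participant_sd),
                 truncation = truncation),
            class = "study_design")
}

#' Generate a synthetic flanker study
#'
#' Draws each participant's baseline parameter offset from zero-mean
#' truncated normals (shared across that participant's conditions),
#' composes participant-by-condition generating parameters as
#' `condition profile + offset` clipped to positive floors and the
#' observation-level upper bounds, and simulates every cell with the SSP
#' simulator. Returns both the trial table and the generating-truth table
#' so recovery can be scored.
#'
#' @param design a [study_design()].
#' @param config a [sim_config()].
#' @param seed RNG seed; the whole study is reproducible given the seed.
#' @return A list of class `ssp_study` with elements `trials` (tibble:
#'   `participant`, `condition`, `congruency`, `rt`, `accuracy`,
#'   `responded`), `truth` (tibble of generating parameters per cell, with
#'   a `clipped` flag and the cell simulation seed), and `censored_prop`
#'   (proportion of trials that never reached a boundary).
#' @export
generate_study <- function(design = study_design(), config = sim_config(),
                           seed = NULL) {
  seed <- resolve_seed(seed)
  set.seed(seed)
  profiles <- design$condition_profiles
  conditions <- profiles$condition
  pids <- sprintf("P%02d", seq_len(design$n_participants))
  n_half <- design$trials_per_condition %/% 2L

  offsets <- vapply(seq_len(6L), function(j) {
    s <- design$participant_sd[j]
    rtruncnorm_vec(design$n_participants, 0, s,
                   -design$truncation * s, design$truncation * s)
  }, numeric(design$n_participants))
  if (design$n_participants == 1L) offsets <- matrix(offsets, nrow = 1L)
  colnames(offsets) <- ssp_param_names

  cell_seeds <- matrix(
    sample.int(.Machine$integer.max, design$n_participants *
                 length(conditions)),
    nrow = design$n_participants)

  trial_rows <- list()
  truth_rows <- list()
  k <- 0L
  for (i in seq_len(design$n_participants)) {
    for (ci in seq_along(conditions)) {
      prof <- as.numeric(profiles[ci, ssp_param_names])
      raw <- prof + offsets[i, ]
      par <- pmin(pmax(raw, .gen_floor), .stage_upper)
      k <- k + 1L
      cell <- simulate_dataset(structure(as_param_vector(par),
                                         class = "ssp_parameters"),
                               n_half, n_half, config,
                               seed = cell_seeds[i, ci],
                               participant = pids[i],
                               condition = conditions[ci])
      trial_rows[[k]] <- cell
      truth_rows[[k]] <- tibble::tibble(
        participant = pids[i], condition = conditions[ci],
        tibble::as_tibble(as.list(as_param_vector(par))),
        clipped = any(raw != par), sim_seed = cell_seeds[i, ci])
    }
  }
  trials <- dplyr::bind_rows(trial_rows)
  structure(list(trials = trials,
                 truth = dplyr::bind_rows(truth_rows),
                 censored_prop = mean(!trials$responded),
                 design = design, seed = seed),
            class = "ssp_study")
}

#' @export
print.ssp_study <- function(x, ...) {
  cat(sprintf("Synthetic flanker study: %d participants x %d conditions x %d trials (%d total)\n",
              x$design$n_participants, nrow(x$design$condition_profiles),
              x$design$trials_per_condition, nrow(x$trials)))
  cat(sprintf("censored (no response): %.2f%%\n", 100 * x$censored_prop))
  invisible(x)
}
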