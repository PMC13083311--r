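#' Fitting control settings
#'
#' Bundles the optimiser and objective settings. Two named profiles are
#' provided: `"study"` reproduces the full study-scale procedure (100 starts,
#' 12,500 simulated trials per congruency per objective evaluation, up to
#' 500 Nelder-Mead iterations per start), and `"desk"` is a scaled-down
#' profile for interactive use and testing (5 starts, 1,250 simulated
#' trials per congruency, 150 iterations).
#'
#' @param profile `"desk"` or `"study"`.
#' @param n_starts number of Nelder-Mead starts.
#' @param n_sim_congruent,n_sim_incongruent simulated trials per congruency
#'   used to evaluate the objective.
#' @param maxit maximum Nelder-Mead iterations per simplex run (0 returns the
#'   best start unoptimised).
#' @param reltol relative convergence tolerance on the objective.
#' @param n_restarts simplex restarts after convergence, from the point just
#'   found (a fresh simplex escapes degenerate shrinkage on the rough
#'   common-random-number surface).
#' @param floor_mult predicted bin probabilities are floored at
#'   `1 / (floor_mult * n_sim)`.
#' @param penalty_weight weight of the quadratic out-of-bounds penalty.
#' @param penalty_scale per-parameter scale used to normalise bound
#'   violations (defaults to the stage start SDs).
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(profile = c("desk", "study"), n_starts = NULL,
                        n_sim_congruent = NULL, n_sim_incongruent = NULL,
                        maxit = NULL, reltol = NULL, n_restarts = 1L,
                        floor_mult = 10, penalty_weight = 1e4,
                        penalty_scale = .start_sds) {
  profile <- match.arg(profile)
  def <- switch(profile,
    study = list(n_starts = 100L, n_sim_congruent = 12500L,
                 n_sim_incongruent = 12500L, maxit = 500L, reltol = 1e-5),
    desk  = list(n_starts = 5L, n_sim_congruent = 1250L,
                 n_sim_incongruent = 1250L, maxit = 150L, reltol = 1e-4))
  structure(list(
    profile = profile,
    n_starts = as.integer(n_starts %||% def$n_starts),
    n_sim_congruent = as.integer(n_sim_congruent %||% def$n_sim_congruent),
    n_sim_incongruent = as.integer(n_sim_incongruent %||%
                                     def$n_sim_incongruent),
    maxit = as.integer(maxit %||% def$maxit),
    reltol = reltol %||% def$reltol,
    n_restarts = as.integer(n_restarts),
    floor_mult = floor_mult,
    penalty_weight = penalty_weight,
    penalty_scale = as_param_vector(penalty_scale)
  ), class = "fit_control")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

obs_for_cpp <- function(s) {
  list(n_total = as.integer(s$n_total),
       cdf_edges = as.numeric(s$cdf_edges),
       cdf_counts = as.integer(s$cdf_counts),
       caf_edges = as.numeric(s$caf_edges),
       caf_n = as.integer(s$caf_n),
       caf_k = as.integer(s$caf_k))
}

#' Fit SSP parameters to one dataset
#'
#' Multistart Nelder-Mead minimisation of the summed -2 log binomial
#' deviance between the dataset's CDF/CAF summary and proportions predicted
#' by simulating the model at each candidate. The objective is evaluated
#' with common random numbers: one simulation seed is fixed for the whole
#' fit, so the objective surface is deterministic and the best start is
#' comparable across starts.
#'
#' When `base` is supplied the candidate vector is a deviation (delta)
#' around it, and the simulated parameters are `base + delta` clamped to
#' `[0, stage_upper]`; candidates outside the bounds incur a quadratic
#' penalty on top of the objective at the clamped point.
#'
#' @param trials trial tibble (`congruency`, `rt`, `accuracy`, optionally
#'   `responded`); both congruency types must be present.
#' @param starts a [start_distribution()]; defaults to the population-stage
#'   distribution when `base` is `NULL` and to
#'   [delta_start_distribution()] around `base` otherwise.
#' @param base optional base parameter vector for deviation fits.
#' @param control a [fit_control()].
#' @param config a [sim_config()].
#' @param seed master seed for the fit (start draws + common-random-number
#'   simulation seed).
#' @return An object of class `ssp_fit`: list with `par` (best candidate,
#'   a deviation when `base` is given), `params` (composed, clamped
#'   parameter vector actually simulated), `objective`, `start_objectives`,
#'   `best_start`, `converged`, `n_starts_run`, `fit_stats` (from
#'   [chi_square_fit()]), `observed`, `sim_seed`.
#' @export
fit_dataset <- function(trials, starts = NULL, base = NULL,
                        control = fit_control(), config = sim_config(),
                        seed = NULL) {
  seed <- resolve_seed(seed)
  seeds <- derive_seeds(seed, 2L)
  absolute <- is.null(base)
  base <- if (absolute) rep(0, 6) else as_param_vector(base)
  if (is.null(starts)) {
    starts <- if (absolute) {
      start_distribution(n_starts = control$n_starts)
    } else {
      delta_start_distribution(base, n_starts = control$n_starts)
    }
  }
  observed <- summarize_trials(trials)
  obs_con <- obs_for_cpp(observed$congruent)
  obs_inc <- obs_for_cpp(observed$incongruent)
  sim_seed <- seeds[2]

  lower <- rep(0, 6)
  upper <- .stage_upper
  scale <- control$penalty_scale

  deviance_at <- function(raw) {
    clamped <- pmin(pmax(raw, lower), upper)
    pen <- control$penalty_weight * sum(((raw - clamped) / scale)^2)
    dev <- fit_objective_cpp(clamped, obs_con, obs_inc,
                             control$n_sim_congruent,
                             control$n_sim_incongruent,
                             config$sigma, config$dt, config$width_floor,
                             config$max_decision_time, as.double(sim_seed),
                             control$floor_mult)
    dev + pen
  }

  # The deviance valley runs along near-constant sd_a0 / r_d (the
  # trade-invariant convergence ratio), which defeats Nelder-Mead in raw
  # coordinates. The simplex therefore searches the composed vector in
  # (sd_a0, ratio, p_input, boundary, ndt_mean, ndt_sd) coordinates, where
  # the valley is axis-aligned; candidates map back to raw parameters for
  # simulation and bound penalties.
  to_internal <- function(raw) {
    ti <- raw
    ti[2] <- raw[1] / max(raw[2], 1e-9)
    ti
  }
  from_internal <- function(ti) {
    raw <- ti
    ratio <- ti[2]
    ratio <- if (ratio >= 0) max(ratio, 1e-6) else min(ratio, -1e-6)
    raw[2] <- ti[1] / ratio
    raw
  }
  internal_scale <- control$penalty_scale
  internal_scale[2] <- 40  # ratio coordinate, ms

  objective <- function(theta_int) deviance_at(from_internal(theta_int))

  start_mat <- draw_starts(starts, seed = seeds[1])
  n_starts <- nrow(start_mat)
  values <- numeric(n_starts)
  pars <- matrix(NA_real_, n_starts, 6L)
  conv <- integer(n_starts)
  failures <- character(0)
  for (i in seq_len(n_starts)) {
    start_int <- to_internal(base + start_mat[i, ])
    if (control$maxit == 0L) {
      pars[i, ] <- start_mat[i, ]
      values[i] <- objective(start_int)
      conv[i] <- 0L
      next
    }
    run_nm <- function(par0) {
      optim(par0, objective, method = "Nelder-Mead",
            control = list(maxit = control$maxit, reltol = control$reltol,
                           parscale = internal_scale))
    }
    res <- tryCatch({
      r <- run_nm(start_int)
      for (k in seq_len(control$n_restarts)) r <- run_nm(r$par)
      r
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      values[i] <- Inf
      conv[i] <- NA_integer_
    } else {
      pars[i, ] <- from_internal(res$par) - base
      values[i] <- res$value
      conv[i] <- res$convergence
    }
  }
  if (all(!is.finite(values))) {
    stop("optimisation failed on every start: ",
         paste(unique(failures), collapse = "; "), call. = FALSE)
  }
  best <- which.min(values)
  # polish the winning start with one more simplex round (same objective)
  if (control$maxit > 0L) {
    polish <- tryCatch(
      optim(to_internal(base + pars[best, ]), objective,
            method = "Nelder-Mead",
            control = list(maxit = control$maxit, reltol = control$reltol,
                           parscale = internal_scale)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= values[best]) {
      pars[best, ] <- from_internal(polish$par) - base
      values[best] <- polish$value
    }
  }
  par_best <- as_param_vector(pars[best, ])
  params <- pmin(pmax(base + par_best, lower), upper)

  sim_best <- simulate_trials(params, control$n_sim_congruent,
                              control$n_sim_incongruent, config, sim_seed)
  fit_stats <- chi_square_fit(observed, sim_best,
                              floor_mult = control$floor_mult)
  fit_stats$rmsea <- rmsea(fit_stats$chi_square, fit_stats$df,
                           fit_stats$n_observations)

  structure(list(par = par_best, params = params, objective = values[best],
                 start_objectives = values, best_start = best,
                 converged = conv[best] == 0L, n_starts_run = n_starts,
                 fit_stats = fit_stats, observed = observed,
                 sim_seed = sim_seed, seed = seed, control = control),
            class = "ssp_fit")
}

#' @export
print.ssp_fit <- function(x, ...) {
  cat(sprintf("SSP fit: deviance %.2f (best of %d starts)\n",
              x$objective, x$n_starts_run))
  print(round(x$params, 4))
  cat(sprintf("chi-square %.1f on %d df (%s fit)\n",
              x$fit_stats$chi_square, x$fit_stats$df,
              if (x$fit_stats$acceptable) "acceptable" else "poor"))
  invisible(x)
}

#' Population-stage fit
#'
#' Fits one parameter vector to all trials pooled across participants and
#' conditions, from the printed population start distribution.
#'
#' @param trials pooled trial tibble.
#' @inheritParams fit_dataset
#' @return An `ssp_fit`.
#' @export
fit_population <- function(trials, control = fit_control(),
                           config = sim_config(), seed = NULL) {
  fit_dataset(trials,
              starts = start_distribution(n_starts = control$n_starts),
              base = NULL, control = control, config = config, seed = seed)
}

fit_delta_group <- function(trials, group_col, base, control, config, seed) {
  groups <- sort(unique(trials[[group_col]]))
  seeds <- derive_seeds(resolve_seed(seed), length(groups))
  fits <- lapply(seq_along(groups), function(i) {
    sub <- trials[trials[[group_col]] == groups[i], , drop = FALSE]
    fit_dataset(sub,
                starts = delta_start_distribution(base,
                                                  n_starts = control$n_starts),
                base = base, control = control, config = config,
                seed = seeds[i])
  })
  names(fits) <- as.character(groups)
  fits
}

delta_matrix <- function(fits) {
  m <- do.call(rbind, lapply(fits, function(f) f$par))
  rownames(m) <- names(fits)
  m
}

#' Condition-stage deviation fits
#'
#' For each condition, fits a deviation vector around the population
#' parameters using only that condition's trials pooled across
#' participants; `population + delta` is constrained to `[0, stage_upper]`.
#'
#' @param trials trial tibble with a `condition` column.
#' @param population population parameter vector (from [fit_population()]).
#' @inheritParams fit_dataset
#' @return A list with `fits` (named list of `ssp_fit`) and `deltas`
#'   (matrix, one row per condition).
#' @export
fit_condition_deltas <- function(trials, population, control = fit_control(),
                                 config = sim_config(), seed = NULL) {
  fits <- fit_delta_group(trials, "condition", population, control, config,
                          seed)
  list(fits = fits, deltas = delta_matrix(fits))
}

#' Participant-stage deviation fits
#'
#' For each participant, independent of condition, fits a deviation vector
#' around the population parameters using that participant's trials pooled
#' across conditions.
#'
#' @param trials trial tibble with a `participant` column.
#' @inheritParams fit_condition_deltas
#' @return A list with `fits` and `deltas` (one row per participant).
#' @export
fit_participant_deltas <- function(trials, population,
                                   control = fit_control(),
                                   config = sim_config(), seed = NULL) {
  fits <- fit_delta_group(trials, "participant", population, control, config,
                          seed)
  list(fits = fits, deltas = delta_matrix(fits))
}

#' Observation-noise deviation fits
#'
#' For each participant-by-condition observation, fits a final deviation
#' around `population + delta_condition + delta_participant`. The composed
#' sum `population + delta_condition + delta_participant + delta_noise`,
#' clamped to `[0, stage_upper]`, is that observation's parameter estimate
#' and feeds the per-observation goodness-of-fit report.
#'
#' @param trials trial tibble with `participant` and `condition`.
#' @param population population parameter vector.
#' @param condition_deltas,participant_deltas delta matrices from the
#'   earlier stages.
#' @inheritParams fit_dataset
#' @return A list with `fits` (named `participant:condition`) and
#'   `estimates`, a tibble of per-observation parameter values and fit
#'   statistics.
#' @export
fit_observation_noise <- function(trials, population, condition_deltas,
                                  participant_deltas,
                                  control = fit_control(),
                                  config = sim_config(), seed = NULL) {
  obs_grid <- unique(trials[, c("participant", "condition")])
  obs_grid <- obs_grid[order(obs_grid$participant, obs_grid$condition), ]
  seeds <- derive_seeds(resolve_seed(seed), nrow(obs_grid))
  fits <- vector("list", nrow(obs_grid))
  rows <- vector("list", nrow(obs_grid))
  for (i in seq_len(nrow(obs_grid))) {
    pid <- as.character(obs_grid$participant[i])
    cond <- as.character(obs_grid$condition[i])
    sub <- trials[trials$participant == obs_grid$participant[i] &
                    trials$condition == obs_grid$condition[i], , drop = FALSE]
    base <- population + condition_deltas[cond, ] +
      participant_deltas[pid, ]
    fit <- fit_dataset(sub,
                       starts = delta_start_distribution(
                         base, n_starts = control$n_starts),
                       base = base, control = control, config = config,
                       seed = seeds[i])
    fits[[i]] <- fit
    rows[[i]] <- tibble::tibble(
      participant = pid, condition = cond,
      tibble::as_tibble(as.list(fit$params)),
      chi_square = fit$fit_stats$chi_square, df = fit$fit_stats$df,
      acceptable = fit$fit_stats$acceptable,
      n_trials = fit$fit_stats$n_observations,
      objective = fit$objective)
  }
  names(fits) <- paste(obs_grid$participant, obs_grid$condition, sep = ":")
  list(fits = fits, estimates = dplyr::bind_rows(rows))
}

#' Within-transformed per-observation values
#'
#' The elementwise sum `population + delta_condition + delta_participant`
#' for every participant-by-condition cell. These sums are not truncated to
#' the parameter bounds: they are intended for linear-model analyses that
#' assume untruncated (normal) values, not for simulation.
#'
#' @param population population parameter vector.
#' @param condition_deltas,participant_deltas delta matrices.
#' @param observations optional two-column tibble (`participant`,
#'   `condition`) restricting the grid; defaults to the full cross.
#' @return A tibble: `participant`, `condition`, and the six parameter
#'   columns.
#' @export
compose_within_transformed <- function(population, condition_deltas,
                                       participant_deltas,
                                       observations = NULL) {
  if (is.null(observations)) {
    observations <- expand.grid(participant = rownames(participant_deltas),
                                condition = rownames(condition_deltas),
                                stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(observations)), function(i) {
    pid <- as.character(observations$participant[i])
    cond <- as.character(observations$condition[i])
    val <- population + condition_deltas[cond, ] + participant_deltas[pid, ]
    tibble::tibble(participant = pid, condition = cond,
                   tibble::as_tibble(as.list(val)))
  })
  dplyr::bind_rows(rows)
}

#' Full hierarchical fit
#'
#' Runs the four estimation stages in sequence: (1) population parameters
#' on all pooled trials; (2) condition deviations, each condition pooled
#' across participants; (3) participant deviations, each participant pooled
#' across conditions; (4, optional) observation-noise deviations per
#' participant-by-condition cell, which also provide the per-observation
#' goodness-of-fit report.
#'
#' @param trials trial tibble with `participant`, `condition`,
#'   `congruency`, `rt`, `accuracy`.
#' @inheritParams fit_dataset
#' @param noise_stage run the observation-noise stage (default `TRUE`).
#' @param condition_control,participant_control,noise_control optional
#'   stage-specific [fit_control()] overrides; the condition stage often
#'   deserves a larger budget than the participant and noise stages since
#'   condition contrasts ride entirely on its deltas. Default to `control`.
#' @return An object of class `ssp_hierarchical`: population fit and
#'   vector, delta matrices, within-transformed estimate table,
#'   observation-level estimate table (when the noise stage runs) and a
#'   model-fit summary (`prop_acceptable`, pooled `rmsea`).
#' @export
fit_hierarchical <- function(trials, control = fit_control(),
                             config = sim_config(), seed = NULL,
                             noise_stage = TRUE,
                             condition_control = control,
                             participant_control = control,
                             noise_control = control) {
  seed <- resolve_seed(seed)
  seeds <- derive_seeds(seed, 4L)
  pop_fit <- fit_population(trials, control, config, seeds[1])
  population <- pop_fit$params
  cond <- fit_condition_deltas(trials, population, condition_control,
                               config, seeds[2])
  part <- fit_participant_deltas(trials, population, participant_control,
                                 config, seeds[3])
  within <- compose_within_transformed(
    population, cond$deltas, part$deltas,
    observations = unique(trials[, c("participant", "condition")]))
  noise <- NULL
  gof <- NULL
  if (noise_stage) {
    noise <- fit_observation_noise(trials, population, cond$deltas,
                                   part$deltas, noise_control, config,
                                   seeds[4])
    est <- noise$estimates
    gof <- list(prop_acceptable = mean(est$acceptable),
                rmsea = pooled_rmsea(est$chi_square, est$df, est$n_trials))
  }
  structure(list(population_fit = pop_fit, population = population,
                 condition_deltas = cond$deltas,
                 participant_deltas = part$deltas,
                 condition_fits = cond$fits, participant_fits = part$fits,
                 noise = noise, within_transformed = within,
                 observation_estimates = if (!is.null(noise)) noise$estimates,
                 gof = gof, seed = seed, control = control),
            class = "ssp_hierarchical")
}

#' @export
print.ssp_hierarchical <- function(x, ...) {
  cat("Hierarchical SSP fit\n")
  cat("population: ")
  cat(paste(sprintf("%s=%.3f", ssp_param_names, x$population),
            collapse = ", "), "\n")
  cat("conditions:", paste(rownames(x$condition_deltas), collapse = ", "),
      " participants:", nrow(x$participant_deltas), "\n")
  if (!is.null(x$gof)) {
    cat(sprintf("fit: %.1f%% observations acceptable, pooled RMSEA %.4f\n",
                100 * x$gof$prop_acceptable, x$gof$rmsea))
  }
  invisible(x)
}

#' Long-format estimates for analysis
#'
#' @param fit an `ssp_hierarchical`.
#' @param level `"within_transformed"` (population + condition +
#'   participant sums) or `"observation"` (noise-stage sums, bounded).
#' @return A tibble `participant`, `condition`, `parameter`, `value`.
#' @export
estimates_long <- function(fit,
                           level = c("within_transformed", "observation")) {
  level <- match.arg(level)
  wide <- switch(level,
    within_transformed = fit$within_transformed,
    observation = {
      if (is.null(fit$observation_estimates)) {
        stop("observation-level estimates unavailable: the noise stage ",
             "was not run", call. = FALSE)
      }
      fit$observation_estimates[, c("participant", "condition",
                                    ssp_param_names)]
    })
  tidyr::pivot_longer(wide, cols = dplyr::all_of(ssp_param_names),
                      names_to = "parameter", values_to = "value")
}
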