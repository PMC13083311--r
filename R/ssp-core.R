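#' Spotlight width at time t
#'
#' The attentional spotlight starts at `sd_a0` and narrows linearly at rate
#' `r_d` per millisecond, never dropping below `floor` (the minimum
#' attentional window).
#'
#' @param t time since stimulus onset (ms); vectorised.
#' @param sd_a0 initial spotlight standard deviation (> 0).
#' @param r_d shrink rate (width/ms, >= 0).
#' @param floor minimum width (default 0.001).
#' @return Spotlight SD at each `t`.
#' @examples
#' spotlight_width(c(0, 100), sd_a0 = 1.8, r_d = 0.017)
#' @export
spotlight_width <- function(t, sd_a0, r_d, floor = 0.001) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (sd_a0 <= 0) stop("sd_a0 must be positive", call. = FALSE)
  if (r_d < 0) stop("r_d must be non-negative", call. = FALSE)
  if (floor <= 0) stop("floor must be positive", call. = FALSE)
  pmax(sd_a0 - r_d * t, floor)
}

#' Item activations under a Gaussian spotlight
#'
#' The five-arrow array occupies unit-width slots centred at 0 (target),
#' +/-1 (inner flankers) and +/-2 (outer flankers). Each item's activation is
#' the normal-CDF mass of the attentional window (mean 0, SD `sd`) over its
#' slot: \[-Inf,-1.5\], \[-1.5,-0.5\], \[-0.5,0.5\], \[0.5,1.5\], \[1.5,Inf\].
#' The five activations sum to 1 for every width.
#'
#' @param sd spotlight standard deviation(s), > 0; vectorised.
#' @return A numeric matrix with one row per `sd` and columns `outer_left`,
#'   `inner_left`, `target`, `inner_right`, `outer_right`.
#' @examples
#' activations(1)  # target activation 2*pnorm(0.5) - 1
#' @export
activations <- function(sd) {
  if (any(sd <= 0)) stop("sd must be positive", call. = FALSE)
  outer <- pnorm(-1.5, mean = 0, sd = sd)
  inner <- pnorm(-0.5, mean = 0, sd = sd) - outer
  target <- 1 - 2 * (outer + inner)
  cbind(outer_left = outer, inner_left = inner, target = target,
        inner_right = inner, outer_right = outer)
}

#' Drift rate of the SSP diffusion process
#'
#' Total drift is the activation-weighted sum of items times the perceptual
#' input P, with nontarget contributions signed positive on congruent trials
#' and negative on incongruent trials. Because activations sum to 1,
#' congruent drift equals `p_input` exactly at any width; incongruent drift
#' is `p_input * (2 * a_target - 1)`, rising towards `p_input` as the
#' spotlight narrows.
#'
#' @param sd spotlight SD(s), > 0; vectorised.
#' @param congruency `"congruent"` or `"incongruent"`.
#' @param p_input perceptual input strength (> 0).
#' @return Drift rate (evidence units per ms) for each `sd`.
#' @export
ssp_drift <- function(sd, congruency, p_input) {
  if (any(sd <= 0)) stop("sd must be positive", call. = FALSE)
  if (p_input <= 0) stop("p_input must be positive", call. = FALSE)
  congruency <- match.arg(congruency, c("congruent", "incongruent"))
  a <- activations(sd)
  if (congruency == "congruent") {
    rep_len(p_input, length(sd))
  } else {
    unname(p_input * (2 * a[, "target"] - 1))
  }
}

#' Simulate SSP flanker trials
#'
#' Evidence starts at 0 and accumulates in steps of `dt` ms with mean
#' `drift(t) * dt` and SD `sigma * sqrt(dt)`. The first step at which the
#' accumulator reaches +boundary (correct) or -boundary (error) sets the
#' decision time; response time adds a nondecision draw from a normal with
#' mean `ndt_mean` and SD `ndt_sd`, truncated at zero. Trials that reach
#' neither boundary by `max_decision_time` are returned unresponded with
#' `NA` rt and accuracy.
#'
#' @param params an [ssp_parameters()] vector (or bare numeric of length 6 in
#'   the same order).
#' @param n_congruent,n_incongruent trial counts per congruency.
#' @param config a [sim_config()].
#' @param seed RNG seed; `NULL` draws one from the R session stream so the
#'   call remains reproducible under `set.seed()`.
#' @return A tibble with columns `congruency`, `rt` (ms), `accuracy` (0/1)
#'   and `responded`.
#' @examples
#' p <- ssp_parameters(1.8, 0.017, 0.6, 60, 250, 30)
#' trials <- simulate_trials(p, 100, 100, seed = 1)
#' mean(trials$accuracy[trials$congruency == "congruent"])
#' @export
simulate_trials <- function(params, n_congruent, n_incongruent,
                            config = sim_config(), seed = NULL) {
  validate_ssp_parameters(unclass(params))
  if (n_congruent < 0 || n_incongruent < 0) {
    stop("trial counts must be non-negative", call. = FALSE)
  }
  seed <- resolve_seed(if (is.null(seed)) config$seed else seed)
  raw <- simulate_trials_cpp(as.numeric(params), as.integer(n_congruent),
                             as.integer(n_incongruent), config$sigma,
                             config$dt, config$width_floor,
                             config$max_decision_time, as.double(seed))
  tibble::tibble(
    congruency = ifelse(raw$congruent, "congruent", "incongruent"),
    rt = raw$rt,
    accuracy = raw$accuracy,
    responded = raw$responded == 1L
  )
}

#' Simulate a single trial
#'
#' Convenience wrapper around [simulate_trials()] for one trial.
#'
#' @inheritParams simulate_trials
#' @param congruency `"congruent"` or `"incongruent"`.
#' @return A one-row tibble (`congruency`, `rt`, `accuracy`, `responded`).
#' @export
simulate_trial <- function(params, congruency, config = sim_config(),
                           seed = NULL) {
  congruency <- match.arg(congruency, c("congruent", "incongruent"))
  n_con <- as.integer(congruency == "congruent")
  simulate_trials(params, n_con, 1L - n_con, config, seed)
}

#' Simulate a labelled trial dataset
#'
#' As [simulate_trials()], but attaches participant and condition labels so
#' the result can feed the fitting pipeline or be written with
#' [write_trials()].
#'
#' @inheritParams simulate_trials
#' @param participant participant label.
#' @param condition condition label (`"FA"`, `"OM"` or `"C"`).
#' @return A tibble with columns `participant`, `condition`, `congruency`,
#'   `rt`, `accuracy`, `responded`.
#' @export
simulate_dataset <- function(params, n_congruent, n_incongruent,
                             config = sim_config(), seed = NULL,
                             participant = "P01", condition = "C") {
  trials <- simulate_trials(params, n_congruent, n_incongruent, config, seed)
  tibble::tibble(participant = participant, condition = condition, trials)
}

#' Per-step drift schedule
#'
#' Drift rate at every time step given a linearly shrinking spotlight;
#' mirrors the schedule the simulator uses internally (step k covers
#' \[(k-1) dt, k dt) and uses the width at its start).
#'
#' @inheritParams simulate_trials
#' @param congruency `"congruent"` or `"incongruent"`.
#' @return Numeric vector of drift rates (per ms), one per step.
#' @export
drift_schedule <- function(params, congruency, config = sim_config()) {
  validate_ssp_parameters(unclass(params))
  congruency <- match.arg(congruency, c("congruent", "incongruent"))
  n_steps <- ceiling(config$max_decision_time / config$dt)
  p <- as_param_vector(params)
  drift_schedule_cpp(p[["sd_a0"]], p[["r_d"]], p[["p_input"]],
                     congruency == "congruent", as.integer(n_steps),
                     config$dt, config$width_floor)
}
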