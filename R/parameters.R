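#' Canonical SSP parameter names
#'
#' Order used by every function that accepts or returns a parameter vector:
#' `sd_a0` (initial spotlight SD, stimulus-width units, target width = 1),
#' `r_d` (linear shrink rate, width/ms), `p_input` (perceptual input P,
#' evidence per ms per unit activation), `boundary` (decision boundary b),
#' `ndt_mean` (mean nondecision time, ms), `ndt_sd` (nondecision-time SD, ms).
#'
#' @export
ssp_param_names <- c("sd_a0", "r_d", "p_input", "boundary", "ndt_mean", "ndt_sd")

# Upper bounds on composed (population + deltas) values at every hierarchical
# stage; lower bound is 0 for all six parameters.
.stage_upper <- c(6.0, 0.2, 5.0, 200, 450, 90)

# Population-stage start distribution (truncated normals).
.start_means <- c(1.8, 0.017, 0.6, 60, 250, 30)
.start_sds   <- c(1.2, 0.05, 0.3, 30, 60, 20)
.start_lower <- c(0.8, 0.005, 0.2, 20, 175, 10)
.start_upper <- c(4.0, 0.15, 2.0, 150, 375, 50)

#' Construct an SSP parameter vector
#'
#' All six parameters are constrained to be strictly positive.
#'
#' @param sd_a0 initial attentional spotlight standard deviation
#'   (stimulus-width units; the target subtends \[-0.5, 0.5\]).
#' @param r_d spotlight shrink rate (width units per ms).
#' @param p_input perceptual input strength P (evidence per ms per unit
#'   activation).
#' @param boundary decision boundary b (evidence units); responses are
#'   triggered at +b (correct) or -b (error).
#' @param ndt_mean mean nondecision time (ms).
#' @param ndt_sd nondecision-time variability (ms; SD of a zero-truncated
#'   normal).
#' @return A named numeric vector of class `ssp_parameters`.
#' @examples
#' ssp_parameters(1.8, 0.017, 0.6, 60, 250, 30)
#' @export
ssp_parameters <- function(sd_a0, r_d, p_input, boundary, ndt_mean, ndt_sd) {
  p <- c(sd_a0 = sd_a0, r_d = r_d, p_input = p_input, boundary = boundary,
         ndt_mean = ndt_mean, ndt_sd = ndt_sd)
  validate_ssp_parameters(p)
  structure(p, class = "ssp_parameters")
}

validate_ssp_parameters <- function(p) {
  if (length(p) != 6L || anyNA(p) || !is.numeric(p)) {
    stop("SSP parameters must be six finite numbers: ",
         paste(ssp_param_names, collapse = ", "), call. = FALSE)
  }
  if (any(p <= 0)) {
    bad <- ssp_param_names[p <= 0]
    stop("SSP parameters must be strictly positive; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(p)
}

#' @export
print.ssp_parameters <- function(x, ...) {
  cat("SSP parameters:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

# Coerce a bare numeric vector (e.g. an optimizer candidate) into the named
# layout without the positivity check; internal use only.
as_param_vector <- function(p) {
  stopifnot(length(p) == 6L)
  stats::setNames(as.numeric(p), ssp_param_names)
}

#' Simulation configuration
#'
#' @param sigma within-trial diffusion noise, SD of the per-step increment at
#'   `dt = 1` ms. Fixed at 7.0 as a scaling constant: drift, boundary and
#'   sigma are not jointly identifiable, so sigma only sets the unit. At other
#'   step sizes the per-step SD is `sigma * sqrt(dt)`.
#' @param dt time step (ms).
#' @param width_floor minimum spotlight width; the spotlight never shrinks
#'   below this (default 0.001).
#' @param max_decision_time censoring horizon for the decision process (ms).
#'   Defaults to the 950-ms response window of the task; trials that fail to
#'   reach a boundary are flagged unresponded.
#' @param seed optional default RNG seed for simulation calls.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sigma = 7, dt = 1, width_floor = 0.001,
                       max_decision_time = 950, seed = NULL) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (width_floor <= 0) stop("width_floor must be positive", call. = FALSE)
  if (max_decision_time <= 0) {
    stop("max_decision_time must be positive", call. = FALSE)
  }
  structure(list(sigma = sigma, dt = dt, width_floor = width_floor,
                 max_decision_time = max_decision_time, seed = seed),
            class = "sim_config")
}

# One reproducible 31-bit seed, either from the user or from the R RNG stream.
resolve_seed <- function(seed) {
  if (is.null(seed)) sample.int(.Machine$integer.max, 1L) else as.integer(seed)
}

# n child seeds derived deterministically from one parent seed.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
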