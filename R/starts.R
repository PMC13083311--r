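#' Start distribution for multistart optimisation
#'
#' Truncated-normal distributions from which Nelder-Mead starting vectors
#' are drawn. Defaults are the population-stage values: means
#' `[1.8, 0.017, 0.6, 60, 250, 30]`, SDs `[1.2, 0.05, 0.3, 30, 60, 20]`,
#' lower bounds `[0.8, 0.005, 0.2, 20, 175, 10]` and upper bounds
#' `[4.0, 0.15, 2.0, 150, 375, 50]`.
#'
#' @param means,sds,lower,upper per-parameter truncated-normal moments and
#'   truncation bounds.
#' @param n_starts number of start vectors to draw (default 100).
#' @return A list of class `start_distribution`.
#' @export
start_distribution <- function(means = .start_means, sds = .start_sds,
                               lower = .start_lower, upper = .start_upper,
                               n_starts = 100L) {
  stopifnot(length(means) == 6L, length(sds) == 6L,
            length(lower) == 6L, length(upper) == 6L)
  if (any(lower > upper)) stop("lower must not exceed upper", call. = FALSE)
  if (any(sds < 0)) stop("sds must be non-negative", call. = FALSE)
  structure(list(means = as_param_vector(means), sds = as_param_vector(sds),
                 lower = as_param_vector(lower),
                 upper = as_param_vector(upper),
                 n_starts = as.integer(n_starts)),
            class = "start_distribution")
}

#' Start distribution for deviation (delta) stages
#'
#' Zero-mean truncated normals with the stage SDs `[1.2, 0.05, 0.3, 30, 60,
#' 20]`, truncated so that `base + delta` stays within `[0, stage_upper]`
#' where `stage_upper = [6.0, 0.2, 5.0, 200, 450, 90]`.
#'
#' @param base the composed parameter vector the deltas deviate around
#'   (population, or population + earlier deltas).
#' @param n_starts number of start vectors (default 100).
#' @param stage_upper upper bounds on the composed values.
#' @return A `start_distribution`.
#' @export
delta_start_distribution <- function(base, n_starts = 100L,
                                     stage_upper = .stage_upper) {
  base <- as_param_vector(base)
  start_distribution(means = rep(0, 6), sds = .start_sds,
                     lower = pmin(-base, stage_upper - base),
                     upper = stage_upper - base, n_starts = n_starts)
}

# Truncated-normal draws by rejection, falling back to inverse-CDF sampling
# if the truncation interval holds almost no normal mass.
rtruncnorm_vec <- function(n, mean, sd, lower, upper) {
  if (sd == 0 || lower == upper) {
    return(rep(min(max(mean, lower), upper), n))
  }
  out <- numeric(0)
  for (round in 1:50) {
    draw <- rnorm(n * 2L, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Draw start vectors
#'
#' @param dist a [start_distribution()].
#' @param seed RNG seed (`NULL` uses the session stream).
#' @return A matrix with `n_starts` rows and six named columns, every entry
#'   inside the distribution's bounds.
#' @export
draw_starts <- function(dist, seed = NULL) {
  stopifnot(inherits(dist, "start_distribution"))
  if (!is.null(seed)) set.seed(seed)
  m <- vapply(seq_len(6L), function(j) {
    rtruncnorm_vec(dist$n_starts, dist$means[j], dist$sds[j],
                   dist$lower[j], dist$upper[j])
  }, numeric(dist$n_starts))
  if (dist$n_starts == 1L) m <- matrix(m, nrow = 1L)
  colnames(m) <- ssp_param_names
  m
}
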