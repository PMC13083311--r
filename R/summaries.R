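#' Default quantile grids for the fitting targets
#'
#' CDF sextile probabilities (0.1, 0.3, 0.5, 0.7, 0.9, 1) applied to
#' correct-response RTs, and CAF quartile probabilities (0.25, 0.5, 0.75, 1)
#' applied to all responded RTs. The final probability 1 closes the top bin
#' at the maximum RT.
#'
#' @name summary_probs
#' @export
cdf_probs_default <- c(0.1, 0.3, 0.5, 0.7, 0.9, 1)

#' @rdname summary_probs
#' @export
caf_probs_default <- c(0.25, 0.5, 0.75, 1)

# Bin index under the rule "bin j is (edge_{j-1}, edge_j]"; values above the
# last edge land in the final bin. Matches the compiled core's binning.
bin_index <- function(x, edges) {
  findInterval(x, edges, left.open = TRUE) + 1L
}

summarize_one_type <- function(rt, accuracy, trial_type, cdf_probs, caf_probs) {
  n_total <- length(rt)
  if (n_total == 0L) {
    stop("no responded trials for trial type '", trial_type, "'",
         call. = FALSE)
  }
  correct_rt <- rt[accuracy == 1]
  if (length(correct_rt) == 0L) {
    stop("no correct trials for trial type '", trial_type,
         "'; CDF quantiles undefined", call. = FALSE)
  }
  cdf_edges <- unname(quantile(correct_rt, probs = head(cdf_probs, -1)))
  caf_edges <- unname(quantile(rt, probs = head(caf_probs, -1)))

  cdf_bin <- bin_index(correct_rt, cdf_edges)
  cdf_counts <- tabulate(cdf_bin, nbins = length(cdf_probs))

  caf_bin <- bin_index(rt, caf_edges)
  caf_n <- tabulate(caf_bin, nbins = length(caf_probs))
  caf_k <- tabulate(caf_bin[accuracy == 1], nbins = length(caf_probs))

  list(trial_type = trial_type,
       n_total = n_total,
       n_correct = length(correct_rt),
       cdf_edges = cdf_edges,
       cdf_counts = cdf_counts,
       caf_edges = caf_edges,
       caf_n = caf_n,
       caf_k = caf_k,
       caf_accuracy = ifelse(caf_n > 0, caf_k / caf_n, NA_real_))
}

#' Distributional summary of flanker trials
#'
#' Computes, per trial type (congruent, incongruent), the fitting targets:
#' RT quantile (CDF) bin edges and correct counts, and conditional accuracy
#' function (CAF) quartile bins with per-bin accuracy. CDF bins are built
#' from correct-response RTs; error information enters through the CAF
#' cells.
#'
#' @param trials a tibble/data frame with columns `congruency`, `rt`,
#'   `accuracy`, and optionally `responded` (unresponded trials are dropped).
#' @param cdf_probs,caf_probs quantile probability grids; defaults
#'   [cdf_probs_default] and [caf_probs_default].
#' @return An object of class `ssp_summary`: a list with elements
#'   `congruent` and `incongruent` (each holding edges, counts and
#'   accuracies) plus the probability grids.
#' @examples
#' p <- ssp_parameters(1.8, 0.017, 0.6, 60, 250, 30)
#' summarize_trials(simulate_trials(p, 500, 500, seed = 1))
#' @export
summarize_trials <- function(trials, cdf_probs = cdf_probs_default,
                             caf_probs = caf_probs_default) {
  stopifnot(all(c("congruency", "rt", "accuracy") %in% names(trials)))
  if ("responded" %in% names(trials)) {
    trials <- trials[trials$responded %in% TRUE, , drop = FALSE]
  }
  if (anyNA(trials$rt) || anyNA(trials$accuracy)) {
    stop("responded trials must have finite rt and accuracy", call. = FALSE)
  }
  out <- list()
  for (type in c("congruent", "incongruent")) {
    sel <- trials$congruency == type
    out[[type]] <- summarize_one_type(trials$rt[sel], trials$accuracy[sel],
                                      type, cdf_probs, caf_probs)
  }
  structure(c(out, list(cdf_probs = cdf_probs, caf_probs = caf_probs)),
            class = "ssp_summary")
}

#' @export
print.ssp_summary <- function(x, ...) {
  for (type in c("congruent", "incongruent")) {
    s <- x[[type]]
    cat(sprintf("%s: n = %d (correct %d)\n", type, s$n_total, s$n_correct))
    cat("  CDF edges (ms): ", paste(round(s$cdf_edges, 1), collapse = ", "),
        "\n", sep = "")
    cat("  CAF accuracy:   ", paste(round(s$caf_accuracy, 3), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Tabular form of a distribution summary
#'
#' One row per bin (CDF and CAF components), suitable for writing to
#' delimited text.
#'
#' @param summary an `ssp_summary`.
#' @return A tibble with columns `trial_type`, `component`, `bin`,
#'   `upper_edge`, `n`, `count`, `proportion`.
#' @export
summary_table <- function(summary) {
  rows <- lapply(c("congruent", "incongruent"), function(type) {
    s <- summary[[type]]
    cdf <- tibble::tibble(
      trial_type = type, component = "cdf",
      bin = seq_along(s$cdf_counts),
      upper_edge = c(s$cdf_edges, Inf),
      n = s$n_total, count = s$cdf_counts,
      proportion = s$cdf_counts / s$n_total)
    caf <- tibble::tibble(
      trial_type = type, component = "caf",
      bin = seq_along(s$caf_n),
      upper_edge = c(s$caf_edges, Inf),
      n = s$caf_n, count = s$caf_k,
      proportion = s$caf_accuracy)
    dplyr::bind_rows(cdf, caf)
  })
  dplyr::bind_rows(rows)
}

# Classify simulated trials of one type into an observed summary's bins and
# return floored model probabilities.
predict_one_type <- function(obs, rt, accuracy, floor_mult = 10) {
  n_sim <- length(rt)
  if (n_sim == 0L) stop("simulated set is empty", call. = FALSE)
  p_floor <- 1 / (floor_mult * n_sim)
  clamp <- function(p) pmin(pmax(p, p_floor), 1 - p_floor)

  cdf_bin <- bin_index(rt[accuracy == 1], obs$cdf_edges)
  pi_cdf <- clamp(tabulate(cdf_bin, length(obs$cdf_counts)) / n_sim)

  caf_bin <- bin_index(rt, obs$caf_edges)
  sim_caf_n <- tabulate(caf_bin, length(obs$caf_n))
  sim_caf_k <- tabulate(caf_bin[accuracy == 1], length(obs$caf_n))
  pi_caf <- ifelse(sim_caf_n > 0, clamp(sim_caf_k / pmax(sim_caf_n, 1)), 0.5)

  # Ten-cell partition of all trials: 6 correct-CDF cells + 4 error-CAF
  # cells; proportions sum to 1 per trial type (before flooring).
  sim_err <- sim_caf_n - sim_caf_k
  part <- clamp(c(tabulate(cdf_bin, length(obs$cdf_counts)), sim_err) / n_sim)
  part <- part / sum(part)

  list(pi_cdf = pi_cdf, pi_caf = pi_caf, partition_pi = part,
       n_sim = n_sim)
}

#' Model-predicted bin probabilities
#'
#' Classifies simulated trials into an observed summary's RT bins and
#' accuracy cells. Per trial type it returns the CDF-bin probabilities
#' (summing to at most 1; error mass occupies the remainder), the predicted
#' CAF accuracies, and a ten-cell full partition (six correct-CDF cells plus
#' four error-CAF cells, renormalised to sum to 1) used by [chi_square_fit()].
#' All probabilities are floored at `1 / (floor_mult * n_sim)`.
#'
#' @param observed an `ssp_summary` from [summarize_trials()].
#' @param simulated a tibble of simulated trials (`congruency`, `rt`,
#'   `accuracy`, optionally `responded`).
#' @param floor_mult flooring multiplier (default 10).
#' @return A list with elements `congruent` and `incongruent`.
#' @export
predicted_proportions <- function(observed, simulated, floor_mult = 10) {
  stopifnot(inherits(observed, "ssp_summary"))
  if ("responded" %in% names(simulated)) {
    simulated <- simulated[simulated$responded %in% TRUE, , drop = FALSE]
  }
  out <- lapply(c(congruent = "congruent", incongruent = "incongruent"),
                function(type) {
    sel <- simulated$congruency == type
    predict_one_type(observed[[type]], simulated$rt[sel],
                     simulated$accuracy[sel], floor_mult)
  })
  out
}

#' Summed -2 log binomial deviance
#'
#' For observed counts `k` out of `n` with model probabilities `pi`, returns
#' `sum(-2 * log BinomialPMF(k | n, pi))`. This is the quantity the fitting
#' routine minimises across CDF and CAF cells; over candidate `pi` it is
#' minimised when `pi` equals the observed proportions.
#'
#' @param k observed successes per cell.
#' @param n trials per cell.
#' @param pi model probability per cell, each strictly inside (0, 1).
#' @return The summed deviance (a single number).
#' @examples
#' neg2_log_binomial(5, 10, 0.5)  # -2 * log choose(10,5)/2^10 = 2.8046
#' @export
neg2_log_binomial <- function(k, n, pi) {
  if (any(pi <= 0) || any(pi >= 1)) {
    stop("pi must lie strictly inside (0, 1); floor upstream", call. = FALSE)
  }
  sum(-2 * dbinom(k, n, pi, log = TRUE))
}

# R mirror of the compiled fit objective: deviance of an observed summary
# against an already-simulated trial set. Used for cross-checking the
# compiled path and for goodness-of-fit reporting.
deviance_from_trials <- function(observed, simulated, floor_mult = 10) {
  pred <- predicted_proportions(observed, simulated, floor_mult)
  dev <- 0
  for (type in c("congruent", "incongruent")) {
    s <- observed[[type]]
    p <- pred[[type]]
    dev <- dev + neg2_log_binomial(s$cdf_counts, s$n_total, p$pi_cdf)
    dev <- dev + neg2_log_binomial(s$caf_k, s$caf_n, p$pi_caf)
  }
  dev
}

#' Chi-square misfit statistic for one trial type
#'
#' `N * sum((p - pi)^2 / pi)` over the cells of a full partition; `p` and
#' `pi` must each sum to 1.
#'
#' @param p observed cell proportions.
#' @param pi predicted cell proportions (> 0).
#' @param n trial count for the trial type.
#' @return The chi-square contribution (a single number).
#' @examples
#' chi_square_stat(c(0.5, 0.5), c(0.6, 0.4), 100)  # 4.1667
#' @export
chi_square_stat <- function(p, pi, n) {
  if (any(pi <= 0)) stop("predicted proportions must be positive",
                         call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(pi) - 1) > 1e-6) {
    stop("p and pi must each sum to 1 per trial type", call. = FALSE)
  }
  n * sum((p - pi)^2 / pi)
}

#' Goodness of fit of simulated predictions to an observed summary
#'
#' Chi-square over the ten-cell partitions of both trial types, with
#' degrees of freedom `cells - 1 per trial type - n_free` and an
#' acceptability flag (non-significant misfit at `alpha`).
#'
#' @inheritParams predicted_proportions
#' @param n_free number of free model parameters charged to the df
#'   (default 6).
#' @param alpha significance level for the acceptability test (default 0.05).
#' @return A list with `chi_square`, `df`, `p_value`, `acceptable`,
#'   `n_observations`.
#' @export
chi_square_fit <- function(observed, simulated, floor_mult = 10, n_free = 6,
                           alpha = 0.05) {
  pred <- predicted_proportions(observed, simulated, floor_mult)
  chisq <- 0
  n_cells <- 0
  n_obs <- 0
  for (type in c("congruent", "incongruent")) {
    s <- observed[[type]]
    p_obs <- c(s$cdf_counts, s$caf_n - s$caf_k) / s$n_total
    chisq <- chisq + chi_square_stat(p_obs, pred[[type]]$partition_pi,
                                     s$n_total)
    n_cells <- n_cells + length(p_obs)
    n_obs <- n_obs + s$n_total
  }
  df <- n_cells - 2L - n_free
  if (df <= 0) stop("non-positive degrees of freedom", call. = FALSE)
  p_value <- pchisq(chisq, df, lower.tail = FALSE)
  list(chi_square = chisq, df = df, p_value = p_value,
       acceptable = p_value > alpha, n_observations = n_obs)
}

#' Root mean square error of approximation
#'
#' `sqrt(max(chi_square - df, 0) / (df * (n - 1)))`; values below 0.05 are
#' conventionally read as acceptable fit.
#'
#' @param chi_square chi-square statistic(s).
#' @param df degrees of freedom (> 0).
#' @param n_observations number of observations underlying the statistic
#'   (> 1).
#' @return The RMSEA value.
#' @examples
#' rmsea(20, 10, 101)  # 0.1
#' @export
rmsea <- function(chi_square, df, n_observations) {
  if (any(df <= 0)) stop("df must be positive", call. = FALSE)
  if (any(n_observations <= 1)) {
    stop("n_observations must exceed 1", call. = FALSE)
  }
  sqrt(pmax(chi_square - df, 0) / (df * (n_observations - 1)))
}

#' Pooled RMSEA across fitted datasets
#'
#' Sums chi-square and df across observations before applying the RMSEA
#' formula, with the pooled trial count as sample size.
#'
#' @param chi_squares per-observation chi-square statistics.
#' @param dfs per-observation degrees of freedom.
#' @param n_observations per-observation trial counts.
#' @return A single pooled RMSEA value.
#' @export
pooled_rmsea <- function(chi_squares, dfs, n_observations) {
  rmsea(sum(chi_squares), sum(dfs), sum(n_observations))
}
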