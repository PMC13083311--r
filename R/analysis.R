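#' Condition-effect ANOVA on estimated parameters
#'
#' Tests the induction-condition effect on one parameter across
#' participant-by-condition estimates, at either analysis level:
#'
#' * `"within_transformed"`: the population + condition + participant sums
#'   already remove participant variance, so condition is tested as a fixed
#'   effect in a general linear model with residual df `N - k`.
#' * `"observation"`: observation-level (bounded) estimates are analysed as
#'   a one-way repeated-measures ANOVA with participant as the error
#'   stratum.
#'
#' Pairwise follow-ups are computed on estimated marginal means via
#' \pkg{emmeans}, with Cohen's d from `emmeans::eff_size()` using the model
#' residual SD.
#'
#' @param data tibble with columns `participant`, `condition`, `value`.
#' @param level `"within_transformed"` or `"observation"`.
#' @param parameter optional parameter name carried into the report.
#' @param adjust p-value adjustment for the pairwise contrasts (default
#'   `"none"`, matching uncorrected pairwise reporting).
#' @return A list of class `condition_effect`: `parameter`, `F`, `df1`,
#'   `df2`, `p`, `eta_sq_p`, and a `pairwise` tibble (`contrast`,
#'   `estimate`, `t`, `df`, `p`, `d`).
#' @export
condition_anova <- function(data, level = c("within_transformed",
                                            "observation"),
                            parameter = NA_character_, adjust = "none") {
  level <- match.arg(level)
  stopifnot(all(c("participant", "condition", "value") %in% names(data)))
  data <- data.frame(participant = factor(data$participant),
                     condition = factor(data$condition),
                     value = as.numeric(data$value))
  if (nlevels(data$condition) < 2L) {
    stop("need at least two conditions", call. = FALSE)
  }
  n_per_participant <- table(data$participant)
  if (any(n_per_participant < 2L)) {
    stop("every participant needs values in at least two conditions",
         call. = FALSE)
  }

  if (level == "within_transformed") {
    model <- lm(value ~ condition, data = data)
    an <- anova(model)
    ss_c <- an["condition", "Sum Sq"]
    ss_e <- an["Residuals", "Sum Sq"]
    f_val <- an["condition", "F value"]
    df1 <- an["condition", "Df"]
    df2 <- an["Residuals", "Df"]
    p_val <- an["condition", "Pr(>F)"]
    resid_sd <- sigma(model)
    edf <- df.residual(model)
    emm <- suppressMessages(emmeans::emmeans(model, "condition", data = data))
  } else {
    # build the call with the data frame embedded so emmeans can recover it
    model <- do.call(stats::aov,
                     list(formula = value ~ condition + Error(participant),
                          data = data))
    tab <- summary(model)[["Error: Within"]][[1]]
    ss_c <- tab["condition", "Sum Sq"]
    ss_e <- tab["Residuals", "Sum Sq"]
    f_val <- tab["condition", "F value"]
    df1 <- tab["condition", "Df"]
    df2 <- tab["Residuals", "Df"]
    p_val <- tab["condition", "Pr(>F)"]
    resid_sd <- sqrt(ss_e / df2)
    edf <- df2
    emm <- suppressMessages(emmeans::emmeans(model, "condition", data = data))
  }
  eta <- if ((ss_c + ss_e) > 0) ss_c / (ss_c + ss_e) else 0

  ctr <- emmeans::contrast(emm, method = "pairwise", adjust = adjust)
  prs <- as.data.frame(summary(ctr))
  eff <- as.data.frame(emmeans::eff_size(emm, sigma = resid_sd, edf = edf))
  pairwise <- tibble::tibble(
    contrast = as.character(prs$contrast),
    estimate = prs$estimate,
    t = prs$t.ratio,
    df = prs$df,
    p = prs$p.value,
    d = eff$effect.size[match(prs$contrast,
                              gsub("[()]", "", eff$contrast))])
  if (anyNA(pairwise$d) && nrow(eff) == nrow(pairwise)) {
    pairwise$d <- eff$effect.size
  }

  structure(list(parameter = parameter, level = level, F = f_val,
                 df1 = df1, df2 = df2, p = p_val, eta_sq_p = eta,
                 means = as.data.frame(emm), pairwise = pairwise),
            class = "condition_effect")
}

#' @export
print.condition_effect <- function(x, ...) {
  lab <- if (is.na(x$parameter)) "" else paste0(x$parameter, ": ")
  cat(sprintf("%sF(%d, %d) = %.2f, p = %.4g, partial eta^2 = %.3f [%s]\n",
              lab, x$df1, x$df2, x$F, x$p, x$eta_sq_p, x$level))
  pw <- x$pairwise
  for (i in seq_len(nrow(pw))) {
    cat(sprintf("  %s: t(%g) = %.2f, p = %.4g, d = %.2f\n",
                pw$contrast[i], pw$df[i], pw$t[i], pw$p[i], pw$d[i]))
  }
  invisible(x)
}

#' Condition ANOVAs for all six parameters
#'
#' @param estimates long tibble from [estimates_long()] (`participant`,
#'   `condition`, `parameter`, `value`).
#' @inheritParams condition_anova
#' @return A tibble with one row per parameter (`F`, `df1`, `df2`, `p`,
#'   `eta_sq_p`) and a `reports` list-column of full `condition_effect`
#'   objects.
#' @export
condition_anova_all <- function(estimates,
                                level = c("within_transformed",
                                          "observation"),
                                adjust = "none") {
  level <- match.arg(level)
  params <- unique(estimates$parameter)
  reports <- lapply(params, function(pm) {
    condition_anova(estimates[estimates$parameter == pm, ], level = level,
                    parameter = pm, adjust = adjust)
  })
  tibble::tibble(
    parameter = params,
    F = vapply(reports, `[[`, numeric(1), "F"),
    df1 = vapply(reports, `[[`, numeric(1), "df1"),
    df2 = vapply(reports, `[[`, numeric(1), "df2"),
    p = vapply(reports, `[[`, numeric(1), "p"),
    eta_sq_p = vapply(reports, `[[`, numeric(1), "eta_sq_p"),
    reports = reports
  )
}

#' Spotlight convergence ratio
#'
#' `sd_a0 / r_d`: the time in milliseconds for the spotlight to shrink from
#' its initial width to (essentially) the minimum attentional window. A
#' trade-invariant index of attentional narrowing speed; computed per
#' observation and then averaged, never as a ratio of averages.
#'
#' @param sd_a0 initial spotlight width(s).
#' @param r_d shrink rate(s), strictly positive.
#' @return Convergence time(s) in ms.
#' @examples
#' convergence_ratio(1.8, 0.017)  # 105.88 ms
#' @export
convergence_ratio <- function(sd_a0, r_d) {
  if (any(r_d <= 0)) {
    stop("r_d must be strictly positive: a non-shrinking spotlight never ",
         "converges", call. = FALSE)
  }
  sd_a0 / r_d
}
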