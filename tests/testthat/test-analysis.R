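toy_table <- function(values) {
  tibble::tibble(
    participant = rep(c("P1", "P2", "P3"), each = 3),
    condition = rep(c("FA", "OM", "C"), times = 3),
    value = values)
}

test_that("equal condition means give a null effect", {
  # latin-square values: condition means all equal, residual variance > 0
  d <- toy_table(c(1, 2, 3,  2, 3, 1,  3, 1, 2))
  r <- condition_anova(d, level = "observation")
  expect_equal(r$F, 0, tolerance = 1e-12)
  expect_true(all(abs(r$pairwise$t) < 1e-6))
  expect_equal(r$eta_sq_p, 0, tolerance = 1e-12)
})

test_that("repeated-measures F matches a hand-computed decomposition", {
  vals <- c(10, 12, 17,   11, 14, 16,   9, 13, 18)
  d <- toy_table(vals)
  r <- condition_anova(d, level = "observation")

  # independent sums-of-squares oracle for a one-way within-subject design
  m <- matrix(vals, nrow = 3, byrow = TRUE)  # participants x conditions
  grand <- mean(m)
  ss_cond <- 3 * sum((colMeans(m) - grand)^2)
  ss_part <- 3 * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_part
  f_oracle <- (ss_cond / 2) / (ss_err / 4)

  expect_equal(r$F, f_oracle, tolerance = 1e-10)
  expect_equal(r$df1, 2)
  expect_equal(r$df2, 4)
  expect_equal(r$eta_sq_p, ss_cond / (ss_cond + ss_err), tolerance = 1e-10)

  # within-transformed level: plain GLM decomposition, df2 = N - k
  r2 <- condition_anova(d, level = "within_transformed")
  ss_err_glm <- ss_tot - ss_cond
  expect_equal(r2$F, (ss_cond / 2) / (ss_err_glm / 6), tolerance = 1e-10)
  expect_equal(r2$df2, 6)
})

test_that("participant shifts leave the repeated-measures test invariant", {
  vals <- c(10, 12, 17,   11, 14, 16,   9, 13, 18)
  d1 <- toy_table(vals)
  d2 <- toy_table(vals + rep(c(100, -40, 7), each = 3))
  r1 <- condition_anova(d1, level = "observation")
  r2 <- condition_anova(d2, level = "observation")
  expect_equal(r1$F, r2$F, tolerance = 1e-10)
  expect_equal(r1$pairwise$t, r2$pairwise$t, tolerance = 1e-8)
})

test_that("pairwise statistics flip sign when the pair is reversed", {
  vals <- c(10, 12, 17,   11, 14, 16,   9, 13, 18)
  d <- toy_table(vals)
  r <- condition_anova(d, level = "observation")
  # swapping the two condition labels negates their contrast
  d_swap <- d
  d_swap$condition <- ifelse(d$condition == "FA", "OM",
                             ifelse(d$condition == "OM", "FA", "C"))
  r_swap <- condition_anova(d_swap, level = "observation")
  pick <- function(x, a, b) {
    i <- grepl(a, x$pairwise$contrast) & grepl(b, x$pairwise$contrast)
    x$pairwise$t[i]
  }
  expect_equal(pick(r, "FA", "OM"), -pick(r_swap, "FA", "OM"),
               tolerance = 1e-8)
  expect_equal(r$F, r_swap$F, tolerance = 1e-10)
})

test_that("condition_anova_all covers every parameter", {
  set.seed(81)
  est <- tidyr::expand_grid(participant = sprintf("P%d", 1:6),
                            condition = c("FA", "OM", "C"),
                            parameter = ssp_param_names)
  est$value <- rnorm(nrow(est), 10, 1)
  tab <- condition_anova_all(est, level = "observation")
  expect_equal(sort(tab$parameter), sort(ssp_param_names))
  expect_true(all(tab$eta_sq_p >= 0 & tab$eta_sq_p <= 1))
  expect_equal(nrow(tab$reports[[1]]$pairwise), 3L)
})

test_that("convergence ratio is per-observation time to the minimum window", {
  expect_equal(convergence_ratio(1.8, 0.017), 105.882, tolerance = 1e-4)
  expect_equal(convergence_ratio(0.05, 0.05), 1)
  expect_error(convergence_ratio(1.8, 0), "positive")

  # agreement with the first step at which the width reaches the floor
  for (pars in list(c(1.8, 0.017), c(4.6, 0.105), c(2.5, 0.03))) {
    t_star <- convergence_ratio(pars[1], pars[2])
    t_grid <- 0:2000
    w <- spotlight_width(t_grid, pars[1], pars[2])
    first_floor <- t_grid[which(w <= 0.001 + 1e-12)[1]]
    expect_lt(abs(first_floor - t_star), 1 + 1e-9)
  }

  # mean of per-observation ratios differs from ratio of means
  sd_a0 <- c(1, 3); r_d <- c(0.01, 0.1)
  expect_gt(mean(convergence_ratio(sd_a0, r_d)),
            mean(sd_a0) / mean(r_d))
})
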