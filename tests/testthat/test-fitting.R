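test_that("start draws respect truncated-normal bounds and moments", {
  d <- start_distribution(n_starts = 200)
  m <- draw_starts(d, seed = 1)
  expect_equal(dim(m), c(200L, 6L))
  for (j in 1:6) {
    expect_true(all(m[, j] >= d$lower[j] & m[, j] <= d$upper[j]))
  }

  # collapsed bounds: every start is that point
  d0 <- start_distribution(lower = rep(1, 6), upper = rep(1, 6),
                           n_starts = 5)
  expect_true(all(draw_starts(d0, seed = 2) == 1))

  # empirical mean against the truncated-normal moment formula (sd_a0 cell)
  n <- 100000
  set.seed(3)
  x <- sspflanker:::rtruncnorm_vec(n, 1.8, 1.2, 0.8, 4.0)
  a <- (0.8 - 1.8) / 1.2
  b <- (4.0 - 1.8) / 1.2
  mu <- 1.8 + 1.2 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(x) - mu), 3 * sd(x) / sqrt(n))
})

test_that("delta start distributions keep base + delta inside stage bounds", {
  base <- as.numeric(ref_params())
  d <- delta_start_distribution(base, n_starts = 100)
  m <- draw_starts(d, seed = 4)
  composed <- sweep(m, 2, base, "+")
  upper <- c(6.0, 0.2, 5.0, 200, 450, 90)
  expect_true(all(composed >= 0))
  expect_true(all(sweep(composed, 2, upper, "-") <= 1e-12))
})

test_that("degenerate optimizer returns the best start's objective", {
  trials <- simulate_trials(ref_params(), 600, 600, seed = 51)
  ctl <- tiny_control(n_starts = 3, maxit = 0)
  fit <- fit_dataset(trials, control = ctl, seed = 52)
  expect_equal(fit$n_starts_run, 3L)
  expect_equal(fit$objective, min(fit$start_objectives))
  expect_equal(fit$best_start, which.min(fit$start_objectives))
})

test_that("fits are bit-reproducible under common random numbers", {
  trials <- simulate_trials(ref_params(), 600, 600, seed = 53)
  f1 <- fit_dataset(trials, control = tiny_control(), seed = 54)
  f2 <- fit_dataset(trials, control = tiny_control(), seed = 54)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$start_objectives, f2$start_objectives)
})

test_that("returned objective is the minimum over evaluated starts", {
  trials <- simulate_trials(ref_params(), 600, 600, seed = 55)
  fit <- fit_dataset(trials, control = tiny_control(n_starts = 4), seed = 56)
  expect_true(all(fit$objective <= fit$start_objectives))
  expect_true(all(fit$params >= 0))
  expect_true(all(fit$params <= c(6.0, 0.2, 5.0, 200, 450, 90)))
})

test_that("hierarchical stages compose and respect bounds", {
  # two participants x two conditions, all generated at the same parameters
  set.seed(57)
  trials <- dplyr::bind_rows(lapply(c("P01", "P02"), function(pid) {
    dplyr::bind_rows(lapply(c("FA", "C"), function(cond) {
      simulate_dataset(ref_params(), 150, 150, participant = pid,
                       condition = cond)
    }))
  }))
  ctl <- tiny_control()
  pop <- fit_population(trials, control = ctl, seed = 58)
  cond <- fit_condition_deltas(trials, pop$params, control = ctl, seed = 59)
  part <- fit_participant_deltas(trials, pop$params, control = ctl, seed = 60)
  expect_equal(rownames(cond$deltas), c("C", "FA"))
  expect_equal(rownames(part$deltas), c("P01", "P02"))

  wt <- compose_within_transformed(pop$params, cond$deltas, part$deltas)
  expect_equal(nrow(wt), 4L)
  # additivity: condition differences are exactly the delta differences
  diffs <- wt[wt$participant == "P01" & wt$condition == "FA",
              ssp_param_names] -
    wt[wt$participant == "P01" & wt$condition == "C", ssp_param_names]
  expect_equal(unlist(diffs, use.names = FALSE),
               unname(cond$deltas["FA", ] - cond$deltas["C", ]))

  # all-zero deltas: every observation equals the population vector
  zero <- matrix(0, 2, 6, dimnames = list(c("FA", "C"), ssp_param_names))
  zero_p <- matrix(0, 2, 6, dimnames = list(c("P01", "P02"),
                                            ssp_param_names))
  wt0 <- compose_within_transformed(pop$params, zero, zero_p)
  for (i in seq_len(nrow(wt0))) {
    expect_equal(unlist(wt0[i, ssp_param_names], use.names = FALSE),
                 unname(pop$params))
  }

  noise <- fit_observation_noise(trials, pop$params, cond$deltas,
                                 part$deltas, control = ctl, seed = 61)
  est <- noise$estimates
  expect_equal(nrow(est), 4L)
  upper <- c(6.0, 0.2, 5.0, 200, 450, 90)
  for (j in seq_along(ssp_param_names)) {
    expect_true(all(est[[ssp_param_names[j]]] >= 0))
    expect_true(all(est[[ssp_param_names[j]]] <= upper[j]))
  }
  expect_true(all(c("chi_square", "df", "acceptable") %in% names(est)))
})
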