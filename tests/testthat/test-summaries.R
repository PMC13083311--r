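test_that("quantile grids default to the sextile/quartile scheme", {
  expect_equal(cdf_probs_default, c(0.1, 0.3, 0.5, 0.7, 0.9, 1))
  expect_equal(caf_probs_default, c(0.25, 0.5, 0.75, 1))
})

test_that("summaries degenerate correctly on constant and bimodal data", {
  # all trials identical and correct: every CDF edge is that RT, CAF = 1
  tr <- make_trials(rep(400, 100), rep(1L, 100))
  tr <- dplyr::bind_rows(tr, make_trials(rep(400, 100), rep(1L, 100),
                                         "incongruent"))
  s <- summarize_trials(tr)
  expect_true(all(s$congruent$cdf_edges == 400))
  expect_true(all(s$congruent$caf_accuracy[s$congruent$caf_n > 0] == 1))

  # fast-correct / slow-error mixture: accuracy 1 below the median bin,
  # 0 in the bin holding the slow errors
  tr2 <- make_trials(c(rep(300, 50), rep(600, 50)),
                     c(rep(1L, 50), rep(0L, 50)))
  tr2 <- dplyr::bind_rows(tr2, make_trials(rep(450, 4), rep(1L, 4),
                                           "incongruent"))
  s2 <- summarize_trials(tr2)
  caf <- s2$congruent
  expect_equal(caf$caf_accuracy[1], 1)            # the 300-ms bin
  last_bin <- max(which(caf$caf_n > 0))
  expect_equal(caf$caf_accuracy[last_bin], 0)     # the 600-ms bin
  expect_equal(sum(caf$caf_n), 100)

  # missing cells are named in the error
  expect_error(summarize_trials(make_trials(300, 1L)), "incongruent")
})

test_that("summary bins partition the trials and export cleanly", {
  p <- ref_params()
  tr <- simulate_trials(p, 800, 800, seed = 41)
  s <- summarize_trials(tr)
  for (type in c("congruent", "incongruent")) {
    expect_equal(sum(s[[type]]$cdf_counts), s[[type]]$n_correct)
    expect_equal(sum(s[[type]]$caf_n), s[[type]]$n_total)
    expect_true(all(diff(s[[type]]$cdf_edges) >= 0))
  }
  tab <- summary_table(s)
  expect_equal(nrow(tab), 20L)  # (6 CDF + 4 CAF) x 2 trial types
  expect_true(all(tab$proportion >= 0 & tab$proportion <= 1))
})

test_that("predicted proportions reproduce observed data on themselves", {
  p <- ref_params()
  tr <- simulate_trials(p, 2000, 2000, seed = 42)
  s <- summarize_trials(tr)
  pred <- predicted_proportions(s, tr)
  for (type in c("congruent", "incongruent")) {
    obs_p <- s[[type]]$cdf_counts / s[[type]]$n_total
    expect_equal(pred[[type]]$pi_cdf, obs_p, tolerance = 1e-3)
    expect_equal(pred[[type]]$pi_caf, s[[type]]$caf_accuracy,
                 tolerance = 1e-3)
    expect_lte(sum(pred[[type]]$pi_cdf), 1)
    expect_equal(sum(pred[[type]]$partition_pi), 1, tolerance = 1e-12)
  }
})

test_that("binomial deviance matches direct arithmetic and is minimised at p", {
  # single cell: -2 log [ C(10,5) 0.5^10 ]
  expect_equal(neg2_log_binomial(5, 10, 0.5),
               -2 * log(choose(10, 5) * 0.5^10))
  expect_equal(neg2_log_binomial(5, 10, 0.5), 2.80409, tolerance = 1e-4)

  # grid search oracle: deviance over candidate pi is minimised at k/n
  k <- 3; n <- 10
  grid <- seq(0.01, 0.99, by = 0.01)
  dev <- vapply(grid, function(pi) neg2_log_binomial(k, n, pi), numeric(1))
  expect_equal(grid[which.min(dev)], k / n)

  # multi-cell sums and the impossibility penalty direction
  expect_equal(neg2_log_binomial(c(5, 3), c(10, 10), c(0.5, 0.3)),
               neg2_log_binomial(5, 10, 0.5) + neg2_log_binomial(3, 10, 0.3))
  expect_gt(neg2_log_binomial(5, 10, 1e-6), neg2_log_binomial(5, 10, 0.5))
  expect_error(neg2_log_binomial(5, 10, 0), "inside")
  expect_error(neg2_log_binomial(5, 10, 1), "inside")
})

test_that("compiled objective equals the R-side deviance mirror", {
  # the compiled path simulates internally with the same generator the
  # exported simulator uses, so at a common seed the two routes must agree
  # to machine precision
  p <- ref_params()
  tr <- simulate_trials(p, 1500, 1500, seed = 43)
  s <- summarize_trials(tr)
  sim_seed <- 977
  dev_cpp <- sspflanker:::fit_objective_cpp(
    as.numeric(p), sspflanker:::obs_for_cpp(s$congruent),
    sspflanker:::obs_for_cpp(s$incongruent), 1500L, 1500L,
    7, 1, 0.001, 950, sim_seed, 10)
  sim <- simulate_trials(p, 1500, 1500, seed = sim_seed)
  expect_equal(dev_cpp, sspflanker:::deviance_from_trials(s, sim),
               tolerance = 1e-10)
})

test_that("chi-square statistic matches direct arithmetic", {
  # N * sum((p - pi)^2 / pi): 100 * (0.01/0.6 + 0.01/0.4)
  expect_equal(chi_square_stat(c(0.5, 0.5), c(0.6, 0.4), 100),
               100 * (0.01 / 0.6 + 0.01 / 0.4))
  expect_equal(chi_square_stat(c(0.5, 0.5), c(0.6, 0.4), 100), 4.1667,
               tolerance = 1e-4)
  # zero iff p == pi; linear in N; invariant to bin relabeling
  expect_equal(chi_square_stat(c(0.3, 0.7), c(0.3, 0.7), 50), 0)
  expect_equal(chi_square_stat(c(0.5, 0.5), c(0.6, 0.4), 200),
               2 * chi_square_stat(c(0.5, 0.5), c(0.6, 0.4), 100))
  expect_equal(chi_square_stat(c(0.5, 0.5), c(0.4, 0.6), 100),
               chi_square_stat(c(0.5, 0.5), c(0.6, 0.4), 100))
  expect_error(chi_square_stat(c(0.5, 0.5), c(1, 0), 10), "positive")
  expect_error(chi_square_stat(c(0.6, 0.6), c(0.5, 0.5), 10), "sum to 1")
})

test_that("rmsea follows its formula and acceptability convention", {
  expect_equal(rmsea(5, 10, 100), 0)            # chi-square below df
  expect_equal(rmsea(20, 10, 101), 0.1)         # sqrt(10 / (10 * 100))
  expect_error(rmsea(5, 0, 100), "df")
  expect_error(rmsea(5, 10, 1), "n_observations")
  expect_equal(pooled_rmsea(c(20, 20), c(10, 10), c(51, 51)),
               rmsea(40, 20, 102))
  expect_lt(rmsea(20, 10, 101), 0.05 * 3)       # scale sanity
})

test_that("goodness-of-fit vanishes on self-prediction and scales sanely", {
  p <- ref_params()
  tr <- simulate_trials(p, 3000, 3000, seed = 44)
  s <- summarize_trials(tr)

  # predictions taken from the observed trials themselves: exact partition
  # match, zero misfit
  gof_self <- chi_square_fit(s, tr)
  expect_equal(gof_self$df, 12)  # 10 cells x 2 types - 2 - 6 free parameters
  expect_lt(gof_self$chi_square, 1e-6)
  expect_true(gof_self$acceptable)

  # an independent simulation at the generating parameters carries only
  # sampling error: far from the gross-misfit regime, RMSEA acceptable
  sim <- simulate_trials(p, 12000, 12000, seed = 45)
  gof <- chi_square_fit(s, sim)
  expect_lt(gof$chi_square, qchisq(0.999, 18) * 2)
  expect_lt(rmsea(gof$chi_square, gof$df, gof$n_observations), 0.05)

  # a wrong model is flagged: double the boundary, RTs shift drastically
  bad <- simulate_trials(ssp_parameters(1.8, 0.017, 0.6, 120, 250, 30),
                         12000, 12000, seed = 46)
  expect_gt(chi_square_fit(s, bad)$chi_square, gof$chi_square * 10)
  expect_false(chi_square_fit(s, bad)$acceptable)
})
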