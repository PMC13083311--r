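test_that("spotlight width starts at sd_a0, shrinks linearly, floors", {
  expect_equal(spotlight_width(0, 1.8, 0.017), 1.8)
  expect_equal(spotlight_width(100, 1.8, 0.017), 0.1)   # 1.8 - 0.017 * 100
  expect_equal(spotlight_width(1e6, 1.8, 0.017), 0.001)
  expect_equal(spotlight_width(50, 2, 0, floor = 0.5), 2)

  t_grid <- seq(0, 2000, by = 7)
  w <- spotlight_width(t_grid, 3.2, 0.05)
  expect_true(all(diff(w) <= 0))
  expect_true(all(w >= 0.001))

  expect_error(spotlight_width(-1, 1.8, 0.017), "non-negative")
  expect_error(spotlight_width(0, 0, 0.017), "positive")
  expect_error(spotlight_width(0, 1.8, -0.1), "non-negative")
})

test_that("activations are normal-CDF slot masses that sum to one", {
  sds <- exp(seq(log(1e-3), log(100), length.out = 200))
  a <- activations(sds)
  expect_true(max(abs(rowSums(a) - 1)) < 1e-9)
  expect_equal(a[, "outer_left"], a[, "outer_right"])
  expect_equal(a[, "inner_left"], a[, "inner_right"])

  # all mass inside the target window as the spotlight hits its floor
  expect_equal(unname(activations(0.001)[, "target"]), 1, tolerance = 1e-12)

  # independent oracle: numeric integration of the normal density per slot
  for (s in c(0.5, 1, 2.5)) {
    tgt <- integrate(dnorm, -0.5, 0.5, sd = s, rel.tol = 1e-12)$value
    inn <- integrate(dnorm, 0.5, 1.5, sd = s, rel.tol = 1e-12)$value
    expect_equal(unname(activations(s)[, "target"]), tgt, tolerance = 1e-9)
    expect_equal(unname(activations(s)[, "inner_right"]), inn,
                 tolerance = 1e-9)
  }
  expect_equal(unname(activations(1)[, "target"]), 2 * pnorm(0.5) - 1)

  expect_error(activations(0), "positive")
})

test_that("drift is the signed activation-weighted input", {
  # congruent drift equals p_input exactly, any width
  set.seed(5)
  for (i in 1:25) {
    sd <- runif(1, 0.01, 10)
    p <- runif(1, 0.1, 2)
    expect_identical(ssp_drift(sd, "congruent", p), p)
  }

  # incongruent drift against the integration oracle at sd = 1
  tgt <- integrate(dnorm, -0.5, 0.5, rel.tol = 1e-12)$value
  expect_equal(ssp_drift(1, "incongruent", 0.6), 0.6 * (2 * tgt - 1),
               tolerance = 1e-9)
  expect_equal(ssp_drift(1, "incongruent", 0.6), -0.1404902,
               tolerance = 1e-6)

  # monotone non-decreasing as the spotlight narrows; converges to p_input
  sds <- seq(5, 0.001, length.out = 400)
  v <- ssp_drift(sds, "incongruent", 0.6)
  expect_true(all(diff(v) >= 0))
  expect_equal(v[length(v)], 0.6, tolerance = 1e-9)

  expect_error(ssp_drift(1, "sideways", 0.6))
})

test_that("drift schedule mirrors spotlight narrowing over steps", {
  p <- ref_params()
  v_con <- drift_schedule(p, "congruent")
  expect_true(all(v_con == 0.6))
  v_inc <- drift_schedule(p, "incongruent")
  expect_equal(length(v_inc), 950L)
  expect_true(all(diff(v_inc) >= 0))
  expect_equal(v_inc[1], ssp_drift(1.8, "incongruent", 0.6))
  expect_equal(v_inc[950], 0.6, tolerance = 1e-9)
})

test_that("simulated trials honor decision and nondecision contracts", {
  # overwhelming drift: first step crosses, everything correct, and with
  # ndt_sd = 0 the response time is decision time + ndt_mean exactly
  p_fast <- ssp_parameters(0.001, 0.0001, 100, 60, 250, 1e-9)
  tr <- simulate_trials(p_fast, 400, 0, seed = 3)
  expect_true(all(tr$accuracy == 1))
  expect_true(all(tr$rt - 250 <= 2))
  # rt = (integer) decision time + ndt_mean, ndt variability degenerate
  expect_true(all(abs(tr$rt - round(tr$rt)) < 1e-6))

  # RNG contract: same seed gives identical datasets
  p <- ref_params()
  a <- simulate_trials(p, 300, 300, seed = 11)
  b <- simulate_trials(p, 300, 300, seed = 11)
  expect_identical(a, b)

  # counts and labels
  expect_equal(nrow(a), 600L)
  expect_equal(sum(a$congruency == "congruent"), 300L)
  expect_equal(nrow(simulate_trials(p, 0, 0)), 0L)

  d <- simulate_dataset(p, 5, 5, seed = 1, participant = "P09",
                        condition = "OM")
  expect_true(all(d$participant == "P09" & d$condition == "OM"))
})

test_that("dt = 1 accuracy matches the overshoot-corrected absorption form", {
  # Constant drift v, symmetric boundaries +/-b: the continuous-time hit
  # probability is 1/(1+exp(-2vb/sigma^2)). A discrete 1-ms walk overshoots
  # the boundary by ~0.583*sigma on average (Siegmund's corrected diffusion
  # approximation), so the discrete walk is compared against the corrected
  # boundary b + 0.583*sigma.
  p <- ssp_parameters(1.8, 1e-9, 0.6, 60, 250, 30)
  tr <- simulate_trials(p, 50000, 0, seed = 21)
  acc <- mean(tr$accuracy[tr$responded])
  corrected <- 1 / (1 + exp(-2 * 0.6 * (60 + 0.5826 * 7) / 49))
  mc_se <- sqrt(corrected * (1 - corrected) / 50000)
  expect_lt(abs(acc - corrected), 3 * mc_se + 0.002)
})

test_that("flanker interference and fast-error signatures emerge", {
  p <- ref_params()
  tr <- simulate_trials(p, 4000, 4000, seed = 31)
  acc <- tapply(tr$accuracy[tr$responded], tr$congruency[tr$responded], mean)
  expect_lt(acc[["incongruent"]], acc[["congruent"]])

  # narrower initial spotlight -> fewer fast errors on incongruent trials
  # (higher first-quartile CAF accuracy)
  first_caf <- function(sd_a0) {
    pp <- ssp_parameters(sd_a0, 0.017, 0.6, 60, 250, 30)
    s <- summarize_trials(simulate_trials(pp, 500, 6000, seed = 32))
    s$incongruent$caf_accuracy[1]
  }
  expect_gt(first_caf(0.6), first_caf(3.0))
})
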