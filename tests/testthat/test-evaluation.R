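test_that("the true growth rate is the averaged per-site geometric mean", {
  const <- tidyr::expand_grid(site = 1:4, year = 1:6)
  const$n_total <- 50
  expect_equal(lambda_true(const), 1)

  halving <- tibble::tibble(site = 1, year = 1:5,
                            n_total = 80 * 0.5^(0:4))
  expect_equal(lambda_true(halving), 0.5)

  # direct arithmetic oracle: ratios (1.2, 0.3) and (0.9, 0.9)
  two <- tibble::tibble(site = rep(1:2, each = 3), year = rep(1:3, 2),
                        n_total = c(10, 12, 3.6, 10, 9, 8.1))
  expect_equal(lambda_true(two), (sqrt(1.2 * 0.3) + 0.9) / 2)
  expect_equal(lambda_true(two, use_root = FALSE),
               (1.2 * 0.3 + 0.9 * 0.9) / 2)
})

test_that("zero-abundance years are excluded and dead sites dropped", {
  tr <- tibble::tibble(site = rep(1:2, each = 4), year = rep(1:4, 2),
                       n_total = c(8, 4, 0, 0,   9, 9, 9, 9))
  # site 1 contributes only the 8 -> 4 ratio; the crash to zero and the
  # absorbed years are log-undefined
  expect_equal(lambda_true(tr), (0.5 + 1) / 2)
  dead <- tibble::tibble(site = rep(1:2, each = 3), year = rep(1:3, 2),
                         n_total = c(5, 0, 0,  10, 5, 5))
  expect_warning(out <- lambda_true(dead), "excluded")
  expect_equal(out, sqrt(0.5 * 1))
})

test_that("true growth is invariant to site labels and uniform rescaling", {
  set.seed(40)
  tr <- tidyr::expand_grid(site = 1:6, year = 1:10)
  tr$n_total <- stats::rpois(nrow(tr), 40) + 1
  base <- lambda_true(tr)
  relabel <- dplyr::mutate(tr, site = match(site, c(4, 2, 6, 1, 5, 3)))
  expect_equal(lambda_true(relabel), base)
  expect_equal(lambda_true(dplyr::mutate(tr, n_total = n_total * 7.3)),
               base)
})

test_that("bias is the signed difference with the documented convention", {
  expect_equal(bias(0.95, 0.72), 0.23)
  expect_equal(bias(0.8, 0.8), 0)
  expect_lt(bias(0.6, 0.7), 0)  # underestimated growth is negative
  expect_equal(bias(c(1, 2), c(0.5, 2.5)), c(0.5, -0.5))
})

test_that("bias summaries give the mean and empirical 95% quantiles", {
  expect_equal(summarize_bias(c(0.1, 0.1, 0.1)),
               tibble::tibble(mean = 0.1, q2.5 = 0.1, q97.5 = 0.1,
                              n_sims = 3L))
  set.seed(12)
  th <- stats::rnorm(4000)
  s <- summarize_bias(th)
  expect_lt(abs(s$mean), 0.05)
  expect_lt(abs(s$q2.5 - stats::qnorm(0.025)), 0.12)
  expect_lt(abs(s$q97.5 - stats::qnorm(0.975)), 0.12)
  expect_lte(s$q2.5, s$q97.5)
  expect_error(summarize_bias(0.1))
})

test_that("first-overlap year scans intervals in order", {
  ints <- tibble::tibble(year = 1:3, lower = 10, upper = 20)
  expect_equal(overlap_year(ints, c(15, 15, 15)), 1)
  expect_equal(overlap_year(ints, c(25, 25, 15)), 3)
  expect_equal(overlap_year(ints, c(25, 25, 25)), Inf)
  expect_equal(overlap_year(ints, c(5, 12, 5)), 2)
  expect_equal(overlap_year(ints,
                            tibble::tibble(year = 3:1, n = c(15, 25, 25))),
               3)
})

test_that("scenario evaluation produces coherent per-simulation rows", {
  ev <- quiet_fit(evaluate_scenario(
    scenario_config(2, n_sims = 3, n_sites = 50, n_years = 15, seed = 21),
    control = mcmc_control(1, 250, 300)))
  expect_equal(nrow(ev), 3)
  expect_equal(ev$theta, ev$lambda_sim - ev$lambda_true)
  expect_true(all(ev$lambda_sim > 0 & ev$lambda_sim < 1))
  expect_true(all(lengths(ev$lambda_draws) == 300))
  td <- tidy(ev)
  expect_equal(td$n_sims, 3L)
  expect_equal(td$theta_mean, mean(ev$theta))
})

test_that("evaluation is deterministic under a fixed master seed", {
  cfg <- scenario_config(7, n_sims = 2, n_sites = 30, n_years = 10,
                         seed = 31)
  a <- quiet_fit(evaluate_scenario(cfg, control = mcmc_control(1, 150, 150)))
  b <- quiet_fit(evaluate_scenario(cfg, control = mcmc_control(1, 150, 150)))
  expect_identical(a$lambda_sim, b$lambda_sim)
  expect_identical(a$theta, b$theta)
  expect_identical(a$overlap_year, b$overlap_year)
})

test_that("the sensitivity sweep orders growth estimates by detection", {
  sw <- quiet_fit(sensitivity_sweep("p", c(0.25, 0.5), n_sims = 2,
                                    n_sites = 40, n_years = 12, seed = 3,
                                    control = mcmc_control(1, 200, 250)))
  expect_equal(nrow(sw), 2)
  expect_true(is.na(sw$dlambda_dvalue[1]))
  # more detection -> larger counts -> steeper estimated decline
  expect_lt(sw$lambda_sim[sw$value == 0.5],
            sw$lambda_sim[sw$value == 0.25])
  expect_lt(sw$dlambda_dvalue[2], 0)
  one <- quiet_fit(sensitivity_sweep("K", 25, n_sims = 1, n_sites = 25,
                                     n_years = 8, seed = 3,
                                     control = mcmc_control(1, 100, 150)))
  expect_equal(nrow(one), 1)
  expect_true(is.na(one$dlambda_dvalue))
})

test_that("plot methods return ggplot objects", {
  sims <- run_scenario(scenario_config(2, n_sims = 2, n_sites = 15,
                                       n_years = 6, seed = 2))
  expect_s3_class(ggplot2::autoplot(sims), "ggplot")
  fit <- quiet_fit(fit_state_space(sims$counts,
                                   control = mcmc_control(1, 100, 120),
                                   seed = 1))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  fitn <- quiet_fit(fit_nmixture(sims$counts,
                                 control = mcmc_control(1, 100, 120),
                                 seed = 1))
  expect_s3_class(plot_detection(fitn), "ggplot")
  ev <- quiet_fit(evaluate_sims(sims, control = mcmc_control(1, 100, 120)))
  expect_s3_class(ggplot2::autoplot(ev), "ggplot")
})
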