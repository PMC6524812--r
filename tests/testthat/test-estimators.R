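test_that("gamma moment matching is exact and Monte-Carlo consistent", {
  expect_equal(gamma_shape_rate(1, 0.1), tibble::tibble(shape = 100,
                                                        rate = 100))
  expect_equal(gamma_shape_rate(2, 1), tibble::tibble(shape = 4, rate = 2))
  expect_error(gamma_shape_rate(0, 1), "positive")
  expect_error(gamma_shape_rate(1, -1), "positive")
  set.seed(17)
  for (pars in list(c(0.7, 0.2), c(1.3, 0.5))) {
    sr <- gamma_shape_rate(pars[1], pars[2])
    x <- stats::rgamma(1e6, sr$shape, sr$rate)
    expect_lt(abs(mean(x) - pars[1]), 4 * pars[2] / sqrt(1e6))
    expect_lt(abs(stats::sd(x) - pars[2]), 0.01 * pars[2])
  }
})

test_that("constant counts imply no trend", {
  d <- tidyr::expand_grid(site = 1:30, year = 1:15)
  d$count <- 35L
  fit <- quiet_fit(fit_state_space(d, control = mcmc_control(1, 400, 600),
                                   seed = 1))
  expect_gt(lambda_bar_sim(fit), 0.9)
  expect_lt(lambda_bar_sim(fit), 1.1)
})

test_that("the state-space fit recovers its own generating parameters", {
  set.seed(101)
  d <- gen_statespace_data(50, 25, 0.85, 0.10)
  fit <- quiet_fit(fit_state_space(d, control = mcmc_control(2, 500, 700),
                                   seed = 5))
  td <- tidy(fit)
  lb <- td[td$term == "lambda_bar", ]
  expect_lt(abs(lb$estimate - 0.85), 0.03)
  sg <- td[td$term == "sigma_lambda", ]
  expect_lt(abs(sg$estimate - 0.10), 0.04)
  expect_true(fit$diagnostics$rhat["lambda_bar"] < 1.1)
})

test_that("state-space posterior matches an independent JAGS fit", {
  skip_if_not_installed("rjags")
  set.seed(55)
  d <- gen_statespace_data(25, 12, 0.9, 0.15, N1 = 30)
  fit <- quiet_fit(fit_state_space(d, control = mcmc_control(2, 1500, 1500),
                                   seed = 6))
  y <- matrix(d$count, 25, 12)
  model_str <- "
  model {
    lambda_bar ~ dgamma(0.10, 0.10)
    sigma_lambda ~ dgamma(3, 1)
    r <- pow(lambda_bar, 2) / pow(sigma_lambda, 2)
    beta <- lambda_bar / pow(sigma_lambda, 2)
    for (i in 1:I) {
      logN1[i] ~ dunif(-300, log(U))
      N[i, 1] <- exp(logN1[i])
      y[i, 1] ~ dpois(N[i, 1])
      for (t in 2:T) {
        N[i, t] ~ dgamma(r, beta / N[i, t - 1])
        y[i, t] ~ dpois(N[i, t])
      }
    }
  }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = y, I = 25, T = 12, U = 10 * (max(y) + 1)),
    inits = list(lambda_bar = 1, sigma_lambda = 0.5,
                 logN1 = log(pmax(y[, 1], 1)),
                 .RNG.name = "base::Mersenne-Twister", .RNG.seed = 7),
    n.chains = 1, n.adapt = 1000, quiet = TRUE)
  update(jm, 1000, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("lambda_bar", "sigma_lambda"),
                            n.iter = 4000, progress.bar = "none")[[1]]
  expect_lt(abs(lambda_bar_sim(fit) - mean(js[, "lambda_bar"])), 0.015)
  expect_lt(abs(mean(fit$draws$sigma_lambda) -
                  mean(js[, "sigma_lambda"])), 0.03)
  expect_lt(abs(stats::sd(fit$draws$lambda_bar) -
                  stats::sd(js[, "lambda_bar"])) /
              stats::sd(js[, "lambda_bar"]), 0.5)
})

test_that("the N-mixture fit recovers a known constant detection", {
  set.seed(202)
  d <- gen_nmixture_data(200, 10, p = 0.5)
  fit <- quiet_fit(fit_nmixture(d, control = mcmc_control(1, 600, 800),
                                seed = 8))
  p_hat <- mean(fit$draws$p_mean)
  expect_lt(abs(p_hat - 0.5), 0.1)
  # latent integer abundance never below the observed maximum
  expect_true(all(fit$xtot >= 0))
})

test_that("identical occasions force detection towards one", {
  set.seed(7)
  X <- matrix(rpois(40 * 8, 25), 40, 8)
  d <- tidyr::expand_grid(site = 1:40, year = 1:8, occasion = 1:2)
  d$count <- X[cbind(d$site, d$year)]
  fit <- quiet_fit(fit_nmixture(d, control = mcmc_control(1, 400, 500),
                                seed = 9))
  expect_gt(mean(fit$draws$p_mean), 0.9)
})

test_that("state-space and N-mixture agree when detection is perfect", {
  sims <- run_scenario(scenario_config(2, n_sims = 1, n_sites = 60,
                                       n_years = 20, seed = 77))
  fit_ss <- quiet_fit(fit_state_space(sims$counts,
                                      control = mcmc_control(1, 500, 700),
                                      seed = 10))
  fit_nm <- quiet_fit(fit_nmixture(sims$counts,
                                   control = mcmc_control(1, 500, 700),
                                   seed = 11))
  expect_gt(mean(fit_nm$draws$p_mean), 0.95)
  expect_lt(abs(lambda_bar_sim(fit_ss) - lambda_bar_sim(fit_nm)), 0.03)
})

test_that("with no data the growth posterior reproduces its prior", {
  # small field so the field <-> (lambda_bar, sigma) Gibbs coupling is weak
  # enough to traverse the very heavy-tailed prior
  d <- tidyr::expand_grid(site = 1:2, year = 1:3)
  d$count <- NA_integer_
  fit <- quiet_fit(fit_state_space(d, control = mcmc_control(1, 2000, 20000),
                                   seed = 12))
  draws <- fit$draws$lambda_bar
  qs <- c(0.25, 0.5, 0.75, 0.9)
  prior_q <- stats::qgamma(qs, 0.10, 0.10)
  emp_q <- stats::quantile(draws, qs, names = FALSE)
  # quantile-quantile agreement, loose: heavy right tail, correlated draws
  for (k in seq_along(qs)) {
    expect_lt(abs(emp_q[k] - prior_q[k]),
              0.30 * max(prior_q[k], 0.2))
  }
})

test_that("the latent growth recursion holds for posterior abundance", {
  # pooled-abundance draws are sums of N that satisfy N_t = N_{t-1} lambda_t
  # with positive gamma multipliers, so pooled totals stay positive and the
  # per-draw trajectory is smooth in log space
  set.seed(1)
  d <- gen_statespace_data(20, 10, 0.9, 0.1)
  fit <- quiet_fit(fit_state_space(d, control = mcmc_control(1, 300, 300),
                                   seed = 13))
  expect_true(all(fit$ntot > 0))
  expect_equal(dim(fit$ntot), c(300L, 10L))
  pa <- pooled_abundance(fit)
  expect_true(all(pa$lower <= pa$mean & pa$mean <= pa$upper))
})

test_that("fits report convergence diagnostics and tidy summaries", {
  set.seed(3)
  d <- gen_statespace_data(15, 8, 0.9, 0.1)
  fit <- quiet_fit(fit_state_space(d, control = mcmc_control(2, 200, 200),
                                   seed = 14))
  td <- tidy(fit)
  expect_setequal(td$term, c("lambda_bar", "sigma_lambda"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_true(all(is.finite(td$rhat)))
  g <- glance(fit)
  expect_equal(g$n_sites, 15L)
  expect_equal(g$n_years, 8L)
  expect_equal(g$n_draws, 400L)
  expect_s3_class(g, "tbl_df")
})
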