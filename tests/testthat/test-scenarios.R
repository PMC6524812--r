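test_that("the scenario grid maps ids to their regimes", {
  s1 <- scenario_config(1)
  expect_equal(s1$attendance$mode, "perfect")
  expect_equal(s1$detection$p, 1)
  s2 <- scenario_config(2)
  expect_equal(s2$attendance$mode, "age_sex_fixed")
  expect_equal(s2$detection$p, 1)
  s6 <- scenario_config(6)
  expect_equal(s6$detection$p, 0.375)
  expect_equal(s6$attendance$p_sy_male, 0.60)
  expect_equal(s6$attendance$p_asy_male, 0.80)
  expect_equal(scenario_config(5)$detection$p, 0.25)
  expect_equal(scenario_config(7)$detection$p, 0.5)
  expect_equal(scenario_config(8)$detection$mode, "uniform_by_site")
  expect_equal(scenario_config(9)$detection$mode, "uniform_by_year")
  expect_equal(scenario_config(10)$detection$mode, "uniform_by_site_year")
  expect_equal(scenario_config(11)$detection$mode, "decreasing_trend")
  for (id in c(4, 12, 13)) {
    expect_equal(scenario_config(id)$attendance$mode, "density")
  }
  expect_equal(scenario_config(13)$detection$mode, "uniform_by_year")
  expect_equal(scenario_config(3)$attendance$mode, "perfect")
  expect_equal(scenario_config(3)$detection$p, 0.5)
  expect_error(scenario_config(1, nmixture = TRUE), "N-mixture")
  expect_error(scenario_config(2, nmixture = TRUE), "N-mixture")
  expect_no_error(scenario_config(3, nmixture = TRUE))
  # defaults mirror the monitoring design
  expect_equal(s1$n_sims, 100L)
  expect_equal(s1$n_sites, 300L)
  expect_equal(s1$n_years, 25L)
  expect_equal(s1$K, 25L)
  expect_equal(state_total(s1$init), 100L)
  expect_equal(s1$init$f_asy / (s1$init$f_asy + s1$init$f_sy), 0.6)
})

test_that("running a scenario yields consistent, reproducible tables", {
  cfg <- scenario_config(5, n_sims = 2, n_sites = 15, n_years = 6, seed = 33)
  a <- run_scenario(cfg)
  b <- run_scenario(cfg)
  expect_identical(a$counts, b$counts)   # bit-identical rerun
  expect_identical(a$truth, b$truth)

  expect_equal(nrow(a$truth), 2 * 15 * 6)
  expect_equal(nrow(a$counts), 2 * 15 * 6 * 2)
  joined <- dplyr::left_join(a$counts, a$truth,
                             by = c("simulation", "site", "year"))
  expect_true(all(joined$count <= joined$n_lek))
  expect_true(all(joined$n_lek <= joined$n_total))
  expect_true(all(a$truth$n_male + a$truth$n_female == a$truth$n_total))

  one_year <- run_scenario(scenario_config(1, n_sims = 1, n_sites = 5,
                                           n_years = 1, seed = 2))
  expect_equal(unique(one_year$counts$year), 1)
  expect_true(all(one_year$counts$count == 100L))
})

test_that("perfect attendance and detection reveal the truth exactly", {
  sims <- run_scenario(scenario_config(1, n_sims = 2, n_sites = 20,
                                       n_years = 8, seed = 14))
  joined <- dplyr::left_join(sims$counts, sims$truth,
                             by = c("simulation", "site", "year"))
  expect_equal(joined$count, joined$n_total)
  expect_true(all(sims$truth$p == 1))
})

test_that("demographic truth is shared across scenarios at a master seed", {
  t1 <- run_scenario(scenario_config(1, n_sims = 2, n_sites = 10,
                                     n_years = 6, seed = 8))$truth
  t2 <- run_scenario(scenario_config(2, n_sims = 2, n_sites = 10,
                                     n_years = 6, seed = 8))$truth
  t13 <- run_scenario(scenario_config(13, n_sims = 2, n_sites = 10,
                                      n_years = 6, seed = 8))$truth
  cols <- c("simulation", "site", "year", "n_total", "n_male", "n_female")
  expect_identical(t1[cols], t2[cols])
  expect_identical(t1[cols], t13[cols])
  # observation layers differ
  expect_false(identical(t1$n_lek, t2$n_lek))
})

test_that("extinction summaries count absorbed sites and pooled totals", {
  cfg <- scenario_config(2, n_sims = 3, n_sites = 40, n_years = 25,
                         seed = 99)
  sims <- run_scenario(cfg)
  ex <- extinction_summary(sims)
  expect_equal(nrow(ex), 3)
  final <- dplyr::filter(sims$truth, year == 25)
  by_hand <- final |>
    dplyr::group_by(simulation) |>
    dplyr::summarise(e = sum(n_total == 0), f = sum(n_total))
  expect_equal(ex$extinct_sites, by_hand$e)
  expect_equal(ex$final_total, by_hand$f)
  # at these rates, most 100-bird sites are extinct within 25 years
  expect_gt(sum(ex$extinct_sites), 0.8 * 3 * 40)
})

test_that("count tables round-trip through CSV", {
  sims <- run_scenario(scenario_config(6, n_sims = 1, n_sites = 8,
                                       n_years = 4, seed = 4))
  dir <- withr::local_tempdir()
  write_lek_counts(sims, dir)
  expect_true(file.exists(file.path(dir, "counts.csv")))
  back <- read_lek_counts(dir)
  expect_equal(as.data.frame(back$counts), as.data.frame(sims$counts))
  expect_equal(as.data.frame(back$truth), as.data.frame(sims$truth),
               tolerance = 1e-12)
})
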