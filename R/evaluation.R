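#' True long-term growth rate of a simulated trajectory set
#'
#' For one simulation, each site's annual growth ratios
#' \eqn{\lambda_{i,t} = N_{i,t}/N_{i,t-1}} are formed for consecutive years
#' in which both abundances are positive; the site's geometric mean of its
#' included ratios is then averaged over sites:
#' \deqn{\bar\lambda_{true} = \frac{1}{I}\sum_i
#'   \Big(\prod_t \lambda_{i,t}\Big)^{1/n_i}.}
#' Ratios with a zero numerator or denominator are log-undefined and are
#' excluded; a site with no valid ratio at all (extinct after year 1) is
#' dropped from the site average with a warning. With `use_root = FALSE`
#' the bare product is averaged instead of the per-year geometric mean.
#'
#' @param trajectories tibble with columns `site`, `year` and an abundance
#'   column (default `n_total`), for a single simulation.
#' @param abundance_col name of the abundance column.
#' @param use_root take the 1/(number of ratios) root (default), making
#'   the result an annual rate.
#' @return A single number.
#' @examples
#' tr <- tibble::tibble(site = rep(1:2, each = 3), year = rep(1:3, 2),
#'                      n_total = c(10, 12, 3.6, 10, 9, 8.1))
#' lambda_true(tr)
#' @export
lambda_true <- function(trajectories, abundance_col = "n_total",
                        use_root = TRUE) {
  stopifnot(all(c("site", "year", abundance_col) %in% names(trajectories)))
  if ("simulation" %in% names(trajectories) &&
      length(unique(trajectories$simulation)) > 1)
    stop("lambda_true() takes one simulation at a time", call. = FALSE)
  per_site <- trajectories |>
    dplyr::arrange(.data$site, .data$year) |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(g = site_geomean(.data[[abundance_col]], .data$year,
                                      use_root), .groups = "drop")
  bad <- is.na(per_site$g)
  if (any(bad))
    warning(sum(bad), " site(s) had no valid growth ratio and were ",
            "excluded", call. = FALSE)
  mean(per_site$g[!bad])
}

site_geomean <- function(n, year, use_root) {
  ok <- diff(year) == 1 & n[-length(n)] > 0 & n[-1] > 0
  if (!any(ok)) return(NA_real_)
  lr <- log(n[-1][ok]) - log(n[-length(n)][ok])
  if (use_root) exp(mean(lr)) else exp(sum(lr))
}

#' Bias of an estimated growth rate
#'
#' The signed difference \eqn{\theta_s = \bar\lambda_{sim,s} -
#' \bar\lambda_{true,s}}; positive values mean the monitoring design
#' overestimated growth.
#'
#' @param lambda_sim posterior-mean growth estimate(s).
#' @param lambda_true true simulated growth rate(s).
#' @return `lambda_sim - lambda_true`, vectorized.
#' @export
bias <- function(lambda_sim, lambda_true) {
  stopifnot(is.finite(lambda_sim), is.finite(lambda_true))
  lambda_sim - lambda_true
}

#' Summarise bias over replicate simulations
#'
#' @param theta vector of per-simulation biases.
#' @return A tibble with `mean`, `q2.5`, `q97.5` and `n_sims`.
#' @export
summarize_bias <- function(theta) {
  stopifnot(length(theta) >= 2)
  tibble::tibble(mean = mean(theta),
                 q2.5 = stats::quantile(theta, 0.025, names = FALSE),
                 q97.5 = stats::quantile(theta, 0.975, names = FALSE),
                 n_sims = length(theta))
}

#' First year the estimated-abundance interval covers the truth
#'
#' @param intervals tibble with columns `year`, `lower`, `upper` (e.g.
#'   from [pooled_abundance()]).
#' @param truth tibble with columns `year`, `n` (true pooled abundance),
#'   or a numeric vector aligned with `intervals$year`.
#' @return The smallest year whose interval contains the true value, or
#'   `Inf` if none does.
#' @examples
#' overlap_year(tibble::tibble(year = 1:3, lower = 10, upper = 20),
#'              c(25, 25, 15))
#' @export
overlap_year <- function(intervals, truth) {
  stopifnot(all(c("year", "lower", "upper") %in% names(intervals)))
  if (is.data.frame(truth)) {
    truth <- truth$n[match(intervals$year, truth$year)]
  }
  stopifnot(length(truth) == nrow(intervals),
            all(intervals$lower <= intervals$upper))
  hit <- which(truth >= intervals$lower & truth <= intervals$upper)
  if (length(hit) == 0) Inf else intervals$year[min(hit)]
}

fit_one_simulation <- function(counts_s, nmixture, control, prior, seed,
                               p_structure) {
  if (nmixture) {
    fit_nmixture(counts_s, p_structure = p_structure, control = control,
                 prior = prior, seed = seed)
  } else {
    fit_state_space(counts_s, control = control, prior = prior, seed = seed)
  }
}

#' Simulate a scenario and evaluate estimator bias per simulation
#'
#' Runs the full virtual-ecologist loop for one scenario: simulate truth
#' and counts, fit the configured estimator (state-space on max counts, or
#' N-mixture on the repeated counts when the scenario's `nmixture` flag is
#' set) separately to each simulation, and compare against the simulated
#' truth.
#'
#' @param config a [scenario_config()].
#' @param control [mcmc_control()] settings for each per-simulation fit.
#' @param prior [growth_prior()].
#' @param keep_draws keep each simulation's \eqn{\bar\lambda} draws as a
#'   list-column (needed for pooled posterior quantiles).
#' @param progress print a dot per fitted simulation.
#' @return An object of class `lek_bias_study`: a tibble with one row per
#'   simulation and columns `scenario`, `nmixture`, `simulation`,
#'   `lambda_sim`, `lambda_true`, `theta`, `lambda_q97.5` (per-sim upper
#'   credible limit), `overlap_year`, `max_rhat` and (optionally) the
#'   list-column `lambda_draws`.
#' @examples
#' \donttest{
#' ev <- evaluate_scenario(scenario_config(2, n_sims = 2, n_sites = 40,
#'                                         n_years = 12, seed = 11),
#'                         control = mcmc_control(1, 200, 300))
#' summarize_bias(ev$theta)
#' }
#' @export
evaluate_scenario <- function(config, control = mcmc_control(),
                              prior = growth_prior(),
                              p_structure = "by_site_year",
                              keep_draws = TRUE, progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  sims <- run_scenario(config)
  evaluate_sims(sims, control = control, prior = prior,
                p_structure = p_structure, keep_draws = keep_draws,
                progress = progress)
}

#' @rdname evaluate_scenario
#' @param sims an existing `lek_sims` object (so the same simulated data
#'   can be evaluated under both estimators).
#' @param nmixture override the scenario's analysis flag.
#' @param p_structure detection pooling used for N-mixture fits; the
#'   default mirrors the scenario analysis in which every site-year has
#'   its own Beta(1, 1) detection probability.
#' @export
evaluate_sims <- function(sims, nmixture = NULL, control = mcmc_control(),
                          prior = growth_prior(),
                          p_structure = "by_site_year", keep_draws = TRUE,
                          progress = FALSE) {
  stopifnot(inherits(sims, "lek_sims"))
  config <- sims$config
  if (is.null(nmixture)) nmixture <- config$nmixture
  truth_pooled <- sims$truth |>
    dplyr::group_by(.data$simulation, .data$year) |>
    dplyr::summarise(n = sum(.data$n_total), .groups = "drop")
  rows <- vector("list", config$n_sims)
  for (s in seq_len(config$n_sims)) {
    counts_s <- dplyr::filter(sims$counts, .data$simulation == s)
    truth_s <- dplyr::filter(sims$truth, .data$simulation == s)
    fit <- fit_one_simulation(counts_s, nmixture, control, prior,
                              seed = sims$seeds[s, 2] %% 1000003L + s,
                              p_structure = p_structure)
    lt <- suppressWarnings(lambda_true(truth_s))
    ls <- lambda_bar_sim(fit)
    ints <- pooled_abundance(fit)
    ov <- overlap_year(ints,
                       dplyr::filter(truth_pooled, .data$simulation == s))
    rows[[s]] <- tibble::tibble(
      scenario = config$id, nmixture = nmixture, simulation = s,
      lambda_sim = ls, lambda_true = lt, theta = bias(ls, lt),
      lambda_q97.5 = stats::quantile(fit$draws$lambda_bar, 0.975,
                                     names = FALSE),
      overlap_year = ov,
      max_rhat = max(fit$diagnostics$rhat, na.rm = TRUE),
      lambda_draws = if (keep_draws) list(fit$draws$lambda_bar) else
        list(NULL))
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  out <- dplyr::bind_rows(rows)
  if (!keep_draws) out$lambda_draws <- NULL
  class(out) <- c("lek_bias_study", class(out))
  out
}

#' Scenario-grid bias study
#'
#' Runs [evaluate_scenario()] over a set of scenario ids (optionally with
#' their N-mixture variants) and binds the per-simulation results,
#' mirroring the scenario-comparison figures of the virtual-ecologist
#' analysis.
#'
#' @param ids scenario ids to run.
#' @param nmixture also run the N-mixture variants of scenarios >= 3.
#' @param seed master seed; each scenario uses the same master seed, so
#'   demographic truth is shared across scenarios and only observation and
#'   analysis differ.
#' @inheritParams scenario_config
#' @inheritParams evaluate_scenario
#' @param ... passed to [scenario_config()].
#' @return A `lek_bias_study` tibble over all requested scenario variants.
#' @export
scenario_bias_study <- function(ids = 1:13, nmixture = FALSE,
                                n_sims = 20L, n_sites = 100L, n_years = 25L,
                                seed = 1L, control = mcmc_control(),
                                prior = growth_prior(),
                                p_structure = "by_site_year",
                                keep_draws = TRUE, progress = FALSE, ...) {
  runs <- list()
  for (id in ids) {
    cfg <- scenario_config(id, nmixture = FALSE, n_sims = n_sims,
                           n_sites = n_sites, n_years = n_years,
                           seed = seed, ...)
    sims <- run_scenario(cfg)
    runs[[length(runs) + 1]] <-
      evaluate_sims(sims, nmixture = FALSE, control = control,
                    prior = prior, keep_draws = keep_draws,
                    progress = progress)
    if (nmixture && id >= 3) {
      runs[[length(runs) + 1]] <-
        evaluate_sims(sims, nmixture = TRUE, control = control,
                      prior = prior, p_structure = p_structure,
                      keep_draws = keep_draws, progress = progress)
    }
  }
  out <- dplyr::bind_rows(runs)
  class(out) <- c("lek_bias_study", class(out))
  out
}

#' @rdname evaluate_scenario
#' @param x a `lek_bias_study`.
#' @param ... unused.
#' @export
tidy.lek_bias_study <- function(x, ...) {
  dplyr::as_tibble(x) |>
    dplyr::group_by(.data$scenario, .data$nmixture) |>
    dplyr::summarise(theta_mean = mean(.data$theta),
                     theta_q2.5 = stats::quantile(.data$theta, 0.025,
                                                  names = FALSE),
                     theta_q97.5 = stats::quantile(.data$theta, 0.975,
                                                   names = FALSE),
                     lambda_sim_mean = mean(.data$lambda_sim),
                     lambda_true_mean = mean(.data$lambda_true),
                     n_sims = dplyr::n(), .groups = "drop")
}

#' Sensitivity of the growth estimate to detection or carrying capacity
#'
#' Re-runs a reduced simulate-and-fit pipeline over a grid of one tuning
#' parameter -- the fixed detection probability `p` (age/sex attendance
#' template) or the lek carrying capacity `K` (density-attendance
#' template, p = 0.5) -- and reports the mean growth estimate, its bias,
#' and the finite-difference sensitivity between neighbouring grid points.
#'
#' @param parameter `"p"` or `"K"`.
#' @param grid numeric grid of parameter values.
#' @param n_sims,n_sites,n_years reduced problem size per grid point.
#' @param seed master seed (shared across grid points, so grid points
#'   differ only through the swept parameter).
#' @param control [mcmc_control()] settings.
#' @return A tibble with one row per grid value: `parameter`, `value`,
#'   `lambda_sim`, `lambda_true`, `theta` and `dlambda_dvalue`.
#' @export
sensitivity_sweep <- function(parameter = c("p", "K"), grid,
                              n_sims = 5L, n_sites = 50L, n_years = 25L,
                              seed = 1L,
                              control = mcmc_control(1L, 300L, 400L)) {
  parameter <- match.arg(parameter)
  stopifnot(length(grid) >= 1, is.numeric(grid))
  rows <- lapply(grid, function(val) {
    cfg <- if (parameter == "p") {
      stopifnot(val >= 0, val <= 1)
      cfg0 <- scenario_config(7, n_sims = n_sims, n_sites = n_sites,
                              n_years = n_years, seed = seed)
      cfg0$detection <- detection_model("fixed", p = val)
      cfg0
    } else {
      scenario_config(12, n_sims = n_sims, n_sites = n_sites,
                      n_years = n_years, seed = seed, K = as.integer(val))
    }
    ev <- evaluate_sims(run_scenario(cfg), control = control,
                        keep_draws = FALSE)
    tibble::tibble(parameter = parameter, value = val,
                   lambda_sim = mean(ev$lambda_sim),
                   lambda_true = mean(ev$lambda_true),
                   theta = mean(ev$theta))
  })
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$value)
  out$dlambda_dvalue <- c(NA_real_,
                          diff(out$lambda_sim) / diff(out$value))
  out
}
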