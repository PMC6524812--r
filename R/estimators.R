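#' Moment-matched Gamma parameters of the growth-rate distribution
#'
#' The annual growth multipliers \eqn{\lambda_{i,t}} are modelled as
#' Gamma(r, \eqn{\beta}) with shape \eqn{r = \bar\lambda^2/\sigma_\lambda^2}
#' and rate \eqn{\beta = \bar\lambda/\sigma_\lambda^2}, so the distribution
#' has mean \eqn{\bar\lambda} and standard deviation \eqn{\sigma_\lambda}.
#'
#' @param lambda_bar long-term mean growth rate (> 0), vectorized.
#' @param sigma_lambda between-site-year SD of growth rates (> 0).
#' @return A tibble with columns `shape` and `rate`.
#' @examples
#' gamma_shape_rate(1, 0.1)
#' @export
gamma_shape_rate <- function(lambda_bar, sigma_lambda) {
  if (any(lambda_bar <= 0) || any(sigma_lambda <= 0))
    stop("lambda_bar and sigma_lambda must be positive", call. = FALSE)
  tibble::tibble(shape = lambda_bar^2 / sigma_lambda^2,
                 rate = lambda_bar / sigma_lambda^2)
}

#' Prior specification for the growth model
#'
#' Defaults: \eqn{\bar\lambda \sim} Gamma(0.10, 0.10) and
#' \eqn{\sigma_\lambda \sim} Gamma(3, 1) (shape, rate).
#'
#' @param lambda_bar_shape,lambda_bar_rate Gamma prior on the long-term
#'   mean growth rate.
#' @param sigma_shape,sigma_rate Gamma prior on the growth-rate SD.
#' @return A named numeric vector used by the fitting functions.
#' @export
growth_prior <- function(lambda_bar_shape = 0.10, lambda_bar_rate = 0.10,
                         sigma_shape = 3, sigma_rate = 1) {
  c(lambda_bar_shape = lambda_bar_shape, lambda_bar_rate = lambda_bar_rate,
    sigma_shape = sigma_shape, sigma_rate = sigma_rate)
}

#' MCMC settings
#'
#' Defaults follow common practice for these models: 3 chains, 2000 warmup
#' and 2000 kept iterations each; convergence is flagged when the
#' rank-normalized split scale-reduction diagnostic exceeds `rhat_max`.
#' Reduced settings (1 chain, a few hundred iterations) are adequate for
#' posterior means in large simulation sweeps.
#'
#' @param n_chains number of independent chains.
#' @param n_warmup discarded warmup iterations per chain.
#' @param n_draws kept iterations per chain.
#' @param rhat_max convergence flag threshold.
#' @return A list of settings.
#' @export
mcmc_control <- function(n_chains = 3L, n_warmup = 2000L, n_draws = 2000L,
                         rhat_max = 1.05) {
  stopifnot(n_chains >= 1, n_warmup >= 0, n_draws >= 1)
  list(n_chains = as.integer(n_chains), n_warmup = as.integer(n_warmup),
       n_draws = as.integer(n_draws), rhat_max = rhat_max)
}

# counts -> I x T matrix of per-site-year max counts; site/year ids mapped
# to contiguous indices. NA where a site-year is absent.
counts_to_matrix <- function(counts, value_col = "count") {
  stopifnot(all(c("site", "year", value_col) %in% names(counts)))
  if ("occasion" %in% names(counts)) {
    counts <- counts |>
      dplyr::group_by(.data$site, .data$year) |>
      dplyr::summarise(count = max(.data[[value_col]]), .groups = "drop")
    value_col <- "count"
  }
  sites <- sort(unique(counts$site))
  years <- sort(unique(counts$year))
  if (!all(diff(years) == 1))
    stop("years must be contiguous", call. = FALSE)
  m <- matrix(NA_real_, length(sites), length(years),
              dimnames = list(sites, years))
  m[cbind(match(counts$site, sites), match(counts$year, years))] <-
    counts[[value_col]]
  m
}

# rank-normalized split-Rhat (chains: list of numeric vectors)
rhat_rank <- function(chains) {
  halves <- unlist(lapply(chains, function(ch) {
    h <- length(ch) %/% 2
    if (h < 2) return(list(ch))
    list(ch[1:h], ch[(h + 1):(2 * h)])
  }), recursive = FALSE)
  x <- unlist(halves)
  if (length(unique(x)) == 1) return(1)
  z <- stats::qnorm((rank(x) - 3 / 8) / (length(x) + 1 / 4))
  zs <- split(z, rep(seq_along(halves), lengths(halves)))
  m <- length(zs)
  n <- min(lengths(zs))
  zs <- lapply(zs, function(v) v[1:n])
  means <- vapply(zs, mean, numeric(1))
  vars <- vapply(zs, stats::var, numeric(1))
  B <- n * stats::var(means)
  W <- mean(vars)
  sqrt(((n - 1) / n * W + B / n) / W)
}

new_lek_fit <- function(kind, draws, ntot, xtot = NULL, p = NULL, nmean,
                        diagnostics, data_dims, control, prior) {
  structure(list(kind = kind, draws = draws, ntot = ntot, xtot = xtot,
                 p = p, nmean = nmean, diagnostics = diagnostics,
                 data_dims = data_dims, control = control, prior = prior),
            class = c(paste0("lek_fit_", kind), "lek_fit"))
}

#' Fit the state-space growth model to max counts
#'
#' The uncorrected analysis: the per-site-year maximum of the repeated
#' counts is treated as a Poisson observation of latent abundance,
#' \eqn{y_{i,t} \sim} Poisson(\eqn{N_{i,t}}), with
#' \eqn{N_{i,t} = N_{i,t-1}\lambda_{i,t}},
#' \eqn{\lambda_{i,t} \sim} Gamma(r, \eqn{\beta}) (see
#' [gamma_shape_rate()]), priors [growth_prior()] on
#' (\eqn{\bar\lambda, \sigma_\lambda}) and, by default, a flat prior on
#' the log initial abundance below \eqn{U = } `init_upper_mult`
#' \eqn{\times} (max count + 1) (see `init_prior`). All sites share
#' \eqn{(\bar\lambda, \sigma_\lambda)}.
#' Sampling uses a slice-within-Gibbs scheme on the exactly equivalent
#' parameterization \eqn{N_{i,t} | N_{i,t-1} \sim}
#' Gamma(r, \eqn{\beta/N_{i,t-1}}).
#'
#' @param counts tibble with columns `site`, `year`, and either `count`
#'   per site-year (already the max) or per-occasion rows with an
#'   `occasion` column, in which case the max is taken here. `NA` counts
#'   are treated as missing observations.
#' @param control [mcmc_control()] settings.
#' @param prior [growth_prior()] hyperparameters.
#' @param init_upper_mult multiplier setting the upper bound U on initial
#'   abundance.
#' @param init_prior prior on initial abundance: `"log_uniform"` (default,
#'   flat on log N over a wide range below U, scale-neutral) or
#'   `"uniform"` (flat on N over (0, U); with only two occasions this
#'   pulls the N-mixture posterior toward large N and small p).
#' @param seed RNG seed for the sampler (uses R's RNG stream if `NULL`).
#' @return A `lek_fit` object with posterior draws of `lambda_bar`,
#'   `sigma_lambda`, pooled abundance per year, posterior-mean site
#'   abundances and convergence diagnostics. `lambda_bar_sim(fit)` gives
#'   the posterior-mean growth rate; see also [tidy()][generics::tidy()],
#'   [glance()][generics::glance()] and [autoplot()][ggplot2::autoplot()].
#' @examples
#' sims <- run_scenario(scenario_config(2, n_sims = 1, n_sites = 20,
#'                                      n_years = 10, seed = 7))
#' fit <- fit_state_space(sims$counts,
#'                        control = mcmc_control(1, 200, 200), seed = 1)
#' glance(fit)
#' @export
fit_state_space <- function(counts, control = mcmc_control(),
                            prior = growth_prior(), init_upper_mult = 10,
                            init_prior = c("log_uniform", "uniform"),
                            seed = NULL) {
  init_prior <- match.arg(init_prior)
  y <- counts_to_matrix(counts)
  if (!is.null(seed)) set.seed(seed)
  ymax <- suppressWarnings(max(y, na.rm = TRUE))
  if (!is.finite(ymax)) ymax <- 0  # fully missing data: prior-only fit
  U <- init_upper_mult * (ymax + 1)
  logN0 <- log(pmax(ifelse(is.na(y), ymax / 2, y), 0.5))
  lbar0 <- init_lambda_bar(y)
  chains <- lapply(seq_len(control$n_chains), function(ch) {
    ss_sampler_cpp(y, U, control$n_warmup, control$n_draws, logN0, lbar0,
                   0.3, unname(prior),
                   if (init_prior == "uniform") 1L else 0L)
  })
  finalize_fit("ss", chains, y, control, prior)
}

#' Fit the N-mixture growth model to repeated counts
#'
#' Corrects for imperfect detection using the within-year repeated counts:
#' \eqn{y_{i,j,t} \sim} Binomial(\eqn{X_{i,t}, p_{t}}) with integer latent
#' abundance \eqn{X_{i,t} \sim} Poisson(\eqn{N_{i,t}}) and the same latent
#' growth process as [fit_state_space()]. Detection has a Beta(1, 1) prior
#' at the chosen pooling level; within-year closure of the attending
#' population is assumed. The integer \eqn{X} is sampled exactly from its
#' full conditional.
#'
#' @param counts tibble with columns `site`, `year`, `occasion`, `count`;
#'   every site-year must have all occasions.
#' @param p_structure pooling of detection probability: one `p` shared by
#'   the whole data set (default, identifiable with two occasions), one
#'   per year, or one per site-year cell (weakly identified).
#' @inheritParams fit_state_space
#' @return A `lek_fit` object; relative to [fit_state_space()] it adds
#'   posterior draws of detection (`p`, site-averaged per year) and of
#'   pooled integer abundance (`xtot`).
#' @examples
#' sims <- run_scenario(scenario_config(7, n_sims = 1, n_sites = 20,
#'                                      n_years = 10, seed = 7))
#' fit <- fit_nmixture(sims$counts,
#'                     control = mcmc_control(1, 200, 200), seed = 1)
#' tidy(fit)
#' @export
fit_nmixture <- function(counts, p_structure = c("shared", "by_year",
                                                 "by_site_year"),
                         control = mcmc_control(), prior = growth_prior(),
                         init_upper_mult = 10,
                         init_prior = c("log_uniform", "uniform"),
                         seed = NULL) {
  p_structure <- match.arg(p_structure)
  init_prior <- match.arg(init_prior)
  stopifnot(all(c("site", "year", "occasion", "count") %in% names(counts)))
  if (anyNA(counts$count)) stop("N-mixture counts cannot be NA",
                                call. = FALSE)
  sites <- sort(unique(counts$site))
  years <- sort(unique(counts$year))
  occ <- sort(unique(counts$occasion))
  J <- length(occ)
  if (!all(diff(years) == 1)) stop("years must be contiguous", call. = FALSE)
  I <- length(sites)
  T <- length(years)
  ym <- matrix(NA_integer_, I, T * J)
  col <- (match(counts$year, years) - 1L) * J + match(counts$occasion, occ)
  ym[cbind(match(counts$site, sites), col)] <- as.integer(counts$count)
  if (anyNA(ym)) stop("every site-year needs all occasions", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ymax_it <- matrix(0, I, T)
  for (j in seq_len(J)) ymax_it <- pmax(ymax_it, ym[, seq(j, T * J, J),
                                                    drop = FALSE])
  U <- init_upper_mult * (max(ym) + 1)
  logN0 <- log(pmax(ymax_it, 0.5))
  lbar0 <- init_lambda_bar(ymax_it)
  pcode <- match(p_structure, c("shared", "by_year", "by_site_year")) - 1L
  chains <- lapply(seq_len(control$n_chains), function(ch) {
    nmix_sampler_cpp(ym, J, U, control$n_warmup, control$n_draws, logN0,
                     lbar0, 0.3, unname(prior), pcode,
                     if (init_prior == "uniform") 1L else 0L)
  })
  finalize_fit("nmix", chains, ymax_it, control, prior,
               p_structure = p_structure)
}

init_lambda_bar <- function(y) {
  tot <- colSums(y, na.rm = TRUE)
  tot <- tot[tot > 0]
  if (length(tot) < 2) return(1)
  lb <- mean(tot[-1] / tot[-length(tot)])
  min(max(lb, 0.2), 2)
}

finalize_fit <- function(kind, chains, y, control, prior,
                         p_structure = NULL) {
  n_chains <- length(chains)
  lb_chains <- lapply(chains, `[[`, "lambda_bar")
  sg_chains <- lapply(chains, `[[`, "sigma_lambda")
  draws <- tibble::tibble(
    chain = rep(seq_len(n_chains), each = control$n_draws),
    iteration = rep(seq_len(control$n_draws), n_chains),
    lambda_bar = unlist(lb_chains),
    sigma_lambda = unlist(sg_chains))
  ntot <- do.call(rbind, lapply(chains, `[[`, "ntot"))
  nmean <- Reduce(`+`, lapply(chains, `[[`, "nmean")) / n_chains
  xtot <- NULL
  p <- NULL
  if (kind == "nmix") {
    xtot <- do.call(rbind, lapply(chains, `[[`, "xtot"))
    p <- do.call(rbind, lapply(chains, `[[`, "p"))
    draws$p_mean <- rowMeans(p)
  }
  diagnostics <- c(lambda_bar = rhat_rank(lb_chains),
                   sigma_lambda = rhat_rank(sg_chains))
  if (!is.null(p))
    diagnostics["p_mean"] <- rhat_rank(split(rowMeans(p),
                                             draws$chain))
  converged <- n_chains < 2 || all(diagnostics < control$rhat_max,
                                   na.rm = TRUE)
  if (n_chains >= 2 && !converged)
    warning("convergence diagnostic exceeded ",
            control$rhat_max, " (max Rhat = ",
            round(max(diagnostics), 3), ")", call. = FALSE)
  fit <- new_lek_fit(kind, draws, ntot, xtot, p, nmean,
                     list(rhat = diagnostics, converged = converged),
                     dim(y), control, prior)
  fit$p_structure <- p_structure
  fit
}

#' Posterior-mean long-term growth rate
#'
#' The scalar summary used throughout the bias evaluation: the mean of the
#' \eqn{\bar\lambda} draws over all kept MCMC iterations.
#'
#' @param fit a `lek_fit` object.
#' @return A single number.
#' @export
lambda_bar_sim <- function(fit) {
  stopifnot(inherits(fit, "lek_fit"))
  mean(fit$draws$lambda_bar)
}

#' Posterior interval of pooled abundance per year
#'
#' @param fit a `lek_fit` object.
#' @param level interval mass.
#' @param which `"n"` for latent mean abundance (both models) or `"x"` for
#'   the integer abundance of the N-mixture model.
#' @return A tibble `year`, `mean`, `lower`, `upper`.
#' @export
pooled_abundance <- function(fit, level = 0.95, which = c("n", "x")) {
  stopifnot(inherits(fit, "lek_fit"))
  which <- match.arg(which)
  m <- if (which == "x") fit$xtot else fit$ntot
  if (is.null(m)) stop("no latent X draws in this fit", call. = FALSE)
  a <- (1 - level) / 2
  tibble::tibble(year = seq_len(ncol(m)),
                 mean = colMeans(m),
                 lower = apply(m, 2, stats::quantile, a),
                 upper = apply(m, 2, stats::quantile, 1 - a))
}

#' @export
print.lek_fit <- function(x, ...) {
  cat(sprintf("<lek_fit: %s> %d sites x %d years, %d chain(s) x %d draws\n",
              if (x$kind == "ss") "state-space" else "N-mixture",
              x$data_dims[1], x$data_dims[2], x$control$n_chains,
              x$control$n_draws))
  print(tidy(x), ...)
  invisible(x)
}

#' @rdname fit_state_space
#' @param x a `lek_fit` object.
#' @param ... unused.
#' @export
tidy.lek_fit <- function(x, ...) {
  pars <- c("lambda_bar", "sigma_lambda",
            if (x$kind == "nmix") "p_mean")
  purrr::map_dfr(pars, function(par) {
    v <- x$draws[[par]]
    tibble::tibble(term = par, estimate = mean(v),
                   std.error = stats::sd(v),
                   conf.low = stats::quantile(v, 0.025, names = FALSE),
                   conf.high = stats::quantile(v, 0.975, names = FALSE),
                   rhat = unname(x$diagnostics$rhat[par]))
  })
}

#' @rdname fit_state_space
#' @export
glance.lek_fit <- function(x, ...) {
  tibble::tibble(lambda_bar = lambda_bar_sim(x),
                 sigma_lambda = mean(x$draws$sigma_lambda),
                 n_sites = x$data_dims[1], n_years = x$data_dims[2],
                 n_chains = x$control$n_chains,
                 n_draws = nrow(x$draws),
                 max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
                 converged = x$diagnostics$converged)
}
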