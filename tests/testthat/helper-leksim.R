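# Shared fixtures and small oracles used across test files.

# vital rates with all SDs zeroed (deterministic realized rates)
vr_means <- function() dplyr::mutate(default_vital_rates(), sd = 0)

# one-row realized-rate tibble at the configured means
rates_at_means <- function(spec = default_vital_rates()) {
  draw_realized_rates(dplyr::mutate(spec, sd = 0), n = 1)
}

# independent closed-form fecundity oracle evaluated from raw numbers
# (kept separate from expected_fecundity on purpose)
fecundity_oracle <- function(r, n1, n2) {
  (r$nest_propensity * r$clutch1 * n1 +
     (1 - n1) * r$renest * r$clutch2 * n2) *
    r$chick_survival * r$juvenile_survival * 0.5 * r$hatch
}

# simulate data from the state-space model itself (the estimator's own
# generative process), for parameter-recovery checks
gen_statespace_data <- function(I, T, lambda_bar, sigma_lambda, N1 = 40) {
  sr <- gamma_shape_rate(lambda_bar, sigma_lambda)
  N <- matrix(0, I, T)
  N[, 1] <- N1
  for (t in 2:T) N[, t] <- N[, t - 1] * stats::rgamma(I, sr$shape, sr$rate)
  tibble::tibble(site = rep(seq_len(I), T), year = rep(seq_len(T), each = I),
                 count = stats::rpois(I * T, as.vector(N)))
}

# two-occasion N-mixture data with known constant X-level and detection
gen_nmixture_data <- function(I, T, p, x_mean = 30) {
  X <- matrix(stats::rpois(I * T, x_mean), I, T)
  d <- tidyr::expand_grid(site = seq_len(I), year = seq_len(T),
                          occasion = 1:2)
  d$count <- stats::rbinom(nrow(d), X[cbind(d$site, d$year)], p)
  d
}

modal_year <- function(x) {
  x <- x[is.finite(x)]
  as.numeric(names(sort(table(x), decreasing = TRUE))[1])
}

quiet_fit <- function(expr) suppressWarnings(expr)
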