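#' Lek-attendance model
#'
#' Describes which fraction of each demographic class is present on the lek
#' (and hence available to be counted) in a given year.
#'
#' * `"perfect"`: every individual attends (probability 1, no noise).
#' * `"age_sex_fixed"`: class-specific annual attendance; by default SY
#'   males 0.60, ASY males 0.80, females 0.30, each with between-year
#'   SD 0.10.
#' * `"density"`: male attendance is governed by the lek carrying capacity,
#'   \eqn{\gamma = \min(1, K / N_{male})} (see [density_gamma()]), with
#'   SD 0.10 noise; female attendance stays at its fixed value.
#'
#' @param mode one of `"perfect"`, `"age_sex_fixed"`, `"density"`.
#' @param p_sy_male,p_asy_male,p_female mean annual attendance
#'   probabilities by class.
#' @param sd between-year SD of the (truncated-normal) attendance draws.
#' @param K lek carrying capacity in males (used by `"density"`).
#' @return An object of class `attendance_model`.
#' @export
attendance_model <- function(mode = c("age_sex_fixed", "perfect", "density"),
                             p_sy_male = 0.60, p_asy_male = 0.80,
                             p_female = 0.30, sd = 0.10, K = 25L) {
  mode <- match.arg(mode)
  stopifnot(p_sy_male >= 0, p_sy_male <= 1, p_asy_male >= 0, p_asy_male <= 1,
            p_female >= 0, p_female <= 1, sd >= 0, K > 0, K == as.integer(K))
  structure(list(mode = mode, p_sy_male = p_sy_male,
                 p_asy_male = p_asy_male, p_female = p_female, sd = sd,
                 K = as.integer(K)),
            class = "attendance_model")
}

#' Density-dependent lek attendance probability
#'
#' When the male population exceeds the lek carrying capacity `K`, only a
#' fraction \eqn{\gamma = K / N_{male}} of males can attend; below capacity
#' everyone attends (\eqn{\gamma = 1}). The boundary `male_total == K`
#' gives 1 under both readings.
#'
#' @param K lek carrying capacity (males), positive.
#' @param male_total total male abundance at the site (vectorized).
#' @return Attendance probability in (0, 1].
#' @examples
#' density_gamma(25, c(10, 25, 50, 100))
#' @export
density_gamma <- function(K, male_total) {
  if (any(K <= 0)) stop("K must be positive", call. = FALSE)
  stopifnot(all(male_total >= 0))
  ifelse(male_total <= K, 1, K / male_total)
}

#' Sample annual lek attendance
#'
#' For each site-year, a class attendance probability is drawn from a
#' normal distribution (mean per the model, SD per the model, truncated to
#' \[0, 1\]) and each individual then attends by an independent Bernoulli
#' trial. Attendance is annual: the attending population is fixed within a
#' year, which is what holds the available count constant across the
#' within-year survey occasions.
#'
#' @param state site-state tibble (one row per site).
#' @param model an [attendance_model()].
#' @return A tibble with columns `n_lek` (total attending), `att_m`
#'   (attending males) and `att_f` (attending females), one row per site.
#' @examples
#' set.seed(1)
#' sample_attendance(site_state(20, 30, 20, 30), attendance_model())
#' @export
sample_attendance <- function(state, model) {
  state <- validate_site_state(state)
  stopifnot(inherits(model, "attendance_model"))
  n <- nrow(state)
  if (model$mode == "perfect") {
    att_m <- state$m_sy + state$m_asy
    att_f <- state$f_sy + state$f_asy
    return(tibble::tibble(n_lek = att_m + att_f, att_m = att_m,
                          att_f = att_f))
  }
  p_f <- rtruncnorm_vec(n, model$p_female, model$sd, 0, 1)
  if (model$mode == "age_sex_fixed") {
    p_sy <- rtruncnorm_vec(n, model$p_sy_male, model$sd, 0, 1)
    p_asy <- rtruncnorm_vec(n, model$p_asy_male, model$sd, 0, 1)
    att_m <- stats::rbinom(n, state$m_sy, p_sy) +
      stats::rbinom(n, state$m_asy, p_asy)
  } else {  # density
    gam <- density_gamma(model$K, state$m_sy + state$m_asy)
    p_m <- rtruncnorm_vec(n, gam, model$sd, 0, 1)
    att_m <- stats::rbinom(n, state$m_sy + state$m_asy, p_m)
  }
  att_f <- stats::rbinom(n, state$f_sy + state$f_asy, p_f)
  tibble::tibble(n_lek = att_m + att_f, att_m = att_m, att_f = att_f)
}

#' Detection-probability model
#'
#' Describes the probability that an attending bird is recorded on one
#' survey occasion.
#'
#' * `"perfect"` / `"fixed"`: constant `p` (1 for perfect).
#' * `"uniform_by_site"`, `"uniform_by_year"`, `"uniform_by_site_year"`:
#'   `p` drawn from Uniform(`low`, `high`) once per site, per year, or per
#'   site-year cell.
#' * `"decreasing_trend"`: `p` starts at `start` and falls by `step` per
#'   year, clamped at `floor` (defaults 0.75, 0.03, 0.25), identical
#'   across sites.
#'
#' @param mode detection regime (see Details).
#' @param p constant detection probability for `"fixed"`.
#' @param low,high bounds of the uniform regimes.
#' @param start,step,floor parameters of the decreasing trend.
#' @return An object of class `detection_model`.
#' @export
detection_model <- function(mode = c("fixed", "perfect", "uniform_by_site",
                                     "uniform_by_year",
                                     "uniform_by_site_year",
                                     "decreasing_trend"),
                            p = 0.5, low = 0.25, high = 0.75, start = 0.75,
                            step = 0.03, floor = 0.25) {
  mode <- match.arg(mode)
  if (mode == "perfect") p <- 1
  stopifnot(p >= 0, p <= 1, low >= 0, high <= 1, low <= high,
            start >= 0, start <= 1, floor >= 0, floor <= start, step >= 0)
  structure(list(mode = mode, p = p, low = low, high = high, start = start,
                 step = step, floor = floor),
            class = "detection_model")
}

#' Realize a detection-probability schedule
#'
#' Produces the site-by-year matrix of detection probabilities implied by a
#' [detection_model()]: constant for the fixed regimes, one uniform draw
#' per site / per year / per cell for the random regimes, and the clamped
#' linear decline \eqn{p_t = \max(floor, start - step (t - 1))} for the
#' trend regime.
#'
#' @param model a [detection_model()].
#' @param n_sites,n_years dimensions of the schedule.
#' @return A numeric `n_sites` x `n_years` matrix of probabilities.
#' @examples
#' detection_schedule(detection_model("decreasing_trend"), 2, 25)[1, ]
#' @export
detection_schedule <- function(model, n_sites, n_years) {
  stopifnot(inherits(model, "detection_model"), n_sites >= 1, n_years >= 1)
  switch(model$mode,
    perfect = ,
    fixed = matrix(model$p, n_sites, n_years),
    uniform_by_site = matrix(stats::runif(n_sites, model$low, model$high),
                             n_sites, n_years),
    uniform_by_year = matrix(stats::runif(n_years, model$low, model$high),
                             n_sites, n_years, byrow = TRUE),
    uniform_by_site_year = matrix(
      stats::runif(n_sites * n_years, model$low, model$high),
      n_sites, n_years),
    decreasing_trend = matrix(
      pmax(model$floor, model$start - model$step * (seq_len(n_years) - 1)),
      n_sites, n_years, byrow = TRUE)
  )
}

#' Simulate repeated lek counts
#'
#' Each survey occasion records an independent Binomial(`n_lek`, `p`) count
#' of the attending birds. The attending total is fixed within a year
#' (annual attendance, within-year closure) and the same `p` applies to
#' every occasion of a year.
#'
#' @param n_lek vector of attending totals (one per site).
#' @param p detection probability, scalar or vector matching `n_lek`.
#' @param n_occasions number of repeated counts per year.
#' @return An integer matrix `length(n_lek)` x `n_occasions`.
#' @examples
#' set.seed(1)
#' observe_counts(c(40, 10), p = 0.5)
#' @export
observe_counts <- function(n_lek, p, n_occasions = 2L) {
  stopifnot(all(n_lek >= 0), all(p >= 0), all(p <= 1), n_occasions >= 1)
  n <- length(n_lek)
  matrix(stats::rbinom(n * n_occasions, rep(n_lek, n_occasions),
                       rep(p, length.out = n * n_occasions)),
         nrow = n, ncol = n_occasions)
}
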