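#' Construct site population states
#'
#' A site state holds the pre-breeding census of one site: non-negative
#' integer head-counts by sex and age class (SY = second-year, ASY =
#' after-second-year) plus the 1-based year index. All demographic
#' operations are vectorized over the rows of a site-state tibble, so a
#' tibble with one row per site represents a whole landscape.
#'
#' @param f_sy,f_asy,m_sy,m_asy head-counts of SY/ASY females and males.
#' @param year 1-based year index.
#' @return A tibble with columns `f_sy`, `f_asy`, `m_sy`, `m_asy`, `year`.
#' @examples
#' site_state(f_sy = 20, f_asy = 30, m_sy = 20, m_asy = 30)
#' @export
site_state <- function(f_sy, f_asy, m_sy, m_asy, year = 1L) {
  st <- tibble::tibble(f_sy = as.integer(f_sy), f_asy = as.integer(f_asy),
                       m_sy = as.integer(m_sy), m_asy = as.integer(m_asy),
                       year = as.integer(year))
  validate_site_state(st)
}

validate_site_state <- function(st) {
  cols <- c("f_sy", "f_asy", "m_sy", "m_asy")
  stopifnot(is.data.frame(st), all(c(cols, "year") %in% names(st)))
  if (any(unlist(st[cols]) < 0))
    stop("site-state counts must be non-negative", call. = FALSE)
  st
}

#' @rdname site_state
#' @param state a site-state tibble.
#' @export
state_total <- function(state) {
  state$f_sy + state$f_asy + state$m_sy + state$m_asy
}

# Recycle a realized-rate tibble to the number of site rows.
recycle_rates <- function(rates, n) {
  if (nrow(rates) == n) return(rates)
  if (nrow(rates) == 1) return(rates[rep(1L, n), ])
  stop("`rates` must have 1 row or one row per site", call. = FALSE)
}

#' Simulate one breeding season of reproduction
#'
#' Runs the stage-wise reproductive chain for every female at each site:
#' nest-success potential and nest initiation, an integer clutch (the
#' site-year's realized clutch size rounded to the nearest non-negative
#' integer), renesting after first-nest failure, per-egg hatching, chick
#' survival to 60 days, juvenile survival to the next breeding season, and
#' a 50:50 offspring sex ratio. Recruits enter the next census as SY birds;
#' their first-year survival is already included in juvenile survival, so
#' they are not exposed to adult mortality in their birth year. The
#' stage-wise expectation per female equals [expected_fecundity()] (up to
#' clutch rounding).
#'
#' @param state site-state tibble (one row per site).
#' @param rates realized-rate tibble with one row per site (or a single
#'   row, recycled).
#' @return A tibble with integer columns `recruit_f`, `recruit_m`.
#' @examples
#' set.seed(1)
#' st <- site_state(20, 30, 20, 30)
#' reproduce(st, draw_realized_rates(default_vital_rates(), n = 1))
#' @export
reproduce <- function(state, rates) {
  state <- validate_site_state(state)
  n <- nrow(state)
  rates <- recycle_rates(rates, n)
  c1 <- pmax(0L, as.integer(round(rates$clutch1)))
  c2 <- pmax(0L, as.integer(round(rates$clutch2)))
  eggs <- integer(n)
  for (age in c("SY", "ASY")) {
    females <- if (age == "SY") state$f_sy else state$f_asy
    n1 <- if (age == "SY") rates$nest1_SY else rates$nest1_ASY
    n2 <- if (age == "SY") rates$nest2_SY else rates$nest2_ASY
    # Latent first-nest success potential is drawn for every female; eggs
    # from a first nest require initiation AND success, while the
    # second-nest chain is triggered by lack of first-nest success. This
    # makes the per-female expectation match the closed-form fecundity, in
    # which nesting propensity multiplies only the first-nest term.
    success_pot <- stats::rbinom(n, females, n1)
    nests1 <- stats::rbinom(n, success_pot, rates$nest_propensity)
    renesters <- stats::rbinom(n, females - success_pot, rates$renest)
    nests2 <- stats::rbinom(n, renesters, n2)
    eggs <- eggs + nests1 * c1 + nests2 * c2
  }
  hatched <- stats::rbinom(n, eggs, rates$hatch)
  chicks <- stats::rbinom(n, hatched, rates$chick_survival)
  juveniles <- stats::rbinom(n, chicks, rates$juvenile_survival)
  recruit_f <- stats::rbinom(n, juveniles, 0.5)
  tibble::tibble(recruit_f = recruit_f, recruit_m = juveniles - recruit_f)
}

#' Apply annual mortality
#'
#' Each male survives with probability `male_adult_survival`; each female
#' survives the year with probability `female_survival_breeding *
#' female_survival_nonbreeding` (the two seasonal survivals act in series).
#' Survival is an independent Bernoulli trial per individual.
#'
#' @inheritParams reproduce
#' @return A site-state tibble of survivors (year unchanged).
#' @export
apply_mortality <- function(state, rates) {
  state <- validate_site_state(state)
  n <- nrow(state)
  rates <- recycle_rates(rates, n)
  s_f <- rates$female_survival_breeding * rates$female_survival_nonbreeding
  s_m <- rates$male_adult_survival
  tibble::tibble(
    f_sy = stats::rbinom(n, state$f_sy, s_f),
    f_asy = stats::rbinom(n, state$f_asy, s_f),
    m_sy = stats::rbinom(n, state$m_sy, s_m),
    m_asy = stats::rbinom(n, state$m_asy, s_m),
    year = state$year
  )
}

#' Age the population by one year
#'
#' Surviving SY birds graduate to ASY; the season's recruits become the new
#' SY cohort; the year index advances by one.
#'
#' @param state site-state tibble of post-mortality survivors.
#' @param recruits tibble with columns `recruit_f`, `recruit_m` (from
#'   [reproduce()]).
#' @return The next year's site-state tibble.
#' @export
advance_age <- function(state, recruits) {
  state <- validate_site_state(state)
  stopifnot(nrow(recruits) == nrow(state))
  tibble::tibble(
    f_sy = as.integer(recruits$recruit_f),
    f_asy = state$f_asy + state$f_sy,
    m_sy = as.integer(recruits$recruit_m),
    m_asy = state$m_asy + state$m_sy,
    year = state$year + 1L
  )
}

#' Advance the population one full year
#'
#' Composes the annual life cycle in order: draw realized vital rates for
#' the site-year, reproduction, annual mortality of adults, and aging
#' (recruits enter as next year's SY cohort). Lek attendance is part of the
#' observation layer, not the demographic transition; see
#' [sample_attendance()].
#'
#' @param state site-state tibble (one row per site).
#' @param spec vital-rate tibble (see [default_vital_rates()]).
#' @return The next year's site-state tibble.
#' @examples
#' set.seed(1)
#' step_year(site_state(20, 30, 20, 30), default_vital_rates())
#' @export
step_year <- function(state, spec) {
  state <- validate_site_state(state)
  rates <- draw_realized_rates(spec, n = nrow(state))
  recruits <- reproduce(state, rates)
  survivors <- apply_mortality(state, rates)
  advance_age(survivors, recruits)
}
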