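#' Default demographic parameters of the simulated grouse population
#'
#' Returns the literature-derived vital rates used by the individual-based
#' model: survival, nesting, clutch size, hatchability, chick and juvenile
#' survival, and age/sex-specific lek attendance, each as a mean and a
#' between-year standard deviation. Clutch sizes are in eggs; all other
#' parameters are probabilities. The hatch rate has no reported SD and is
#' treated as fixed (sd = 0).
#'
#' @return A tibble with columns `parameter`, `mean`, `sd` and `kind`
#'   (`"probability"` or `"count"`), one row per parameter.
#' @examples
#' default_vital_rates()
#' @export
default_vital_rates <- function() {
  vr <- tibble::tribble(
    ~parameter,                   ~mean, ~sd,  ~kind,
    "male_adult_survival",         0.45, 0.06, "probability",
    "female_survival_breeding",    0.49, 0.05, "probability",
    "female_survival_nonbreeding", 0.73, 0.04, "probability",
    "nest_propensity",             0.95, 0.04, "probability",
    "clutch1",                    10.80, 2.17, "count",
    "nest1_SY",                    0.47, 0.04, "probability",
    "nest1_ASY",                   0.44, 0.05, "probability",
    "renest",                      0.33, 0.15, "probability",
    "clutch2",                     8.17, 2.02, "count",
    "nest2_SY",                    0.50, 0.01, "probability",
    "nest2_ASY",                   0.33, 0.08, "probability",
    "hatch",                       0.93, 0.00, "probability",
    "chick_survival",              0.26, 0.01, "probability",
    "juvenile_survival",           0.54, 0.09, "probability",
    "attendance_SY_male",          0.60, 0.10, "probability",
    "attendance_ASY_male",         0.80, 0.10, "probability",
    "attendance_female",           0.30, 0.10, "probability"
  )
  validate_vital_rates(vr)
}

validate_vital_rates <- function(vr) {
  stopifnot(is.data.frame(vr),
            all(c("parameter", "mean", "sd", "kind") %in% names(vr)))
  probs <- vr$kind == "probability"
  if (any(vr$mean[probs] < 0 | vr$mean[probs] > 1))
    stop("probability means must lie in [0, 1]", call. = FALSE)
  if (any(vr$mean[!probs] <= 0))
    stop("clutch-size means must be positive", call. = FALSE)
  if (any(vr$sd < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  miss <- setdiff(default_parameter_names(), vr$parameter)
  if (length(miss) > 0)
    stop("missing vital-rate parameters: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tibble::as_tibble(vr)
}

default_parameter_names <- function() {
  c("male_adult_survival", "female_survival_breeding",
    "female_survival_nonbreeding", "nest_propensity", "clutch1", "nest1_SY",
    "nest1_ASY", "renest", "clutch2", "nest2_SY", "nest2_ASY", "hatch",
    "chick_survival", "juvenile_survival", "attendance_SY_male",
    "attendance_ASY_male", "attendance_female")
}

#' Read vital-rate overrides from a YAML configuration file
#'
#' The file maps parameter names to `{mean: ..., sd: ...}` entries; any
#' parameter not listed keeps its default value. See
#' [default_vital_rates()] for the parameter names.
#'
#' @param path path to a YAML file.
#' @param defaults tibble of defaults to override.
#' @return A vital-rate tibble like [default_vital_rates()].
#' @export
read_vital_rates <- function(path, defaults = default_vital_rates()) {
  cfg <- yaml::read_yaml(path)
  vr <- defaults
  for (nm in names(cfg)) {
    if (!nm %in% vr$parameter)
      stop("unknown vital-rate parameter in config: ", nm, call. = FALSE)
    i <- match(nm, vr$parameter)
    if (!is.null(cfg[[nm]]$mean)) vr$mean[i] <- as.numeric(cfg[[nm]]$mean)
    if (!is.null(cfg[[nm]]$sd)) vr$sd[i] <- as.numeric(cfg[[nm]]$sd)
  }
  validate_vital_rates(vr)
}

# Draw one truncated-normal realization per (row, parameter). Probabilities
# are truncated to [0, 1], clutch sizes to [0, Inf); sd = 0 parameters are
# returned at their mean. Exact inverse-CDF truncation, vectorized.
rtruncnorm_vec <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, length.out = n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Draw annual realizations of the vital rates
#'
#' Each parameter is drawn independently from a normal distribution with
#' its configured mean and SD, truncated to the parameter's valid range
#' ([0, 1] for probabilities, non-negative for clutch sizes). Parameters
#' with sd = 0 are returned at their mean. One independent realization is
#' produced per requested row, representing independent site-years.
#'
#' @param spec vital-rate tibble from [default_vital_rates()] or
#'   [read_vital_rates()].
#' @param n number of independent realizations (site-years).
#' @return A tibble with `n` rows and one column per parameter.
#' @examples
#' set.seed(1)
#' draw_realized_rates(default_vital_rates(), n = 3)
#' @export
draw_realized_rates <- function(spec, n = 1) {
  spec <- validate_vital_rates(spec)
  out <- lapply(seq_len(nrow(spec)), function(i) {
    hi <- if (spec$kind[i] == "probability") 1 else Inf
    rtruncnorm_vec(n, spec$mean[i], spec$sd[i], 0, hi)
  })
  names(out) <- spec$parameter
  tibble::as_tibble(out)
}

#' Expected recruits per female (single-sex fecundity)
#'
#' Closed-form expectation of the number of same-sex recruits produced per
#' female that survive to the next breeding season:
#' \deqn{F_j = [P \times C_1 \times S_{1,j} + (1 - S_{1,j}) \times R \times
#'   C_2 \times S_{2,j}] \times \phi_c \times \phi_juv \times 0.5 \times H}
#' where \eqn{P} is nesting propensity, \eqn{C_1, C_2} the clutch sizes,
#' \eqn{S_{1,j}, S_{2,j}} the age-specific nest success of first and second
#' nests, \eqn{R} the renesting probability, \eqn{H} the hatch rate,
#' \eqn{\phi_c} chick survival to 60 days and \eqn{\phi_{juv}} survival
#' from 60 days to the next breeding season; the factor 0.5 is the offspring
#' sex ratio. Nesting propensity enters only the first-nest term.
#'
#' @param rates a one-row realized-rate tibble (see
#'   [draw_realized_rates()]) or any list with the named parameters.
#' @param age `"SY"` (second-year) or `"ASY"` (after-second-year) female.
#' @return Expected recruits per female, per offspring sex.
#' @examples
#' vr <- default_vital_rates()
#' means <- draw_realized_rates(dplyr::mutate(vr, sd = 0), n = 1)
#' expected_fecundity(means, "SY")
#' @export
expected_fecundity <- function(rates, age = c("SY", "ASY")) {
  age <- match.arg(age)
  n1 <- if (age == "SY") rates$nest1_SY else rates$nest1_ASY
  n2 <- if (age == "SY") rates$nest2_SY else rates$nest2_ASY
  (rates$nest_propensity * rates$clutch1 * n1 +
     (1 - n1) * rates$renest * rates$clutch2 * n2) *
    rates$chick_survival * rates$juvenile_survival * 0.5 * rates$hatch
}
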