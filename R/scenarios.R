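#' Build a monitoring scenario configuration
#'
#' Materializes one row of the scenario grid that crosses lek-attendance
#' regimes with detection regimes:
#'
#' | id | attendance | detection |
#' |----|------------|-----------|
#' | 1  | perfect (1.0, all classes) | perfect (p = 1) |
#' | 2  | age/sex (0.60 / 0.80 males, 0.30 females) | perfect (p = 1) |
#' | 3  | perfect | fixed p = 0.5 |
#' | 4  | density (gamma = K/N) | fixed p = 0.5 |
#' | 5-7 | age/sex | fixed p = 0.25 / 0.375 / 0.5 |
#' | 8-10 | age/sex | Uniform(0.25, 0.75) by site / year / site-year |
#' | 11 | age/sex | trend 0.75 falling 0.03/yr to 0.25 |
#' | 12 | density | fixed p = 0.5 |
#' | 13 | density | Uniform(0.25, 0.75) by year |
#'
#' Scenarios 3-13 each have an `nmixture` variant ("3N"..."13N") in which
#' the two-occasion counts are analyzed with the N-mixture model instead of
#' the uncorrected state-space model; scenarios 1-2 (p = 1) have none.
#'
#' @param id scenario number, 1-13.
#' @param nmixture analyze with the N-mixture model (invalid for ids 1-2).
#' @param n_sims number of replicate simulations.
#' @param n_sites number of independent sites.
#' @param n_years length of the monitoring horizon.
#' @param n_occasions repeated counts per year.
#' @param K lek carrying capacity in males.
#' @param init per-site initial census; defaults to 50 females and 50 males
#'   at a 60:40 ASY:SY age ratio.
#' @param vital_rates vital-rate tibble (see [default_vital_rates()]).
#' @param seed master seed from which all per-simulation process and
#'   observation streams are derived.
#' @return An object of class `scenario_config`.
#' @examples
#' scenario_config(6)
#' @export
scenario_config <- function(id, nmixture = FALSE, n_sims = 100L,
                            n_sites = 300L, n_years = 25L, n_occasions = 2L,
                            K = 25L,
                            init = site_state(f_sy = 20, f_asy = 30,
                                              m_sy = 20, m_asy = 30),
                            vital_rates = default_vital_rates(),
                            seed = 1L) {
  stopifnot(length(id) == 1, id %in% 1:13)
  if (nmixture && id %in% 1:2)
    stop("scenarios 1 and 2 (p = 1) have no N-mixture variant",
         call. = FALSE)
  att <- switch(as.character(id),
    "1" = attendance_model("perfect", K = K),
    "3" = attendance_model("perfect", K = K),
    "4" = ,
    "12" = ,
    "13" = attendance_model("density", K = K),
    attendance_model("age_sex_fixed", K = K))
  det <- switch(as.character(id),
    "1" = ,
    "2" = detection_model("perfect"),
    "3" = ,
    "4" = detection_model("fixed", p = 0.5),
    "5" = detection_model("fixed", p = 0.25),
    "6" = detection_model("fixed", p = 0.375),
    "7" = detection_model("fixed", p = 0.5),
    "8" = detection_model("uniform_by_site"),
    "9" = detection_model("uniform_by_year"),
    "10" = detection_model("uniform_by_site_year"),
    "11" = detection_model("decreasing_trend"),
    "12" = detection_model("fixed", p = 0.5),
    "13" = detection_model("uniform_by_year"))
  structure(list(id = as.integer(id), nmixture = nmixture,
                 attendance = att, detection = det,
                 n_sims = as.integer(n_sims), n_sites = as.integer(n_sites),
                 n_years = as.integer(n_years),
                 n_occasions = as.integer(n_occasions), K = as.integer(K),
                 init = validate_site_state(init),
                 vital_rates = validate_vital_rates(vital_rates),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario %d%s> attendance: %s, detection: %s\n", x$id,
              if (x$nmixture) "N" else "", x$attendance$mode,
              x$detection$mode))
  cat(sprintf("  %d sims x %d sites x %d years, %d occasions, K = %d, seed %d\n",
              x$n_sims, x$n_sites, x$n_years, x$n_occasions, x$K, x$seed))
  invisible(x)
}

# Per-simulation seeds: row s of the matrix is reserved for simulation s
# (process stream, observation stream), so extending n_sims never changes
# the streams of earlier simulations.
derive_seeds <- function(master, n_sims) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(master)
  matrix(sample.int(.Machine$integer.max - 1L, 2L * n_sims), nrow = n_sims,
         ncol = 2L, byrow = TRUE)
}

# Demographic truth for one simulation: census arrays over sites x years.
# Returns integer matrices (n_sites x n_years) for each class.
simulate_process_matrices <- function(config) {
  n_sites <- config$n_sites
  n_years <- config$n_years
  init <- config$init
  state <- tibble::tibble(
    f_sy = rep(init$f_sy, n_sites), f_asy = rep(init$f_asy, n_sites),
    m_sy = rep(init$m_sy, n_sites), m_asy = rep(init$m_asy, n_sites),
    year = 1L)
  cls <- c("f_sy", "f_asy", "m_sy", "m_asy")
  out <- lapply(cls, function(cl) matrix(0L, n_sites, n_years))
  names(out) <- cls
  for (t in seq_len(n_years)) {
    for (cl in cls) out[[cl]][, t] <- state[[cl]]
    if (t < n_years) state <- step_year(state, config$vital_rates)
  }
  out
}

# Observation pass over stored truth matrices for one simulation.
observe_process_matrices <- function(proc, config) {
  n_sites <- config$n_sites
  n_years <- config$n_years
  J <- config$n_occasions
  p_mat <- detection_schedule(config$detection, n_sites, n_years)
  n_lek <- matrix(0L, n_sites, n_years)
  counts <- array(0L, dim = c(n_sites, n_years, J))
  for (t in seq_len(n_years)) {
    st <- tibble::tibble(f_sy = proc$f_sy[, t], f_asy = proc$f_asy[, t],
                         m_sy = proc$m_sy[, t], m_asy = proc$m_asy[, t],
                         year = t)
    att <- sample_attendance(st, config$attendance)
    n_lek[, t] <- att$n_lek
    counts[, t, ] <- observe_counts(att$n_lek, p_mat[, t], J)
  }
  list(n_lek = n_lek, p = p_mat, counts = counts)
}

#' Run the full simulate-and-observe pipeline for one scenario
#'
#' For each replicate simulation the demographic truth is generated first
#' from its own seeded stream, then the observation layer (attendance and
#' detection) is applied from a second, independent stream. The separation
#' means the demographic trajectories of two scenarios run with the same
#' master seed are bit-identical; only the observations differ.
#'
#' @param config a [scenario_config()].
#' @param progress print a dot per simulation.
#' @return An object of class `lek_sims`: a list with
#'   * `counts`: tibble `simulation`, `site`, `year`, `occasion`, `count`;
#'   * `truth`: tibble `simulation`, `site`, `year`, `n_total`, `n_male`,
#'     `n_female`, `n_lek`, `p` (evaluation only -- the estimators never
#'     read it);
#'   * `config`: the scenario configuration;
#'   * `seeds`: the per-simulation (process, observation) seeds.
#' @examples
#' sims <- run_scenario(scenario_config(1, n_sims = 2, n_sites = 10,
#'                                      n_years = 5, seed = 42))
#' dplyr::count(sims$counts, occasion)
#' @export
run_scenario <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  seeds <- derive_seeds(config$seed, config$n_sims)
  truth_list <- vector("list", config$n_sims)
  counts_list <- vector("list", config$n_sims)
  grid <- tidyr::expand_grid(site = seq_len(config$n_sites),
                             year = seq_len(config$n_years))
  for (s in seq_len(config$n_sims)) {
    set.seed(seeds[s, 1])
    proc <- simulate_process_matrices(config)
    set.seed(seeds[s, 2])
    obs <- observe_process_matrices(proc, config)
    n_f <- proc$f_sy + proc$f_asy
    n_m <- proc$m_sy + proc$m_asy
    truth_list[[s]] <- tibble::tibble(
      simulation = s, site = grid$site, year = grid$year,
      n_total = flatten_site_year(n_f + n_m),
      n_male = flatten_site_year(n_m),
      n_female = flatten_site_year(n_f),
      n_lek = flatten_site_year(obs$n_lek),
      p = flatten_site_year(obs$p))
    counts_list[[s]] <- tibble::tibble(
      simulation = s,
      site = rep(grid$site, times = config$n_occasions),
      year = rep(grid$year, times = config$n_occasions),
      occasion = rep(seq_len(config$n_occasions),
                     each = nrow(grid)),
      count = as.integer(unlist(lapply(seq_len(config$n_occasions),
                                       function(j)
                                         flatten_site_year(obs$counts[, , j])))))
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(list(counts = dplyr::bind_rows(counts_list),
                 truth = dplyr::bind_rows(truth_list),
                 config = config, seeds = seeds),
            class = "lek_sims")
}

# site-major flatten of a sites x years matrix aligned with
# expand_grid(site, year)
flatten_site_year <- function(m) {
  as.vector(t(m))
}

#' @export
print.lek_sims <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<lek_sims> scenario %d%s: %d sims x %d sites x %d years\n",
              cfg$id, if (cfg$nmixture) "N" else "", cfg$n_sims,
              cfg$n_sites, cfg$n_years))
  invisible(x)
}

#' Extinction statistics of a simulated scenario
#'
#' A site-simulation is extinct when its total abundance reaches zero at or
#' before the final year (extinction is absorbing in the demographic
#' model). Pooled totals sum true abundance over all sites within a
#' simulation.
#'
#' @param sims a `lek_sims` object from [run_scenario()].
#' @return A tibble with one row per simulation: `simulation`,
#'   `extinct_sites` (sites extinct by the final year), `final_total`
#'   (pooled abundance in the final year). The total count of extinct
#'   site-simulations is `sum(extinct_sites)`.
#' @export
extinction_summary <- function(sims) {
  stopifnot(inherits(sims, "lek_sims"))
  final_year <- max(sims$truth$year)
  sims$truth |>
    dplyr::filter(.data$year == final_year) |>
    dplyr::group_by(.data$simulation) |>
    dplyr::summarise(extinct_sites = sum(.data$n_total == 0),
                     final_total = sum(.data$n_total), .groups = "drop")
}

#' Write / read simulated counts as CSV
#'
#' `write_lek_counts()` writes `counts.csv` (simulation, site, year,
#' occasion, count) and `truth.csv` (the evaluation-only truth table) into
#' `dir`; `read_lek_counts()` reads them back.
#'
#' @param sims a `lek_sims` object.
#' @param dir output directory (created if missing).
#' @return `write_lek_counts()` returns `dir` invisibly;
#'   `read_lek_counts()` returns a list with `counts` and `truth` tibbles.
#' @export
write_lek_counts <- function(sims, dir) {
  stopifnot(inherits(sims, "lek_sims"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(sims$counts, file.path(dir, "counts.csv"))
  readr::write_csv(sims$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' @rdname write_lek_counts
#' @export
read_lek_counts <- function(dir) {
  list(counts = readr::read_csv(file.path(dir, "counts.csv"),
                                show_col_types = FALSE),
       truth = readr::read_csv(file.path(dir, "truth.csv"),
                               show_col_types = FALSE))
}
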