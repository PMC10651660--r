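#' Observed study summaries (packaged clinical fixture)
#'
#' Loads the packaged table of the 24 mean plasma profiles used for model
#' development (6 training rows) and verification (18 test rows): study,
#' phenotype, route, dose, regimen, observed mean AUC and Cmax with their
#' absolute acceptance bounds, and the originally reported predicted means.
#' The load validates the fixture (row count, bound ordering, positivity)
#' and fails on any corruption.
#'
#' @return data.frame with 24 rows.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_observed.csv", package = "inhpbpk",
                      mustWork = TRUE)
  t1 <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(t1) != 24)
    .stop_invalid("fixture corrupted: expected 24 rows, found %d", nrow(t1))
  num <- c("obs_auc", "auc_lo", "auc_hi", "pred_auc",
           "obs_cmax", "cmax_lo", "cmax_hi", "pred_cmax", "dose_mg")
  if (any(!vapply(t1[num], is.numeric, logical(1))) ||
      any(vapply(t1[num], function(x) any(is.na(x) | x <= 0), logical(1))))
    .stop_invalid("fixture corrupted: non-numeric or non-positive summary values")
  ok <- t1$auc_lo <= t1$obs_auc & t1$obs_auc <= t1$auc_hi &
    t1$cmax_lo <= t1$obs_cmax & t1$obs_cmax <= t1$cmax_hi
  if (!all(ok))
    .stop_invalid("fixture corrupted: observed mean outside its own bounds")
  if (sum(t1$training) != 6)
    .stop_invalid("fixture corrupted: expected 6 training rows")
  t1
}

#' Synthetic observed concentration set
#'
#' Stand-in for digitized literature mean curves: applies multiplicative
#' lognormal residual noise per time point to a model-generated mean curve.
#' Regeneration with the same seed is exact; the output is flagged
#' `synthetic`.
#'
#' @param mean_curve data.frame `time`, `conc` (a model mean curve).
#' @param noise_cv_pct residual noise CV, percent (0 = return the mean).
#' @param seed integer seed.
#' @return data.frame `time`, `conc` with attributes `provenance`
#'   (`"synthetic"`), `noise_cv_pct` and `seed`.
#' @export
generate_synthetic_observed <- function(mean_curve, noise_cv_pct, seed = 1L) {
  if (noise_cv_pct < 0) .stop_invalid("noise_cv_pct must be >= 0")
  conc <- mean_curve$conc
  if (noise_cv_pct > 0) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    sdl <- .cv_to_sdlog(noise_cv_pct)
    conc <- conc * rlnorm(length(conc), meanlog = -sdl^2 / 2, sdlog = sdl)
  }
  out <- data.frame(time = mean_curve$time, conc = conc)
  attr(out, "provenance") <- "synthetic"
  attr(out, "noise_cv_pct") <- noise_cv_pct
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Read / write a flat drug + clearance configuration
#'
#' Flat key-value JSON with keys `molecular_weight, log_p, fu_plasma,
#' blood_plasma_ratio, fa, ka, fu_gut, lag_time, cl_renal, cl_other,
#' clu_int_fa, clu_int_sa, km, cppgl, liver_weight_ref`.
#'
#' @param path file path.
#' @return `read_drug_config`: named list; `write_drug_config`: `path`,
#'   invisibly.
#' @export
read_drug_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- .config_keys()
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    .stop_invalid("config missing key(s): %s", paste(miss, collapse = ", "))
  cfg[need]
}

#' @rdname read_drug_config
#' @param drug an `inh_drug`.
#' @param clearances clearance configuration list.
#' @export
write_drug_config <- function(path, drug = inh_drug_parameters(),
                              clearances = inh_clearance_defaults()) {
  cfg <- c(drug[c("molecular_weight", "log_p", "fu_plasma",
                  "blood_plasma_ratio", "fa", "ka", "fu_gut", "lag_time")],
           clearances[c("cl_renal", "cl_other", "clu_int_fa", "clu_int_sa",
                        "km", "cppgl", "liver_weight_ref")])
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.config_keys <- function() {
  c("molecular_weight", "log_p", "fu_plasma", "blood_plasma_ratio", "fa",
    "ka", "fu_gut", "lag_time", "cl_renal", "cl_other", "clu_int_fa",
    "clu_int_sa", "km", "cppgl", "liver_weight_ref")
}

#' Simulate one packaged study scenario
#'
#' Builds the study's regimen and a demographic-matched virtual population
#' (10 trials, 1:1 sex ratio and ages 20-55 where the study reported none)
#' and runs the phenotype model for that row of the packaged study table.
#'
#' @param row one row of [load_table1_fixture()].
#' @param seed root seed for the virtual population.
#' @param n_subjects,n_trials trial design (default 10 x 10).
#' @param model optional pre-built `inh_model` (rebuilt from defaults when
#'   `NULL`).
#' @param n_md_doses number of doses simulated for multiple-dose rows
#'   (metrics are taken over the final dosing interval).
#' @return An `inh_simulation`.
#' @export
run_study_scenario <- function(row, seed = 1L, n_subjects = 100,
                               n_trials = 10, model = NULL, n_md_doses = 4) {
  if (is.null(model)) model <- inh_model(row$phenotype)
  reg <- if (row$route == "iv") {
    dosing_regimen("iv_infusion", row$dose_mg,
                   infusion_duration = row$inf_min / 60)
  } else if (identical(row$regimen, "md")) {
    dosing_regimen("oral", row$dose_mg, n_doses = n_md_doses, interval = 24)
  } else {
    dosing_regimen("oral", row$dose_mg)
  }
  spec <- population_spec(n_subjects = n_subjects, n_trials = n_trials,
                          age_range = c(20, 55), proportion_female = 0.5,
                          seed = seed)
  pop <- sample_population(spec)
  simulate_trialset(pop, model, reg)
}
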