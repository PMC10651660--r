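#' Pregnancy-induced change in oral clearance
#'
#' Simulates a matched pair of female populations - pregnant at the given
#' gestational week and non-pregnant, with identical demographics and
#' inter-individual draws - after a single oral 300 mg dose, and returns
#' the percent change in oral clearance (dose over the grand mean AUC).
#' With `nat2_scale = other_scale = 1` the change reflects pregnancy
#' physiology alone (chiefly the rise in glomerular filtration).
#'
#' @param phenotype `"FA"`, `"IA"` or `"SA"`.
#' @param gestational_week gestational week of the pregnant arm.
#' @param nat2_scale,other_scale pregnancy activity multipliers on NAT2
#'   Vmax and CL_other.
#' @param n_subjects,n_trials trial design (default 100 subjects, 10 x 10).
#' @param age_range maternal age range, years.
#' @param dose oral dose, mg.
#' @param seed root seed (both arms share it: matched subjects).
#' @return List with `pct_change`, `cl_pregnant`, `cl_nonpregnant` (L/h)
#'   and the two `inh_simulation` objects.
#' @export
pregnancy_cl_change <- function(phenotype, gestational_week = 28,
                                nat2_scale = 1, other_scale = 1,
                                n_subjects = 100, n_trials = 10,
                                age_range = c(18, 45), dose = 300,
                                seed = 1L) {
  spec <- population_spec(n_subjects = n_subjects, n_trials = n_trials,
                          age_range = age_range, proportion_female = 1,
                          gestational_week = gestational_week, seed = seed)
  pop <- sample_population(spec)
  reg <- dosing_regimen("oral", dose)
  m_np <- inh_model(phenotype)
  m_pr <- inh_model(phenotype, nat2_scale = nat2_scale,
                    other_scale = other_scale)
  sim_np <- simulate_trialset(pop, m_np, reg, gestational_week = 0)
  sim_pr <- simulate_trialset(pop, m_pr, reg,
                              gestational_week = gestational_week)
  cl_np <- sim_np$summary$cl
  cl_pr <- sim_pr$summary$cl
  list(pct_change = 100 * (cl_pr / cl_np - 1),
       cl_pregnant = cl_pr, cl_nonpregnant = cl_np,
       sim_pregnant = sim_pr, sim_nonpregnant = sim_np)
}

#' Sensitivity of pregnancy clearance change to enzyme activity
#'
#' Sweeps NAT2 Vmax and CL_other multipliers over a percent-increase grid
#' and tabulates the predicted oral clearance at the given gestational week
#' and its percent change versus the matched non-pregnant baseline, per
#' phenotype and pathway.
#'
#' @param phenotypes phenotypes to evaluate.
#' @param pct_increase percent increases applied to one pathway at a time.
#' @param gestational_week gestational week.
#' @param n_subjects,n_trials trial design per cell.
#' @param seed root seed.
#' @return data.frame with columns `pathway`, `pct_increase`, `phenotype`,
#'   `cl` (L/h) and `pct_change`.
#' @export
sensitivity_grid <- function(phenotypes = c("FA", "SA"),
                             pct_increase = seq(0, 80, by = 10),
                             gestational_week = 28,
                             n_subjects = 30, n_trials = 3, seed = 1L) {
  if (any(pct_increase < 0) || any(1 + pct_increase / 100 > 3))
    .stop_invalid("pct_increase must map to scales in (0, 3]")
  rows <- list()
  for (ph in phenotypes) {
    base <- pregnancy_cl_change(ph, gestational_week,
                                n_subjects = n_subjects,
                                n_trials = n_trials, seed = seed)
    for (pw in c("other", "nat2")) {
      for (pct in pct_increase) {
        if (pct == 0) {
          cl <- base$cl_pregnant
        } else {
          sc <- 1 + pct / 100
          res <- pregnancy_cl_change(ph, gestational_week,
                                     nat2_scale = if (pw == "nat2") sc else 1,
                                     other_scale = if (pw == "other") sc else 1,
                                     n_subjects = n_subjects,
                                     n_trials = n_trials, seed = seed)
          cl <- res$cl_pregnant
        }
        rows[[length(rows) + 1]] <- data.frame(
          pathway = pw, pct_increase = pct, phenotype = ph, cl = cl,
          pct_change = 100 * (cl / base$cl_nonpregnant - 1))
      }
    }
  }
  do.call(rbind, rows)
}

#' Infer pregnancy enzyme-activity scaling from observed clearance changes
#'
#' Grid search for the NAT2 and CL_other pregnancy multipliers that best
#' reproduce observed percent increases in oral clearance across
#' phenotypes (least squares over the grid). With a single-phenotype
#' target the problem is under-determined (a flat ridge of near-optimal
#' cells) and a warning is raised.
#'
#' @param targets named numeric, percent clearance increase per phenotype
#'   (e.g. `c(FA = 16, IA = 21, SA = 30)`).
#' @param nat2_grid,other_grid candidate multipliers.
#' @param gestational_week gestational week.
#' @param n_subjects,n_trials trial design per grid cell (matched pairs
#'   make the per-cell estimate nearly deterministic, so small cells
#'   suffice).
#' @param seed root seed.
#' @return List with `nat2_scale`, `other_scale`, `objective` (the full
#'   surface as a data.frame) and `predicted` (the % changes at the
#'   optimum).
#' @export
infer_pregnancy_scaling <- function(targets,
                                    nat2_grid = seq(1, 2, by = 0.1),
                                    other_grid = seq(1, 2, by = 0.1),
                                    gestational_week = 28,
                                    n_subjects = 20, n_trials = 2,
                                    seed = 1L) {
  if (length(nat2_grid) < 1 || length(other_grid) < 1 ||
      (length(nat2_grid) == 1 && length(other_grid) == 1))
    .stop_invalid("degenerate search grid")
  phens <- names(targets)
  if (is.null(phens) || !all(phens %in% c("FA", "IA", "SA")))
    .stop_invalid("targets must be named with phenotypes FA/IA/SA")

  # pre-simulate the matched non-pregnant baseline once per phenotype
  spec <- population_spec(n_subjects = n_subjects, n_trials = n_trials,
                          age_range = c(18, 45), proportion_female = 1,
                          gestational_week = gestational_week, seed = seed)
  pop <- sample_population(spec)
  reg <- dosing_regimen("oral", 300)
  cl_np <- vapply(phens, function(ph)
    simulate_trialset(pop, inh_model(ph), reg)$summary$cl, numeric(1))

  grid <- expand.grid(nat2_scale = nat2_grid, other_scale = other_grid)
  pred <- matrix(NA_real_, nrow(grid), length(phens),
                 dimnames = list(NULL, phens))
  for (i in seq_len(nrow(grid))) {
    for (ph in phens) {
      sim <- simulate_trialset(pop,
        inh_model(ph, nat2_scale = grid$nat2_scale[i],
                  other_scale = grid$other_scale[i]),
        reg, gestational_week = gestational_week)
      pred[i, ph] <- 100 * (sim$summary$cl / cl_np[[ph]] - 1)
    }
  }
  grid$objective <- rowSums((pred - matrix(unlist(targets[phens]),
                                           nrow(grid), length(phens),
                                           byrow = TRUE))^2)
  best <- which.min(grid$objective)
  if (length(phens) < 2) {
    near <- sum(grid$objective <= grid$objective[best] +
                  0.01 * max(grid$objective))
    warning("two activity scales fitted to a single-phenotype target: ",
            "solution not identifiable (", near,
            " near-optimal grid cells on a flat ridge)", call. = FALSE)
  }
  list(nat2_scale = grid$nat2_scale[best],
       other_scale = grid$other_scale[best],
       objective = grid,
       predicted = setNames(pred[best, ], phens))
}

#' Therapeutic-window classification of peak concentrations
#'
#' Fractions of subjects with Cmax below, within and above the recommended
#' 3-6 mg/L window for a 300 mg isoniazid dose.
#'
#' @param x an `inh_simulation` or a numeric vector of per-subject Cmax.
#' @param lo,hi window bounds, mg/L.
#' @return Named numeric `(pct_below, pct_within, pct_above)` in percent,
#'   summing to 100.
#' @export
therapeutic_window_fractions <- function(x, lo = 3, hi = 6) {
  cmax <- if (inherits(x, "inh_simulation")) x$nca$cmax else x
  if (length(cmax) == 0) .stop_invalid("empty population")
  c(pct_below = 100 * mean(cmax < lo),
    pct_within = 100 * mean(cmax >= lo & cmax <= hi),
    pct_above = 100 * mean(cmax > hi))
}

#' Phenotype mixture
#'
#' @param freq named fractions over `FA`, `IA`, `SA`; must sum to 1.
#' @return Validated named numeric of class `inh_mixture`.
#' @export
phenotype_mixture <- function(freq) {
  if (!all(c("FA", "IA", "SA") %in% names(freq)))
    .stop_invalid("mixture needs FA, IA and SA frequencies")
  freq <- freq[c("FA", "IA", "SA")]
  if (any(freq < 0) || abs(sum(freq) - 1) > 1e-9)
    .stop_invalid("mixture fractions must be >= 0 and sum to 1")
  structure(freq, class = "inh_mixture")
}

#' Regional NAT2 phenotype frequencies
#'
#' Reported phenotype distributions for the Africa (AFR) and South Asia
#' (SAS) regions.
#'
#' @param region `"AFR"` or `"SAS"`.
#' @return An `inh_mixture`.
#' @export
regional_mixture <- function(region = c("AFR", "SAS")) {
  region <- match.arg(region)
  f <- switch(region,
    AFR = c(FA = 0.2, IA = 0.48, SA = 0.32),
    # the reported SAS frequencies sum to 0.999; renormalized to 1
    SAS = c(FA = 0.059, IA = 0.331, SA = 0.609))
  phenotype_mixture(f / sum(f))
}

#' Simulate a phenotype-mixture population
#'
#' Assigns each subject of a sampled population a NAT2 phenotype by seeded
#' multinomial draw from the mixture, simulates each stratum with its
#' phenotype model, and pools the per-subject metrics.
#'
#' @param mixture an `inh_mixture`.
#' @param spec an `inh_population_spec` (use `gestational_week > 0` and
#'   `proportion_female = 1` for pregnant populations).
#' @param nat2_scale,other_scale pregnancy activity multipliers.
#' @param dose oral dose, mg.
#' @return List with `pooled` (per-subject phenotype + metrics), `window`
#'   (therapeutic-window fractions of the pool), `strata` (per-phenotype
#'   `inh_simulation`s) and `mean_cmax`.
#' @export
simulate_mixture <- function(mixture, spec, nat2_scale = 1, other_scale = 1,
                             dose = 300) {
  stopifnot(inherits(mixture, "inh_mixture"),
            inherits(spec, "inh_population_spec"))
  pop <- sample_population(spec)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed + 999983L)
  assign_ph <- sample(c("FA", "IA", "SA"), nrow(pop), replace = TRUE,
                      prob = mixture)
  reg <- dosing_regimen("oral", dose)
  strata <- list()
  pooled <- NULL
  for (ph in unique(assign_ph)) {
    sub <- pop[assign_ph == ph, , drop = FALSE]
    sim <- simulate_trialset(sub,
      inh_model(ph, nat2_scale = nat2_scale, other_scale = other_scale),
      reg, gestational_week = spec$gestational_week)
    strata[[ph]] <- sim
    pooled <- rbind(pooled, cbind(phenotype = ph, sim$nca))
  }
  list(pooled = pooled,
       window = therapeutic_window_fractions(pooled$cmax),
       strata = strata,
       mean_cmax = mean(pooled$cmax),
       frequencies = mixture)
}

#' Write the sensitivity grid as CSV
#'
#' Wide layout mirroring the sensitivity table: one row per pathway and
#' percent increase, one clearance and percent-change column pair per
#' phenotype.
#'
#' @param grid result of [sensitivity_grid()].
#' @param path output path.
#' @export
write_sensitivity_csv <- function(grid, path) {
  phs <- unique(grid$phenotype)
  wide <- unique(grid[c("pathway", "pct_increase")])
  for (ph in phs) {
    sub <- grid[grid$phenotype == ph, ]
    m <- match(paste(wide$pathway, wide$pct_increase),
               paste(sub$pathway, sub$pct_increase))
    wide[[paste0("cl_", tolower(ph))]] <- sub$cl[m]
    wide[[paste0("pct_change_", tolower(ph))]] <- sub$pct_change[m]
  }
  write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
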