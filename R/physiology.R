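# Reference physiology tables (adult, approximate ICRP-style values).
# Volumes in L at the sex reference body weight; flows as fractions of
# cardiac output (systemic fractions sum to 1; the lung receives the whole
# cardiac output in series).

.ref_anthro <- list(
  male   = list(bw = 70, height = 176, co = 360, gfr = 6.6,
                plasma = 3.0, erythrocytes = 2.2, liver_g = 1650),
  female = list(bw = 60, height = 163, co = 312, gfr = 5.9,
                plasma = 2.7, erythrocytes = 1.8, liver_g = 1450)
)

.ref_volumes <- list(
  male = c(adipose = 12.5, bone = 10.3, brain = 1.45, gut = 1.65,
           heart = 0.33, kidney = 0.31, liver = 1.65, lung = 0.52,
           muscle = 27.0, skin = 3.3, spleen = 0.15, rest = 2.34),
  female = c(adipose = 15.5, bone = 8.0, brain = 1.30, gut = 1.45,
             heart = 0.27, kidney = 0.27, liver = 1.45, lung = 0.44,
             muscle = 19.5, skin = 2.6, spleen = 0.13, rest = 1.73)
)

.flow_fractions <- c(adipose = 0.05, bone = 0.05, brain = 0.12, gut = 0.15,
                     heart = 0.04, kidney = 0.19, liver = 0.065,
                     muscle = 0.17, skin = 0.05, spleen = 0.03, rest = 0.085)

#' Gestational scaling multipliers
#'
#' Smooth (linear-in-week) interpolants from conception pinned at
#' gestational week 28: glomerular filtration x1.40, cardiac output x1.30,
#' plasma volume x1.35, and +9 kg body weight (maternal fat, uterus,
#' fetus/placenta/amniotic fluid, lumped into the adipose and rest
#' compartments). Hepatic blood flow is held at its absolute non-pregnant
#' value; the cardiac output surplus is routed to the kidney (with
#' filtration) and the rest compartment (utero-placental flow).
#'
#' @param gestational_week week of gestation, 0 (non-pregnant) to 40.
#' @return List of multipliers `gfr`, `cardiac_output`, `plasma_volume` and
#'   the absolute gain `body_weight_gain` (kg).
#' @export
gestational_scaling <- function(gestational_week) {
  if (gestational_week < 0 || gestational_week > 40)
    .stop_invalid("gestational_week must be in [0, 40]")
  s <- gestational_week / 28
  list(gfr = 1 + 0.40 * s,
       cardiac_output = 1 + 0.30 * s,
       plasma_volume = 1 + 0.35 * s,
       body_weight_gain = 9 * s)
}

#' Reference or subject physiology
#'
#' Builds a deterministic `PhysiologyState`: organ volumes, blood flows,
#' cardiac output, glomerular filtration rate, liver weight and cytosolic
#' protein content for an adult of the given sex, age and body size, with
#' optional gestational scaling. Volumes scale linearly with (non-pregnant)
#' body weight relative to the sex reference; flows and GFR scale with the
#' 0.75 allometric power. The liver is 1650 g for the 70 kg male reference
#' (1450 g for the 60 kg female) and scales with body weight; pregnancy does
#' not change liver size, liver blood flow or metabolic capacity.
#'
#' @param sex `"male"` or `"female"`.
#' @param age years, in `[18, 65]`.
#' @param body_weight kg; defaults to the sex reference (70/60 kg). For
#'   pregnant subjects this is the non-pregnant weight; gestational gain is
#'   added on top.
#' @param height cm; defaults to the sex reference.
#' @param gestational_week 0 for non-pregnant, otherwise in `[4, 40]`
#'   (females only).
#' @param cppgl cytosolic protein per gram liver, mg/g.
#' @return Object of class `inh_physiology` with elements `organ_volumes`
#'   (L; the 12 perfused tissues plus `plasma` and `erythrocytes`),
#'   `organ_flows` (L/h; `lung` carries the full cardiac output),
#'   `cardiac_output`, `gfr` (L/h), `liver_weight` (g), `cppgl`,
#'   `hematocrit`, and the demographic fields.
#' @export
reference_physiology <- function(sex, age, body_weight = NULL, height = NULL,
                                 gestational_week = 0, cppgl = 81.033) {
  sex <- match.arg(sex, c("male", "female"))
  if (age < 18 || age > 65) .stop_invalid("age must be in [18, 65]")
  if (gestational_week != 0 && (gestational_week < 4 || gestational_week > 40))
    .stop_invalid("gestational_week must be 0 or in [4, 40]")
  if (gestational_week > 0 && sex != "female")
    .stop_invalid("pregnant physiology requires sex = 'female'")

  ref <- .ref_anthro[[sex]]
  if (is.null(body_weight)) body_weight <- ref$bw
  if (is.null(height)) height <- ref$height
  if (body_weight <= 0) .stop_invalid("body_weight must be > 0")

  size <- body_weight / ref$bw          # linear volume scaling
  allo <- size^0.75                     # flow / GFR scaling

  vols <- .ref_volumes[[sex]] * size
  plasma <- ref$plasma * size
  ery <- ref$erythrocytes * size
  co <- ref$co * allo
  gfr <- ref$gfr * allo
  liver_weight <- ref$liver_g * size

  flows <- .flow_fractions * co
  gw <- gestational_week
  bw_total <- body_weight
  if (gw > 0) {
    g <- gestational_scaling(gw)
    plasma_gain <- plasma * (g$plasma_volume - 1)
    other_gain <- max(g$body_weight_gain - plasma_gain, 0)
    plasma <- plasma + plasma_gain
    vols[["adipose"]] <- vols[["adipose"]] + 0.4 * other_gain
    vols[["rest"]] <- vols[["rest"]] + 0.6 * other_gain
    bw_total <- body_weight + g$body_weight_gain
    gfr <- gfr * g$gfr
    co_new <- co * g$cardiac_output
    flows[["kidney"]] <- flows[["kidney"]] * g$gfr
    # hepatic inflow (gut, spleen, hepatic artery) unchanged in absolute
    # terms; the remaining surplus perfuses the utero-placental unit (rest)
    flows[["rest"]] <- flows[["rest"]] + co_new - co -
      flows[["kidney"]] + .flow_fractions[["kidney"]] * co
    co <- co_new
  }
  flows <- c(flows, lung = co)

  structure(list(
    sex = sex, age = age,
    body_weight = bw_total,
    body_weight_nonpregnant = body_weight,
    height = height,
    gestational_week = gw,
    organ_volumes = c(vols, plasma = unname(plasma), erythrocytes = unname(ery)),
    organ_flows = flows[c(.tissues)],
    cardiac_output = unname(co),
    gfr = unname(gfr),
    liver_weight = unname(liver_weight),
    cppgl = cppgl,
    hematocrit = unname(ery / (ery + plasma))
  ), class = "inh_physiology")
}

#' Virtual population specification
#'
#' @param n_subjects total number of subjects; must equal
#'   `n_trials * subjects-per-trial` exactly.
#' @param n_trials number of simulated trials.
#' @param age_range two ages, years.
#' @param proportion_female fraction of female subjects.
#' @param gestational_week gestational week applied when subjects are
#'   simulated pregnant (demographic draws are gestation-independent).
#' @param variability named CV% vector for the lognormal inter-individual
#'   variability on `clu_int`, `cl_other`, `cl_renal`, `ka`.
#' @param seed integer root seed; per-subject substreams are derived by
#'   counter so membership does not depend on evaluation order.
#' @return Object of class `inh_population_spec`.
#' @export
population_spec <- function(n_subjects = 100, n_trials = 10,
                            age_range = c(20, 55), proportion_female = 0.5,
                            gestational_week = 0,
                            variability = c(clu_int = 30, cl_other = 30,
                                            cl_renal = 20, ka = 40),
                            seed = 1L) {
  if (n_subjects < 1 || n_trials < 1 || n_subjects %% n_trials != 0)
    .stop_invalid("n_subjects (%d) must be a positive multiple of n_trials (%d)",
                  n_subjects, n_trials)
  if (proportion_female < 0 || proportion_female > 1)
    .stop_invalid("proportion_female must be in [0, 1]")
  if (any(variability < 0)) .stop_invalid("CV%% must be >= 0")
  need <- c("clu_int", "cl_other", "cl_renal", "ka")
  miss <- setdiff(need, names(variability))
  if (length(miss))
    .stop_invalid("variability missing CV%% for: %s", paste(miss, collapse = ", "))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 age_range = sort(age_range),
                 proportion_female = proportion_female,
                 gestational_week = gestational_week,
                 variability = variability,
                 seed = as.integer(seed)),
            class = "inh_population_spec")
}

# deterministic per-subject seed, order-invariant, < 2^31
.subject_seed <- function(root, i) {
  (abs(root) %% 1000003L) * 2017L + 13L * i
}

.cv_to_sdlog <- function(cv_pct) sqrt(log(1 + (cv_pct / 100)^2))

#' Sample a virtual population
#'
#' Draws `n_subjects` subjects grouped into `n_trials` trials: sex by
#' `proportion_female`, age uniform over the range, sex-specific normal
#' weight and height, and unit-mean lognormal inter-individual factors on
#' NAT2 intrinsic clearance, non-NAT2 clearance, renal clearance and the
#' absorption rate constant. Each subject uses its own counter-derived seed,
#' so the same spec and seed reproduce the population exactly.
#'
#' @param spec an `inh_population_spec`.
#' @return data.frame with one row per subject: `subject_id`, `trial`,
#'   `sex`, `age`, `body_weight`, `height` and the factors `f_clu_int`,
#'   `f_cl_other`, `f_cl_renal`, `f_ka`.
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "inh_population_spec"))
  n <- spec$n_subjects
  per_trial <- n %/% spec$n_trials
  cv <- spec$variability

  one <- function(i) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(.subject_seed(spec$seed, i))
    sex <- if (runif(1) < spec$proportion_female) "female" else "male"
    age <- runif(1, spec$age_range[1], spec$age_range[2])
    if (sex == "male") {
      bw <- min(max(rnorm(1, 76, 10), 50), 110)
      ht <- rnorm(1, 176, 7)
    } else {
      bw <- min(max(rnorm(1, 64, 9), 42), 100)
      ht <- rnorm(1, 163, 6.5)
    }
    f <- vapply(c("clu_int", "cl_other", "cl_renal", "ka"), function(p) {
      sdl <- .cv_to_sdlog(cv[[p]])
      rlnorm(1, meanlog = -sdl^2 / 2, sdlog = sdl)
    }, numeric(1))
    data.frame(subject_id = i, trial = (i - 1L) %/% per_trial + 1L,
               sex = sex, age = age, body_weight = bw, height = ht,
               f_clu_int = f[["clu_int"]], f_cl_other = f[["cl_other"]],
               f_cl_renal = f[["cl_renal"]], f_ka = f[["ka"]],
               stringsAsFactors = FALSE)
  }
  pop <- do.call(rbind, lapply(seq_len(n), one))
  attr(pop, "spec") <- spec
  pop
}

#' Export a sampled population to CSV
#'
#' @param population data.frame from [sample_population()].
#' @param path output file path.
#' @export
write_population_csv <- function(population, path) {
  write.csv(population, path, row.names = FALSE)
  invisible(path)
}
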