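# shared small fixtures; everything is generated in code

ref_male <- reference_physiology("male", 30)
ref_female <- reference_physiology("female", 30)

# a tiny population data.frame of identical subjects (no variability)
identical_population <- function(n = 4, n_trials = 2, sex = "female") {
  data.frame(subject_id = seq_len(n),
             trial = rep(seq_len(n_trials), each = n / n_trials),
             sex = sex, age = 30,
             body_weight = if (sex == "male") 70 else 60,
             height = if (sex == "male") 176 else 163,
             f_clu_int = 1, f_cl_other = 1, f_cl_renal = 1, f_ka = 1,
             stringsAsFactors = FALSE)
}

small_spec <- function(n = 10, trials = 1, seed = 5, gw = 0, female = 1) {
  population_spec(n_subjects = n, n_trials = trials, age_range = c(18, 45),
                  proportion_female = female, gestational_week = gw,
                  seed = seed)
}

# analytic total clearance in the linear regime for a given physiology
analytic_linear_cl <- function(model, phys) {
  q_h <- sum(phys$organ_flows[c("liver", "gut", "spleen")])
  clu <- per_mg_to_intrinsic(model$pheno$clu_int_per_mg, phys$cppgl,
                             phys$liver_weight) * model$nat2_scale
  cl_nat2 <- wellstirred(clu, q_h, model$drug$fu_plasma,
                         model$drug$blood_plasma_ratio)
  clr <- model$pheno$cl_renal * phys$gfr / model$clearances$gfr_ref
  cl_nat2 + clr + model$pheno$cl_other * model$other_scale
}
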