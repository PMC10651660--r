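test_that("mass is conserved to 1e-6 for oral, multiple oral and iv dosing", {
  m <- inh_model("FA")
  oral <- simulate_subject(m, ref_male, dosing_regimen("oral", 300),
                           full = TRUE)
  expect_lt(mass_balance_error(oral), 1e-6)
  md <- simulate_subject(m, ref_male,
                         dosing_regimen("oral", 300, n_doses = 3,
                                        interval = 24),
                         t_end = 72, full = TRUE)
  expect_lt(mass_balance_error(md), 1e-6)
  iv <- simulate_subject(m, ref_male,
                         dosing_regimen("iv_infusion", 200,
                                        infusion_duration = 1 / 3),
                         full = TRUE)
  expect_lt(mass_balance_error(iv), 1e-6)
  expect_true(all(oral$conc >= 0) && oral$time[1] == 0)
})

test_that("linear-regime i.v. exposure equals dose over the analytic clearance", {
  for (ph in c("FA", "SA")) {
    m <- inh_model(ph)
    reg <- dosing_regimen("iv_infusion", 0.1, infusion_duration = 0.2)
    pr <- simulate_subject(m, ref_male, reg, t_end = 36)
    auc <- nca(pr$time, pr$conc)$auc_0_inf
    expect_equal(0.1 / auc, analytic_linear_cl(m, ref_male), tolerance = 0.01)
  }
})

test_that("collapsed system matches an independent one-compartment integrator", {
  # all Kp = 1, no renal/other clearance, flows made fast: the whole body
  # behaves as one well-mixed volume with saturable elimination
  defs <- inh_clearance_defaults()
  defs$cl_renal <- 0
  defs$cl_other <- 0
  m <- inh_model("FA", clearances = defs)
  m$partitions$kp[] <- 1
  phys <- ref_male
  phys$organ_flows <- phys$organ_flows * 1000
  phys$cardiac_output <- phys$cardiac_output * 1000

  dose <- 300
  pr <- simulate_subject(m, phys, dosing_regimen("iv_infusion", dose,
                                                 infusion_duration = 0.01),
                         t_end = 12)

  v_tot <- sum(phys$organ_volumes)
  fu <- m$drug$fu_plasma
  clu <- per_mg_to_intrinsic(m$pheno$clu_int_per_mg, phys$cppgl,
                             phys$liver_weight)
  vmax <- clu * m$pheno$km
  km <- m$pheno$km

  # independent oracle: hand-coded RK4 on dA/dt = -Vmax*Cu/(Km+Cu)
  h <- 0.001
  tt <- seq(0, 12, by = h)
  a <- numeric(length(tt)); a[1] <- dose
  f <- function(a) {
    cu <- fu * a / v_tot
    -vmax * cu / (km + cu)
  }
  for (i in seq_len(length(tt) - 1)) {
    k1 <- f(a[i]); k2 <- f(a[i] + h / 2 * k1)
    k3 <- f(a[i] + h / 2 * k2); k4 <- f(a[i] + h * k3)
    a[i + 1] <- a[i] + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  oracle_conc <- a / v_tot

  idx <- pr$time >= 0.5   # after the short infusion/mixing transient
  ref <- approx(tt, oracle_conc, xout = pr$time[idx])$y
  expect_lt(max(abs(pr$conc[idx] - ref) / ref), 0.005)
})

test_that("exposure is superlinear in dose and ordered SA > IA > FA", {
  auc <- function(ph, dose) {
    pr <- simulate_subject(inh_model(ph), ref_male,
                           dosing_regimen("oral", dose))
    nca(pr$time, pr$conc)$auc_0_inf
  }
  a100 <- auc("FA", 100); a300 <- auc("FA", 300); a900 <- auc("FA", 900)
  # AUC/dose non-decreasing with dose (saturable elimination)
  expect_gt(a300 / 300, a100 / 100)
  expect_gt(a900 / 900, a300 / 300)
  expect_gt(auc("SA", 300), auc("IA", 300))
  expect_gt(auc("IA", 300), a300)
})

test_that("doubling a tiny dose doubles exposure (linear limit)", {
  a <- sapply(c(0.1, 0.2), function(d) {
    pr <- simulate_subject(inh_model("FA"), ref_male,
                           dosing_regimen("oral", d))
    nca(pr$time, pr$conc)$auc_0_inf
  })
  expect_equal(a[2] / a[1], 2, tolerance = 1e-3)
})

test_that("halving the output grid leaves NCA metrics unchanged to 0.1%", {
  m <- inh_model("IA")
  reg <- dosing_regimen("oral", 300)
  r1 <- with(simulate_subject(m, ref_female, reg, dt = 0.05),
             nca(time, conc))
  r2 <- with(simulate_subject(m, ref_female, reg, dt = 0.025),
             nca(time, conc))
  expect_equal(r2$auc_0_inf, r1$auc_0_inf, tolerance = 1e-3)
  expect_equal(r2$cmax, r1$cmax, tolerance = 1e-3)
})

test_that("a trial set of identical subjects reproduces the single-subject curve", {
  pop <- identical_population(4, 2)
  m <- inh_model("SA")
  reg <- dosing_regimen("oral", 300)
  sim <- simulate_trialset(pop, m, reg)
  single <- simulate_subject(m, ref_female, reg, subject = pop[1, ])
  expect_equal(sim$mean_curve$conc, single$conc, tolerance = 1e-10)
  expect_equal(sim$summary$auc, nca(single$time, single$conc)$auc_0_inf,
               tolerance = 1e-8)
  expect_equal(nrow(sim$trial_summary), 2)
  expect_equal(nrow(sim$nca), 4)
})

test_that("trial sets are reproducible from the population seed", {
  spec <- small_spec(n = 6, trials = 2, seed = 21, female = 0.5)
  m <- inh_model("FA")
  reg <- dosing_regimen("oral", 300)
  s1 <- simulate_trialset(sample_population(spec), m, reg)
  s2 <- simulate_trialset(sample_population(spec), m, reg)
  expect_identical(s1$conc, s2$conc)
  expect_identical(s1$summary, s2$summary)
})

test_that("regimen validation rejects inconsistent inputs", {
  expect_error(dosing_regimen("oral", -1), "dose")
  expect_error(dosing_regimen("iv_infusion", 200), "infusion_duration")
  expect_error(dosing_regimen("oral", 300, n_doses = 3, interval = 0),
               "interval")
})
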