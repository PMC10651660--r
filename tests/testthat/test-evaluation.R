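test_that("trapezoidal AUC handles constant and mono-exponential profiles", {
  tt <- seq(0, 10, by = 0.5)
  r <- nca(tt, rep(4, length(tt)), extrapolate = FALSE)
  expect_equal(r$auc_0_last, 40)
  expect_equal(r$cmax, 4)

  k <- 0.35; c0 <- 12
  tt <- seq(0, 30, by = 0.1)
  r <- nca(tt, c0 * exp(-k * tt))
  expect_equal(r$auc_0_inf, c0 / k, tolerance = 0.005)
  expect_equal(r$lambda_z, k, tolerance = 1e-3)
  expect_equal(r$tmax, 0)

  expect_error(nca(c(0, 1), c(1, 0.5)), "3 time points")
  expect_error(nca(c(0, 1, 2), c(1, 0.9, 0.8)), "terminal slope")
  expect_error(nca(c(0, 1, 1), c(1, 1, 1)), "increasing")
})

test_that("duplicating interior points does not change the AUC", {
  tt <- c(0, 0.5, 1, 2, 4, 8, 12, 16, 24)
  cc <- 10 * exp(-0.3 * tt) * (1 - exp(-2 * tt))
  base <- nca(tt, cc, extrapolate = FALSE)$auc_0_last
  tt2 <- sort(c(tt, 2 + 1e-9, 8 + 1e-9))
  cc2 <- approx(tt, cc, xout = tt2)$y
  expect_equal(nca(tt2, cc2, extrapolate = FALSE)$auc_0_last, base,
               tolerance = 1e-6)
})

test_that("acceptance limits follow the lognormal fold-limit statistics", {
  # frozen hand computation: cv 40%, n 10
  sigma <- sqrt(log(0.4^2 + 1))
  a <- acceptance_limits(20, 40, 10)
  expect_equal(a$sigma, sigma)
  expect_equal(a$fold_upper, exp(4.26 * sigma / sqrt(10)))
  expect_equal(a$fold_upper, 1.6803, tolerance = 1e-4)

  # zero variability collapses the bounds onto the mean
  z <- acceptance_limits(12.3, 0, 8)
  expect_equal(z$bound_lower, 12.3)
  expect_equal(z$bound_upper, 12.3)

  # log-symmetry: lower * upper = mean^2
  for (cv in c(10, 35, 80)) for (n in c(4, 12)) {
    r <- acceptance_limits(7.7, cv, n)
    expect_equal(r$bound_lower * r$bound_upper, 7.7^2, tolerance = 1e-9)
    expect_equal(r$fold_lower * r$fold_upper, 1, tolerance = 1e-12)
  }

  # bounds shrink with n, widen with cv
  expect_lt(acceptance_limits(10, 40, 16)$bound_upper,
            acceptance_limits(10, 40, 4)$bound_upper)
  expect_gt(acceptance_limits(10, 60, 8)$bound_upper,
            acceptance_limits(10, 30, 8)$bound_upper)

  # the alternative scaling reading divides by N
  n_read <- acceptance_limits(10, 40, 9, denominator = "N")
  expect_equal(n_read$fold_upper, exp(4.26 * sigma / 9))
})

test_that("phenotype fold limits reproduce every packaged study bound", {
  t1 <- load_table1_fixture()
  folds <- inh_fold_limits()
  for (i in seq_len(nrow(t1))) {
    fa <- apply_fold_limits(t1$obs_auc[i], folds$AUC[[t1$phenotype[i]]])
    expect_equal(fa[1], t1$auc_lo[i], tolerance = 0.006)
    expect_equal(fa[2], t1$auc_hi[i], tolerance = 0.006)
    fc <- apply_fold_limits(t1$obs_cmax[i], folds$Cmax[[t1$phenotype[i]]])
    expect_equal(fc[1], t1$cmax_lo[i], tolerance = 0.006)
    expect_equal(fc[2], t1$cmax_hi[i], tolerance = 0.006)
  }
  expect_equal(apply_fold_limits(20.4, c(0.50, 1.97)), c(10.20, 40.19),
               tolerance = 1e-4)
})

test_that("fold error statistic is symmetric, >= 1 and matches hand cases", {
  expect_equal(aafe(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(aafe(2 * c(1, 5, 9), c(1, 5, 9)), 2)
  expect_equal(aafe(c(2, 0.5), c(1, 1)), 2)
  set.seed(1)
  p <- runif(20, 0.1, 10); o <- runif(20, 0.1, 10)
  expect_equal(aafe(p, o), aafe(o, p))
  expect_gte(aafe(p, o), 1)
  expect_error(aafe(c(1, -1), c(1, 1)), "positive")
  expect_error(aafe(1:3, 1:2), "equal length")
})

test_that("study verification applies closed intervals and the AAFE rule", {
  fake_sim <- function(auc, cmax) {
    tt <- seq(0, 24, by = 0.5)
    cc <- cmax * exp(-0.3 * tt)
    structure(list(summary = list(auc = auc, cmax = cmax),
                   mean_curve = data.frame(time = tt, conc = cc)),
              class = "inh_simulation")
  }
  obs <- list(obs_auc = 10, auc_lo = 8, auc_hi = 12,
              obs_cmax = 5, cmax_lo = 4, cmax_hi = 7)
  v <- verify_study(fake_sim(9, 5), obs)
  expect_true(v$auc_pass && v$cmax_pass && v$overall_pass)
  # exactly on a bound passes (closed interval)
  expect_true(verify_study(fake_sim(8, 7), obs)$overall_pass)
  expect_false(verify_study(fake_sim(12.01, 5), obs)$auc_pass)
  # missing observed fields are not evaluated
  v2 <- verify_study(fake_sim(9, 5), list(obs_auc = 10, auc_lo = 8,
                                          auc_hi = 12))
  expect_true(is.na(v2$cmax_pass))
  expect_true(v2$overall_pass)
  # AAFE against a matching profile
  sim <- fake_sim(9, 5)
  prof <- data.frame(time = c(1, 2, 4, 8), conc = 5 * exp(-0.3 * c(1, 2, 4, 8)))
  v3 <- verify_study(sim, obs, observed_profile = prof)
  expect_equal(v3$aafe, 1, tolerance = 1e-6)
  expect_true(v3$aafe_pass)
})
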