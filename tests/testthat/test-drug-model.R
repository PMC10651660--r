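test_that("hepatic clearance is systemic minus renal, with input validation", {
  expect_equal(hepatic_clearance_from_systemic(25, 2.76), 22.24)
  expect_equal(hepatic_clearance_from_systemic(10, 2.76), 7.24)
  expect_equal(hepatic_clearance_from_systemic(2.76, 2.76), 0)
  expect_error(hepatic_clearance_from_systemic(2, 3), "exceeds")
  expect_error(hepatic_clearance_from_systemic(-1, -2), "non-negative")
})

test_that("pathway partition solves the two-phenotype linear system", {
  # independent oracle: base linear solve of
  #   cl_hep_fa = cl_other + cl_nat2 ; cl_hep_sa = cl_other + f * cl_nat2
  oracle <- solve(matrix(c(1, 1, 1, 0.12), 2, byrow = TRUE),
                  c(22.24, 7.24))  # (cl_other, cl_nat2)
  got <- partition_hepatic_clearance(22.24, 7.24, 0.12)
  expect_equal(got$cl_other, oracle[1], tolerance = 1e-12)
  expect_equal(got$cl_nat2_fa, oracle[2], tolerance = 1e-12)
  expect_equal(got$cl_nat2_fa, 17.045, tolerance = 1e-3)
  expect_equal(got$cl_other, 5.195, tolerance = 1e-3)

  # equal hepatic clearances imply no NAT2 contribution
  for (x in c(0, 3.7, 22.24)) {
    g <- partition_hepatic_clearance(x, x, 0.12)
    expect_equal(g$cl_nat2_fa, 0)
    expect_equal(g$cl_other, x)
  }
  expect_error(partition_hepatic_clearance(22.24, 7.24, 1), "singular")

  # recomposition reproduces the inputs exactly
  g <- partition_hepatic_clearance(22.24, 7.24, 0.12)
  expect_equal(g$cl_other + g$cl_nat2_fa, 22.24)
  expect_equal(g$cl_other + 0.12 * g$cl_nat2_fa, 7.24)
})

test_that("well-stirred model round-trips and matches hand arithmetic", {
  for (x in c(1, 10, 50))
    expect_equal(wellstirred_backcalc(wellstirred(x, 90, 0.95), 90, 0.95), x,
                 tolerance = 1e-10)
  # 90 * (0.95*19.92) / (90 + 0.95*19.92)
  expect_equal(wellstirred(19.92, 90, 0.95), 90 * 18.924 / 108.924,
               tolerance = 1e-12)
  expect_equal(wellstirred(19.92, 90, 0.95), 15.64, tolerance = 1e-3)
  # low-extraction limit: CLh -> fu * clu_int / bp
  expect_equal(wellstirred(10, 1e9, 0.95), 9.5, tolerance = 1e-6)
  # forward result strictly below hepatic flow
  expect_lt(wellstirred(1e6, 90, 0.95), 90)
  expect_error(wellstirred_backcalc(95, 90, 0.95), "infeasible")
})

test_that("per-mg cytosolic protein conversion matches direct arithmetic", {
  expect_equal(intrinsic_to_per_mg(19.92, 81.033, 1650),
               19.92e6 / (81.033 * 1650 * 60), tolerance = 1e-12)
  expect_equal(intrinsic_to_per_mg(19.92, 81.033, 1650), 2.4831,
               tolerance = 1e-4)
  expect_equal(intrinsic_to_per_mg(2.39, 81.033, 1650), 0.2979,
               tolerance = 1e-3)
  expect_equal(intrinsic_to_per_mg(0, 81.033, 1650), 0)
  # exact round trip; linear in clu_int, inverse in liver weight
  for (x in c(0.3, 2.39, 19.92)) {
    expect_equal(per_mg_to_intrinsic(intrinsic_to_per_mg(x, 81.033, 1650),
                                     81.033, 1650), x)
    expect_equal(intrinsic_to_per_mg(2 * x, 81.033, 1650),
                 2 * intrinsic_to_per_mg(x, 81.033, 1650))
    expect_equal(intrinsic_to_per_mg(x, 81.033, 3300),
                 intrinsic_to_per_mg(x, 81.033, 1650) / 2)
  }
  expect_error(intrinsic_to_per_mg(1, 0, 1650), "cppgl")
})

test_that("phenotype sets order FA >= IA >= SA and keep Vmax consistent", {
  fa <- build_phenotype_set("FA")
  ia <- build_phenotype_set("IA")
  sa <- build_phenotype_set("SA")
  expect_equal(sa$clu_int_nat2, 0.12 * 19.92, tolerance = 2e-3)
  expect_equal(ia$clu_int_nat2, 0.5 * (19.92 + 2.39))
  expect_true(fa$clu_int_nat2 >= ia$clu_int_nat2 &&
                ia$clu_int_nat2 >= sa$clu_int_nat2)
  for (p in list(fa, ia, sa))
    expect_equal(p$vmax_per_mg, p$clu_int_per_mg * p$km / 1000)
  expect_error(build_phenotype_set("XX"), "unknown phenotype")
})

test_that("partition prediction behaves in limiting cases and for isoniazid", {
  # hydrophilic neutral, unbound drug distributes with tissue water
  d0 <- inh_drug_parameters(log_p = -10, fu_plasma = 1)
  kp0 <- predict_kp_rodgers_rowland(d0)
  tc <- tissue_composition()
  fw <- setNames(tc$f_water, tc$tissue)
  expect_equal(unname(kp0$kp), unname(fw[names(kp0$kp)] / fw["plasma"]),
               tolerance = 0.1)

  # monotone non-decreasing in logP
  vss <- sapply(seq(-2, 3, by = 0.5), function(lp)
    predict_kp_rodgers_rowland(inh_drug_parameters(log_p = lp))$kp)
  expect_true(all(apply(vss, 1, function(r) all(diff(r) >= -1e-12))))

  # isoniazid: total body water distribution, about 0.6 L/kg
  kp <- predict_kp_rodgers_rowland(inh_drug_parameters())
  expect_gt(kp$vss_pred, 0.6 * 0.8)
  expect_lt(kp$vss_pred, 0.6 * 1.2)
  expect_true(all(kp$kp > 0))

  # Vss invariant to tissue enumeration order in the composition table
  kp_shuf <- predict_kp_rodgers_rowland(
    inh_drug_parameters(), tissue_comp = tc[rev(seq_len(nrow(tc))), ])
  expect_equal(kp_shuf$vss_pred, kp$vss_pred)

  expect_error(predict_kp_rodgers_rowland(inh_drug_parameters(),
                                          tissue_comp = tc[-3, ]), "missing")
})

test_that("Kp scaling hits a target Vss and recovers a known scale factor", {
  kp <- predict_kp_rodgers_rowland(inh_drug_parameters())
  same <- optimize_kp_scalars(kp, kp$vss_pred)
  expect_equal(attr(same, "scale_factor"), 1, tolerance = 1e-9)
  expect_equal(same$kp, kp$kp, tolerance = 1e-9)

  # manufacture a target by scaling adipose+skin by 1.7 and recover it
  kp17 <- kp
  kp17$kp[c("adipose", "skin")] <- kp17$kp[c("adipose", "skin")] * 1.7
  target <- inhpbpk:::.vss_from_kp(kp17$kp, ref_male)
  rec <- optimize_kp_scalars(kp, target)
  expect_equal(attr(rec, "scale_factor"), 1.7, tolerance = 1e-3)
  expect_equal(rec$vss_pred, target, tolerance = 1e-6)

  # target below the plasma-only volume is infeasible
  expect_error(optimize_kp_scalars(kp, 0.02), "infeasible")
})
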