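#' Physicochemical and absorption parameters for isoniazid
#'
#' Returns the drug parameter set used for tissue partition prediction and
#' oral absorption. Isoniazid is a small hydrophilic molecule (MW 137.14
#' g/mol, logP about -0.7), essentially un-ionized at physiological pH and
#' minimally protein bound (fu = 0.95); it distributes into total body water
#' (Vss about 0.6 L/kg). Absorption is described with a first-order model
#' (fraction absorbed `fa`, rate constant `ka`, lag time).
#'
#' @param ... named overrides for any default field.
#' @return An object of class `inh_drug`: a list with fields
#'   `molecular_weight` (g/mol), `log_p`, `pka_list`, `ionization_class`
#'   (one of `"neutral"`, `"acid"`, `"base"`, `"ampholyte"`), `fu_plasma`,
#'   `blood_plasma_ratio`, `fa`, `ka` (1/h), `fu_gut`, `lag_time` (h).
#' @export
inh_drug_parameters <- function(...) {
  d <- list(
    molecular_weight   = 137.14,
    log_p              = -0.70,
    pka_list           = numeric(0),
    ionization_class   = "neutral",
    fu_plasma          = 0.95,
    blood_plasma_ratio = 1.0,
    fa                 = 0.88,
    ka                 = 4.5,
    fu_gut             = 1.0,
    lag_time           = 0.25
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(d))
  if (length(unknown))
    .stop_invalid("unknown drug parameter(s): %s", paste(unknown, collapse = ", "))
  d[names(ov)] <- ov
  validate_drug_parameters(d)
  class(d) <- "inh_drug"
  d
}

validate_drug_parameters <- function(d) {
  fr <- c("fu_plasma", "fa", "fu_gut")
  for (f in fr)
    if (d[[f]] < 0 || d[[f]] > 1)
      .stop_invalid("%s must be in [0, 1], got %g", f, d[[f]])
  if (d$ka <= 0) .stop_invalid("ka must be > 0")
  if (d$molecular_weight <= 0) .stop_invalid("molecular_weight must be > 0")
  if (d$blood_plasma_ratio <= 0) .stop_invalid("blood_plasma_ratio must be > 0")
  if (d$lag_time < 0) .stop_invalid("lag_time must be >= 0")
  invisible(d)
}

#' Hepatic clearance from systemic and renal clearance
#'
#' CLhep = CL - CLr. With the observed systemic clearances of 25 and 10 L/h
#' in NAT2 fast and slow acetylators and CLr = 2.76 L/h this gives 22.24 and
#' 7.24 L/h.
#'
#' @param cl_systemic systemic (total) clearance, L/h.
#' @param cl_renal renal clearance, L/h.
#' @return Hepatic clearance, L/h.
#' @export
hepatic_clearance_from_systemic <- function(cl_systemic, cl_renal) {
  if (any(cl_renal < 0) || any(cl_systemic < 0))
    .stop_invalid("clearances must be non-negative")
  if (any(cl_renal > cl_systemic))
    .stop_invalid("renal clearance exceeds systemic clearance")
  cl_systemic - cl_renal
}

#' Partition hepatic clearance into NAT2 and non-NAT2 pathways
#'
#' Solves the two-phenotype linear system
#' \deqn{CL_{hep,FA} = CL_{other} + CL_{NAT2,FA}}
#' \deqn{CL_{hep,SA} = CL_{other} + f_{SA} \cdot CL_{NAT2,FA}}
#' where `f_SA` is the residual NAT2 activity of the slow-acetylator
#' genotype relative to fast acetylators (0.12 for NAT2*5 in vitro).
#' CL_other (amidase / oxidative pathways) is assumed phenotype-independent.
#'
#' @param cl_hep_fa,cl_hep_sa hepatic clearance in FA and SA, L/h.
#' @param sa_activity_fraction residual NAT2 activity in SA, in [0, 1).
#' @return List with `cl_nat2_fa` and `cl_other`, both L/h.
#' @export
partition_hepatic_clearance <- function(cl_hep_fa, cl_hep_sa,
                                        sa_activity_fraction = 0.12) {
  if (sa_activity_fraction < 0 || sa_activity_fraction >= 1)
    .stop_invalid("sa_activity_fraction must be in [0, 1); 1 makes the system singular")
  if (cl_hep_sa < 0 || cl_hep_fa < cl_hep_sa)
    .stop_invalid("need cl_hep_fa >= cl_hep_sa >= 0")
  cl_nat2_fa <- (cl_hep_fa - cl_hep_sa) / (1 - sa_activity_fraction)
  cl_other <- cl_hep_fa - cl_nat2_fa
  if (cl_other < -1e-12)
    .stop_invalid("infeasible: implied CL_other is negative (%g)", cl_other)
  list(cl_nat2_fa = cl_nat2_fa, cl_other = max(cl_other, 0))
}

#' Well-stirred liver model (forward and inverse)
#'
#' Maps unbound intrinsic clearance to hepatic blood clearance,
#' \deqn{CL_h = \frac{Q_h \cdot (fu/bp) \cdot CL_{u,int}}{Q_h + (fu/bp) \cdot CL_{u,int}}}
#' with hepatic blood flow `q_h`, plasma unbound fraction `fu` and
#' blood:plasma ratio `bp` (fu/bp is the unbound fraction referenced to
#' blood). `wellstirred_backcalc` is the algebraic inverse.
#'
#' @param clu_int unbound intrinsic clearance, L/h.
#' @param q_h hepatic blood flow, L/h.
#' @param fu unbound fraction in plasma, (0, 1].
#' @param bp blood:plasma concentration ratio.
#' @return Hepatic clearance (forward) or intrinsic clearance (inverse), L/h.
#' @export
wellstirred <- function(clu_int, q_h, fu, bp = 1) {
  .check_ws(q_h, fu, bp)
  if (any(clu_int < 0)) .stop_invalid("clu_int must be >= 0")
  fub <- fu / bp
  q_h * fub * clu_int / (q_h + fub * clu_int)
}

#' @rdname wellstirred
#' @param cl_hepatic hepatic clearance, L/h; must be strictly below `q_h`,
#'   otherwise no finite intrinsic clearance reproduces it.
#' @export
wellstirred_backcalc <- function(cl_hepatic, q_h, fu, bp = 1) {
  .check_ws(q_h, fu, bp)
  if (any(cl_hepatic < 0)) .stop_invalid("cl_hepatic must be >= 0")
  if (any(cl_hepatic >= q_h))
    .stop_invalid("infeasible: hepatic clearance (%g) approaches or exceeds hepatic blood flow (%g)",
                  max(cl_hepatic), q_h)
  fub <- fu / bp
  q_h * cl_hepatic / (fub * (q_h - cl_hepatic))
}

.check_ws <- function(q_h, fu, bp) {
  if (q_h <= 0) .stop_invalid("q_h must be > 0")
  if (fu <= 0 || fu > 1) .stop_invalid("fu must be in (0, 1]")
  if (bp <= 0) .stop_invalid("bp must be > 0")
}

#' Convert whole-liver intrinsic clearance to a per-mg cytosolic protein scale
#'
#' \deqn{CL_{u,int,H} = \frac{CL_{u,int} \times 10^6}{CPPGL \times LW \times 60}}
#' with CL_u,int in L/h, CPPGL the cytosolic protein per gram of liver
#' (mg/g) and LW the liver weight (g); the result is in uL/min/mg cytosolic
#' protein. `per_mg_to_intrinsic` is the exact inverse.
#'
#' @param clu_int whole-liver unbound intrinsic clearance, L/h.
#' @param cppgl cytosolic protein per gram liver, mg/g.
#' @param liver_weight liver weight, g.
#' @return Intrinsic clearance in uL/min/mg cytosolic protein.
#' @export
intrinsic_to_per_mg <- function(clu_int, cppgl, liver_weight) {
  .check_liver_scalars(cppgl, liver_weight)
  if (any(clu_int < 0)) .stop_invalid("clu_int must be >= 0")
  clu_int * 1e6 / (cppgl * liver_weight * 60)
}

#' @rdname intrinsic_to_per_mg
#' @param clu_int_per_mg intrinsic clearance, uL/min/mg cytosolic protein.
#' @export
per_mg_to_intrinsic <- function(clu_int_per_mg, cppgl, liver_weight) {
  .check_liver_scalars(cppgl, liver_weight)
  if (any(clu_int_per_mg < 0)) .stop_invalid("clu_int_per_mg must be >= 0")
  clu_int_per_mg * cppgl * liver_weight * 60 / 1e6
}

.check_liver_scalars <- function(cppgl, liver_weight) {
  if (cppgl <= 0) .stop_invalid("cppgl must be > 0")
  if (liver_weight <= 0) .stop_invalid("liver_weight must be > 0")
}

#' Phenotype-resolved clearance parameter set
#'
#' Builds the clearance parameters for one NAT2 phenotype. FA uses the
#' fast-acetylator whole-liver intrinsic clearance, SA the slow-acetylator
#' value (12% of FA), and IA - carriers of one fast and one slow allele -
#' the allele-additive mean `0.5 * (FA + SA)`. Michaelis-Menten Vmax is
#' defined from the per-mg intrinsic clearance and Km in the linear regime:
#' `vmax_per_mg [ug/min/mg] = clu_int_per_mg [uL/min/mg] * km [mg/L] / 1000`
#' (the unit factor 1/1000 converts uL * mg/L to ug).
#'
#' @param phenotype `"FA"`, `"IA"` or `"SA"`.
#' @param clu_int_fa,clu_int_sa whole-liver unbound intrinsic NAT2 clearance
#'   in FA and SA at the reference liver, L/h.
#' @param km Michaelis constant on the unbound liver-water concentration
#'   scale, mg/L.
#' @param cl_other non-NAT2 (amidase/oxidative) clearance, L/h.
#' @param cl_renal renal clearance, L/h.
#' @param cppgl cytosolic protein per gram liver, mg/g.
#' @param liver_weight reference liver weight, g.
#' @return Object of class `inh_phenotype_set`.
#' @export
build_phenotype_set <- function(phenotype,
                                clu_int_fa = 19.92,
                                clu_int_sa = 2.39,
                                km = inh_clearance_defaults()$km,
                                cl_other = NULL,
                                cl_renal = 2.76,
                                cppgl = 81.033,
                                liver_weight = 1650) {
  if (!phenotype %in% c("FA", "IA", "SA"))
    .stop_invalid("unknown phenotype '%s' (expected FA, IA or SA)", phenotype)
  if (km <= 0) .stop_invalid("km must be > 0")
  if (is.null(cl_other)) {
    defs <- inh_clearance_defaults()
    cl_other <- defs$cl_other
  }
  if (cl_other < 0 || cl_renal < 0) .stop_invalid("clearances must be >= 0")
  clu_int <- switch(phenotype,
    FA = clu_int_fa,
    SA = clu_int_sa,
    IA = 0.5 * clu_int_fa + 0.5 * clu_int_sa)
  per_mg <- intrinsic_to_per_mg(clu_int, cppgl, liver_weight)
  structure(list(
    phenotype       = phenotype,
    cl_renal        = cl_renal,
    cl_other        = cl_other,
    clu_int_nat2    = clu_int,
    clu_int_per_mg  = per_mg,
    km              = km,
    vmax_per_mg     = per_mg * km / 1000,  # ug/min/mg cytosolic protein
    cppgl           = cppgl,
    liver_weight    = liver_weight
  ), class = "inh_phenotype_set")
}

#' Default clearance parameterization for isoniazid
#'
#' The printed observed values the model is built from: systemic clearance
#' 25 (FA) and 10 (SA) L/h, renal clearance 2.76 L/h, residual SA NAT2
#' activity 12%, whole-liver unbound intrinsic NAT2 clearance 19.92 (FA) and
#' 2.39 (SA) L/h, CPPGL 81.033 mg/g, reference liver 1650 g. `cl_other` is
#' the solution of the two-phenotype pathway partition (5.195 L/h). `km` is
#' the Michaelis constant on the unbound liver-water scale, calibrated once
#' so that the fast-acetylator AUC rises more than dose-proportionally from
#' 300 to 900 mg in line with the observed nonlinearity; `sa_vss_target` is
#' the steady-state volume the slow-acetylator partition set is scaled to.
#'
#' @return Named list of clearance/configuration constants.
#' @export
inh_clearance_defaults <- function() {
  cl_hep_fa <- hepatic_clearance_from_systemic(25, 2.76)
  cl_hep_sa <- hepatic_clearance_from_systemic(10, 2.76)
  part <- partition_hepatic_clearance(cl_hep_fa, cl_hep_sa, 0.12)
  list(
    cl_systemic_fa = 25,
    cl_systemic_sa = 10,
    cl_renal = 2.76,
    sa_activity = 0.12,
    cl_hep_fa = cl_hep_fa,
    cl_hep_sa = cl_hep_sa,
    cl_nat2_fa = part$cl_nat2_fa,
    cl_other = part$cl_other,
    clu_int_fa = 19.92,
    clu_int_sa = 2.39,
    km = 10,
    cppgl = 81.033,
    liver_weight_ref = 1650,
    gfr_ref = 6.25,
    sa_vss_target = 0.53
  )
}

#' Tissue composition table for partition prediction
#'
#' Reads the packaged tissue composition table (fractional water, neutral
#' lipid, phospholipid, relative binding-protein content and pH per tissue,
#' plus a plasma reference row).
#'
#' @param path optional path to an alternative CSV with columns
#'   `tissue,f_water,f_nl,f_pl,f_protein,ph`.
#' @return data.frame keyed by tissue.
#' @export
tissue_composition <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tissue_composition.csv",
                        package = "inhpbpk", mustWork = TRUE)
  tc <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue", "f_water", "f_nl", "f_pl", "f_protein", "ph")
  if (!all(need %in% names(tc)))
    .stop_invalid("tissue composition table must have columns %s",
                  paste(need, collapse = ","))
  tc
}

#' Predict tissue:plasma partition coefficients (Rodgers-Rowland)
#'
#' Tissue-to-plasma partition coefficients from tissue composition: drug in
#' tissue water (with an ionization correction from the Henderson-
#' Hasselbalch ratio at tissue vs plasma pH), partitioning into neutral
#' lipid (proportional to P = 10^logP) and into phospholipid (0.3 P + 0.7),
#' plus a residual plasma-protein binding term anchored so that the plasma
#' row itself yields Kp = 1. For a neutral, minimally bound, hydrophilic
#' drug the result approaches the tissue-water fraction - total body water
#' distribution.
#'
#' @param drug an `inh_drug` object.
#' @param tissue_comp tissue composition table (see [tissue_composition()]);
#'   must contain a `plasma` row and every model tissue.
#' @param physiology a `PhysiologyState` used for the predicted steady-state
#'   volume; defaults to the 30-year-old male reference subject.
#' @return Object of class `inh_partition_set`: list with `kp` (named vector
#'   over tissues) and `vss_pred` (L/kg).
#' @export
predict_kp_rodgers_rowland <- function(drug,
                                       tissue_comp = tissue_composition(),
                                       physiology = reference_physiology("male", 30)) {
  missing_t <- setdiff(c(.tissues, "plasma"), tissue_comp$tissue)
  if (length(missing_t))
    .stop_invalid("tissue composition table missing row(s): %s",
                  paste(missing_t, collapse = ", "))
  P <- 10^drug$log_p
  fu <- drug$fu_plasma

  ion <- function(ph) {
    # ionized:neutral ratio correction on the water term
    switch(drug$ionization_class,
      neutral = rep(1, length(ph)),
      base = {
        if (!length(drug$pka_list)) .stop_invalid("base drug needs pka_list")
        pka <- max(drug$pka_list)
        (1 + 10^(pka - ph)) / (1 + 10^(pka - 7.4))
      },
      acid = {
        if (!length(drug$pka_list)) .stop_invalid("acid drug needs pka_list")
        pka <- min(drug$pka_list)
        (1 + 10^(ph - pka)) / (1 + 10^(7.4 - pka))
      },
      ampholyte = {
        if (length(drug$pka_list) < 2) .stop_invalid("ampholyte needs two pka values")
        pka_a <- max(drug$pka_list); pka_b <- min(drug$pka_list)
        (1 + 10^(pka_b - ph) + 10^(ph - pka_a)) /
          (1 + 10^(pka_b - 7.4) + 10^(7.4 - pka_a))
      },
      .stop_invalid("unsupported ionization class '%s'", drug$ionization_class))
  }

  pl <- tissue_comp[tissue_comp$tissue == "plasma", ]
  kpu_lipid <- function(row) P * row$f_nl + (0.3 * P + 0.7) * row$f_pl
  # residual protein binding in plasma, distributed to tissues by relative
  # binding-protein content; clamped at zero (keeps Kp monotone in logP)
  resid <- max(0, 1 / fu - (pl$f_water * 1 + kpu_lipid(pl)))

  rows <- tissue_comp[match(.tissues, tissue_comp$tissue), ]
  kpu <- rows$f_water * ion(rows$ph) + P * rows$f_nl +
    (0.3 * P + 0.7) * rows$f_pl + resid * rows$f_protein
  kp <- setNames(fu * kpu, .tissues)
  if (any(kp <= 0)) .stop_invalid("non-positive Kp predicted")

  structure(list(kp = kp,
                 vss_pred = .vss_from_kp(kp, physiology, drug$blood_plasma_ratio)),
            class = "inh_partition_set")
}

# Vss (L/kg) = (sum Kp_t V_t + V_plasma + Ke V_ery) / BW, erythrocyte
# partition Ke from the blood:plasma ratio and hematocrit.
.vss_from_kp <- function(kp, physiology, bp = 1) {
  v <- physiology$organ_volumes
  hct <- physiology$hematocrit
  ke <- (bp - (1 - hct)) / hct
  (sum(kp[.tissues] * v[.tissues]) + v[["plasma"]] + ke * v[["erythrocytes"]]) /
    physiology$body_weight
}

#' Scale selected tissue partition coefficients to match a target Vss
#'
#' Applies one common scalar to the named tissues (default the two major
#' distribution organs, adipose and skin) so that the predicted steady-state
#' volume equals `target_vss`. Used for the slow-acetylator model, whose
#' observed Vss exceeds the fast-acetylator prediction.
#'
#' @param partitions an `inh_partition_set`.
#' @param target_vss target steady-state volume, L/kg.
#' @param tissues_to_scale character vector of tissue names to scale.
#' @param physiology `PhysiologyState` defining organ volumes.
#' @param bp blood:plasma ratio.
#' @return A new `inh_partition_set` with scaled Kp and `vss_pred` equal to
#'   `target_vss` (to well below 0.1% relative).
#' @export
optimize_kp_scalars <- function(partitions, target_vss,
                                tissues_to_scale = c("adipose", "skin"),
                                physiology = reference_physiology("male", 30),
                                bp = 1) {
  stopifnot(inherits(partitions, "inh_partition_set"))
  bad <- setdiff(tissues_to_scale, .tissues)
  if (length(bad)) .stop_invalid("unknown tissue(s): %s", paste(bad, collapse = ", "))
  kp <- partitions$kp
  v <- physiology$organ_volumes
  bw <- physiology$body_weight
  hct <- physiology$hematocrit
  ke <- (bp - (1 - hct)) / hct
  fixed <- sum(kp[setdiff(.tissues, tissues_to_scale)] *
                 v[setdiff(.tissues, tissues_to_scale)]) +
    v[["plasma"]] + ke * v[["erythrocytes"]]
  scalable <- sum(kp[tissues_to_scale] * v[tissues_to_scale])
  s <- (target_vss * bw - fixed) / scalable
  if (!is.finite(s) || s <= 0)
    .stop_invalid("infeasible target_vss %g L/kg: below the contribution of unscaled tissues (%g L/kg)",
                  target_vss, fixed / bw)
  kp[tissues_to_scale] <- kp[tissues_to_scale] * s
  out <- structure(list(kp = kp, vss_pred = .vss_from_kp(kp, physiology, bp)),
                   class = "inh_partition_set")
  attr(out, "scale_factor") <- s
  out
}
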