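#' Non-compartmental analysis of a concentration-time profile
#'
#' Linear-up/log-down trapezoidal AUC with optional log-linear tail
#' extrapolation. The terminal rate constant is estimated by least squares
#' on the log concentrations of the terminal points (the last third of the
#' profile after Cmax, at least three points).
#'
#' @param times strictly increasing times, h.
#' @param conc concentrations, mg/L.
#' @param extrapolate add the `C_last / lambda_z` tail for `auc_0_inf`.
#' @return List with `auc_0_last`, `auc_0_inf` (`NA` when the terminal
#'   slope is not estimable), `cmax`, `tmax`, `lambda_z`.
#' @export
nca <- function(times, conc, extrapolate = TRUE) {
  if (length(times) < 3) .stop_invalid("need at least 3 time points")
  if (any(diff(times) <= 0)) .stop_invalid("times must be strictly increasing")
  if (any(conc < 0) || any(!is.finite(conc)))
    .stop_invalid("concentrations must be finite and >= 0")

  n <- length(times)
  dt <- diff(times)
  c1 <- conc[-n]; c2 <- conc[-1]
  logdown <- c2 < c1 & c2 > 0 & c1 > 0
  seg <- ifelse(logdown, (c1 - c2) * dt / log(c1 / c2), (c1 + c2) / 2 * dt)
  auc_last <- sum(seg)

  imax <- which.max(conc)
  res <- list(auc_0_last = auc_last, auc_0_inf = NA_real_,
              cmax = conc[imax], tmax = times[imax], lambda_z = NA_real_)
  if (!extrapolate) return(res)

  # terminal points: after Cmax, last third of the remaining profile
  idx <- which(seq_len(n) > imax & conc > 0)
  if (length(idx) >= 3)
    idx <- idx[times[idx] >= times[idx[1]] +
                 2 / 3 * (times[idx[length(idx)]] - times[idx[1]])]
  if (length(idx) < 3)
    .stop_invalid("terminal slope not estimable: fewer than 3 usable terminal points")
  fit <- lm(log(conc[idx]) ~ times[idx])
  lz <- -coef(fit)[[2]]
  if (!is.finite(lz) || lz <= 0)
    .stop_invalid("terminal slope not estimable: non-negative slope")
  res$lambda_z <- lz
  res$auc_0_inf <- auc_last + conc[n] / lz
  res
}

#' Drug-specific acceptance limits around an observed mean
#'
#' Lognormal fold limits reflecting intra- and inter-study variability:
#' \deqn{\sigma = \sqrt{\ln((CV\%/100)^2 + 1)}}
#' \deqn{A = \exp(+4.26\,\sigma/\sqrt{N}), \quad B = \exp(-4.26\,\sigma/\sqrt{N})}
#' with `N` the mean number of study participants; bounds are the observed
#' mean times the fold limits. The alternative `denominator = "N"` reading
#' of the scaling is supported behind a flag.
#'
#' @param observed_mean observed mean AUC or Cmax.
#' @param cv_pct observed mean coefficient of variation, percent.
#' @param n mean number of participants (>= 1).
#' @param denominator `"sqrtN"` (default) or `"N"`.
#' @return Object of class `inh_acceptance_range`: list with
#'   `observed_mean`, `cv_pct`, `n`, `sigma`, `fold_lower`, `fold_upper`,
#'   `bound_lower`, `bound_upper`.
#' @export
acceptance_limits <- function(observed_mean, cv_pct, n,
                              denominator = c("sqrtN", "N")) {
  denominator <- match.arg(denominator)
  if (cv_pct < 0) .stop_invalid("cv_pct must be >= 0")
  if (n < 1) .stop_invalid("n must be >= 1")
  if (observed_mean <= 0) .stop_invalid("observed_mean must be > 0")
  sigma <- sqrt(log((cv_pct / 100)^2 + 1))
  den <- if (denominator == "sqrtN") sqrt(n) else n
  fu <- exp(4.26 * sigma / den)
  structure(list(observed_mean = observed_mean, cv_pct = cv_pct, n = n,
                 sigma = sigma, fold_lower = 1 / fu, fold_upper = fu,
                 bound_lower = observed_mean / fu,
                 bound_upper = observed_mean * fu),
            class = "inh_acceptance_range")
}

#' Apply phenotype fold limits to an observed mean
#'
#' The phenotype-level fold limits computed by the acceptance-criterion
#' statistics (AUC: FA 0.67-1.48, IA 0.85-1.17, SA 0.50-1.97; Cmax: FA
#' 0.50-1.98, IA 0.61-1.63, SA 0.28-3.56) applied to a study's observed
#' mean give that study's absolute acceptance bounds.
#'
#' @param observed_mean observed mean value.
#' @param folds length-2 numeric `(lower, upper)` fold limits.
#' @return Numeric `(bound_lower, bound_upper)`.
#' @export
apply_fold_limits <- function(observed_mean, folds) {
  if (length(folds) != 2 || any(folds <= 0) || folds[1] > folds[2])
    .stop_invalid("folds must be (lower, upper), both > 0")
  observed_mean * folds
}

#' Phenotype-level acceptance fold limits
#'
#' The fold limits used for the isoniazid model, as constants so that
#' verification does not depend on the CV%/N inputs behind them.
#'
#' @return Nested list: `$AUC` and `$Cmax`, each with `FA`, `IA`, `SA`
#'   length-2 vectors.
#' @export
inh_fold_limits <- function() {
  list(AUC = list(FA = c(0.67, 1.48), IA = c(0.85, 1.17), SA = c(0.50, 1.97)),
       Cmax = list(FA = c(0.50, 1.98), IA = c(0.61, 1.63), SA = c(0.28, 3.56)))
}

#' Absolute average fold error
#'
#' \deqn{AAFE = 10^{\frac{1}{n}\sum_i |\log_{10}(pred_i / obs_i)|}}
#' Symmetric in prediction and observation and always >= 1; <= 1.5 is the
#' pass criterion for distribution kinetics.
#'
#' @param predicted,observed positive vectors of equal length.
#' @return AAFE, unitless.
#' @export
aafe <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    .stop_invalid("predicted and observed must have equal length")
  if (any(predicted <= 0) || any(observed <= 0))
    .stop_invalid("AAFE requires strictly positive concentrations")
  10^mean(abs(log10(predicted / observed)))
}

#' Verify a simulation against an observed study summary
#'
#' Compares the simulated grand mean AUC and Cmax against the study's
#' absolute acceptance bounds (closed intervals) and, when an observed mean
#' profile is supplied, computes the AAFE against it (pass at <= 1.5).
#'
#' @param sim an `inh_simulation`.
#' @param observed list or one-row data.frame with `obs_auc`, `auc_lo`,
#'   `auc_hi` and optionally `obs_cmax`, `cmax_lo`, `cmax_hi`.
#' @param observed_profile optional data.frame `time`, `conc`; simulated
#'   concentrations are interpolated onto its times.
#' @return Object of class `inh_verification`: per-metric simulated value,
#'   bounds, pass flag (`NA` = not evaluated) and overall pass.
#' @export
verify_study <- function(sim, observed, observed_profile = NULL) {
  gv <- function(x) if (!is.null(observed[[x]]) && !is.na(observed[[x]]))
    observed[[x]] else NA_real_
  check <- function(value, lo, hi) {
    if (is.na(lo) || is.na(hi)) return(NA)
    value >= lo & value <= hi
  }
  auc_pass <- check(sim$summary$auc, gv("auc_lo"), gv("auc_hi"))
  cmax_pass <- check(sim$summary$cmax, gv("cmax_lo"), gv("cmax_hi"))
  aafe_val <- NA_real_
  aafe_pass <- NA
  if (!is.null(observed_profile)) {
    pred <- stats::approx(sim$mean_curve$time, sim$mean_curve$conc,
                          xout = observed_profile$time, rule = 2)$y
    keep <- pred > 0 & observed_profile$conc > 0
    aafe_val <- aafe(pred[keep], observed_profile$conc[keep])
    aafe_pass <- aafe_val <= 1.5
  }
  passes <- c(auc = auc_pass, cmax = cmax_pass, aafe = aafe_pass)
  structure(list(
    sim_auc = sim$summary$auc, sim_cmax = sim$summary$cmax,
    auc_bounds = c(gv("auc_lo"), gv("auc_hi")),
    cmax_bounds = c(gv("cmax_lo"), gv("cmax_hi")),
    auc_pass = auc_pass, cmax_pass = cmax_pass,
    aafe = aafe_val, aafe_pass = aafe_pass,
    overall_pass = all(passes[!is.na(passes)])
  ), class = "inh_verification")
}

#' Serialize a verification report
#'
#' @param report an `inh_verification`.
#' @param path output JSON path.
#' @export
write_verification_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
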