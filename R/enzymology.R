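## Quantitative characterization: reducing-sugar activity units,
## Michaelis-Menten fitting (Lineweaver-Burk and nonlinear), turnover and
## catalytic-efficiency derivation, thermal T50 and half-life fits, and
## degree-of-synergy analysis.

#' Specific activity from a reducing-sugar assay
#'
#' One unit (1 U) is the release of 1 umol of xylose equivalents per minute;
#' specific activity is units per mg enzyme.
#'
#' @param released_umol umol of xylose equivalents released.
#' @param minutes Assay duration (min).
#' @param enzyme_mg Enzyme amount (mg).
#' @return Specific activity in U/mg.
#' @examples
#' activity_units(10, 10, 1)   # 1 U/mg
#' @export
activity_units <- function(released_umol, minutes, enzyme_mg) {
  if (any(c(released_umol, minutes, enzyme_mg) <= 0))
    stop("all inputs must be positive", call. = FALSE)
  released_umol / minutes / enzyme_mg
}

#' Fit Michaelis-Menten kinetics
#'
#' `method = "lineweaver_burk"` (the default, matching how polymeric-substrate
#' xylanase kinetics are conventionally reported): ordinary least squares of
#' `1/v` on `1/[S]`; `Km = slope/intercept`, `Vmax = 1/intercept`.
#' `method = "nonlinear"`: Levenberg-Marquardt least squares on
#' `v = Vmax [S] / (Km + [S])`, initialized from the Lineweaver-Burk
#' estimate. The double-reciprocal fit is statistically fragile (it
#' up-weights low-rate points), so the nonlinear route is provided as a
#' cross-check.
#'
#' @param data An `assay_table` of kind `"kinetics"`, or a data.frame with
#'   columns `substrate_mg_per_mL` and `rate`.
#' @param method `"lineweaver_burk"` or `"nonlinear"`.
#' @return Object of class `mm_fit`: `Km` (mg/mL), `Vmax` (umol/min/mg),
#'   `method`, `r_squared`, `se` (named standard errors), `data`.
#'   A fit driven to the `Km -> 0` saturation boundary carries a warning.
#' @examples
#' d <- make_kinetics(seed = 1, km = 0.75, vmax = 680)$table
#' fit <- fit_michaelis_menten(d)
#' coef(fit)
#' @export
fit_michaelis_menten <- function(data, method = c("lineweaver_burk", "nonlinear")) {
  method <- match.arg(method)
  s <- data$substrate_mg_per_mL
  v <- data$rate
  if (length(unique(s)) < 4L)
    stop("need at least 4 distinct substrate concentrations", call. = FALSE)
  if (any(!is.finite(s)) || any(!is.finite(v)))
    stop("non-finite kinetics data", call. = FALSE)
  if (any(v <= 0))
    stop("non-positive rate: cannot take reciprocals for the Lineweaver-Burk estimate",
         call. = FALSE)
  lb <- stats::lm(I(1 / v) ~ I(1 / s))
  intercept <- stats::coef(lb)[[1]]
  slope <- stats::coef(lb)[[2]]
  if (intercept <= 0)
    stop("Lineweaver-Burk intercept <= 0: data inconsistent with saturation kinetics",
         call. = FALSE)
  km_lb <- slope / intercept
  vmax_lb <- 1 / intercept
  if (method == "lineweaver_burk") {
    sm <- suppressWarnings(summary(lb))  # noise-free data is a legal input
    se_lb <- sm$coefficients[, "Std. Error"]
    ## delta-method propagation to (Km, Vmax)
    se <- c(Km = sqrt((se_lb[2] / intercept)^2 +
                        (slope * se_lb[1] / intercept^2)^2),
            Vmax = se_lb[1] / intercept^2)
    fit <- list(Km = km_lb, Vmax = vmax_lb, method = method,
                r_squared = sm$r.squared, se = se,
                model = lb, data = data.frame(substrate_mg_per_mL = s, rate = v))
  } else {
    start <- list(Km = max(km_lb, .Machine$double.eps), Vmax = vmax_lb)
    nl <- minpack.lm::nlsLM(v ~ Vmax * s / (Km + s), start = start,
                            lower = c(Km = 0, Vmax = 0),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(nl)
    ss_res <- sum(stats::resid(nl)^2)
    ss_tot <- sum((v - mean(v))^2)
    fit <- list(Km = cf[["Km"]], Vmax = cf[["Vmax"]], method = method,
                r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                se = suppressWarnings(summary(nl))$coefficients[, "Std. Error"],
                model = nl, data = data.frame(substrate_mg_per_mL = s, rate = v))
  }
  if (fit$Km < 1e-8 * max(s))
    warning("Km at the saturation boundary (rates constant across [S])",
            call. = FALSE)
  class(fit) <- "mm_fit"
  fit
}

#' @export
print.mm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<mm_fit> %s: Km = %s mg/mL, Vmax = %s umol/min/mg (R^2 = %.4f)\n",
              x$method, signif(x$Km, digits), signif(x$Vmax, digits),
              x$r_squared))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) c(Km = object$Km, Vmax = object$Vmax)

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$data$substrate_mg_per_mL
       else newdata$substrate_mg_per_mL
  object$Vmax * s / (object$Km + s)
}

#' @export
residuals.mm_fit <- function(object, ...) {
  object$data$rate - predict(object)
}

#' @export
plot.mm_fit <- function(x, ...) {
  s <- x$data$substrate_mg_per_mL
  graphics::plot(s, x$data$rate, xlab = "[S] (mg/mL)",
                 ylab = "v (umol/min/mg)", main = x$method, ...)
  sg <- seq(min(s), max(s), length.out = 100)
  graphics::lines(sg, x$Vmax * sg / (x$Km + sg))
  invisible(x)
}

#' Turnover number from Vmax and molecular mass
#'
#' `kcat = Vmax * MW / 60`: with Vmax in umol/(min mg) and the mass in kDa
#' (= mg/umol), the product is per-minute turnover, divided by 60 for /s.
#'
#' @param vmax Vmax in umol/min/mg.
#' @param mw_kda Molecular mass of the mature protein in kDa.
#' @return kcat in /s.
#' @export
kcat_from_vmax <- function(vmax, mw_kda) {
  if (any(c(vmax, mw_kda) <= 0)) stop("inputs must be positive", call. = FALSE)
  vmax * mw_kda / 60
}

#' Catalytic efficiency kcat/Km
#'
#' Reported in mL/s/mg because polymeric substrates are quantified by mass
#' concentration.
#'
#' @param kcat Turnover number (/s).
#' @param km Michaelis constant (mg/mL).
#' @return kcat/Km in mL/s/mg.
#' @export
catalytic_efficiency <- function(kcat, km) {
  if (any(km <= 0)) stop("Km must be positive", call. = FALSE)
  kcat / km
}

#' Protein molecular mass from sequence
#'
#' Average residue masses; mass of water added once for the intact chain.
#'
#' @param seq Amino-acid string or `seq_record`.
#' @return Mass in kDa.
#' @export
protein_mw_kda <- function(seq) {
  if (inherits(seq, "seq_record")) seq <- seq$seq
  masses <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(chars, names(masses))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ","),
                        call. = FALSE)
  (sum(masses[chars]) + 18.0153) / 1000
}

#' Fold changes relative to a reference enzyme
#'
#' @param values Named numeric vector (one value per enzyme), e.g. catalytic
#'   efficiencies or specific activities.
#' @param reference Name of the reference enzyme (must be in `names(values)`).
#' @return List with `fold` (named vector `value / reference`), and `min` /
#'   `max` over the non-reference entries.
#' @examples
#' fold_changes(c(XylE = 570, `XylE-M3/M6` = 2280), "XylE")
#' @export
fold_changes <- function(values, reference) {
  if (!reference %in% names(values))
    stop("reference '", reference, "' not found", call. = FALSE)
  ref <- values[[reference]]
  if (!is.finite(ref) || ref == 0)
    stop("reference value must be nonzero and finite", call. = FALSE)
  fold <- values / ref
  others <- fold[setdiff(names(fold), reference)]
  others <- others[is.finite(others)]
  list(fold = fold, min = min(others), max = max(others))
}

## ---- thermal fits ----------------------------------------------------------

#' Fit the thermal-inactivation midpoint T50
#'
#' T50 is the pre-incubation temperature at which half the maximal activity
#' survives a fixed heating period. The default model is a 2-parameter
#' falling logistic on the percent scale,
#' `R(T) = 100 / (1 + exp((T - T50) / s))` with slope `s > 0`, fit by
#' Levenberg-Marquardt least squares; `method = "interpolation"` instead
#' returns the model-free linear interpolation of the 50% crossing.
#'
#' @param data An `assay_table` of kind `"thermal_T50"`, or a data.frame with
#'   columns `temperature_C` and `residual_pct`.
#' @param method `"logistic"` (default) or `"interpolation"`.
#' @return Object of class `t50_fit`: `T50` (degrees C), `slope` (`NA` for
#'   interpolation), `method`, `r_squared`, `data`.
#' @export
fit_t50 <- function(data, method = c("logistic", "interpolation")) {
  method <- match.arg(method)
  temp <- data$temperature_C
  r <- data$residual_pct
  if (length(temp) < 3L) stop("need at least 3 temperature points", call. = FALSE)
  if (min(r) > 50 || max(r) < 50)
    stop("residual activity never crosses 50% within the assayed range; cannot extrapolate T50",
         call. = FALSE)
  cross <- .interp_crossing(temp, r, 50)
  if (method == "interpolation") {
    fit <- list(T50 = cross, slope = NA_real_, method = method,
                r_squared = NA_real_,
                data = data.frame(temperature_C = temp, residual_pct = r))
    class(fit) <- "t50_fit"
    return(fit)
  }
  nl <- minpack.lm::nlsLM(r ~ 100 / (1 + exp((temp - T50) / s)),
                          start = list(T50 = cross, s = 2),
                          lower = c(T50 = min(temp), s = 1e-6),
                          upper = c(T50 = max(temp), s = Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(nl)
  ss_res <- sum(stats::resid(nl)^2)
  ss_tot <- sum((r - mean(r))^2)
  fit <- list(T50 = cf[["T50"]], slope = cf[["s"]], method = method,
              r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
              model = nl,
              data = data.frame(temperature_C = temp, residual_pct = r))
  class(fit) <- "t50_fit"
  fit
}

## first downward linear-interpolation crossing of `level`
.interp_crossing <- function(x, y, level) {
  for (i in seq_len(length(x) - 1L)) {
    y1 <- y[i]; y2 <- y[i + 1L]
    if ((y1 - level) * (y2 - level) <= 0 && y1 != y2)
      return(x[i] + (level - y1) * (x[i + 1L] - x[i]) / (y2 - y1))
    if (y1 == level) return(x[i])
  }
  x[which.min(abs(y - level))]
}

#' @export
print.t50_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<t50_fit> %s: T50 = %s C", x$method, signif(x$T50, digits)))
  if (!is.na(x$slope)) cat(sprintf(", slope = %s C", signif(x$slope, digits)))
  cat("\n")
  invisible(x)
}

#' @export
coef.t50_fit <- function(object, ...) c(T50 = object$T50, s = object$slope)

#' @export
predict.t50_fit <- function(object, newdata = NULL, ...) {
  temp <- if (is.null(newdata)) object$data$temperature_C
          else newdata$temperature_C
  if (is.na(object$slope))
    stop("interpolation fit has no predictive model", call. = FALSE)
  100 / (1 + exp((temp - object$T50) / object$slope))
}

#' @export
plot.t50_fit <- function(x, ...) {
  graphics::plot(x$data$temperature_C, x$data$residual_pct,
                 xlab = "pre-incubation temperature (C)",
                 ylab = "residual activity (%)", ...)
  if (!is.na(x$slope)) {
    tg <- seq(min(x$data$temperature_C), max(x$data$temperature_C),
              length.out = 200)
    graphics::lines(tg, 100 / (1 + exp((tg - x$T50) / x$slope)))
  }
  graphics::abline(h = 50, v = x$T50, lty = 3)
  invisible(x)
}

#' Fit a first-order thermal-inactivation half-life
#'
#' Least squares on the log scale, `ln R(t) = ln R0 - k t`; the half-life is
#' `t1/2 = ln 2 / k`. Residual activities must be positive. If the fitted
#' rate is not positive the enzyme shows no decay over the assayed window and
#' `t_half = Inf` is returned with a warning.
#'
#' @param data An `assay_table` of kind `"thermal_decay"`, or a data.frame
#'   with columns `time_h` and `residual_pct`.
#' @return Object of class `decay_fit`: `t_half` (h), `k` (/h), `R0`,
#'   `r_squared`, `data`.
#' @export
fit_half_life <- function(data) {
  t <- data$time_h
  r <- data$residual_pct
  if (length(t) < 3L) stop("need at least 3 time points", call. = FALSE)
  if (any(r <= 0)) stop("residual activities must be positive for the log-linear fit",
                        call. = FALSE)
  m <- stats::lm(log(r) ~ t)
  k <- -stats::coef(m)[[2]]
  r0 <- exp(stats::coef(m)[[1]])
  if (k <= 0) {
    warning("no decay over the assayed window; t_half = Inf", call. = FALSE)
    t_half <- Inf
  } else t_half <- log(2) / k
  fit <- list(t_half = t_half, k = k, R0 = r0,
              r_squared = suppressWarnings(summary(m))$r.squared, model = m,
              data = data.frame(time_h = t, residual_pct = r))
  class(fit) <- "decay_fit"
  fit
}

#' @export
print.decay_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<decay_fit> k = %s /h, t1/2 = %s h (R^2 = %.4f)\n",
              signif(x$k, digits), signif(x$t_half, digits), x$r_squared))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) c(k = object$k, t_half = object$t_half)

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_h else newdata$time_h
  object$R0 * exp(-object$k * t)
}

## ---- synergy ---------------------------------------------------------------

#' Degree of synergy for mixed-enzyme hydrolysis
#'
#' `DS(t) = Y_both(t) / (Y_cellulase(t) + Y_xylanase(t))`, the reducing sugar
#' released by the simultaneous treatment divided by the sum released by each
#' enzyme alone. DS > 1 indicates synergy. The published formula carries no
#' control term, so no control subtraction is applied by default; with
#' `subtract_control = TRUE` the control arm is subtracted from each
#' treatment arm first. Time points whose denominator is not positive are
#' skipped with a warning.
#'
#' @param tc An `assay_table` of kind `"synergy"`, or a data.frame with
#'   columns `time_h`, `both`, `cellulase_only`, `xylanase_only` (optionally
#'   `control`).
#' @param subtract_control Subtract the no-enzyme control arm first?
#' @return Object of class `synergy_ds`: `ds` data.frame (`time_h`, `DS`),
#'   `max_ds`, `t_max`, `t_first_gt1` (first assayed time with DS > 1, `NA`
#'   if never).
#' @examples
#' degree_of_synergy(data.frame(time_h = 15, both = 3.9,
#'                              cellulase_only = 3.2, xylanase_only = 0.45))
#' @export
degree_of_synergy <- function(tc, subtract_control = FALSE) {
  need <- c("time_h", "both", "cellulase_only", "xylanase_only")
  miss <- setdiff(need, names(tc))
  if (length(miss)) stop("missing arm(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  yb <- tc$both; yc <- tc$cellulase_only; yx <- tc$xylanase_only
  if (subtract_control) {
    if (is.null(tc$control)) stop("no control arm to subtract", call. = FALSE)
    yb <- yb - tc$control; yc <- yc - tc$control; yx <- yx - tc$control
  }
  if (any(c(tc$both, tc$cellulase_only, tc$xylanase_only) < 0))
    stop("sugar measurements must be non-negative", call. = FALSE)
  denom <- yc + yx
  ds <- ifelse(denom > 0, yb / denom, NA_real_)
  if (anyNA(ds))
    warning(sum(is.na(ds)), " time point(s) skipped: Y_cellulase + Y_xylanase <= 0",
            call. = FALSE)
  out <- data.frame(time_h = tc$time_h, DS = ds)
  valid <- which(!is.na(ds))
  gt1 <- valid[ds[valid] > 1]
  res <- list(ds = out,
              max_ds = if (length(valid)) max(ds[valid]) else NA_real_,
              t_max = if (length(valid)) out$time_h[valid[which.max(ds[valid])]]
                      else NA_real_,
              t_first_gt1 = if (length(gt1)) out$time_h[gt1[1]] else NA_real_,
              subtract_control = subtract_control)
  class(res) <- "synergy_ds"
  res
}

#' @export
print.synergy_ds <- function(x, digits = 4, ...) {
  cat(sprintf("<synergy_ds> %d time points; max DS = %s at %s h; first DS > 1 at %s h\n",
              nrow(x$ds), signif(x$max_ds, digits), x$t_max,
              ifelse(is.na(x$t_first_gt1), "never", x$t_first_gt1)))
  invisible(x)
}

#' @export
plot.synergy_ds <- function(x, ...) {
  graphics::plot(x$ds$time_h, x$ds$DS, type = "b", xlab = "time (h)",
                 ylab = "degree of synergy", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Percent change relative to a reference
#'
#' @param treated Treated quantity.
#' @param reference Reference quantity (> 0).
#' @return `(treated - reference) / reference * 100`.
#' @export
percent_change <- function(treated, reference) {
  if (any(reference <= 0)) stop("reference must be positive", call. = FALSE)
  (treated - reference) / reference * 100
}

#' Full kinetics summary row
#'
#' Combines a Michaelis-Menten fit with the turnover/catalytic-efficiency
#' derivation. The molecular mass can be supplied (the usual case: the mature
#' protein's theoretical mass) or computed from a sequence with
#' [protein_mw_kda()].
#'
#' @param fit An `mm_fit`.
#' @param mw_kda Molecular mass (kDa) of the mature protein; required unless
#'   `seq` is given.
#' @param seq Optional sequence from which to compute the mass when `mw_kda`
#'   is absent.
#' @param specific_activity Optional independently assayed specific activity
#'   (U/mg), recorded alongside.
#' @return Named list: `Km`, `Vmax`, `kcat`, `kcat_over_Km`,
#'   `specific_activity`, `mw_kda`, `method`, `r_squared`.
#' @export
kinetics_summary <- function(fit, mw_kda = NULL, seq = NULL,
                             specific_activity = NA_real_) {
  stopifnot(inherits(fit, "mm_fit"))
  if (is.null(mw_kda)) {
    if (is.null(seq)) stop("supply mw_kda or a sequence", call. = FALSE)
    mw_kda <- protein_mw_kda(seq)
    message("molecular mass computed from sequence: ", signif(mw_kda, 4), " kDa")
  }
  kcat <- kcat_from_vmax(fit$Vmax, mw_kda)
  list(Km = fit$Km, Vmax = fit$Vmax, kcat = kcat,
       kcat_over_Km = catalytic_efficiency(kcat, fit$Km),
       specific_activity = specific_activity, mw_kda = mw_kda,
       method = fit$method, r_squared = fit$r_squared)
}

#' Check internal arithmetic of a published kinetics table
#'
#' Recomputes `kcat/Km` from the printed `kcat` and `Km` of each row and
#' flags rows whose printed efficiency deviates from the recomputed value by
#' more than `tol_rel`. Useful for auditing literature tables before using
#' them as references; discrepant rows are reported, never silently
#' "corrected".
#'
#' @param table data.frame with columns `enzyme`, `km_mg_ml`, `kcat_s`,
#'   `kcat_over_km_ml_s_mg` (such as [xyle_reference_tables()]`$kinetics`).
#' @param tol_rel Relative tolerance (default 0.02, i.e. printed rounding).
#' @return data.frame with `enzyme`, `printed`, `recomputed`, `consistent`.
#' @export
kinetics_consistency <- function(table, tol_rel = 0.02) {
  recomputed <- catalytic_efficiency(table$kcat_s, table$km_mg_ml)
  data.frame(enzyme = table$enzyme,
             printed = table$kcat_over_km_ml_s_mg,
             recomputed = recomputed,
             consistent = abs(recomputed - table$kcat_over_km_ml_s_mg) <=
               tol_rel * table$kcat_over_km_ml_s_mg)
}

#' Bundled reference characterization tables for the XylE / XYL10C family
#'
#' Published measurements for the GH10 xylanase XylE, its thermophilic
#' homolog XYL10C, and the fragment-replacement hybrids between them, bundled
#' as plain-text data for use as inputs (fold-change analyses, consistency
#' audits, reference points for the fitting examples). `kinetics` carries Km
#' (mg/mL), Vmax (umol/min/mg), kcat (/s), kcat/Km (mL/s/mg) and specific
#' activity (U/mg); rows with no detectable activity are `NA`. `thermal`
#' carries the inactivation midpoint T50 (degrees C, where reported), the
#' calorimetric melting temperature Tm (degrees C; an external DSC
#' measurement stored as data, never computed here, and approximate for the
#' hybrids), and the 65 C half-life (h, wild type only). `synergy_15h`
#' carries the 15-hour reducing-sugar yields (umol/mL) of the mulberry-bark
#' hydrolysis arms.
#'
#' @return List of data.frames: `kinetics`, `thermal`, `synergy_15h`.
#' @export
xyle_reference_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "fragswap",
                                  mustWork = TRUE)
  list(kinetics = utils::read.csv(path("xyle_hybrid_kinetics.csv"),
                                  check.names = FALSE),
       thermal = utils::read.csv(path("xyle_hybrid_thermal.csv"),
                                 check.names = FALSE),
       synergy_15h = utils::read.csv(path("mulberry_hydrolysis_15h.csv"),
                                     check.names = FALSE))
}
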