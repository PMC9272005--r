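# Quantification layer for the methylglyoxal (DNPH, 432 nm) and glutathione
# (DTNB/glutathione-reductase recycling, 412 nm) assays: linear calibration
# with inverse prediction, glutathione pool arithmetic, and the
# MG-activity correlation statistic.

#' Fit a linear calibration curve
#'
#' Unweighted ordinary least squares of response on standard concentration
#' (intercept fitted, not forced through zero), with inverse prediction
#' `conc = (response - intercept) / slope`.
#'
#' @param conc Standard concentrations (uM), >= 3 standards over >= 2
#'   distinct levels.
#' @param response Absorbance responses (non-negative).
#' @return A `glyi_calibration` list: `slope`, `intercept`, `r_squared`,
#'   `range` (of the standards), `predict(conc)` and `invert(response)`
#'   closures. `invert` flags responses mapping outside the standard range.
#' @export
fit_calibration <- function(conc, response) {
  stopifnot(length(conc) == length(response))
  if (length(conc) < 3) stop("need >= 3 standards")
  if (length(unique(conc)) < 2) stop("need >= 2 distinct concentrations")
  if (any(response < 0)) stop("responses must be non-negative")
  fit <- stats::lm(response ~ conc)
  slope <- stats::coef(fit)[[2]]; intercept <- stats::coef(fit)[[1]]
  if (abs(slope) < 1e-12) stop("non-identifiable calibration: zero slope")
  rng <- range(conc)
  structure(list(
    slope = slope, intercept = intercept,
    # suppressed: summary.lm warns on exact (zero-residual) standards
    r_squared = suppressWarnings(summary(fit)$r.squared), range = rng,
    fit = fit,
    predict = function(at) intercept + slope * at,
    invert = function(resp) {
      est <- (resp - intercept) / slope
      outside <- est < rng[1] | est > rng[2]
      if (any(outside)) {
        warning("prediction outside the standard range [",
                rng[1], ", ", rng[2], "] uM (extrapolation)")
      }
      est
    }
  ), class = "glyi_calibration")
}

#' Quantify methylglyoxal in a tissue extract
#'
#' Converts an extract absorbance to tissue content through the calibration
#' curve and the unit chain: concentration (uM) x dilution factor x extract
#' volume (mL) gives nmol in the extract; dividing by tissue fresh weight (g)
#' and scaling to umol yields umol g^-1 FW.
#'
#' @param response Extract absorbance (432 nm).
#' @param curve A `glyi_calibration`.
#' @param dilution Dilution factor applied to the extract before the assay.
#' @param mass_g Tissue fresh weight extracted (g).
#' @param volume_ml Extract volume (mL).
#' @return Content in umol g^-1 FW (negative predictions clipped to 0 with a
#'   warning).
#' @export
quantify_mg <- function(response, curve, dilution = 1, mass_g, volume_ml) {
  stopifnot(inherits(curve, "glyi_calibration"), mass_g > 0, volume_ml > 0,
            dilution > 0)
  conc_um <- curve$invert(response)          # uM in the diluted reaction
  conc_um <- conc_um * dilution              # uM in the extract
  if (any(conc_um < 0)) {
    warning("negative predicted concentration clipped to 0")
    conc_um <- pmax(conc_um, 0)
  }
  conc_um * volume_ml / mass_g / 1000        # umol / g FW
}

#' Glutathione pool bookkeeping
#'
#' Reduced glutathione is the difference between the total pool and the
#' oxidized fraction: `GSH = total - GSSG`; the redox ratio is `GSH/GSSG`.
#'
#' @param total_measured Total glutathione (GSH + GSSG), umol g^-1 FW.
#' @param gssg_measured Oxidized glutathione, umol g^-1 FW.
#' @return A `glyi_glutathione_pool` list: `total`, `gssg`, `gsh`, `ratio`
#'   (`NA` with `ratio_defined = FALSE` when GSSG is zero).
#' @export
glutathione_pool <- function(total_measured, gssg_measured) {
  if (gssg_measured < 0 || total_measured < 0) {
    stop("glutathione amounts must be non-negative")
  }
  if (gssg_measured > total_measured) {
    stop("inconsistent inputs: GSSG (", gssg_measured,
         ") exceeds total glutathione (", total_measured, ")")
  }
  gsh <- total_measured - gssg_measured
  structure(list(
    total = total_measured, gssg = gssg_measured, gsh = gsh,
    ratio = if (gssg_measured > 0) gsh / gssg_measured else NA_real_,
    ratio_defined = gssg_measured > 0
  ), class = "glyi_glutathione_pool")
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation; the p-value comes from the t transform with
#' n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List: `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
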