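# GLYI rate models and estimation. Rates are specific activities in
# umol min^-1 mg^-1 protein (enzyme units per mg); substrate S is the
# hemithioacetal (mM); inhibitor I is free GSH (mM).

#' Specific activity from an absorbance slope (Beer-Lambert)
#'
#' Converts a spectrophotometric slope to specific activity:
#' `|slope| / (epsilon * path) * volume / protein`. The default molar
#' absorption coefficient 2.86 mM^-1 cm^-1 is the 240 nm coefficient of the
#' HA -> S-D-lactoylglutathione conversion; the magnitude of the slope is
#' used, the direction of absorbance change being a documented property of
#' each assay (increase at 240 nm for GLYI, increase at 412 nm for the
#' TNB-based glutathione assay with epsilon 13.6 mM^-1 cm^-1).
#'
#' @param slope Absorbance change per minute (A min^-1).
#' @param epsilon Molar absorption coefficient (mM^-1 cm^-1).
#' @param path Optical path (cm).
#' @param volume Assay volume (mL).
#' @param protein Protein in the assay (mg), positive.
#' @return Specific activity (umol min^-1 mg^-1).
#' @examples
#' rate_from_absorbance(0.0286, protein = 0.025)  # 0.16 E.U./mg
#' @export
rate_from_absorbance <- function(slope, epsilon = 2.86, path = 1,
                                 volume = 0.4, protein) {
  if (protein <= 0) stop("protein amount must be positive")
  if (epsilon <= 0) stop("epsilon must be positive")
  abs(slope) / (epsilon * path) * volume / protein
}

#' Michaelis-Menten rate
#'
#' `v = vmax * S / (km + S)`.
#'
#' @param params List/vector with `vmax` (umol min^-1 mg^-1) and `km` (mM).
#' @param S Substrate concentration (mM), non-negative.
#' @return Rate (umol min^-1 mg^-1).
#' @export
mm_rate <- function(params, S) {
  stopifnot(all(S >= 0))
  params$vmax * S / (params$km + S)
}

#' Competitive-inhibition rate
#'
#' `v = vmax * S / (km * (1 + I/ki) + S)`: the inhibitor raises the apparent
#' Km without touching Vmax.
#'
#' @param params List with `vmax`, `km` and `ki` (mM).
#' @param S Substrate (mM), non-negative.
#' @param I Inhibitor (mM), non-negative.
#' @return Rate (umol min^-1 mg^-1).
#' @export
competitive_rate <- function(params, S, I) {
  stopifnot(all(S >= 0), all(I >= 0))
  if (is.null(params$ki)) stop("ki absent from params")
  params$vmax * S / (params$km * (1 + I / params$ki) + S)
}

#' Assemble a kinetics dataset
#'
#' @param S Substrate concentrations (mM).
#' @param v Rates (umol min^-1 mg^-1).
#' @param I Inhibitor concentrations (mM), default 0.
#' @param replicate Optional replicate index.
#' @return A `glyi_kinetics` data frame with columns `S`, `I`, `v`,
#'   `replicate`.
#' @export
kinetics_dataset <- function(S, v, I = 0, replicate = 1L) {
  d <- data.frame(S = S, I = I, v = v, replicate = replicate)
  stopifnot(all(d$S >= 0), all(d$I >= 0), all(d$v >= 0))
  class(d) <- c("glyi_kinetics", "data.frame")
  d
}

#' Fit the Michaelis-Menten model by nonlinear least squares
#'
#' Untransformed nonlinear least squares (Levenberg-Marquardt) on
#' `v = vmax*S/(km+S)`, with starting values from a Hanes linearization
#' (`S/v` against `S`). Linearizations are diagnostics only; the NLS fit is
#' the primary estimator.
#'
#' @param data A `glyi_kinetics` data frame (inhibitor column ignored;
#'   supply inhibited series to [dixon_ki()] or [fit_competitive()]).
#' @return List of class `glyi_kinetic_fit`: `vmax`, `km`, standard errors
#'   (`vmax_se`, `km_se`), `rss`, `converged`, and the underlying `fit`.
#' @export
fit_mm <- function(data) {
  d <- data[data$v > 0 & data$S > 0, , drop = FALSE]
  if (length(unique(d$S)) < 2) stop("need >= 2 distinct substrate levels")
  if (length(unique(d$S)) < 3) {
    warning("fewer than 3 distinct substrate levels; fit may be ill-posed")
  }
  hanes <- stats::lm(I(S / v) ~ S, data = d)
  start <- list(vmax = max(1 / stats::coef(hanes)[2], 1e-6),
                km = max(stats::coef(hanes)[1] / stats::coef(hanes)[2], 1e-6))
  fit <- minpack.lm::nlsLM(v ~ vmax * S / (km + S), data = d, start = start,
                           lower = c(1e-12, 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  span_warn <- min(d$S) > est[["km"]] || max(d$S) < est[["km"]]
  if (span_warn) warning("design does not bracket the fitted Km")
  structure(list(vmax = est[["vmax"]], km = est[["km"]],
                 vmax_se = se[["vmax"]], km_se = se[["km"]],
                 rss = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv, fit = fit),
            class = "glyi_kinetic_fit")
}

#' Global competitive-inhibition fit
#'
#' Nonlinear least squares on `v = vmax*S/(km*(1+I/ki)+S)` over all
#' (S, I, v) observations jointly.
#'
#' @param data A `glyi_kinetics` data frame with >= 2 distinct inhibitor
#'   levels.
#' @return List of class `glyi_kinetic_fit` with `vmax`, `km`, `ki`, their
#'   standard errors, `rss` and `converged`.
#' @export
fit_competitive <- function(data) {
  d <- data[data$v > 0 & data$S > 0, , drop = FALSE]
  if (length(unique(d$I)) < 2) stop("need >= 2 distinct inhibitor levels")
  base <- suppressWarnings(
    fit_mm(kinetics_dataset(d$S[d$I == min(d$I)], d$v[d$I == min(d$I)]))
  )
  start <- list(vmax = base$vmax, km = base$km, ki = max(stats::median(d$I), 0.1))
  fit <- minpack.lm::nlsLM(v ~ vmax * S / (km * (1 + I / ki) + S), data = d,
                           start = start, lower = rep(1e-12, 3),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(vmax = est[["vmax"]], km = est[["km"]], ki = est[["ki"]],
                 vmax_se = se[["vmax"]], km_se = se[["km"]], ki_se = se[["ki"]],
                 rss = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv, fit = fit),
            class = "glyi_kinetic_fit")
}

LINEARIZATION_KINDS <- c("lineweaver_burk", "eadie_hofstee", "hanes",
                         "eadie_scatchard")

#' Linearization diagnostics for Michaelis-Menten data
#'
#' Transforms (S, v) points to one of the classical linear forms and fits an
#' ordinary least-squares line. Parameter interpretation:
#' \describe{
#'   \item{lineweaver_burk}{`1/v` vs `1/S`; intercept `1/vmax`, slope `km/vmax`.}
#'   \item{eadie_hofstee}{`v` vs `v/S`; intercept `vmax`, slope `-km`.}
#'   \item{hanes}{`S/v` vs `S`; slope `1/vmax`, intercept `km/vmax`.}
#'   \item{eadie_scatchard}{`v/S` vs `v`; slope `-1/km`, intercept `vmax/km`.}
#' }
#'
#' @param data A `glyi_kinetics` data frame.
#' @param kind One of `"lineweaver_burk"`, `"eadie_hofstee"`, `"hanes"`,
#'   `"eadie_scatchard"`.
#' @return List: `kind`, `points` (transformed x, y), `slope`, `intercept`,
#'   `vmax`, `km` (back-computed), `excluded` (points dropped for zero
#'   rate/substrate, with a warning).
#' @export
linearize <- function(data, kind = LINEARIZATION_KINDS) {
  kind <- match.arg(kind)
  usable <- data$v > 0 & data$S > 0
  if (any(!usable)) {
    warning(sum(!usable), " point(s) with zero rate or substrate excluded")
  }
  d <- data[usable, , drop = FALSE]
  xy <- switch(kind,
    lineweaver_burk = list(x = 1 / d$S, y = 1 / d$v),
    eadie_hofstee = list(x = d$v / d$S, y = d$v),
    hanes = list(x = d$S, y = d$S / d$v),
    eadie_scatchard = list(x = d$v, y = d$v / d$S)
  )
  line <- stats::lm(y ~ x, data = xy)
  b <- stats::coef(line)[[1]]; m <- stats::coef(line)[[2]]
  params <- switch(kind,
    lineweaver_burk = list(vmax = 1 / b, km = m / b),
    eadie_hofstee = list(vmax = b, km = -m),
    hanes = list(vmax = 1 / m, km = b / m),
    eadie_scatchard = list(vmax = -b / m, km = -1 / m)
  )
  list(kind = kind, points = as.data.frame(xy), slope = m, intercept = b,
       vmax = params$vmax, km = params$km, excluded = sum(!usable))
}

#' Dixon analysis: competitive Ki from per-substrate inhibition lines
#'
#' Fits `1/v` against inhibitor concentration separately for each substrate
#' level; for competitive inhibition the lines share a common intersection at
#' `I = -Ki`. The consensus intersection is the least-squares common point of
#' all lines (for exact competitive data this recovers Ki exactly); a global
#' fit of the competitive model is reported alongside for comparison.
#'
#' @param data A `glyi_kinetics` data frame: >= 2 substrate series, each with
#'   >= 2 inhibitor levels, all rates positive.
#' @return List of class `glyi_dixon`: `ki` (mM, consensus intersection),
#'   `ki_global` (from [fit_competitive()]), `lines` (per-S slope/intercept),
#'   `global_fit`.
#' @export
dixon_ki <- function(data) {
  d <- data[data$v > 0, , drop = FALSE]
  if (length(unique(d$I)) < 2) stop("degenerate design: need >= 2 inhibitor levels")
  s_levels <- sort(unique(d$S))
  if (length(s_levels) < 2) stop("need >= 2 substrate series")
  lines <- do.call(rbind, lapply(s_levels, function(s) {
    ds <- d[d$S == s, , drop = FALSE]
    if (length(unique(ds$I)) < 2) {
      stop("substrate series S = ", s, " has < 2 inhibitor levels")
    }
    fit <- stats::lm(I(1 / v) ~ I, data = ds)
    data.frame(S = s, intercept = stats::coef(fit)[[1]],
               slope = stats::coef(fit)[[2]])
  }))
  if (max(lines$slope) - min(lines$slope) < 1e-12 * max(abs(lines$slope), 1)) {
    stop("no finite intersection: Dixon lines are parallel ",
         "(non-competitive pattern)")
  }
  # Common point (x, y) minimizing sum_i (y - m_i x - b_i)^2:
  # regressing b_i on m_i gives slope -x, i.e. the fitted slope equals Ki.
  consensus <- stats::lm(intercept ~ slope, data = lines)
  ki <- stats::coef(consensus)[[2]]
  if (ki <= 0) warning("consensus intersection at non-negative I; ",
                       "inhibition may not be competitive")
  global_fit <- tryCatch(fit_competitive(kinetics_dataset(d$S, d$v, d$I)),
                         error = function(e) NULL)
  structure(list(ki = ki,
                 ki_global = if (is.null(global_fit)) NA_real_ else global_fit$ki,
                 lines = lines, global_fit = global_fit),
            class = "glyi_dixon")
}

#' Metal-activation dose-response line
#'
#' Ordinary least-squares line of percent activation against metal dose over
#' the assayed range; the intercept is reported as fitted (not forced through
#' the origin).
#'
#' @param dose Metal concentrations (mM), >= 2 values.
#' @param activation Percent activation relative to the no-metal control.
#' @return List: `slope` (percent per mM), `intercept`, `fit`, and
#'   `predict(dose)` closure for doses within the assayed range (values
#'   outside the range are flagged with a warning).
#' @export
metal_activation <- function(dose, activation) {
  if (length(dose) < 2 || length(unique(dose)) < 2) {
    stop("need >= 2 distinct doses")
  }
  stopifnot(length(dose) == length(activation))
  fit <- stats::lm(activation ~ dose)
  rng <- range(dose)
  list(
    slope = stats::coef(fit)[[2]], intercept = stats::coef(fit)[[1]],
    fit = fit,
    predict = function(at) {
      if (any(at < rng[1] | at > rng[2])) {
        warning("dose outside the assayed range [", rng[1], ", ", rng[2], "]")
      }
      stats::coef(fit)[[1]] + stats::coef(fit)[[2]] * at
    }
  )
}
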