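# Hemithioacetal (HA) equilibrium between methylglyoxal (MG) and reduced
# glutathione (GSH):  Kdiss = [GSH_free][MG_free] / [HA].
# All concentrations in mM.

#' Solve the MG/GSH hemithioacetal equilibrium from total concentrations
#'
#' Given total MG and total GSH, the equilibrium HA concentration is the
#' smaller root of `x^2 - (mg_total + gsh_total + kdiss) x +
#' mg_total*gsh_total = 0`; free species follow by mass balance. The root is
#' computed with the numerically stable quadratic formula (no cancellation
#' when `kdiss` dominates the totals), and the larger root is rejected
#' because it exceeds `min(mg_total, gsh_total)`.
#'
#' @param mg_total,gsh_total Total MG and GSH (mM), non-negative.
#' @param kdiss Dissociation constant (mM), default 3.0.
#' @return A `glyi_equilibrium` list: `mg_total`, `gsh_total`, `kdiss`, `ha`,
#'   `mg_free`, `gsh_free` (all mM).
#' @examples
#' solve_hemithioacetal(12, 0.95)  # the standard assay: HA 0.75 mM
#' @export
solve_hemithioacetal <- function(mg_total, gsh_total, kdiss = 3.0) {
  if (mg_total < 0 || gsh_total < 0) stop("totals must be non-negative")
  if (kdiss <= 0) stop("kdiss must be positive")
  s <- mg_total + gsh_total + kdiss
  p <- mg_total * gsh_total
  disc <- s^2 - 4 * p
  # s >= 2*sqrt(p) + kdiss > 2*sqrt(p), so disc > 0 whenever kdiss > 0
  ha <- 2 * p / (s + sqrt(disc))       # smaller root, stable form
  ha <- min(ha, mg_total, gsh_total)   # guard against rounding overshoot
  state <- list(mg_total = mg_total, gsh_total = gsh_total, kdiss = kdiss,
                ha = ha, mg_free = mg_total - ha, gsh_free = gsh_total - ha)
  stopifnot(ha >= 0, state$mg_free >= 0, state$gsh_free >= 0)
  structure(state, class = "glyi_equilibrium")
}

#' Design assay totals for a target HA at fixed free GSH
#'
#' Inverse of [solve_hemithioacetal()]: chooses total MG and total GSH so
#' that the equilibrium gives the requested HA concentration while free GSH
#' stays at the requested level (the assay convention of holding free GSH
#' constant, e.g. at 0.2 mM, while varying substrate).
#'
#' @param ha_target Target equilibrium HA (mM), non-negative.
#' @param gsh_free_target Free GSH at equilibrium (mM), positive (may be 0
#'   only when `ha_target` is 0).
#' @param kdiss Dissociation constant (mM).
#' @return List with `mg_total` and `gsh_total` (mM).
#' @examples
#' design_assay(0.75, 0.2)  # 12 mM MG, 0.95 mM GSH
#' @export
design_assay <- function(ha_target, gsh_free_target, kdiss = 3.0) {
  if (ha_target < 0) stop("ha_target must be non-negative")
  if (kdiss <= 0) stop("kdiss must be positive")
  if (gsh_free_target <= 0) {
    if (ha_target > 0) stop("infeasible: positive HA requires free GSH > 0")
    return(list(mg_total = 0, gsh_total = max(gsh_free_target, 0)))
  }
  mg_free <- kdiss * ha_target / gsh_free_target
  list(mg_total = mg_free + ha_target, gsh_total = gsh_free_target + ha_target)
}
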