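## Regional oxygen demand from the fiber stress-strain area (SSA) and the
## metabolic regulation law for coronary flow.

shoelace <- function(x, y) {
  n <- length(x)
  0.5 * sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)
}

#' External work of a stress-strain loop
#'
#' Signed polygon (shoelace) area of one beat's (strain, stress)
#' trajectory; counterclockwise loops (normal contraction) are positive.
#' Since stress is in kPa and strain dimensionless, the area is an energy
#' density in kJ/m^3. Early-activated segments under dyssynchrony can show
#' clockwise sub-loops, i.e. negative external work.
#'
#' @param eps Strain samples over one beat (closed loop; the polygon is
#'   closed implicitly).
#' @param sigma Stress samples (kPa).
#' @return External work density (kJ/m^3).
#' @export
externalWork <- function(eps, sigma) {
  if (length(eps) < 3 || length(sigma) != length(eps))
    stop("a stress-strain loop needs at least 3 paired samples")
  ## signed loop area in the (eps, sigma) plane, counterclockwise
  ## positive; equals the net work density -closed-integral(sigma d eps)
  shoelace(eps, sigma)
}

## ES sample: maximal stress-to-strain ratio above the zero-stress strain
## (maximal-elastance analogue); ED sample: the sample at index `i_ed`
## (ventricular activation onset).
esIndex <- function(eps, sigma, eps0) {
  el <- sigma / pmax(eps - eps0, 1e-6)
  which.max(el)
}

#' Potential energy of a stress-strain loop
#'
#' Area enclosed by the end-systolic stress-strain relation (a straight
#' line from the zero-stress point `(eps0, 0)` to the end-systolic sample),
#' the diastolic limb of the loop (end-systole to end-diastole), the
#' end-diastolic stress-strain relation (straight line back to
#' `(eps0, 0)`), and the strain axis. Non-negative by construction.
#'
#' @param eps,sigma Loop samples as in [externalWork()].
#' @param eps0 Strain at zero transmural pressure (zero-stress anchor).
#' @param i_es,i_ed Indices of the end-systolic and end-diastolic samples;
#'   by default end-systole maximizes `sigma/(eps - eps0)` and end-diastole
#'   is the first sample.
#' @return Potential energy density (kJ/m^3), `>= 0`.
#' @export
potentialEnergy <- function(eps, sigma, eps0, i_es = NULL, i_ed = 1L) {
  if (length(eps) < 3) stop("a stress-strain loop needs at least 3 paired samples")
  if (is.null(i_es)) i_es <- esIndex(eps, sigma, eps0)
  ## diastolic limb: samples from ES forward (cyclically) to ED
  n <- length(eps)
  idx <- if (i_es <= i_ed) seq(i_es, i_ed) else c(seq(i_es, n), seq_len(i_ed))
  px <- c(eps0, eps[idx], eps0)
  py <- c(0, sigma[idx], 0)
  pe <- abs(shoelace(px, py))
  if (pe < 1e-12) {
    warning("degenerate potential-energy polygon; PE set to 0")
    pe <- 0
  }
  pe
}

#' Stress-strain area decomposition of a beat
#'
#' Convenience wrapper returning external work, potential energy and their
#' sum (the stress-strain area, SSA) for one segment's loop.
#'
#' @inheritParams potentialEnergy
#' @param Vw Segment wall volume (mL), for the absolute SSA in Joule.
#' @return A list with `EW`, `PE`, `SSA` (kJ/m^3) and `SSA_abs` (J).
#' @export
ssaDecompose <- function(eps, sigma, eps0, Vw = NA, i_es = NULL, i_ed = 1L) {
  ew <- externalWork(eps, sigma)
  pe <- potentialEnergy(eps, sigma, eps0, i_es = i_es, i_ed = i_ed)
  ssa <- ew + pe
  list(EW = ew, PE = pe, SSA = ssa, SSA_abs = ssa * Vw * 1e-6 * 1e3)
}

#' Regional oxygen demand from stress-strain area
#'
#' Linear relation between the per-beat stress-strain area density and
#' oxygen consumption rate: `VO2 = c1 * SSA / t_cycle + c2`, with
#' `c1 = 4.94 mmol/kJ` and `c2 = 24.2 mmol m^-3 s^-1` (paced canine
#' calibration). `SSA` in kJ/m^3 gives demand per tissue volume.
#'
#' @param SSA_density Stress-strain area density (kJ/m^3).
#' @param t_cycle Cardiac cycle duration (s).
#' @param c1,c2 Calibration constants.
#' @return Oxygen demand density (mmol m^-3 s^-1).
#' @export
oxygenDemand <- function(SSA_density, t_cycle, c1 = 4.94, c2 = 24.2) {
  if (any(t_cycle <= 0)) stop("t_cycle must be positive")
  c1 * SSA_density / t_cycle + c2
}

#' Incremental update of the target coronary flow
#'
#' The target flow of a regulated compartment follows its oxygen demand
#' multiplicatively: `q0_new = q0_old * VO2 / VO2_old`.
#'
#' @param q0_old Previous target flow (mL/s).
#' @param VO2,VO2_old Current and previous oxygen demand.
#' @return Updated target flow.
#' @export
updateTargetFlow <- function(q0_old, VO2, VO2_old) {
  if (any(VO2_old == 0)) stop("VO2_old must be nonzero")
  q0_old * VO2 / VO2_old
}

#' Vasodilator signal update
#'
#' Between beats the vasodilation factor of each regulated compartment is
#' updated from the ratio of measured beat-averaged flow to target flow:
#' `fDil_new = clamp(fDil_old * exp(alpha * (1 - q_bar/q0)), fDilMin,
#' fDilMax)`. `alpha < 1` damps the iteration; flow below target dilates,
#' above target constricts.
#'
#' @param fDil_old Current vasodilation factor.
#' @param q_bar Beat-averaged flow (mL/s).
#' @param q0 Target flow (mL/s).
#' @param alpha Damping factor in (0, 1).
#' @param fDilMin,fDilMax Clamp bounds.
#' @return Updated vasodilation factor.
#' @export
updateVasodilation <- function(fDil_old, q_bar, q0, alpha = 0.2,
                               fDilMin = 0.5, fDilMax = 3.0) {
  if (any(q0 <= 0)) stop("q0 must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  pmin(pmax(fDil_old * exp(alpha * (1 - q_bar / q0)), fDilMin), fDilMax)
}

#' Myocardial flow reserve
#'
#' Element-wise ratio of hyperemic to resting mean segmental flow.
#'
#' @param resting,hyperemic Per-segment mean flows (mL/s), matched order.
#' @return Per-segment MFR.
#' @export
mfr <- function(resting, hyperemic) {
  if (length(resting) != length(hyperemic)) stop("segment sets must match")
  if (any(resting <= 0)) stop("zero or negative resting flow")
  hyperemic / resting
}

#' Calibrate per-segment target flows to the reference demand
#'
#' Distributes the total reference coronary flow (a fixed fraction of
#' cardiac output, 4% by default) across segments proportionally to their
#' absolute oxygen demand.
#'
#' @param VO2_abs Per-segment absolute oxygen demand (mmol/s or any
#'   proportional measure).
#' @param CO Cardiac output (mL/s).
#' @param frac Total coronary flow as a fraction of CO.
#' @return Per-segment target flows q0 (mL/s) summing to `frac * CO`.
#' @export
normalizeReferenceDemand <- function(VO2_abs, CO, frac = 0.04) {
  if (any(VO2_abs < 0)) stop("demand must be non-negative")
  frac * CO * VO2_abs / sum(VO2_abs)
}

#' Demand per tissue weight
#'
#' @param VO2_abs Absolute oxygen demand of a segment (mmol/s).
#' @param mass Segment mass (g).
#' @return Demand per tissue weight (mmol/s/g).
#' @export
demandPerWeight <- function(VO2_abs, mass) {
  if (any(mass <= 0)) stop("zero mass")
  VO2_abs / mass
}
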