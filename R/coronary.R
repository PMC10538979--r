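## Coronary compartment constitutive laws and network assembly checks.

#' Intramyocardial pressure from cavity pressures and fiber stress
#'
#' Extravascular pressure on intramural vessels is the sum of two
#' mechanisms: linear transmission of cavity pressure through the wall
#' (cavity-induced extracellular pressure, CEP) and a myocardial-stiffness
#' component proportional to local fiber stress (varying elastance, VE):
#' `IMP = (r*P1 + (1-r)*P2) + gamma*sigma_f`, with `r` the radial layer
#' position (5/6 subendo, 3/6 mid, 1/6 subepi). For LV and RV free walls
#' `P1` is the cavity pressure and `P2` the pericardial pressure; for the
#' septum `P1` is LV and `P2` RV cavity pressure.
#'
#' @param layer `"subendo"`, `"mid"` or `"subepi"` (or the numeric radial
#'   position `r`).
#' @param P1,P2 Bounding pressures (kPa).
#' @param sigma_f Fiber stress of the owning wall segment (kPa).
#' @param gamma VE scaling factor (default 0.06, identical for all walls).
#' @return A list with components `IMP`, `CEP` and `VE` (kPa).
#' @export
intramyocardialPressure <- function(layer, P1, P2, sigma_f, gamma = 0.06) {
  if (is.character(layer)) {
    r_map <- c(subendo = 5 / 6, mid = 3 / 6, subepi = 1 / 6)
    if (!layer %in% names(r_map)) stop("unknown layer: ", layer)
    r <- r_map[[layer]]
  } else r <- layer
  CEP <- r * P1 + (1 - r) * P2
  VE <- gamma * sigma_f
  list(IMP = CEP + VE, CEP = CEP, VE = VE)
}

#' Transmural pressure of an intramyocardial compartment (collapsible tube law)
#'
#' Nonlinear pressure-area relation with vasodilation: the vasodilation
#' factor `fDil` shifts the relation to the right (a larger area at the
#' same transmural pressure, as in smooth-muscle relaxation). The second
#' bracket term handles negative transmural pressures (vessel collapse).
#'
#' `p_trans = p0 * ( ((A + 0.5*Aw)/(fDil*A0 + 0.5*Aw))^(k/3) - 1
#'                  - max(0, (A/(fDil*A0))^0.7 * (Aw/(fDil*A0))^(-0.4) - 1)^2 )`
#'
#' @param A Current lumen cross-sectional area (cm^2), or equivalently a
#'   volume for a fixed-length compartment (the law is scale-invariant in
#'   the A units as long as `A0` and `Aw` use the same units).
#' @param A0 Reference lumen area at `p_trans = 0` (with `Aw = A0`,
#'   `fDil = 1`).
#' @param Aw Vessel wall area.
#' @param k Stiffness exponent.
#' @param p0 Reference pressure (kPa).
#' @param fDil Vasodilation factor.
#' @return Transmural pressure (kPa).
#' @export
transmuralPressure <- function(A, A0, Aw, k, p0, fDil = 1) {
  if (any(A <= 0) || any(A0 <= 0) || any(Aw <= 0))
    stop("areas must be positive")
  term1 <- ((A + 0.5 * Aw) / (fDil * A0 + 0.5 * Aw))^(k / 3)
  coll <- pmax(0, (A / (fDil * A0))^0.7 * (Aw / (fDil * A0))^(-0.4) - 1)^2
  p0 * (term1 - 1 - coll)
}

#' Check monotonicity of the tube law over an operating range
#'
#' The collapse term of the tube law as formulated does not vanish at the
#' reference area for general wall areas, and can in principle make the
#' pressure-area relation non-monotone. This startup check samples the
#' relation over a relative area range and warns on violation.
#'
#' @param A0,Aw,k,p0,fDil Tube-law parameters.
#' @param range Relative area range to check, as multiples of `A0`.
#' @return `TRUE` (invisibly) if monotone; otherwise warns and returns
#'   `FALSE`.
#' @export
checkTubeLawMonotone <- function(A0, Aw, k, p0, fDil = 1, range = c(0.3, 3)) {
  A <- seq(range[1] * A0, range[2] * A0, length.out = 200)
  p <- transmuralPressure(A, A0, Aw, k, p0, fDil)
  ok <- all(diff(p) > 0)
  if (!ok) warning("tube law is non-monotone over the operating range")
  invisible(ok)
}

#' Flow through a coronary compartment (volume-dependent Poiseuille law)
#'
#' The hydraulic resistance of a fixed-length compartment follows
#' Poiseuille's law referenced to its volume: `q = (q0_ref/dp0) *
#' (V/V0)^2 * dp`. At the reference state (`V = V0`, `dp = dp0`) the flow
#' equals the reference flow `q0_ref`. Vasodilation acts on flow through
#' the tube law: a dilated compartment holds a larger volume at the same
#' pressure and its resistance falls with the inverse square of volume.
#'
#' @param dp Pressure difference between proximal and distal node (kPa).
#' @param V Current compartment volume (mL).
#' @param V0 Reference compartment volume (mL).
#' @param q0_ref Reference flow (mL/s).
#' @param dp0 Reference pressure drop (kPa).
#' @return Flow (mL/s).
#' @export
compartmentFlow <- function(dp, V, V0, q0_ref, dp0) {
  if (any(V0 <= 0) || any(dp0 <= 0)) stop("config error: V0 and dp0 must be positive")
  if (any(V <= 0)) stop("compartment volume must be positive")
  (q0_ref / dp0) * (V / V0)^2 * dp
}

#' Intravascular pressure of an intramyocardial compartment
#'
#' Intravascular pressure is transmural pressure plus the intramyocardial
#' pressure squeezing the vessel: `p = p_trans + IMP`.
#'
#' @param p_trans Transmural pressure (kPa).
#' @param IMP Intramyocardial pressure (kPa).
#' @return Intravascular pressure (kPa).
#' @export
intravascularPressure <- function(p_trans, IMP) p_trans + IMP

#' Assemble and validate the coronary network topology
#'
#' Builds the reduced coronary tree implied by a segment table: one
#' arterial sub-branch per perfused segment hanging off its parent
#' proximal vessel (left main feeding LAD and LCx; RCA, whose
#' inferoseptal/inferior sub-branches form the posterior descending
#' artery), and a mirrored venous path per segment draining through
#' branch veins into the coronary sinus.
#'
#' @param segments Segment table as in `defaultConfig()$segments`.
#' @return A list describing the network: `arteries` (per-segment
#'   sub-branch table with parent vessel), `mains` (sub-branch counts per
#'   main vessel), `n_chains` (number of layer chains).
#' @export
assembleTree <- function(segments) {
  req <- c("id", "wall", "branch", "frac", "lenf")
  if (!all(req %in% names(segments))) stop("topology error: missing segment columns")
  if (anyDuplicated(segments$id)) stop("topology error: duplicate segment ids")
  ok_branch <- segments$branch %in% c("LAD", "LCx", "RCA", "PDA")
  if (!all(ok_branch)) stop("topology error: unknown coronary branch")
  if (any(segments$frac <= 0)) stop("topology error: non-positive segment fraction")
  ## every segment must be supplied by exactly one sub-branch: by
  ## construction one sub-branch per row; orphan = missing branch
  if (any(is.na(segments$branch))) stop("topology error: orphan segment without supply")
  parent <- ifelse(segments$branch %in% c("PDA", "RCA"), "RCA", segments$branch)
  arteries <- data.frame(segment = segments$id, subbranch = paste0(segments$branch, ".", segments$id),
                         parent = parent, lenf = segments$lenf, stringsAsFactors = FALSE)
  mains <- table(parent)
  list(arteries = arteries,
       mains = c(LAD = sum(parent == "LAD"), LCx = sum(parent == "LCx"),
                 RCA = sum(parent == "RCA")),
       n_chains = nrow(segments) * 3L)
}
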