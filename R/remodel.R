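## Demand-driven remodeling of LV wall mass under chronic asynchronous
## activation: segment masses adapt toward a homogeneous distribution of
## oxygen demand per tissue weight, capped at +/-25%, with the hyperemic
## dilation capacity scaling linearly with mass.

#' One wall-mass adaptation step
#'
#' Multiplicative update of each LV/septal segment's mass factor toward
#' the LV-wide mean demand per tissue weight:
#' `m_new = clamp(m_old * (d/d_mean)^beta, 1-cap, 1+cap)`.
#'
#' @param m Current mass factors (per segment).
#' @param d Demand per tissue weight (per segment).
#' @param beta Damping exponent.
#' @param cap Maximal relative mass change (0.25).
#' @return Updated mass factors.
#' @export
adaptWallMass <- function(m, d, beta = 0.5, cap = 0.25) {
  dbar <- mean(d)
  pmin(pmax(m * (d / dbar)^beta, 1 - cap), 1 + cap)
}

#' Chronic LBBB: iterate mass adaptation to convergence
#'
#' Alternates wall-mass adaptation with re-convergence of resting
#' regulation, starting from a converged acute-LBBB state, until the
#' largest relative mass change per iteration falls below `tol` or all
#' still-changing segments sit at the 25% cap. The RV free wall does not
#' remodel. Returns the chronic resting and hyperemic runs plus the
#' adaptation history.
#'
#' @param model A [CoroModel-class].
#' @param acute An acute-LBBB [CoroRun-class].
#' @param max_iter Outer iteration budget.
#' @param rest_beats Resting beat budget per iteration.
#' @param quiet Progress output.
#' @return A [CoroRun-class] with protocol `"chronic-lbbb"`; the
#'   adaptation history is attached to `@rest$adaptation`.
#' @export
runChronicLbbb <- function(model, acute, max_iter = NULL, rest_beats = 40,
                           quiet = TRUE) {
  cfg <- model@config$remodeling
  if (is.null(max_iter)) max_iter <- cfg$max_iter
  sp <- segPatchIndex(model)
  lv <- model@segments$wall %in% c("LV", "SEP")
  st <- acute@rest$st
  rest <- acute@rest
  hist <- list()
  for (it in seq_len(max_iter)) {
    dem <- rest$demand
    mass <- 1.055 * model@patches$Vw[sp] * st$m[sp]
    d <- demandPerWeight(dem$VO2_abs, mass)
    m_seg <- st$m[sp]
    m_new_seg <- m_seg
    m_new_seg[lv] <- adaptWallMass(m_seg[lv], d[lv], cfg$beta, cfg$cap)
    dm <- abs(m_new_seg / m_seg - 1)
    st$m[sp] <- m_new_seg
    hist[[it]] <- data.frame(iter = it, segment = model@segments$id,
                             m = m_new_seg, d = d)
    if (!quiet)
      message(sprintf("remodeling iter %d: max dm %.4f, spread(d) %.4f",
                      it, max(dm[lv]), diff(range(d[lv]))))
    at_cap <- m_new_seg[lv] <= 1 - cfg$cap + 1e-9 |
              m_new_seg[lv] >= 1 + cfg$cap - 1e-9
    rest <- runResting(model, st, max_beats = rest_beats, homeo = TRUE,
                       regulate = TRUE, anchor = FALSE, burnin = 1,
                       quiet = quiet)
    st <- rest$st
    if (max(dm[lv]) < cfg$tol || all(at_cap | dm[lv] < cfg$tol)) break
  }
  hyper <- runHyperemia(model, rest)
  run <- makeRun(model, "chronic-lbbb", rest, hyper)
  run@rest$adaptation <- do.call(rbind, hist)
  run
}
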