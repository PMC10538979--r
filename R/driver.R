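## Beat-to-beat orchestration: demand estimation, homeostatic control,
## metabolic flow regulation, steady-state detection, hyperemia.

#' Homeostatic adjustment of peripheral resistance and blood volume
#'
#' Multiplicative beat-to-beat updates with damping `kappa`:
#' `Rsys <- Rsys * (MAP_target/MAP)^kappa` and
#' `Vtot <- Vtot * (CO_target/CO)^kappa`. The fixed point is exactly the
#' target pair; applied once per beat during resting simulations only.
#' Pressure above target relaxes peripheral resistance; cardiac output
#' below target expands circulating volume.
#'
#' @param CO,MAP Measured beat averages (mL/s, kPa).
#' @param CO_target,MAP_target Targets.
#' @param Rsys,Vtot Current values.
#' @param kappa Damping in (0, 1].
#' @return List with updated `Rsys` and `Vtot`.
#' @export
homeostaticControl <- function(CO, MAP, CO_target, MAP_target, Rsys, Vtot,
                               kappa = 0.5) {
  if (CO_target <= 0 || MAP_target <= 0) stop("config error: non-physiological targets")
  if (kappa <= 0 || kappa > 1) stop("config error: kappa must be in (0,1]")
  ## rate-limited multiplicative updates: large errors are corrected over
  ## several beats rather than by yanking the venous reservoir in one
  fR <- min(max((MAP_target / MAP)^(kappa * 0.6), 0.95), 1.05)
  fV <- min(max((CO_target / CO)^(kappa * 0.5), 0.975), 1.025)
  list(Rsys = Rsys * fR, Vtot = Vtot * fV)
}

#' Steady-state detection from beat summaries
#'
#' True when, for at least `min_beats` consecutive beats, the relative
#' beat-to-beat change of every stroke volume and every regulated mean
#' flow stays below `tol` (default 0.1%). Scale-invariant.
#'
#' @param history A list of per-beat numeric vectors
#'   `c(SV_LV, SV_RV, regulated mean flows...)`.
#' @param tol Relative tolerance.
#' @param min_beats Number of consecutive beats required.
#' @return Logical.
#' @export
detectSteadyState <- function(history, tol = 1e-3, min_beats = 3) {
  n <- length(history)
  if (n < min_beats) return(FALSE)
  for (k in (n - min_beats + 2):n) {
    a <- history[[k - 1]]; b <- history[[k]]
    rel <- abs(b - a) / pmax(abs(a), 1e-9)
    if (any(rel >= tol)) return(FALSE)
  }
  TRUE
}

## Per-segment demand from one beat's patch stress/strain series.
beatDemand <- function(model, st, out, par) {
  cfg <- model@config
  seg_patch <- segPatchIndex(model)
  S <- nrow(model@segments)
  eps0 <- log(cfg$sarcomere$Ls0 / cfg$sarcomere$Ls_ref)
  tcycle <- par$tcycle
  dt <- par$dt
  res <- data.frame(segment = model@segments$id, EW = NA_real_, PE = NA_real_,
                    SSA = NA_real_, VO2_den = NA_real_, VO2_abs = NA_real_)
  ## global end-systole: the instant of minimal LV cavity volume, shared
  ## by all segments; a per-segment elastance maximum would misplace
  ## end-systole for early-activated segments under dyssynchrony
  i_es <- which.min(out$hemo[, 10])
  for (s in seq_len(S)) {
    p <- seg_patch[s]
    i_ed <- max(1L, min(nrow(out$eps), round(st$t_act[p] / dt)))
    dec <- ssaDecompose(out$eps[, p], out$sig[, p], eps0,
                        Vw = par$patch_Vw[p], i_es = i_es, i_ed = i_ed)
    res$EW[s] <- dec$EW; res$PE[s] <- dec$PE; res$SSA[s] <- dec$SSA
    res$VO2_den[s] <- oxygenDemand(dec$SSA, tcycle)
    res$VO2_abs[s] <- res$VO2_den[s] * par$patch_Vw[p] * 1e-6
  }
  res
}

## Mean arteriolar flow per segment x layer from a beat summary.
arteriolarFlows <- function(model, out) {
  S <- nrow(model@segments)
  mq <- out$summary$meanQ
  t(vapply(seq_len(S), function(s)
    mq[((s - 1) * 15) + c(2, 7, 12)], numeric(3)))
}

## Mean capillary flow per segment x layer (perfusion measure).
capillaryFlows <- function(model, out) {
  S <- nrow(model@segments)
  mq <- out$summary$meanQ
  t(vapply(seq_len(S), function(s)
    mq[((s - 1) * 15) + c(3, 8, 13)], numeric(3)))
}

#' Run resting beats with homeostasis and metabolic flow regulation
#'
#' Advances the model beat by beat. Each completed beat supplies the
#' regional stress-strain area and hence oxygen demand; target flows
#' follow demand multiplicatively, the vasodilator signal of every
#' arteriolar compartment is updated from the ratio of measured to target
#' flow, and systemic resistance and circulating volume are nudged toward
#' the cardiac-output and pressure targets. Stops when the hemodynamic
#' steady-state criterion, the homeostatic targets (within 1%) and the
#' regulation tolerance (every unsaturated compartment within 0.5% of its
#' target flow) are met simultaneously.
#'
#' @param model A [CoroModel-class].
#' @param st Run state (internal); `NULL` starts a fresh run.
#' @param max_beats Beat budget.
#' @param homeo,regulate Enable homeostatic control / flow regulation.
#' @param anchor If `TRUE`, target flows are (re)anchored to total
#'   reference coronary flow = 4% of target cardiac output, distributed
#'   across segments proportional to absolute demand, once the early
#'   transient has passed.
#' @param burnin Beats to run before regulation starts.
#' @param record Recording level passed to the core.
#' @param quiet Suppress progress output.
#' @return List with the final run state `st`, the last beat's series
#'   `out`, the demand table `demand`, and the per-beat `log`.
#' @export
runResting <- function(model, st = NULL, max_beats = NULL, homeo = TRUE,
                       regulate = TRUE, anchor = FALSE, burnin = 6,
                       record = 1L, quiet = TRUE) {
  cfg <- model@config
  reg <- cfg$regulation
  if (is.null(st)) st <- newRunState(model)
  if (is.null(max_beats)) max_beats <- reg$max_beats
  lw <- cfg$coronary$layer_weights / sum(cfg$coronary$layer_weights)
  hist <- list(); logrows <- list()
  co_hist <- numeric(); map_hist <- numeric()
  demand <- NULL; out <- NULL
  converged <- FALSE
  for (beat in seq_len(max_beats)) {
    rb <- runBeat(model, st, record = record)
    st <- rb$st; out <- rb$out; par <- rb$par
    sm <- out$summary
    demand <- beatDemand(model, st, out, par)
    qart <- arteriolarFlows(model, out)

    reg_active <- regulate && beat > burnin
    ## demand used for regulation: floored at a small positive fraction of
    ## the mean so start-up transients with locally negative stress-strain
    ## area cannot produce negative target flows
    vo2_reg <- pmax(demand$VO2_abs, 0.05 * mean(abs(demand$VO2_abs)))
    near_target <- abs(sm$CO / cfg$hemodynamics$CO_target - 1) < 0.05 &&
      abs(sm$MAP / cfg$hemodynamics$MAP_target - 1) < 0.05
    ## demand -> target flow
    if (reg_active) {
      if (anchor && is.null(st$q0)) {
        if (near_target || !homeo) {
          st$q0 <- normalizeReferenceDemand(vo2_reg,
                                            cfg$hemodynamics$CO_target,
                                            reg$cor_flow_frac)
          st$VO2_old <- vo2_reg
        }
      } else if (!is.null(st$q0)) {
        st$q0 <- updateTargetFlow(st$q0, vo2_reg, st$VO2_old)
        st$VO2_old <- vo2_reg
      }
    }
    ## vasodilator update
    reg_res <- NA_real_
    if (reg_active && !is.null(st$q0)) {
      q0l <- outer(st$q0, lw)
      fmax <- fDilMaxMatrix(model, st)
      fnew <- st$fDil_art * exp(reg$alpha * (1 - qart / q0l))
      fnew <- pmin(pmax(fnew, reg$fDilMin), fmax)
      st$fDil_art <- fnew
      sa_cap <- rep(reg$fDilMax_sa, nrow(model@segments))
      st$fDil_sa <- pmin(sa_cap, apply(st$fDil_art, 1, max))
      at_bound <- (st$fDil_art <= reg$fDilMin + 1e-9) | (st$fDil_art >= fmax - 1e-9)
      resid <- abs(qart / q0l - 1)
      reg_res <- max(resid[!at_bound], 0)
    }
    ## homeostasis: a damped decoupling controller acting every fourth
    ## beat on 3-beat averages. The multiplicative corrections to
    ## peripheral resistance and circulating volume are computed through
    ## the inverse of the measured steady-state log-gain matrix of this
    ## plant (d lnMAP/d lnRsys ~ 0.58, d lnMAP/d lnVtot ~ 6.2,
    ## d lnCO/d lnRsys ~ -0.25, d lnCO/d lnVtot ~ 6.3): circulating
    ## volume has a very high gain on both outputs, so raw proportional
    ## loops limit-cycle
    co_hist <- c(co_hist, sm$CO); map_hist <- c(map_hist, sm$MAP)
    if (homeo && beat > 2 && beat %% 4 == 0) {
      e1 <- log(cfg$hemodynamics$MAP_target / mean(utils::tail(map_hist, 3)))
      e2 <- log(cfg$hemodynamics$CO_target / mean(utils::tail(co_hist, 3)))
      lam <- cfg$hemodynamics$kappa
      du1 <- lam * (1.21 * e1 - 1.19 * e2)             # ln Rsys
      du2 <- lam * (0.048 * e1 + 0.111 * e2)           # ln Vtot
      st$Rsys <- st$Rsys * min(max(exp(du1), 0.85), 1.18)
      fV <- min(max(exp(du2), 0.985), 1.015)
      Vtot_cur <- out$hemo[nrow(out$hemo), 12]
      ix <- stateIndices(par)
      st$y[ix$Vsv] <- st$y[ix$Vsv] + (fV - 1) * Vtot_cur
    }
    hist[[length(hist) + 1]] <- c(sm$SV_LV, sm$SV_RV, as.numeric(qart))
    logrows[[beat]] <- data.frame(
      beat = beat, CO = sm$CO, MAP = sm$MAP, SV_LV = sm$SV_LV,
      SV_RV = sm$SV_RV, peak_pLV = sm$peak_pLV, reg_res = reg_res,
      Vtot_drift = sm$Vtot_drift)
    if (!quiet)
      message(sprintf("beat %d CO %.1f MAP %.1f regres %.4f", beat,
                      sm$CO * 60 / 1000, sm$MAP / MMHG, reg_res))
    ## convergence
    steady <- detectSteadyState(hist, cfg$steady$tol, cfg$steady$min_beats)
    nbf <- min(6, length(co_hist))
    homeo_ok <- !homeo ||
      (abs(mean(utils::tail(co_hist, nbf)) / cfg$hemodynamics$CO_target - 1) < 0.01 &&
       abs(mean(utils::tail(map_hist, nbf)) / cfg$hemodynamics$MAP_target - 1) < 0.01)
    reg_ok <- !reg_active || is.null(st$q0) ||
      (!is.na(reg_res) && reg_res < reg$tol)
    if (steady && homeo_ok && reg_ok && beat > burnin + 4) {
      converged <- TRUE
      break
    }
  }
  list(st = st, out = out, demand = demand, log = do.call(rbind, logrows),
       converged = converged, qart = arteriolarFlows(model, out))
}

#' Hyperemic simulation from a converged resting state
#'
#' Sets every arteriolar vasodilation factor to its maximum (left profile
#' 3.00 subendo to 1.70 subepi, right 2.40/2.30, scaled by the segment's
#' wall-mass factor) and every small-artery factor to its 1.4 cap (also
#' mass-scaled), freezes systemic resistance, circulating volume and the
#' demand feedback, and runs to a periodic steady state.
#'
#' @param model A [CoroModel-class].
#' @param rest A converged resting run from [runResting()].
#' @param max_beats Beat budget.
#' @return As [runResting()].
#' @export
runHyperemia <- function(model, rest, max_beats = 30) {
  if (!isTRUE(rest$converged))
    stop("hyperemia requires a converged resting state")
  st <- rest$st
  st$fDil_art <- fDilMaxMatrix(model, st)
  st$fDil_sa <- rep(model@config$regulation$fDilMax_sa, nrow(model@segments))
  runResting(model, st, max_beats = max_beats, homeo = FALSE,
             regulate = FALSE)
}
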