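## Model object, C++ parameter assembly, state initialization and the
## single-beat runner.

#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib coroflow, .registration = TRUE
NULL

#' Class \code{CoroModel}
#'
#' Container for a validated configuration and the derived tables (segment
#' map, patch partition, coronary topology) of one heart-coronary model.
#' Build with [coroModel()]; run with [runReference()] and friends.
#'
#' @slot config The configuration list (see [defaultConfig()]).
#' @slot segments Segment table with wall, territory and partition columns.
#' @slot patches Patch table (one ventricular wall patch per row).
#' @slot topology Coronary network description from [assembleTree()].
#' @export
setClass("CoroModel", representation(
  config = "list", segments = "data.frame", patches = "data.frame",
  topology = "list"
))

setValidity("CoroModel", function(object) {
  cfg <- object@config
  msgs <- character()
  if (cfg$hemodynamics$HR <= 0) msgs <- c(msgs, "heart rate must be positive")
  if (cfg$hemodynamics$CO_target <= 0 || cfg$hemodynamics$MAP_target <= 0)
    msgs <- c(msgs, "non-physiological hemodynamic targets")
  if (cfg$sarcomere$TR <= 0 || cfg$sarcomere$TD <= 0)
    msgs <- c(msgs, "twitch time constants must be positive")
  a <- cfg$regulation$alpha
  if (a <= 0 || a >= 1) msgs <- c(msgs, "regulation alpha must be in (0,1)")
  if (length(msgs)) msgs else TRUE
})

#' Build a heart-coronary model from a configuration
#'
#' Validates the configuration, partitions each ventricular wall into its
#' segments (midwall reference area and wall volume proportional to the
#' segment volume fraction), assembles the coronary topology, and runs the
#' tube-law monotonicity check for each compartment class.
#'
#' @param config Configuration list, as from [defaultConfig()] or
#'   [fixtureConfig()].
#' @return A [CoroModel-class] object.
#' @export
coroModel <- function(config = defaultConfig()) {
  seg <- config$segments
  topo <- assembleTree(seg)
  ## patches: LV first, then SEP, then RV; add an unperfused RV patch if
  ## the segment table does not carry one (reduced fixtures)
  ord <- order(match(seg$wall, c("LV", "SEP", "RV")))
  pat <- seg[ord, c("id", "wall", "frac"), drop = FALSE]
  if (!any(pat$wall == "RV"))
    pat <- rbind(pat, data.frame(id = NA_integer_, wall = "RV", frac = 1))
  pat$Vw <- config$walls[[1]]$Vw * NA
  for (w in c("LV", "SEP", "RV")) {
    i <- pat$wall == w
    pat$Vw[i] <- config$walls[[w]]$Vw * pat$frac[i]
    pat$Am_ref[i] <- config$walls[[w]]$Am_ref * pat$frac[i]
  }
  pat$m <- 1.0
  pat$t_act <- config$hemodynamics$AV_delay
  rownames(pat) <- NULL
  cls <- config$coronary$micro$classes
  for (i in seq_len(nrow(cls)))
    checkTubeLawMonotone(1, cls$aw[i], cls$k[i], cls$p0[i], fDil = 1,
                         range = c(0.4, 2.5))
  new("CoroModel", config = config, segments = seg, patches = pat,
      topology = topo)
}

setMethod("show", "CoroModel", function(object) {
  cfg <- object@config
  cat("CoroModel:", nrow(object@patches), "wall patches,",
      nrow(object@segments), "perfused segments\n")
  cat("  HR", cfg$hemodynamics$HR, "bpm; CO target",
      round(cfg$hemodynamics$CO_target * 60 / 1000, 2), "L/min; MAP target",
      round(cfg$hemodynamics$MAP_target / MMHG, 1), "mmHg\n")
  invisible(object)
})

## Mutable per-run state carried between beats.
newRunState <- function(model) {
  cfg <- model@config
  S <- nrow(model@segments)
  list(
    y = NULL, yprev = NULL, t = 0,
    Rsys = cfg$systemic$Rsys,
    fDil_art = matrix(1, S, 3),    # arterioles, [segment x layer]
    fDil_sa = rep(1, S),           # small arteries, per segment
    m = rep(1, nrow(model@patches)),  # wall-mass factors, per patch
    q0 = NULL,                     # per-segment target flow (mL/s)
    VO2_old = NULL,                # per-segment demand at last update
    t_act = rep(cfg$hemodynamics$AV_delay, nrow(model@patches)),
    Vperi_ref = NA,
    log = NULL                     # per-beat convergence log
  )
}

## Arteriolar dilation caps per segment and layer (left vs right coronary
## profile), scaled by the segment's wall-mass factor.
fDilMaxMatrix <- function(model, st) {
  ## the caps themselves do not scale with the wall-mass factor: the
  ## intramural bed (reference volumes and flows) already grows linearly
  ## with mass, which carries the mass dependence of hyperemic flow
  cfg <- model@config$regulation
  S <- nrow(model@segments)
  out <- matrix(NA_real_, S, 3)
  for (s in seq_len(S)) {
    left <- model@segments$wall[s] %in% c("LV", "SEP")
    prof <- if (left) cfg$fDilMax_left else cfg$fDilMax_right
    out[s, ] <- prof
  }
  out
}

segPatchIndex <- function(model) {
  match(model@segments$id, model@patches$id)
}

## Assemble the flat parameter list consumed by the C++ core.
buildParams <- function(model, st) {
  cfg <- model@config
  pat <- model@patches
  seg <- model@segments
  S <- nrow(seg); P <- nrow(pat)
  wall_id <- match(pat$wall, c("LV", "SEP", "RV")) - 1L
  Vw <- pat$Vw * st$m
  wall_Vw <- vapply(0:2, function(w) sum(Vw[wall_id == w]), 0)
  wall_Am <- vapply(c("LV", "SEP", "RV"), function(w) cfg$walls[[w]]$Am_ref, 0)
  sarc <- cfg$sarcomere
  at <- cfg$atria
  sys <- cfg$systemic
  cor <- cfg$coronary
  cls <- cor$micro$classes
  seg_patch <- segPatchIndex(model)
  parent <- match(ifelse(seg$branch %in% c("RCA", "PDA"), "RCA", seg$branch),
                  c("LAD", "LCx", "RCA")) - 1L
  lw <- cor$layer_weights / sum(cor$layer_weights)

  ## micro arrays [seg][layer][class]
  n <- S * 15
  mc_V0 <- mc_Vw <- mc_p0 <- mc_k <- mc_dp0 <- mc_q0 <- mc_fDil <- numeric(n)
  Vw_seg <- Vw[seg_patch]
  qref_seg <- cfg$regulation$cor_flow_frac * cfg$hemodynamics$CO_target *
    Vw_seg / sum(Vw_seg)
  idx <- function(s, l, c) (s - 1) * 15 + (l - 1) * 5 + c
  for (s in seq_len(S)) {
    Vmic <- cor$micro$blood_vol_per_mL * Vw_seg[s]
    for (l in 1:3) {
      for (c in 1:5) {
        i <- idx(s, l, c)
        mc_V0[i] <- Vmic * cls$vshare[c] / 3
        mc_Vw[i] <- cls$aw[c] * mc_V0[i]
        mc_p0[i] <- cls$p0[c]
        mc_k[i] <- cls$k[c]
        mc_dp0[i] <- cls$dp0[c] *
          (if (c == 2) cor$micro$art_layer_scale[l] else 1)
        mc_q0[i] <- qref_seg[s] * lw[l]
        mc_fDil[i] <- if (c == 1) st$fDil_sa[s] else if (c == 2) st$fDil_art[s, l] else 1
      }
    }
  }

  list(
    P = P, S = S,
    patch_wall = as.integer(wall_id),
    patch_Vw = Vw, patch_Am_ref = pat$Am_ref, patch_t_act = st$t_act,
    wall_Vw = wall_Vw, wall_Am_ref = wall_Am,
    sarc = c(sarc$sig_act_max, sarc$TR, sarc$TD, sarc$Ls_ref, sarc$Ls0,
             sarc$Lsc0, sarc$Lse_iso, sarc$v_max, sarc$sig_pas0, sarc$k_pas,
             sarc$k_lin, sarc$k_comp),
    atria = c(at$V0, at$V_ref, at$E_pas, at$E_act, at$k_exp, at$sig_exp,
              at$TR, at$TD),
    valve_Aopen = unname(cfg$valves$A_open), valve_Aleak = cfg$valves$A_leak,
    valve_len = cfg$valves$len, valve_rho = cfg$valves$rho,
    valve_psw = cfg$valves$p_switch, valve_tau = cfg$valves$tau,
    systemic = c(st$Rsys, sys$C_sa, sys$V0_sa, sys$C_sv, sys$V0_sv, sys$R_vr,
                 sys$Rpulm, sys$C_pa, sys$V0_pa, sys$C_pv, sys$V0_pv, sys$R_pl),
    pericardium = c(cfg$pericardium$k1, cfg$pericardium$k2,
                    if (is.na(st$Vperi_ref)) 1e9 else st$Vperi_ref,
                    sum(wall_Vw) + 30),
    ves_E = cor$vessels$E, ves_V0 = unname(cor$vessels$V0),
    ves_Rint = cor$vessels$R_int, ves_Rin = cor$vessels$R_in,
    ves_Lin = cor$vessels$L_in, ves_Rjunc = cor$vessels$R_junc,
    seg_parent = as.integer(parent), seg_patch = as.integer(seg_patch - 1L),
    seg_Rsub_art = cor$subbranch$R_art * seg$lenf,
    seg_Rsub_ven = cor$subbranch$R_ven * seg$lenf,
    vein_E = cor$veins$E, vein_V0 = unname(cor$veins$V0),
    vein_Rcs = cor$veins$R_cs, cs_E = cor$veins$E, cs_V0 = cor$veins$V0_cs,
    R_csra = cor$veins$R_csra,
    layer_w = lw, layer_r = unname(cor$imp$r), gamma = cor$imp$gamma,
    mc_V0 = mc_V0, mc_Vw = mc_Vw, mc_p0 = mc_p0, mc_k = mc_k,
    mc_dp0 = mc_dp0, mc_q0 = mc_q0, mc_fDil = mc_fDil,
    ## cycle length commensurate with the step grid so activation stays
    ## phase-locked across beats
    tcycle = round(60 / cfg$hemodynamics$HR / cfg$solver$dt) * cfg$solver$dt,
    dt = cfg$solver$dt,
    newton_tol = cfg$solver$newton_tol, newton_maxit = cfg$solver$newton_maxit,
    jac_refresh = cfg$solver$jac_refresh
  )
}

stateIndices <- function(par) {
  P <- par$P; S <- par$S
  iLsc <- 31L; iMC <- iLsc + P
  ND <- iMC + S * 15L
  list(VLA = 1L, VRA = 2L, VLV = 3L, VRV = 4L, Q = 5:8, Vsa = 9L, Vsv = 10L,
       Vpa = 11L, Vpv = 12L, Qlm = 13L, Qrca = 14L, Vves = 15:22,
       Vvein = 23:25, Vcs = 26L, Sv = 27:30, Lsc = iLsc:(iLsc + P - 1L),
       MC = iMC:(ND - 1L) + 0L, ND = ND - 1L,
       Vs = ND, Ys = ND + 1L, Am = (ND + 2L):(ND + 1L + P),
       N = ND + 1L + P)
}

## Initial state vector (R indexing helpers are 1-based; the C++ core uses
## the same layout 0-based).
initState <- function(model, st) {
  par <- buildParams(model, st)
  ix <- stateIndices(par)
  Vperi_ref <- NA
  y <- numeric(ix$N)
  y[ix$VLA] <- 60; y[ix$VRA] <- 60; y[ix$VLV] <- 120; y[ix$VRV] <- 120
  y[ix$Q] <- 0
  y[ix$Sv] <- 0.05
  sys <- model@config$systemic
  y[ix$Vsa] <- sys$V0_sa + sys$C_sa * 12.3
  y[ix$Vsv] <- sys$V0_sv + sys$C_sv * 0.50
  y[ix$Vpa] <- sys$V0_pa + sys$C_pa * 1.8
  y[ix$Vpv] <- sys$V0_pv + sys$C_pv * 1.0
  cor <- model@config$coronary
  y[ix$Vves] <- rep(unname(cor$vessels$V0) / 2, each = 2) * (1 + 12 / cor$vessels$E)
  y[ix$Vvein] <- unname(cor$veins$V0) * exp(0.5 / cor$veins$E)
  y[ix$Vcs] <- cor$veins$V0_cs * exp(0.5 / cor$veins$E)
  y[ix$Lsc] <- model@config$sarcomere$Ls_ref - model@config$sarcomere$Lse_iso
  y[ix$MC] <- par$mc_V0
  y[ix$Vs] <- 0.25 * y[ix$VLV]
  y[ix$Ys] <- 3.1
  y[ix$Am] <- model@patches$Am_ref * 1.05
  if (is.na(st$Vperi_ref)) {
    Vperi_ref <- sum(y[c(ix$VLA, ix$VRA, ix$VLV, ix$VRV, ix$Vves, ix$Vvein,
                         ix$Vcs)]) + sum(par$wall_Vw) + 30
    st$Vperi_ref <- Vperi_ref
    par <- buildParams(model, st)
  }
  y <- cf_init_geometry(par, y)
  list(y = y, Vperi_ref = st$Vperi_ref)
}

## Advance one beat (or `nsteps` explicit steps) and return the series.
runBeat <- function(model, st, record = 1L, nsteps = NULL) {
  if (is.null(st$y)) {
    ini <- initState(model, st)
    st$y <- ini$y
    st$Vperi_ref <- ini$Vperi_ref
  }
  par <- buildParams(model, st)
  if (is.null(nsteps)) nsteps <- round(par$tcycle / par$dt)
  out <- cf_simulate(par, st$y, st$yprev, as.integer(nsteps), st$t, record)
  st$y <- out$y; st$yprev <- out$yprev; st$t <- out$t_end
  list(st = st, out = out, par = par)
}
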