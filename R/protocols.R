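## Activation schedules and the four experiment protocols: reference
## (synchronous), acute LBBB, chronic LBBB (demand-driven remodeling),
## each with resting regulation convergence followed by hyperemia.

#' Build the LBBB mechanical activation schedule
#'
#' Left-bundle-branch-block-like activation: the RV free wall activates at
#' the fixed atrioventricular delay (139 ms after atrial activation); the
#' earliest septal segments follow 25 ms later; activation then spreads
#' through five anatomical groups (septum first, lateral wall last) with
#' 10 ms between groups, so the total ventricular activation span is
#' 65 ms. For the AHA numbering the groups are: apical septal and mid
#' inferoseptal {14, 9}; mid anteroseptal and basal inferoseptal {8, 3};
#' basal anteroseptal, apical anterior and apex {2, 13, 17}; the
#' anterior/inferior column {1, 4, 7, 10, 15}; the lateral wall
#' {5, 6, 11, 12, 16}.
#'
#' @param segments Segment table (see [defaultConfig()]).
#' @param AV_delay Atrioventricular delay (s).
#' @return Data frame `segment`, `t_act` (s within the cycle).
#' @export
buildLbbbSchedule <- function(segments, AV_delay = 0.139) {
  groups <- list(`0.025` = c(14, 9),
                 `0.035` = c(8, 3),
                 `0.045` = c(2, 13, 17),
                 `0.055` = c(1, 4, 7, 10, 15),
                 `0.065` = c(5, 6, 11, 12, 16))
  t_act <- rep(NA_real_, nrow(segments))
  if (all(segments$id[segments$wall != "RV"] %in% 1:17)) {
    for (g in names(groups)) {
      off <- as.numeric(g)
      t_act[segments$id %in% groups[[g]]] <- AV_delay + off
    }
  } else {
    ## generic reduced maps: septum first, LV free wall spread afterwards
    sep <- which(segments$wall == "SEP")
    lv <- which(segments$wall == "LV")
    t_act[sep] <- AV_delay + 0.025
    if (length(lv))
      t_act[lv] <- AV_delay + 0.025 + 0.040 * seq_along(lv) / length(lv)
  }
  t_act[segments$wall == "RV"] <- AV_delay
  if (any(is.na(t_act))) stop("unmapped segment in activation schedule")
  data.frame(segment = segments$id, t_act = t_act)
}

## apply a schedule to the run state's per-patch activation times
applySchedule <- function(model, st, schedule = NULL) {
  cfg <- model@config
  if (is.null(schedule)) {
    st$t_act <- rep(cfg$hemodynamics$AV_delay, nrow(model@patches))
  } else {
    st$t_act <- rep(cfg$hemodynamics$AV_delay, nrow(model@patches))
    i <- match(schedule$segment, model@patches$id)
    st$t_act[i[!is.na(i)]] <- schedule$t_act[!is.na(i)]
  }
  st
}

#' Per-segment perfusion report
#'
#' Combines a resting and a hyperemic run into the standard per-segment
#' table: activation delay, wall thickness, oxygen demand (per volume and
#' absolute), resting and hyperemic mean flow, and myocardial flow
#' reserve.
#'
#' @param model A [CoroModel-class].
#' @param rest,hyper Runs from [runResting()] / [runHyperemia()].
#' @return A `data.frame`, one row per perfused segment.
#' @export
perfusionReport <- function(model, rest, hyper) {
  seg <- model@segments
  sp <- segPatchIndex(model)
  st <- rest$st
  Vw <- model@patches$Vw[sp] * st$m[sp]
  thick <- Vw / model@patches$Am_ref[sp]
  q_rest <- rest$out$summary$meanQsub
  q_hyp <- hyper$out$summary$meanQsub
  data.frame(
    segment = seg$id, name = seg$name, wall = seg$wall, ring = seg$ring,
    territory = seg$branch, t_act = st$t_act[sp] - model@config$hemodynamics$AV_delay,
    thickness = thick, mass = 1.055 * Vw,
    VO2_den = rest$demand$VO2_den, VO2_abs = rest$demand$VO2_abs,
    EW = rest$demand$EW, PE = rest$demand$PE,
    q_rest = q_rest, q_hyper = q_hyp, MFR = mfr(q_rest, q_hyp),
    stringsAsFactors = FALSE
  )
}

## layer flow totals over left-ventricular (LV + septal) segments
endoEpiRatio <- function(model, run) {
  qcap <- capillaryFlows(model, run$out)
  lv <- model@segments$wall %in% c("LV", "SEP")
  sum(qcap[lv, 1]) / sum(qcap[lv, 3])
}

#' Class \code{CoroRun}
#'
#' Result of one protocol: the converged resting and hyperemic runs, the
#' per-segment perfusion report and global summaries.
#'
#' @slot protocol Protocol name.
#' @slot report Per-segment perfusion report.
#' @slot rest,hyper Run lists (state, last-beat series, demand, log).
#' @slot global Named list of global quantities (CO, MAP, total coronary
#'   flow, endo/epi ratio, ...).
#' @export
setClass("CoroRun", representation(
  protocol = "character", report = "data.frame", rest = "list",
  hyper = "list", global = "list"
))

setMethod("show", "CoroRun", function(object) {
  g <- object@global
  cat("CoroRun:", object@protocol, "\n")
  cat(sprintf("  CO %.2f L/min  MAP %.1f mmHg  coronary flow %.1f mL/min (%.2f%% CO)\n",
              g$CO * 60 / 1000, g$MAP / MMHG, g$q_cor * 60,
              100 * g$q_cor / g$CO))
  cat(sprintf("  mean LV MFR %.2f  endo/epi (rest) %.3f\n",
              g$MFR_lv, g$endo_epi_rest))
  invisible(object)
})

makeRun <- function(model, protocol, rest, hyper) {
  rep <- perfusionReport(model, rest, hyper)
  lv <- rep$wall %in% c("LV", "SEP")
  global <- list(
    CO = rest$out$summary$CO, MAP = rest$out$summary$MAP,
    q_cor = sum(rest$out$summary$meanQsub),
    q_cor_hyper = sum(hyper$out$summary$meanQsub),
    MFR_lv = mean(rep$MFR[lv]),
    endo_epi_rest = endoEpiRatio(model, rest),
    endo_epi_hyper = endoEpiRatio(model, hyper),
    peak_pLV = rest$out$summary$peak_pLV,
    q_prox = colMeans(rest$out$corQ),
    q_prox_hyper = colMeans(hyper$out$corQ)
  )
  new("CoroRun", protocol = protocol, report = rep,
      rest = rest, hyper = hyper, global = global)
}

#' Run the reference (synchronous activation) protocol
#'
#' Starting from the built-in initial state, runs resting beats with
#' homeostatic control and metabolic flow regulation to steady state
#' (heart rate 70/min, cardiac output 5.1 L/min, mean arterial pressure
#' 92 mmHg; total coronary flow anchored at 4% of cardiac output), then
#' simulates hyperemia.
#'
#' @param model A [CoroModel-class] (default configuration if missing).
#' @param max_beats Resting beat budget.
#' @param quiet Progress output.
#' @return A [CoroRun-class].
#' @export
runReference <- function(model = coroModel(), max_beats = NULL, quiet = TRUE) {
  st <- newRunState(model)
  st <- applySchedule(model, st, NULL)
  rest <- runResting(model, st, max_beats = max_beats, homeo = TRUE,
                     regulate = TRUE, anchor = TRUE, quiet = quiet)
  hyper <- runHyperemia(model, rest)
  makeRun(model, "reference", rest, hyper)
}

#' Run the acute LBBB protocol
#'
#' Applies the LBBB activation schedule to a converged reference state,
#' re-converges resting regulation (target flows keep following demand
#' from their reference anchoring), then simulates hyperemia.
#'
#' @param model A [CoroModel-class].
#' @param reference A reference [CoroRun-class].
#' @param max_beats Resting beat budget.
#' @param quiet Progress output.
#' @return A [CoroRun-class].
#' @export
runAcuteLbbb <- function(model, reference, max_beats = NULL, quiet = TRUE) {
  st <- reference@rest$st
  st <- applySchedule(model, st, buildLbbbSchedule(model@segments,
                                                   model@config$hemodynamics$AV_delay))
  rest <- runResting(model, st, max_beats = max_beats, homeo = TRUE,
                     regulate = TRUE, anchor = FALSE, burnin = 1, quiet = quiet)
  hyper <- runHyperemia(model, rest)
  makeRun(model, "acute-lbbb", rest, hyper)
}
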