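## Default model configuration and config I/O.
##
## Units used throughout: pressure kPa, volume mL, flow mL/s, time s,
## stress kPa (= kJ/m^3 for energy densities), length (sarcomere) um,
## area cm^2. 1 mmHg = 0.133322 kPa.

MMHG <- 0.133322

## AHA 17-segment table for the left ventricle plus the right ventricular
## free wall ("RV"). `wall` assigns each segment to one of the three
## mechanical walls (LV lateral free wall, septum, RV free wall); `branch`
## is the coronary territory (the posterior descending artery, PDA, is the
## RCA sub-branch serving the inferoseptal/inferior column); `frac` is the
## share of the wall's volume carried by the segment; `lenf` scales the
## sub-branch (epicardial feeding) resistance with vascular path length,
## which grows toward the apex and is larger for the PDA.
ahaSegmentTable <- function() {
  seg <- data.frame(
    id = c(1:17, 0L),
    name = c("basal anterior", "basal anteroseptal", "basal inferoseptal",
             "basal inferior", "basal inferolateral", "basal anterolateral",
             "mid anterior", "mid anteroseptal", "mid inferoseptal",
             "mid inferior", "mid inferolateral", "mid anterolateral",
             "apical anterior", "apical septal", "apical inferior",
             "apical lateral", "apex", "RV free wall"),
    wall = c("LV", "SEP", "SEP", "LV", "LV", "LV",
             "LV", "SEP", "SEP", "LV", "LV", "LV",
             "LV", "SEP", "LV", "LV", "LV", "RV"),
    ring = c(rep("basal", 6), rep("mid", 6), rep("apical", 4), "apex", "rv"),
    branch = c("LAD", "LAD", "PDA", "RCA", "LCx", "LCx",
               "LAD", "LAD", "PDA", "RCA", "LCx", "LCx",
               "LAD", "LAD", "PDA", "LCx", "LAD", "RCA"),
    stringsAsFactors = FALSE
  )
  ## ring weights: basal segments are larger than apical ones
  rw <- c(basal = 1.25, mid = 1.0, apical = 0.75, apex = 0.6, rv = 1.0)
  seg$w <- rw[seg$ring]
  seg$frac <- stats::ave(seg$w, seg$wall, FUN = function(x) x / sum(x))
  seg$w <- NULL
  ## vascular path length factor: basal 1, mid 1.35, apical/apex 1.75;
  ## PDA runs around the inferior wall, add 35%
  lf <- c(basal = 1.0, mid = 1.35, apical = 1.75, apex = 1.9, rv = 1.0)
  seg$lenf <- lf[seg$ring] * ifelse(seg$branch == "PDA", 1.55, 1.0)
  seg
}

#' Default model configuration
#'
#' Builds the reference configuration of the closed-loop heart-coronary
#' model: a normal adult at heart rate 70 beats/min with target cardiac
#' output 5.1 L/min and mean arterial pressure 92 mmHg, a 12 + 5 + 1
#' segment ventricular wall division with AHA coronary territories, and a
#' reduced coronary tree (proximal left main, LAD, LCx and RCA vessels
#' feeding one sub-branch per perfused segment, three transmural layers of
#' five lumped compartment classes each).
#'
#' All parameters are plain numbers in kPa / mL / s units and can be edited
#' before building a model with [coroModel()].
#'
#' @param hr Heart rate in beats/min.
#' @return A nested list of configuration sections (`hemodynamics`,
#'   `sarcomere`, `walls`, `atria`, `valves`, `systemic`, `pericardium`,
#'   `coronary`, `regulation`, `remodeling`, `schedule`, `solver`).
#' @export
defaultConfig <- function(hr = 70) {
  seg <- ahaSegmentTable()
  cfg <- list(
    hemodynamics = list(
      HR = hr,
      CO_target = 5.1 * 1000 / 60,        # mL/s
      MAP_target = 92 * MMHG,             # kPa
      kappa = 0.5,                        # homeostatic damping
      AV_delay = 0.139                    # s, atrial to ventricular onset
    ),
    sarcomere = list(
      sig_act_max = 120,   # kPa, isometric active stress scale
      TR = 0.090,          # s, twitch rise time (onset to peak)
      TD = 0.260,          # s, twitch decay time (peak to zero)
      Ls_ref = 2.0,        # um, sarcomere length at reference midwall area
      Ls0 = 1.8,           # um, sarcomere length at zero transmural pressure
      Lsc0 = 1.38,         # um, contractile length at zero active stress
      Lse_iso = 0.05,      # um, series-elastic stretch at isometric stress
      v_max = 7.0,         # um/s, unloaded shortening velocity scale
      sig_pas0 = 1.35,     # kPa, passive exponential scale
      k_pas = 13,          # passive exponential stiffness
      k_lin = 0.8,         # kPa, small linear passive slope (stability)
      k_comp = 10          # compressive-branch stiffness exponent
    ),
    walls = list(
      LV  = list(Vw = 76,  Am_ref = 88),   # mL, cm^2 (12 segments)
      SEP = list(Vw = 36,  Am_ref = 41),   # 5 segments
      RV  = list(Vw = 30,  Am_ref = 105)   # 1 segment
    ),
    segments = seg,
    atria = list(
      V0 = 25,          # mL, unstressed cavity volume
      V_ref = 75,       # mL, reference for exponential stiffening
      E_pas = 0.012,    # kPa/mL
      E_act = 0.06,     # kPa/mL
      k_exp = 8.0, sig_exp = 0.05,
      TR = 0.09, TD = 0.13
    ),
    valves = list(
      ## effective open orifice areas (cm^2), leak areas and lengths (cm)
      A_open = c(mitral = 6.5, aortic = 5.0, tricuspid = 7.0, pulmonary = 5.5),
      A_leak = 1e-3, len = 1.5, rho = 1050, p_switch = 0.04,
      tau = 0.005      # s, leaflet opening/closing time constant
    ),
    systemic = list(
      Rsys = 0.140,     # kPa s/mL, adjusted by homeostasis
      C_sa = 11.0, V0_sa = 560,
      C_sv = 600, V0_sv = 2800,
      R_vr = 0.0035,
      Rpulm = 0.0105,
      C_pa = 38, V0_pa = 110,
      C_pv = 80, V0_pv = 420,
      R_pl = 0.0028,
      Vtot = 5000       # mL, adjusted by homeostasis
    ),
    pericardium = list(
      k1 = 0.12,        # kPa
      k2 = 12,          # stiffness exponent
      V_ref = NA        # mL; NA = set from the initial enclosed volume
    ),
    coronary = list(
      imp = list(gamma = 0.06, r = c(subendo = 5 / 6, mid = 3 / 6, subepi = 1 / 6)),
      ## layer resting flow weights give endo:epi = 1.11 with mid between
      layer_weights = c(1.11, 1.055, 1.0) / sum(c(1.11, 1.055, 1.0)),
      vessels = list(
        ## proximal epicardial vessels, two elastic nodes each
        E = 45,                      # kPa per unit relative volume
        V0 = c(LM = 2.2, LAD = 2.8, LCx = 2.4, RCA = 2.6),
        R_int = 0.010,               # kPa s/mL between the two nodes
        R_in = 0.012,                # inlet resistance aorta -> LM / RCA
        L_in = 4e-5,                 # kPa s^2/mL inlet inertance
        R_junc = 0.010               # LM -> LAD / LCx junction resistance
      ),
      subbranch = list(R_art = 1.30, R_ven = 0.28),  # kPa s/mL per unit lenf
      veins = list(E = 1.2, V0 = c(LAD = 2.2, LCx = 1.9, RCA = 2.1),
                   R_cs = 0.012, V0_cs = 3.0, R_csra = 0.010),
      micro = list(
        ## per class: reference pressure drop dp0 (kPa) at reference flow,
        ## share of the segment micro blood volume, tube-law reference
        ## pressure p0 (kPa), stiffness exponent k, wall-to-lumen ratio aw
        classes = data.frame(
          class = c("small_artery", "arteriole", "capillary", "venule", "small_vein"),
          dp0 = c(1.40, 16.50, 0.38, 0.22, 0.14),
          vshare = c(0.08, 0.08, 0.42, 0.22, 0.20),
          p0 = c(3.2, 1.30, 1.1, 0.8, 0.7),
          k = c(13, 9, 8, 8, 9),
          aw = c(1.0, 1.0, 1.0, 1.0, 1.0),
          stringsAsFactors = FALSE
        ),
        ## arteriolar reference-drop multiplier per layer (subendo, mid,
        ## subepi): encodes the higher baseline tone of subendocardial
        ## resistance vessels needed to keep the hyperemic endo-to-epi
        ## ratio at 1.11 given the layer-dependent dilation caps
        art_layer_scale = c(1.35, 1.11, 0.89),
        blood_vol_per_mL = 0.10      # mL intramyocardial blood per mL tissue
      )
    ),
    regulation = list(
      alpha = 0.2,
      tol = 0.005,
      fDilMin = 0.5,
      ## arteriolar dilation caps: left (LV + septal) subendo 3.00 linear to
      ## subepi 1.70; right (RV) 2.40 / 2.30 -> same midwall cap 2.35
      fDilMax_left = c(3.00, 2.35, 1.70),
      fDilMax_right = c(2.40, 2.35, 2.30),
      fDilMax_sa = 1.40,
      cor_flow_frac = 0.04,          # total resting coronary flow / CO
      max_beats = 240
    ),
    remodeling = list(beta = 0.5, cap = 0.25, tol = 0.005, max_iter = 12,
                      rho_myo = 1.055),  # g/mL myocardial density
    schedule = list(mode = "synchronous"),
    solver = list(dt = 1e-3, newton_tol = 1e-8, newton_maxit = 30,
                  jac_refresh = 400),
    steady = list(tol = 1e-3, min_beats = 3)
  )
  cfg
}

#' Reduced test-fixture configuration
#'
#' A deterministic, self-consistent reduced model for fast tests: the LV
#' free wall carries 2 segments, the septum 1, each with its own coronary
#' sub-branch and three transmural layers (9 layer chains in total). The
#' RV free wall is retained mechanically but not perfused.
#'
#' @param scale `"unit"` for the 3-segment fixture, `"full"` for the
#'   default 17 + RV configuration.
#' @return A configuration list as from [defaultConfig()].
#' @export
fixtureConfig <- function(scale = c("unit", "full")) {
  scale <- match.arg(scale)
  cfg <- defaultConfig()
  if (scale == "full") return(cfg)
  seg <- data.frame(
    id = c(101L, 102L, 103L),
    name = c("LV segment A", "LV segment B", "septal segment"),
    wall = c("LV", "LV", "SEP"),
    ring = c("basal", "mid", "mid"),
    branch = c("LCx", "LAD", "LAD"),
    frac = c(0.55, 0.45, 1.0),
    lenf = c(1.0, 1.2, 1.2),
    stringsAsFactors = FALSE
  )
  cfg$segments <- seg
  cfg$regulation$max_beats <- 60
  cfg
}

#' Read or write a configuration as YAML
#'
#' @param path File path.
#' @param cfg Configuration list.
#' @return `readConfig` returns the configuration list.
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$segments)) cfg$segments <- as.data.frame(cfg$segments)
  if (!is.null(cfg$coronary$micro$classes))
    cfg$coronary$micro$classes <- as.data.frame(cfg$coronary$micro$classes)
  cfg
}

#' @rdname readConfig
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
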