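## Myofiber mechanics: strain, active/passive Cauchy fiber stress, wall
## tension. These are the segment-level constitutive relations used by the
## simulator core; they are exported both as the documented model equations
## and for post-processing.

#' Natural fiber strain from midwall area
#'
#' The one-fiber wall model relates midwall area change to fiber strain:
#' an isotropic area stretch `Am/Am_ref` corresponds to a linear fiber
#' stretch of `sqrt(Am/Am_ref)`, so the natural (logarithmic) fiber strain
#' is `0.5 * log(Am / Am_ref)`; zero at the reference area.
#'
#' @param Am Current midwall area (cm^2).
#' @param Am_ref Reference midwall area (cm^2).
#' @return Natural fiber strain (dimensionless).
#' @export
fiberStrain <- function(Am, Am_ref) {
  if (any(Am <= 0) || any(Am_ref <= 0))
    stop("invalid geometry: midwall areas must be positive")
  0.5 * log(Am / Am_ref)
}

## Smooth twitch activation: zero before onset, C1-continuous rise to a
## peak of 1 at t = TR, decay back to zero at TR + TD.
twitchActivation <- function(t_rel, TR, TD) {
  if (TR <= 0 || TD <= 0) stop("config error: twitch time constants must be positive")
  C <- numeric(length(t_rel))
  ris <- t_rel > 0 & t_rel < TR
  dec <- t_rel >= TR & t_rel < TR + TD
  C[ris] <- 0.5 * (1 - cos(pi * t_rel[ris] / TR))
  C[dec] <- 0.5 * (1 + cos(pi * (t_rel[dec] - TR) / TD))
  C
}

#' Active Cauchy fiber stress of the three-element Hill-type sarcomere
#'
#' A prescribed smooth twitch (rise time `TR`, decay time `TD`) scales an
#' isometric stress that increases linearly with contractile-element
#' length above its zero-stress length (length-dependent activation, the
#' cellular basis of the Frank-Starling mechanism). The series-elastic
#' element carries the stress: `sigma_act` is proportional to the
#' series-elastic stretch `(Ls - Lsc)/Lse_iso`, equal to 1 under isometric
#' conditions.
#'
#' @param t_rel Time since activation onset (s); stress is zero for
#'   `t_rel < 0`.
#' @param Ls Current sarcomere length (um).
#' @param Lsc Contractile-element length (um). If `NULL`, isometric
#'   conditions are assumed (`Lsc = Ls - Lse_iso`).
#' @param params Sarcomere parameter list as in
#'   `defaultConfig()$sarcomere`.
#' @return Active Cauchy fiber stress (kPa), non-negative.
#' @export
activeFiberStress <- function(t_rel, Ls, Lsc = NULL, params = defaultConfig()$sarcomere) {
  if (params$TR <= 0 || params$TD <= 0)
    stop("config error: twitch time constants must be positive")
  if (is.null(Lsc)) Lsc <- Ls - params$Lse_iso
  C <- twitchActivation(t_rel, params$TR, params$TD)
  g <- pmax(0, (Lsc - params$Lsc0) / (params$Ls_ref - params$Lse_iso - params$Lsc0))
  se <- pmax(0, (Ls - Lsc) / params$Lse_iso)
  params$sig_act_max * C * g * se
}

#' Passive Cauchy fiber stress
#'
#' Exponential strain stiffening above the zero-stress strain `eps0`
#' (strain at the sarcomere length observed at zero transmural pressure)
#' plus a small linear slope. Zero at `eps0`; strictly increasing and
#' convex above it.
#'
#' @param eps_f Natural fiber strain.
#' @param params Sarcomere parameter list.
#' @param compressive If `TRUE` (the simulator's convention) a
#'   slope-matched exponential compression branch gives negative stress
#'   below `eps0` (the tissue resists crumpling); if `FALSE` stress is
#'   clamped at zero below `eps0`.
#' @return Passive Cauchy fiber stress (kPa).
#' @export
passiveFiberStress <- function(eps_f, params = defaultConfig()$sarcomere,
                               compressive = TRUE) {
  eps0 <- log(params$Ls0 / params$Ls_ref)
  d <- eps_f - eps0
  sig_comp <- params$sig_pas0 * params$k_pas / params$k_comp
  s <- params$k_lin * d + ifelse(d > 0, params$sig_pas0 * expm1(params$k_pas * d),
                                 -sig_comp * expm1(-params$k_comp * d))
  if (!compressive) s <- pmax(0, s)
  s
}

#' Midwall tension from fiber stress
#'
#' Thin-wall one-fiber closure: a wall segment of volume `Vw` spread over
#' midwall area `Am` under fiber stress `sigma_f` carries a membrane
#' tension `Tm = sigma_f * Vw / (2 * Am)`.
#'
#' @param sigma_f Total Cauchy fiber stress (kPa).
#' @param Vw Wall segment volume (mL).
#' @param Am Midwall area of the segment (cm^2).
#' @return Midwall tension (kPa cm, i.e. 10 N/m per unit).
#' @export
wallTension <- function(sigma_f, Vw, Am) {
  if (any(Am <= 0)) stop("invalid geometry: midwall area must be positive")
  sigma_f * Vw / (2 * Am)
}
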