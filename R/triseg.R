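## Quasi-static TriSeg junction equilibrium, valve flow and pericardium:
## the chamber-level relations also used inside the compiled core, exposed
## at the R level for analysis and testing.

capHeightR <- function(Vm, Ys) {
  p <- 3 * Ys^2; qh <- 6 * Vm / pi
  s <- sqrt(qh^2 / 4 + p^3 / 27)
  sign(qh / 2 + s) * abs(qh / 2 + s)^(1 / 3) +
    sign(qh / 2 - s) * abs(qh / 2 - s)^(1 / 3)
}

trisegGeometry <- function(Vs, Ys, V_LV, V_RV, Vw) {
  Vm <- c(L = Vs - (V_LV + 0.5 * (Vw[1] + Vw[2])),
          S = Vs,
          R = Vs + V_RV + 0.5 * (Vw[2] + Vw[3]))
  xm <- vapply(Vm, capHeightR, 0, Ys = Ys)
  Am <- pi * (xm^2 + Ys^2)
  Cm <- 2 * xm / (xm^2 + Ys^2)
  list(Vm = Vm, xm = xm, Am = Am, Cm = Cm)
}

trisegResidual <- function(Vs, Ys, Tm, V_LV, V_RV, Vw) {
  g <- trisegGeometry(Vs, Ys, V_LV, V_RV, Vw)
  d2 <- g$xm^2 + Ys^2
  c(axial = sum(Tm * 2 * g$xm * Ys / d2),
    radial = sum(Tm * (Ys^2 - g$xm^2) / d2))
}

#' Solve the TriSeg junction equilibrium for given wall tensions
#'
#' Finds the septal cap volume `Vs` and junction radius `Ys` that null the
#' net axial and radial tension at the junction of the three ventricular
#' walls (LV free wall, septum, RV free wall), for fixed cavity volumes
#' and per-wall midwall tensions. Returns the resulting geometry and the
#' transmural pressures `2*Tm*Cm` of the three walls.
#'
#' @param Tm Wall tensions `c(L, S, R)` (kPa cm).
#' @param V_LV,V_RV Cavity volumes (mL).
#' @param Vw Wall volumes `c(L, S, R)` (mL).
#' @param Vs0,Ys0 Initial guesses.
#' @param tol Residual tolerance relative to the tension scale.
#' @return List with `Vs`, `Ys`, `xm`, `Am`, `Cm`, `ptrans` (per wall,
#'   kPa) and the final `residual`.
#' @export
solveTriseg <- function(Tm, V_LV, V_RV, Vw, Vs0 = 0.25 * V_LV, Ys0 = 3.0,
                        tol = 1e-9) {
  Tsc <- max(abs(Tm), 1e-12)
  x <- c(Vs0, Ys0)
  rnorm2 <- function(x) max(abs(trisegResidual(x[1], x[2], Tm, V_LV, V_RV, Vw)))
  for (it in 1:300) {
    r <- trisegResidual(x[1], x[2], Tm, V_LV, V_RV, Vw)
    if (max(abs(r)) < tol * Tsc) break
    ## central-difference Jacobian for accuracy near flat directions
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      e <- c(1e-3 * max(abs(x[1]), 10), 1e-4 * max(abs(x[2]), 1))[j]
      xp <- x; xm <- x
      xp[j] <- xp[j] + e; xm[j] <- xm[j] - e
      J[, j] <- (trisegResidual(xp[1], xp[2], Tm, V_LV, V_RV, Vw) -
                 trisegResidual(xm[1], xm[2], Tm, V_LV, V_RV, Vw)) / (2 * e)
    }
    dx <- tryCatch(solve(J, r), error = function(e) r * 0)
    dx[1] <- max(min(dx[1], 20), -20)
    dx[2] <- max(min(dx[2], 0.4), -0.4)
    ## backtracking on the residual norm
    step <- 1
    r0n <- max(abs(r))
    repeat {
      xn <- x - step * dx
      xn[2] <- max(xn[2], 0.3)
      if (rnorm2(xn) < r0n || step < 1 / 64) break
      step <- step / 2
    }
    x <- xn
    if (it == 300 && max(abs(r)) > 1e-6 * Tsc)
      stop("TriSeg solve did not converge; residual ", max(abs(r)))
  }
  g <- trisegGeometry(x[1], x[2], V_LV, V_RV, Vw)
  list(Vs = x[1], Ys = x[2], xm = g$xm, Am = g$Am, Cm = g$Cm,
       ptrans = 2 * Tm * g$Cm,
       residual = trisegResidual(x[1], x[2], Tm, V_LV, V_RV, Vw))
}

#' Pericardial pressure
#'
#' Monotone exponential pressure-volume relation of the pericardial sac,
#' approximately zero at the reference enclosed volume:
#' `P = k1 * (exp(k2 * (V/V_ref - 1)) - 1)`.
#'
#' @param V_enc Enclosed volume (cavities + wall volumes + epicardial
#'   coronary volume, mL).
#' @param V_ref Reference enclosed volume (mL).
#' @param k1 Pressure scale (kPa).
#' @param k2 Stiffness exponent.
#' @return Pericardial pressure (kPa).
#' @export
pericardialPressure <- function(V_enc, V_ref, k1 = 0.12, k2 = 12) {
  k1 * expm1(k2 * (V_enc / V_ref - 1))
}

#' Valve flow update over a time step
#'
#' Bernoulli pressure-flow relation with blood inertia and smooth
#' opening/closing: the effective orifice area follows the larger of the
#' pressure and flow signals, so an ejecting valve stays open under a
#' decelerating (slightly negative) pressure gradient, while a closed
#' valve under sustained negative pressure carries no flow (leak-free
#' default).
#'
#' @param dp Pressure difference across the valve (kPa).
#' @param q Current flow (mL/s).
#' @param dt Time step (s).
#' @param A_open Open orifice area (cm^2).
#' @param A_leak Leak area (cm^2); 0 for a leak-free valve.
#' @param len Effective blood column length (cm).
#' @param rho Blood density (kg/m^3).
#' @param p_switch Opening/closing pressure width (kPa).
#' @return Updated flow (mL/s).
#' @export
valveFlow <- function(dp, q, dt, A_open = 5, A_leak = 0, len = 1.5,
                      rho = 1050, p_switch = 0.04) {
  if (dt <= 0) stop("dt must be positive")
  L <- rho * (len * 1e-2) / (A_open * 1e-4) * 1e-9
  B <- 0.5 * rho * 1e-7
  nsub <- max(1L, ceiling(dt / 2e-4))
  h <- dt / nsub
  for (i in seq_len(nsub)) {
    a <- q / 20
    sp <- if (a > 30) a else log1p(exp(a))
    m <- dp / p_switch + sp
    s <- 1 / (1 + exp(-m))
    Aeff <- A_leak + (A_open - A_leak) * s
    if (Aeff < 1e-9) { q <- 0; next }
    ## semi-implicit in the (regularized) quadratic drag for stability
    drag <- B * sqrt(q^2 + 0.25) / Aeff^2
    q <- (q + h * dp / L) / (1 + h * drag / L)
  }
  q
}

#' Advance the full model state by explicit time steps
#'
#' Thin wrapper over the compiled integrator: advances the complete
#' closed-loop state (cavities, valves, vascular beds, coronary
#' compartments, sarcomeres and the TriSeg algebraic geometry) by
#' `nsteps` steps of the configured step size using BDF2 (implicit Euler
#' on the first step), and returns the recorded series.
#'
#' @param model A [CoroModel-class].
#' @param st Run state from [newRunState()]/previous calls; `NULL` to
#'   initialize.
#' @param nsteps Number of steps (default one full beat).
#' @param record Recording level (1 standard, 2 adds intramyocardial
#'   pressure series).
#' @return List with updated state `st` and the series `out`.
#' @export
stepSystem <- function(model, st = NULL, nsteps = NULL, record = 1L) {
  if (is.null(st)) st <- newRunState(model)
  rb <- runBeat(model, st, record = record, nsteps = nsteps)
  list(st = rb$st, out = rb$out)
}
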