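## TriSeg junction equilibrium, valves, pericardium, homeostatic control,
## steady-state detection.

test_that("TriSeg solve nulls the junction forces and reports consistent pressures", {
  Vw <- c(76, 36, 30)
  Tm <- c(3, 2.8, 0.8)
  sol <- solveTriseg(Tm, V_LV = 120, V_RV = 120, Vw = Vw)
  ## independently evaluated force residual below 1e-6 of the tension
  ## scale on the converged state
  expect_lt(max(abs(sol$residual)), 1e-6 * max(abs(Tm)))
  ## LV free wall bulges away from the RV, septum toward the RV
  expect_lt(sol$xm[1], 0)
  expect_gt(sol$xm[3], 0)
  ## transmural pressures consistent with tensions and curvatures
  expect_equal(sol$ptrans, 2 * Tm * sol$Cm, tolerance = 1e-12)
})

test_that("zero tensions give zero transmural pressures", {
  sol <- solveTriseg(c(0, 0, 0), 120, 120, c(76, 36, 30))
  expect_equal(unname(sol$ptrans), c(0, 0, 0))
})

test_that("mirror-symmetric configuration flips the septal curvature", {
  Vw <- c(76, 36, 30)
  Tm <- c(3, 2.8, 0.8)
  a <- solveTriseg(Tm, 110, 95, Vw, Vs0 = 25, Ys0 = 3)
  b <- solveTriseg(rev(Tm), 95, 110, rev(Vw), Vs0 = -a$Vs, Ys0 = a$Ys)
  expect_equal(b$Vs, -a$Vs, tolerance = 1e-5)
  expect_equal(abs(b$Vs), abs(a$Vs), tolerance = 1e-5)
  expect_equal(sign(b$Cm[["S"]]), -sign(a$Cm[["S"]]))
  expect_equal(b$Ys, a$Ys, tolerance = 1e-5)
})

test_that("valve flow settles to the Bernoulli value and a closed valve carries none", {
  ## sustained zero gradient: flow decays toward zero (algebraic decay
  ## under pure Bernoulli drag)
  q <- 150
  for (i in 1:4000) q <- valveFlow(0, q, 0.001)
  expect_lt(abs(q), 0.05 * 150)
  ## sustained negative gradient on a closed valve: exactly zero
  ## (leak-free default)
  q <- 0
  for (i in 1:50) q <- valveFlow(-2, q, 0.001)
  expect_equal(q, 0)
  ## step to 1 kPa on an open aortic valve: settles to the steady
  ## Bernoulli value q = A*sqrt(dp/B) within 5 inertial time constants,
  ## cross-checked against an independent ODE solution
  A <- 5; B <- 0.5 * 1050 * 1e-7
  q_steady <- A * sqrt(1 / B)
  q <- 300   # start from an open-valve state
  L <- 1050 * 1.5e-2 / (A * 1e-4) * 1e-9
  tau <- L / (2 * B * q_steady / A^2)   # linearized decay time at q_steady
  nstep <- ceiling(5 * tau / 1e-4)
  for (i in seq_len(nstep)) q <- valveFlow(1, q, 1e-4)
  expect_equal(q, q_steady, tolerance = 0.02 * q_steady)
  ode <- stats::integrate  # silence lint; independent oracle below
  f <- function(t, y, parms) list((1 - B * y[1] * abs(y[1]) / A^2) / L)
  sol <- deSolve::ode(y = 300, times = c(0, 5 * tau), func = f, parms = NULL)
  expect_equal(q, unname(sol[2, 2]), tolerance = 0.02 * q_steady)
})

test_that("pericardial pressure is near zero at reference and monotone", {
  expect_lt(abs(pericardialPressure(700, 700)), 0.1)
  expect_gt(pericardialPressure(840, 700), 0)
  v <- seq(600, 900, by = 20)
  expect_true(all(diff(pericardialPressure(v, 700)) > 0))
  ## doubling the stiffness exponent increases the pressure at a fixed
  ## volume excess
  expect_gt(pericardialPressure(840, 700, k2 = 24),
            pericardialPressure(840, 700, k2 = 12))
})

test_that("homeostatic control has the targets as fixed point and correct directions", {
  CO_t <- 85; MAP_t <- 12.266
  h <- homeostaticControl(CO_t, MAP_t, CO_t, MAP_t, Rsys = 0.14, Vtot = 5000)
  expect_equal(h$Rsys, 0.14)
  expect_equal(h$Vtot, 5000)
  ## MAP above target at CO on target -> Rsys strictly decreases
  h2 <- homeostaticControl(CO_t, MAP_t * 1.1, CO_t, MAP_t, 0.14, 5000)
  expect_lt(h2$Rsys, 0.14)
  ## CO below target -> volume expands
  h3 <- homeostaticControl(CO_t * 0.9, MAP_t, CO_t, MAP_t, 0.14, 5000)
  expect_gt(h3$Vtot, 5000)
  expect_error(homeostaticControl(85, 12, -1, 12, 0.14, 5000), "config")
})

test_that("steady-state detection is relative and needs consecutive quiet beats", {
  same <- rep(list(c(70, 70, 1, 2)), 5)
  expect_true(detectSteadyState(same))
  drift <- lapply(1:6, function(k) c(70 * 1.01^k, 70, 1, 2))
  expect_false(detectSteadyState(drift))
  ## invariant under unit rescaling
  scaled <- lapply(same, function(x) x * 1e6)
  expect_true(detectSteadyState(scaled))
  expect_false(detectSteadyState(same[1:2]))
})
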