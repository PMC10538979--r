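## Stress-strain area decomposition and the metabolic regulation laws.

test_that("external work is the signed shoelace area of the loop", {
  ## counterclockwise rectangle spanning deps = 0.1, dsigma = 50 kPa
  eps <- c(0, 0.1, 0.1, 0)
  sig <- c(0, 0, 50, 50)
  expect_equal(externalWork(eps, sig), 5)
  ## clockwise traversal flips the sign
  expect_equal(externalWork(rev(eps), rev(sig)), -5)
  ## invariant under cyclic rotation of the samples
  expect_equal(externalWork(eps[c(3, 4, 1, 2)], sig[c(3, 4, 1, 2)]), 5)
  expect_error(externalWork(c(0, 1), c(0, 1)), "3")
})

test_that("external work matches a dense polygon oracle on a smooth loop", {
  ## ellipse loop traversed counterclockwise: area = pi*a*b
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  eps <- 0.05 * cos(th)
  sig <- 30 + 25 * sin(th)
  expect_equal(externalWork(eps, sig), pi * 0.05 * 25, tolerance = 1e-3)
})

test_that("potential energy is the area bounded by ESSSR, diastolic limb, EDSSR and the axis", {
  ## straight-line ESSSR from (eps0 = -0.2, 0) to ES (0, 60) with the
  ## diastolic limb along the axis: triangle area 6 kJ/m^3
  eps <- c(0, 0, -0.0001, -0.2, -0.1)
  sig <- c(1e-9, 60, 1e-9, 1e-9, 1e-9)
  pe <- potentialEnergy(eps, sig, eps0 = -0.2, i_es = 2L, i_ed = 1L)
  expect_equal(pe, 6, tolerance = 1e-3)
  ## ES stress ~ 0 -> degenerate polygon, PE ~ 0 with warning
  expect_warning(pe0 <- potentialEnergy(c(0, 0.01, 0.02), c(0, 0, 0), -0.2,
                                        i_es = 1L, i_ed = 1L), "degenerate")
  expect_equal(pe0, 0)
})

test_that("SSA = EW + PE identity holds on simulated loops", {
  m <- coroModel(fixtureConfig("unit"))
  s1 <- stepSystem(m)
  s2 <- stepSystem(m, s1$st)   # one full settled beat
  p <- m@config$sarcomere
  eps0 <- log(p$Ls0 / p$Ls_ref)
  for (j in 1:3) {
    d <- ssaDecompose(s2$out$eps[, j], s2$out$sig[, j], eps0, Vw = 20)
    expect_equal(d$SSA, d$EW + d$PE, tolerance = 1e-12)
    expect_gte(d$PE, 0)
  }
})

test_that("oxygen demand is linear in SSA density over cycle time", {
  expect_equal(oxygenDemand(0, 60 / 70), 24.2)
  expect_equal(oxygenDemand(5, 60 / 70), 4.94 * 5 / (60 / 70) + 24.2)
  expect_equal(oxygenDemand(5, 60 / 70), 53.02, tolerance = 1e-3)
  ## doubling SSA doubles the increment above the intercept
  d1 <- oxygenDemand(4, 0.8) - 24.2
  d2 <- oxygenDemand(8, 0.8) - 24.2
  expect_equal(d2, 2 * d1)
  expect_error(oxygenDemand(5, 0), "positive")
})

test_that("target-flow updates are multiplicative and path-independent", {
  expect_equal(updateTargetFlow(2, 10, 10), 2)
  expect_equal(updateTargetFlow(2, 11, 10), 2.2)
  ## compounding a sequence of ratios equals the single overall ratio
  q <- 1.7
  demands <- c(10, 12, 9, 14, 14.5)
  for (k in 2:length(demands))
    q <- updateTargetFlow(q, demands[k], demands[k - 1])
  expect_equal(q, 1.7 * demands[length(demands)] / demands[1], tolerance = 1e-12)
  expect_error(updateTargetFlow(1, 1, 0), "nonzero")
})

test_that("vasodilator update moves fDil toward the target flow and clamps", {
  expect_equal(updateVasodilation(1.3, 2, 2, 0.2), 1.3)
  expect_equal(updateVasodilation(1, 0.5, 1, 0.2, fDilMax = 10), exp(0.1))
  expect_equal(updateVasodilation(1, 0.5, 1, 0.2, fDilMax = 10), 1.1052,
               tolerance = 1e-4)
  ## under-perfusion dilates, over-perfusion constricts
  expect_gt(updateVasodilation(1.2, 0.8, 1, 0.3), 1.2)
  expect_lt(updateVasodilation(1.2, 1.3, 1, 0.3), 1.2)
  ## clamping
  expect_equal(updateVasodilation(2.9, 0.1, 1, 0.9, fDilMax = 3), 3)
  expect_equal(updateVasodilation(0.55, 10, 1, 0.9, fDilMin = 0.5), 0.5)
  expect_error(updateVasodilation(1, 1, 1, alpha = 1.5), "alpha")
})

test_that("vasodilation iteration converges on a static linearized plant", {
  ## plant: q = g0 * fDil^2 (volume law under a fixed pressure head);
  ## iterate the update law and check convergence to q = q0 for the
  ## default damping
  alpha <- defaultConfig()$regulation$alpha
  g0 <- 0.7; q0 <- 1.3
  fDil <- 1
  for (k in 1:200) fDil <- updateVasodilation(fDil, g0 * fDil^2, q0, alpha,
                                              fDilMin = 0.2, fDilMax = 5)
  expect_equal(g0 * fDil^2, q0, tolerance = 1e-6)
})

test_that("myocardial flow reserve is the hyperemic-to-resting ratio", {
  expect_equal(mfr(1, 1), 1)
  expect_equal(mfr(0.5, 2.1), 4.2)
  expect_equal(mfr(c(1, 2), c(4, 5)), c(4, 2.5))
  expect_error(mfr(c(0, 1), c(1, 1)), "resting")
  expect_error(mfr(1, c(1, 2)), "match")
})

test_that("reference target flows are demand-proportional and sum to 4% of CO", {
  CO <- 5.1 * 1000 / 60
  vo2 <- c(2, 2, 4, 6)
  q0 <- normalizeReferenceDemand(vo2, CO)
  expect_equal(sum(q0) * 60, 0.04 * 5.1 * 1000)  # 204 mL/min
  expect_equal(q0[1], q0[2])
  expect_equal(q0[4] / q0[3], 1.5)
  ## doubling one segment's wall volume at fixed demand density doubles
  ## its share
  q0b <- normalizeReferenceDemand(c(2, 2, 4, 12), CO)
  expect_equal(q0b[4] / q0b[3], 3)
})

test_that("demand per tissue weight scales as expected", {
  expect_equal(demandPerWeight(4, 2), 2)
  expect_equal(demandPerWeight(8, 2), 2 * demandPerWeight(4, 2))
  expect_equal(demandPerWeight(4, 4), 0.5 * demandPerWeight(4, 2))
  ## uniform demand density across segments of any mass gives uniform d
  rho <- 1.055
  Vw <- c(3, 7, 11)
  vo2_den <- 80
  d <- demandPerWeight(vo2_den * Vw * 1e-6, rho * Vw)
  expect_equal(max(d) - min(d), 0)
  expect_error(demandPerWeight(1, 0), "mass")
})
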