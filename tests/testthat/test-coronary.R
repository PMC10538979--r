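## Coronary constitutive laws and network assembly.

test_that("intramyocardial pressure is CEP + VE with layer positions 1/6, 3/6, 5/6", {
  ## septal mid layer: r = 1/2, P1 = 12 (LV), P2 = 4 (RV), no stress
  r <- intramyocardialPressure("mid", 12, 4, 0)
  expect_equal(r$IMP, 8)
  expect_equal(r$CEP, 8)
  expect_equal(r$VE, 0)
  ## VE component: gamma * sigma_f, layer-independent
  for (l in c("subendo", "mid", "subepi"))
    expect_equal(intramyocardialPressure(l, 0, 0, 50, gamma = 0.06)$VE, 3)
  ## transmural CEP gradient: subendo > mid > subepi when P1 > P2
  imps <- vapply(c("subendo", "mid", "subepi"),
                 function(l) intramyocardialPressure(l, 12, 0.5, 20)$IMP, 0)
  expect_true(all(diff(imps) < 0))
  expect_error(intramyocardialPressure("epicardium", 1, 1, 1), "unknown layer")
})

test_that("tube law passes through zero at the reference state and shifts right with dilation", {
  ## Aw = A0, fDil = 1, A = A0: both bracket terms vanish
  expect_equal(transmuralPressure(1, 1, 1, 10, 2, fDil = 1), 0)
  ## rightward shift: at fixed p_trans the solving area increases with fDil
  solveA <- function(fD, p_target) {
    stats::uniroot(function(A) transmuralPressure(A, 1, 1, 10, 2, fD) - p_target,
                   c(0.05, 12))$root
  }
  A1 <- solveA(1, 1.5); A2 <- solveA(2, 1.5); A3 <- solveA(3, 1.5)
  expect_true(A1 < A2 && A2 < A3)
  ## regression pin: fDil = 1, Aw = 0.5*A0, k = 10, A = 1.2*A0, evaluated
  ## directly from the formula
  A <- 1.2; A0 <- 1; Aw <- 0.5; k <- 10; p0 <- 1
  direct <- p0 * (((A + 0.5 * Aw) / (A0 + 0.5 * Aw))^(k / 3) - 1 -
                    max(0, (A / A0)^0.7 * (Aw / A0)^(-0.4) - 1)^2)
  expect_equal(transmuralPressure(A, A0, Aw, k, p0), direct, tolerance = 1e-12)
  expect_error(transmuralPressure(-1, 1, 1, 10, 2), "positive")
})

test_that("tube-law monotonicity check passes for all default compartment classes", {
  cls <- defaultConfig()$coronary$micro$classes
  for (i in seq_len(nrow(cls)))
    expect_true(checkTubeLawMonotone(1, cls$aw[i], cls$k[i], cls$p0[i]))
})

test_that("compartment flow follows the volume-dependent Poiseuille law", {
  expect_equal(compartmentFlow(0, 1, 1, 2, 4), 0)
  ## reference point: V = V0, dp = dp0 -> q = q0_ref
  expect_equal(compartmentFlow(4, 1, 1, 2, 4), 2)
  ## halving the volume quarters the flow at fixed dp
  expect_equal(compartmentFlow(4, 0.5, 1, 2, 4), 0.5)
  ## linear in dp
  expect_equal(compartmentFlow(2, 1, 1, 2, 4), 1)
  expect_error(compartmentFlow(1, 1, -1, 2, 4), "config")
  expect_error(compartmentFlow(1, 0, 1, 2, 4), "positive")
})

test_that("intravascular pressure is transmural plus intramyocardial", {
  expect_equal(intravascularPressure(3, 0), 3)
  expect_equal(intravascularPressure(-2, 10), 8)
  ## additivity: a systolic IMP rise at fixed vessel volume raises p by
  ## the same amount
  expect_equal(intravascularPressure(1.5, 7) - intravascularPressure(1.5, 2), 5)
})

test_that("coronary tree assembly validates the AHA territory map", {
  seg <- defaultConfig()$segments
  net <- assembleTree(seg)
  ## LAD feeds 7 sub-branches, RCA 6 (incl. RV and the PDA column), LCx 5
  expect_equal(unname(net$mains["LAD"]), 7)
  expect_equal(unname(net$mains["RCA"]), 6)
  expect_equal(unname(net$mains["LCx"]), 5)
  expect_equal(net$n_chains, 54L)
  ## orphan segment -> error
  seg2 <- seg
  seg2$branch[3] <- NA
  expect_error(assembleTree(seg2), "orphan|unknown")
  ## 3-segment fixture: 3 sub-branches, 9 layer chains
  net3 <- assembleTree(fixtureConfig("unit")$segments)
  expect_equal(net3$n_chains, 9L)
  expect_equal(sum(net3$mains), 3)
})
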