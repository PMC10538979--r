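## Segment-level constitutive relations: strain, active/passive stress,
## wall tension.

test_that("natural fiber strain is logarithmic in midwall area", {
  expect_equal(fiberStrain(50, 50), 0)
  expect_equal(fiberStrain(exp(2) * 50, 50), 1)
  expect_equal(fiberStrain(1.21 * 80, 80), 0.5 * log(1.21), tolerance = 1e-12)
  expect_equal(fiberStrain(1.21 * 80, 80), 0.09531, tolerance = 1e-4)
  expect_error(fiberStrain(-1, 50), "geometry")
  expect_error(fiberStrain(50, 0), "geometry")
})

test_that("active stress is a twitch: zero before onset, longer sarcomeres stronger", {
  p <- defaultConfig()$sarcomere
  expect_equal(activeFiberStress(-0.05, 2.0, params = p), 0)
  expect_equal(activeFiberStress(-1e-9, 2.0, params = p), 0)
  ## Frank-Starling: a 10% longer sarcomere develops strictly greater
  ## peak stress over the whole twitch
  tt <- seq(0.005, p$TR + p$TD - 0.005, by = 0.005)
  s_short <- max(activeFiberStress(tt, 2.0, params = p))
  s_long <- max(activeFiberStress(tt, 2.2, params = p))
  expect_gt(s_long, s_short)
  ## zero again after the twitch
  expect_equal(activeFiberStress(p$TR + p$TD + 0.01, 2.0, params = p), 0)
  expect_error(activeFiberStress(0.1, 2.0, params = modifyList(p, list(TR = -1))),
               "config")
})

test_that("peak isometric active stress at reference length matches the configured scale", {
  ## independent numeric maximization of the twitch curve under isometric
  ## conditions (series element at its isometric stretch)
  p <- defaultConfig()$sarcomere
  peak <- stats::optimize(function(t) -activeFiberStress(t, p$Ls_ref, params = p),
                          c(0, p$TR + p$TD))
  expect_equal(-peak$objective, p$sig_act_max, tolerance = 0.01)
})

test_that("passive stress is zero at the zero-stress strain and increases monotonically", {
  p <- defaultConfig()$sarcomere
  eps0 <- log(p$Ls0 / p$Ls_ref)
  expect_equal(passiveFiberStress(eps0, p), 0)
  e <- eps0 + seq(0.01, 0.25, by = 0.01)
  s <- passiveFiberStress(e, p)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0))
  ## convexity above the reference
  expect_true(all(diff(diff(s)) > 0))
  ## independent evaluation of the configured law at eps0 + 0.1
  direct <- p$k_lin * 0.1 + p$sig_pas0 * expm1(p$k_pas * 0.1)
  expect_equal(passiveFiberStress(eps0 + 0.1, p), direct, tolerance = 1e-12)
  ## clamped variant is zero at/below the reference
  expect_equal(passiveFiberStress(eps0 - 0.1, p, compressive = FALSE), 0)
})

test_that("midwall tension is the thin-wall closure sigma*Vw/(2*Am)", {
  expect_equal(wallTension(0, 10, 50), 0)
  expect_equal(wallTension(80, 10, 50), 2 * wallTension(40, 10, 50))
  ## 40 kPa * 10 mL / (2 * 50 cm^2) = 4 kPa cm = 40 N/m
  expect_equal(wallTension(40, 10, 50) * 10, 40)
  expect_error(wallTension(40, 10, 0), "geometry")
})

test_that("stress decomposition sigma_f = sigma_act + sigma_pas holds on simulated beats", {
  m <- coroModel(fixtureConfig("unit"))
  sres <- stepSystem(m, nsteps = 400L)
  p <- m@config$sarcomere
  eps0 <- log(p$Ls0 / p$Ls_ref)
  sig_pas <- passiveFiberStress(sres$out$eps, p)
  resid <- abs(sres$out$sig - sres$out$sigact - sig_pas)
  expect_lt(max(resid / pmax(1, abs(sres$out$sig))), 1e-9)
  expect_true(all(sres$out$sigact >= 0))
})
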