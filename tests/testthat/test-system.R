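## Closed-loop system behavior on the reduced 3-segment fixture:
## conservation, convergence, self-consistency of the integrator.

fixture_model <- function() coroModel(fixtureConfig("unit"))

test_that("blood volume is conserved to well under 0.01% per beat", {
  m <- fixture_model()
  s1 <- stepSystem(m)                      # beat 1 (includes start-up)
  s2 <- stepSystem(m, s1$st)               # beat 2
  expect_lt(s1$out$summary$Vtot_drift, 1e-4)
  expect_lt(s2$out$summary$Vtot_drift, 1e-4)
})

test_that("the fixture reaches a periodic state with a single systolic peak per beat", {
  m <- fixture_model()
  st <- NULL
  for (b in 1:12) { r <- stepSystem(m, st); st <- r$st }
  p <- r$out$hemo[, 1]
  ## single systolic peak: one contiguous interval above half-max
  above <- p > (min(p) + 0.5 * (max(p) - min(p)))
  runs <- rle(above)
  expect_equal(sum(runs$values), 1L)
  ## left and right stroke volumes agree at the periodic state
  expect_equal(r$out$summary$SV_LV, r$out$summary$SV_RV,
               tolerance = 0.02 * r$out$summary$SV_LV)
})

test_that("TriSeg junction residuals are below tolerance on accepted states", {
  m <- fixture_model()
  s1 <- stepSystem(m)
  st <- s1$st
  par <- coroflow:::buildParams(m, st)
  ev <- coroflow:::cf_eval(par, st$y, st$t)
  ## residual oracle: independent evaluation of the algebraic system at
  ## the accepted state (tension-scaled residuals)
  expect_lt(max(abs(ev$g[1:2])), 1e-5)
})

test_that("halving the time step changes the converged stroke volume by < 0.5%", {
  cfg <- fixtureConfig("unit")
  run_sv <- function(dt) {
    cfg$solver$dt <- dt
    m <- coroModel(cfg)
    st <- NULL
    for (b in 1:10) { r <- stepSystem(m, st); st <- r$st }
    r$out$summary$SV_LV
  }
  sv1 <- run_sv(1e-3)
  sv2 <- run_sv(5e-4)
  expect_lt(abs(sv2 / sv1 - 1), 0.005)
})

test_that("delaying a segment's activation shifts its stress twitch by that delay", {
  ## two runs identical except one patch activated 40 ms later; compare
  ## the active-stress onset of that patch
  cfg <- fixtureConfig("unit")
  m <- coroModel(cfg)
  st1 <- coroflow:::newRunState(m)
  st2 <- coroflow:::newRunState(m)
  st2$t_act[2] <- st2$t_act[2] + 0.040
  r1 <- coroflow:::runBeat(m, st1)
  r2 <- coroflow:::runBeat(m, st2)
  onset <- function(sig) which(sig > 0.5)[1]
  o1 <- onset(r1$out$sigact[, 2])
  o2 <- onset(r2$out$sigact[, 2])
  expect_equal(o2 - o1, 40, tolerance = 3)
})

test_that("the unit fixture converges regulation with the default damping", {
  m <- fixture_model()
  r <- runResting(m, max_beats = 60, homeo = FALSE, regulate = TRUE,
                  anchor = TRUE, burnin = 4)
  expect_false(is.null(r$st$q0))
  lw <- m@config$coronary$layer_weights
  q0l <- outer(r$st$q0, lw / sum(lw))
  resid <- abs(r$qart / q0l - 1)
  fmax <- coroflow:::fDilMaxMatrix(m, r$st)
  at_bound <- r$st$fDil_art <= 0.5 + 1e-9 | r$st$fDil_art >= fmax - 1e-9
  expect_lt(max(resid[!at_bound], 0), 0.01)
})

test_that("identical configurations produce bit-identical beats (determinism)", {
  m <- fixture_model()
  a <- stepSystem(m)
  b <- stepSystem(m)
  expect_identical(a$out$hemo, b$out$hemo)
  expect_identical(a$out$sig, b$out$sig)
})
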