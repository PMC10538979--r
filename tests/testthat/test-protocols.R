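## Activation schedules, report/bullseye plumbing, remodeling updates.

test_that("LBBB schedule: RV at 139 ms, septum +25 ms, 65 ms span", {
  seg <- defaultConfig()$segments
  sch <- buildLbbbSchedule(seg)
  rv <- sch$t_act[sch$segment == 0]
  expect_equal(rv, 0.139)
  sep_ids <- seg$id[seg$wall == "SEP"]
  expect_equal(min(sch$t_act[sch$segment %in% sep_ids]), 0.139 + 0.025)
  ## total ventricular activation span
  expect_equal(max(sch$t_act) - rv, 0.065)
  ## five distinct onsets after the RV, 10 ms apart
  on <- sort(unique(sch$t_act[sch$segment != 0]))
  expect_equal(diff(on), rep(0.010, 4))
  ## septum before lateral: all septal onsets at or before all
  ## anterolateral/inferolateral onsets
  lat <- sch$t_act[sch$segment %in% c(5, 6, 11, 12, 16)]
  sep <- sch$t_act[sch$segment %in% sep_ids]
  expect_true(max(sep) < min(lat))
  ## generic reduced map still orders septum first
  sch3 <- buildLbbbSchedule(fixtureConfig("unit")$segments)
  expect_true(all(sch3$t_act >= 0.139))
})

test_that("bullseye export maps 17 LV segments with territories and rejects unknowns", {
  rep <- data.frame(segment = c(1:17, 0), wall = c(rep(c("LV", "SEP"), c(12, 5))[
    order(match(defaultConfig()$segments$wall[1:17], c("LV", "SEP")))], "RV"),
    stringsAsFactors = FALSE)
  ## build a minimal synthetic report from the segment table itself
  seg <- defaultConfig()$segments
  rep <- data.frame(segment = seg$id, name = seg$name, wall = seg$wall,
                    ring = seg$ring, territory = seg$branch,
                    MFR = seq(4.6, by = -0.05, length.out = 18),
                    stringsAsFactors = FALSE)
  be <- exportBullseye(rep, "MFR")
  expect_equal(nrow(be), 17L)
  expect_setequal(unique(be$territory), c("LAD", "LCx", "RCA", "PDA"))
  expect_error(exportBullseye(rep, "nope"), "unknown quantity")
  ## files round-trip
  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  exportBullseye(rep, "MFR", csv = csv, json = json)
  expect_equal(nrow(utils::read.csv(csv)), 17L)
  j <- jsonlite::read_json(json)
  expect_equal(j$quantity, "MFR")
})

test_that("wall-mass adaptation homogenizes demand per weight and caps at 25%", {
  ## fixed point: homogeneous demand per weight
  m0 <- rep(1, 5)
  d <- rep(2.5, 5)
  expect_equal(adaptWallMass(m0, d), m0)
  ## overloaded segments grow, underloaded shrink
  d2 <- c(3, 2, 2.5, 2.5, 2.5)
  m2 <- adaptWallMass(m0, d2, beta = 0.5)
  expect_gt(m2[1], 1); expect_lt(m2[2], 1)
  ## a segment at persistently twice the mean saturates at +25%
  m <- rep(1, 4)
  for (k in 1:60) m <- adaptWallMass(m, c(2, 1, 1, 1) * mean(c(2, 1, 1, 1)))
  expect_equal(m[1], 1.25)
  expect_true(all(m >= 0.75 & m <= 1.25))
  ## iteration shrinks the spread of demand per weight on a toy plant
  ## where demand density is fixed (d ~ 1/m per segment)
  m <- rep(1, 6)
  dfix <- c(1.3, 1.15, 1, 0.95, 0.85, 0.75)
  spread <- function(m) diff(range(dfix / m))
  s0 <- spread(m)
  for (k in 1:40) m <- adaptWallMass(m, dfix / m)
  expect_lt(spread(m), 0.2 * s0)
})

test_that("perfusion report exposes MFR as the element-wise flow ratio", {
  ## structural invariant checked on synthetic numbers
  q_rest <- c(0.5, 0.8); q_hyp <- c(2.1, 2.4)
  expect_equal(mfr(q_rest, q_hyp), q_hyp / q_rest)
})
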