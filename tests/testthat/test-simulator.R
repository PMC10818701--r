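test_that("simulation is deterministic in (scenario, seed)", {
  a <- simulate_scenario("walk_uneven", duration = 10, seed = 42)
  b <- simulate_scenario("walk_uneven", duration = 10, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_scenario("walk_uneven", duration = 10, seed = 43)
  expect_false(identical(a$ax, c$ax))
  expect_error(simulate_scenario("moonwalk"), class = "imufall_argument_error")
})

test_that("rest is quiet and all-safe; labels always match the phase plan", {
  r <- simulate_scenario("rest", duration = 120, seed = 1)
  expect_equal(nrow(r), 1200L)
  expect_true(all(r$label == 0L))
  expect_lt(stats::sd(svma(r$ax, r$ay, r$az)), 0.15)
  # label-phase consistency and conservation of time across kinds and seeds
  for (seed in 1:5) {
    for (kind in c("fall_height", "stumble_rear", "coma_abrupt", "stairs")) {
      rec <- simulate_scenario(kind, seed = seed)
      plan <- phase_plan(rec)
      expect_equal(max(plan$end), nrow(rec) * 0.1)
      for (ph in seq_len(nrow(plan))) {
        idx <- which(rec$t >= plan$start[ph] - 1e-9 &
                       rec$t < plan$end[ph] - 1e-9)
        expect_true(all(rec$label[idx] == plan$label[ph]),
                    info = sprintf("%s seed %d phase %s", kind, seed,
                                   plan$phase[ph]))
      }
    }
  }
})

test_that("a fall shows free-fall dip immediately followed by impact", {
  r <- simulate_fall(seed = 1)
  s <- svma(r$ax, r$ay, r$az)
  plan <- phase_plan(r)
  ff_end <- which(abs(r$t - plan$end[plan$phase == "freefall"]) < 1e-9)
  expect_lt(s[ff_end - 1], 0.35)       # below the free-fall ceiling
  expect_gt(s[ff_end], 3.5)            # next sample above the impact floor
  # fall labels span exactly free-fall + impact
  expect_equal(which(r$label == 1L),
               which(r$t >= plan$start[2] - 1e-9 & r$t < plan$end[3] - 1e-9))
})

test_that("fall morphology: phase-wise minima/maxima sit where they should", {
  r <- simulate_fall(seed = 1)
  s <- svma(r$ax, r$ay, r$az)
  plan <- phase_plan(r)
  in_phase <- function(name) {
    which(r$t >= plan$start[plan$phase == name] - 1e-9 &
            r$t < plan$end[plan$phase == name] - 1e-9)
  }
  expect_lt(min(s[in_phase("freefall")]), min(s[in_phase("sway")]))
  expect_true(which.max(s) %in% in_phase("impact"))
})

test_that("zero-noise free fall hits the configured mean exactly", {
  r <- simulate_fall(params = list(axis_noise_sd = 0,
                                   fall = list(freefall_sd = 0)),
                     seed = 7)
  s <- svma(r$ax, r$ay, r$az)
  plan <- phase_plan(r)
  ff <- which(r$t >= plan$start[2] - 1e-9 & r$t < plan$end[2] - 1e-9)
  expect_equal(unname(s[ff]), rep(0.15, length(ff)), tolerance = 1e-12)
})

test_that("stumbles last 2-3 s, tilt along their direction, and stay below falls", {
  for (seed in 1:5) {
    r <- simulate_stumble("fwd", seed = seed)
    span <- sum(r$label == 2L) * 0.1
    expect_gte(span, 2)
    expect_lte(span, 3)
  }
  fwd <- simulate_stumble("fwd", seed = 3)
  lft <- simulate_stumble("left", seed = 3)
  expect_gt(max(abs(fwd$pitch)), max(abs(fwd$roll)))   # pitch-dominant
  expect_gt(max(abs(lft$roll)), max(abs(lft$pitch)))   # roll-dominant
  quiet <- list(axis_noise_sd = 0, posture = list(drift_sd = 0))
  s_st <- simulate_stumble("rear", params = quiet, seed = 2)
  s_fa <- simulate_fall(params = quiet, seed = 2)
  expect_lt(max(svma(s_st$ax, s_st$ay, s_st$az)),
            max(svma(s_fa$ax, s_fa$ay, s_fa$az)))
})

test_that("a progressive coma ends in at least 30 s of labelled stillness", {
  r <- simulate_scenario("coma_progressive", seed = 1)
  runs <- rle(r$label)
  last <- length(runs$values)
  expect_equal(runs$values[last], 3L)
  expect_gte(runs$lengths[last] * 0.1, 30)
  s <- svma(r$ax, r$ay, r$az)
  still <- s[(nrow(r) - runs$lengths[last] + 1):nrow(r)]
  expect_lt(stats::var(still), 1e-3)
})

test_that("cohort simulation is seeded per participant and sized per plan", {
  plan <- data.frame(kind = "rest", duration = 2)
  ds1 <- simulate_cohort(2, seed = 10, plan = plan)
  expect_equal(nrow(ds1$recordings[[1]]), 20L)
  ds2 <- simulate_cohort(2, seed = 10, plan = plan)
  expect_identical(as.data.frame(ds1$recordings[[2]]),
                   as.data.frame(ds2$recordings[[2]]))
  expect_false(identical(ds1$recordings[[1]]$ax, ds1$recordings[[2]]$ax))
  expect_error(simulate_cohort(0), class = "imufall_argument_error")
  expect_error(simulate_cohort(1, plan = plan[0, ]),
               class = "imufall_argument_error")
})

test_that("the default session plan carries the study's event mix", {
  plan <- default_session_plan()
  expect_equal(sum(plan$kind == "fall_height"), 2L)
  expect_equal(sum(startsWith(plan$kind, "stumble_")), 4L)
  expect_equal(sum(startsWith(plan$kind, "coma_")), 2L)
  r <- simulate_cohort(1, seed = 2)$recordings[[1]]
  expect_equal(nrow(r), sum(plan$duration) * 10)
  ev <- truth_events(r)
  expect_equal(sum(ev$type == 1L), 2L)
  expect_equal(sum(ev$type == 2L), 4L)
  expect_equal(sum(ev$type == 3L), 2L)
})

test_that("phase plans survive the JSON sidecar round trip", {
  r <- simulate_fall(seed = 4)
  f <- withr::local_tempfile(fileext = ".plan.json")
  write_phase_plan(r, f)
  plan2 <- read_phase_plan(f)
  expect_equal(plan2$phase, phase_plan(r)$phase)
  expect_equal(plan2$start, phase_plan(r)$start)
  expect_equal(plan2$label, phase_plan(r)$label)
})
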