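test_that("LVDFT/RR and IVMD are the defining arithmetic", {
  expect_equal(lvdft_rr(400, rr = 1000), 40.0)
  expect_equal(lvdft_rr(500, rr = 1000), 50.0)
  expect_equal(lvdft_rr(0, rr = 1000), 0.0)
  expect_error(lvdft_rr(400, rr = 0), "positive")

  expect_equal(ivmd(140, 100), 40)
  expect_equal(ivmd(100, 100), 0)
  expect_equal(ivmd(90, 120), -30)
  expect_error(ivmd(140, NA), "required")

  tm <- default_timing()
  expect_equal(lvdft_rr(tm), 100 * 350 / 860)
  expect_equal(ivmd(tm), 40)
})

test_that("SPWMD is the signed posterior-minus-septal peak delay", {
  t <- seq(0, 600, by = 5)
  sep <- list(times = t, values = 8 * exp(-((t - 150) / 40)^2 / 2))
  post <- list(times = t, values = 8 * exp(-((t - 230) / 40)^2 / 2))
  expect_equal(spwmd(sep, post), 80)
  expect_equal(spwmd(sep, sep), 0)

  pair <- make_motion_pair(-44, dt = 1)
  expect_equal(spwmd(pair$septal, pair$posterior), -44)

  flat <- list(times = t, values = rep(0, length(t)))
  res <- spwmd(sep, flat)
  expect_true(is.na(res))
  expect_false(attr(res, "assessable"))
})

test_that("a synchronous velocity set gives zero delays and a single outlier the range", {
  tm <- default_timing()
  ids <- velocity_segment_ids()
  sync <- make_velocity_set(setNames(rep(150, 12), ids), tm)
  panel <- timing_panel(sync, tm)
  expect_equal(unname(panel$view_max_delay), c(0, 0, 0))
  expect_equal(panel$max_time_delay, 0)
  expect_equal(panel$opposing_wall_delay, 0)
  expect_equal(panel$yu_index, 0)

  ttp <- setNames(rep(100, 12), ids)
  ttp[12] <- 260
  one_late <- make_velocity_set(ttp, tm)
  expect_equal(timing_panel(one_late, tm)$max_time_delay, 160)
})

test_that("panel statistics match the exhaustive-pair oracle on random sets", {
  tm <- default_timing()
  ids <- velocity_segment_ids()
  parts <- strsplit(ids, "_")
  view <- vapply(parts, `[`, character(1), 1)
  wall <- vapply(parts, `[`, character(1), 2)
  level <- vapply(parts, `[`, character(1), 3)
  set.seed(61)
  for (i in 1:200) {
    ttp <- setNames(sample(seq(50, 300, by = 5), 12, replace = TRUE), ids)
    panel <- timing_panel(make_velocity_set(ttp, tm), tm)
    orc <- oracle_panel(panel$time_to_peak, view, wall, level)
    expect_equal(panel$max_time_delay, orc$max_time_delay)
    expect_equal(unname(panel$view_max_delay),
                 unname(orc$view_max_delay[names(panel$view_max_delay)]))
    expect_equal(panel$opposing_wall_delay, orc$opposing_wall_delay)
    expect_equal(panel$yu_index, orc$yu_index)
    expect_gte(panel$max_time_delay, max(panel$view_max_delay))
    expect_gte(panel$max_time_delay, panel$opposing_wall_delay)
  }
})

test_that("Yu index denominator option matches the two SD definitions", {
  tm <- default_timing()
  ids <- velocity_segment_ids()
  set.seed(62)
  ttp <- setNames(sample(seq(60, 280, by = 5), 12), ids)
  vel <- make_velocity_set(ttp, tm)
  x <- timing_panel(vel, tm)$time_to_peak
  expect_equal(timing_panel(vel, tm, sd_type = "sample")$yu_index, sd(x))
  expect_equal(timing_panel(vel, tm, sd_type = "population")$yu_index,
               sd(x) * sqrt(11 / 12))
  expect_error(timing_panel(vel[1:11], tm), "12 velocity traces")
})

test_that("responder classification uses an inclusive 15% LVESV reduction", {
  r1 <- classify_responder(200, 170)
  expect_true(r1$responder)
  expect_equal(r1$delta_lvesv_pct, 15.0)

  r2 <- classify_responder(200, 171)
  expect_false(r2$responder)
  expect_equal(r2$delta_lvesv_pct, 14.5)

  r3 <- classify_responder(200, 244)
  expect_false(r3$responder)
  expect_equal(r3$delta_lvesv_pct, -22.0)

  expect_error(classify_responder(0, 100), "positive")
})
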