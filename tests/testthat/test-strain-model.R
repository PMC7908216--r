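test_that("trace and timing constructors validate their invariants", {
  expect_error(strain_trace(c(0, 10, 10), c(0, -1, -2), "4CH", "septal", "mid"),
               "strictly increasing")
  expect_error(strain_trace(c(0, 5, 10), c(0, NA, -2), "4CH", "septal", "mid"),
               "finite")
  expect_error(strain_trace(c(0, 5), c(0, -1), "5CH", "septal", "mid"))
  expect_error(cardiac_timing(avc = -10, aortic_preejection = 140,
                              pulmonary_preejection = 100,
                              lv_filling_time = 350, rr = 860),
               "positive")
  expect_error(cardiac_timing(avc = 300, aortic_preejection = 140,
                              pulmonary_preejection = 100,
                              lv_filling_time = 900, rr = 860),
               "RR")
  tm <- default_timing()
  expect_equal(ejection_length(tm), tm$avc)
})

test_that("view sets enforce wall/view consistency and basal/mid levels", {
  tm <- default_timing()
  t <- seq(0, 500, by = 5)
  tr4 <- strain_trace(t, -t / 50, "4CH", "septal", "mid")
  tr2 <- strain_trace(t, -t / 50, "2CH", "anterior", "basal")
  apex <- strain_trace(t, -t / 50, "4CH", "septal", "apical")
  expect_error(view_strain_set("4CH", list(tr2), list(tr4), tm), "tagged view")
  expect_error(view_strain_set("4CH", list(apex), list(tr4), tm), "basal/mid")
  expect_error(view_strain_set("4CH", list(tr4, tr4, tr4), list(tr4), tm),
               "at most two")
})

test_that("find_shortening_peak rejects monotone and flat curves, finds the deepest dip", {
  t <- seq(0, 300, by = 5)
  ramp <- strain_trace(t, -15 * t / 300, "4CH", "septal", "mid")
  expect_null(find_shortening_peak(ramp, c(0, 300), 1))
  flat <- strain_trace(t, rep(0, length(t)), "4CH", "septal", "mid")
  expect_null(find_shortening_peak(flat, c(0, 300), 1))

  tt <- seq(0, 400, by = 5)
  v <- -8 * exp(-((tt - 100) / 30)^2 / 2) - 10 * exp(-((tt - 350) / 30)^2 / 2)
  two_dips <- strain_trace(tt, v, "4CH", "septal", "mid")
  pk <- find_shortening_peak(two_dips, c(0, 400), 1)
  expect_equal(pk$time, 350)
  expect_lt(pk$value, -9.9)
  orc <- oracle_shortening_peak(tt, v, 0, 400, 1)
  expect_equal(pk$time, orc$time)
  expect_equal(pk$value, orc$value)

  expect_error(find_shortening_peak(two_dips, c(-50, 400), 1),
               "outside trace support")
})

test_that("find_shortening_peak matches the exhaustive oracle on random traces", {
  set.seed(101)
  for (i in 1:60) {
    tr <- random_strain_trace()
    for (prom in c(0, 1, 3)) {
      got <- find_shortening_peak(tr, range(tr$times), prom)
      orc <- oracle_shortening_peak(tr$times, tr$values,
                                    tr$times[1], tr$times[length(tr$times)],
                                    prom)
      if (is.null(orc)) {
        expect_null(got)
      } else {
        expect_equal(got$time, orc$time)
        expect_equal(got$value, orc$value)
        expect_equal(got$prominence, orc$prominence)
      }
    }
  }
})

test_that("raising the prominence threshold never turns an absent peak present", {
  set.seed(202)
  for (i in 1:40) {
    tr <- random_strain_trace()
    lo <- find_shortening_peak(tr, range(tr$times), 1)
    hi <- find_shortening_peak(tr, range(tr$times), 4)
    if (is.null(lo)) expect_null(hi)
    if (!is.null(hi)) expect_false(is.null(lo))
  }
})

test_that("find_stretch_max returns the most positive sample, earliest on ties", {
  t <- seq(0, 200, by = 5)
  rising <- strain_trace(t, 3 * exp(-((t - 60) / 25)^2 / 2) - 0.01 * t,
                         "4CH", "lateral", "basal")
  s <- find_stretch_max(rising, c(0, 200))
  expect_equal(s$time, 60)
  expect_equal(s$value, 3 - 0.6, tolerance = 1e-6)

  allneg <- strain_trace(t, -5 - t / 100, "4CH", "lateral", "basal")
  expect_equal(find_stretch_max(allneg, c(0, 200))$value, -5)

  const <- strain_trace(t, rep(0, length(t)), "4CH", "lateral", "basal")
  expect_equal(find_stretch_max(const, c(0, 200))$time, 0)

  set.seed(303)
  for (i in 1:30) {
    tr <- random_strain_trace()
    got <- find_stretch_max(tr, range(tr$times))
    expect_equal(got$time, oracle_argmax_time(tr$times, tr$values,
                                              tr$times[1], max(tr$times)))
  }
})

test_that("time_to_peak_velocity finds the ejection-phase argmax, earliest on ties", {
  tm <- default_timing()
  t <- seq(0, 400, by = 5)
  bump <- velocity_trace(t, 5 * exp(-((t - 120) / 30)^2 / 2), "4CH", "septal",
                         "basal")
  expect_equal(time_to_peak_velocity(bump, tm), 120)

  two <- velocity_trace(t, 4 * exp(-((t - 100) / 20)^2 / 2) +
                          4 * exp(-((t - 200) / 20)^2 / 2), "4CH", "septal",
                        "basal")
  expect_equal(time_to_peak_velocity(two, tm), 100)

  short <- velocity_trace(seq(0, 200, 5), rnorm(41), "4CH", "septal", "basal")
  expect_error(time_to_peak_velocity(short, tm), "outside trace support")

  set.seed(404)
  for (i in 1:30) {
    v <- rnorm(100)
    tr <- velocity_trace(seq(0, 495, 5), v, "4CH", "septal", "basal")
    expect_equal(time_to_peak_velocity(tr, tm),
                 oracle_argmax_time(tr$times, v, 0, tm$avc))
  }
})

test_that("global_peak_shortening_time is the exhaustive argmin, earliest on ties", {
  t <- seq(0, 500, by = 5)
  v <- -18 * exp(-((t - 380) / 40)^2 / 2)
  tr <- strain_trace(t, v, "4CH", "lateral", "basal")
  expect_equal(global_peak_shortening_time(tr, 500), 380)

  plateau <- c(seq(0, -10, length.out = 51), rep(-10, 10), seq(-10, 0, length.out = 40))
  trp <- strain_trace(seq(0, by = 5, length.out = length(plateau)), plateau,
                      "4CH", "lateral", "basal")
  expect_equal(global_peak_shortening_time(trp, 500), 250)

  set.seed(505)
  for (i in 1:30) {
    tr <- random_strain_trace()
    expect_equal(global_peak_shortening_time(tr, max(tr$times)),
                 oracle_argmin_time(tr$times, tr$values, 0, max(tr$times)))
  }
})

test_that("detected peak times are stable under finer uniform resampling", {
  f <- function(t) -12 * exp(-((t - 150) / 35)^2 / 2) - 3 * t / 500 +
    2 * exp(-((t - 60) / 25)^2 / 2)
  coarse_t <- seq(0, 500, by = 5)
  fine_t <- seq(0, 500, by = 1)
  coarse <- strain_trace(coarse_t, f(coarse_t), "4CH", "septal", "mid")
  fine <- strain_trace(fine_t, f(fine_t), "4CH", "septal", "mid")
  pc <- find_shortening_peak(coarse, c(0, 500), 2)
  pf <- find_shortening_peak(fine, c(0, 500), 2)
  expect_lte(abs(pc$time - pf$time), 5)
  expect_lte(abs(find_stretch_max(coarse, c(0, 300))$time -
                   find_stretch_max(fine, c(0, 300))$time), 5)
  expect_lte(abs(global_peak_shortening_time(coarse, 500) -
                   global_peak_shortening_time(fine, 500)), 5)
})
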