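test_that("worked view examples score 3, 2 and 3 points", {
  # 4CH: early mid-septal peak just past 70% of ejection, lateral basal
  # prestretch +2.5%, lateral peak contraction 60 ms after AVC
  v4 <- make_view("4CH", c(1, 1, 0, 1), prestretch_amp = 2.5,
                  early_peak_fraction = 0.75)
  b4 <- component_bits(score_view(v4))
  expect_equal(unname(b4), c(1, 1, 0, 1))
  expect_equal(sum(b4), 3)

  # 2CH: anterior basal contraction at 85% of ejection, no inferior
  # prestretch, inferior peak 50 ms after AVC
  v2 <- make_view("2CH", c(1, 0, 0, 1), early_peak_fraction = 0.85,
                  late_peak_delay = 50)
  b2 <- component_bits(score_view(v2))
  expect_equal(unname(b2), c(1, 0, 0, 1))
  expect_equal(sum(b2), 2)

  # 3CH: anteroseptal basal peak at 80% of ejection, posterior basal
  # prestretch, posterior peak after AVC
  v3 <- make_view("3CH", c(1, 1, 0, 1), early_peak_fraction = 0.80)
  b3 <- component_bits(score_view(v3))
  expect_equal(unname(b3), c(1, 1, 0, 1))
  expect_equal(sum(b3), 3)
})

test_that("RSPI spans 0 to 12 and the cutoff is boundary-inclusive", {
  all_bits <- list("4CH" = c(1, 1, 1, 1), "2CH" = c(1, 1, 1, 1),
                   "3CH" = c(1, 1, 1, 1))
  pmax <- make_patient("max", bits_by_view = all_bits, seed = 11)
  rmax <- compute_rspi(pmax)
  expect_equal(rmax$total, 12L)
  expect_true(rmax$high)

  psync <- make_patient("sync", target_score = 0, seed = 12)
  rsync <- compute_rspi(psync)
  expect_equal(rsync$total, 0L)
  expect_false(rsync$high)

  expect_true(classify_high_rspi(7))
  expect_false(classify_high_rspi(6))
  expect_true(classify_high_rspi(12))
  expect_error(classify_high_rspi(13), "0..12")
  expect_error(classify_high_rspi(-1), "0..12")
})

test_that("the 70% criterion is only scored when an early peak exists (c3 <= c1)", {
  set.seed(21)
  for (i in 1:50) {
    v <- sample(c("4CH", "2CH", "3CH"), 1)
    cv <- score_view(make_view(v, random_bits(), noise_sd = 0.8))
    b <- component_bits(cv)
    expect_lte(b[["c3"]], b[["c1"]])
  }
  expect_error(make_view("4CH", c(0, 0, 1, 0)), "c3 = 1 requires c1 = 1")
})

test_that("raising detection thresholds never raises the score", {
  set.seed(22)
  strict <- scoring_config(contraction_prominence = 5, prestretch_threshold = 3)
  for (i in 1:30) {
    v <- sample(c("4CH", "2CH", "3CH"), 1)
    vs <- make_view(v, random_bits(), noise_sd = 0.6)
    expect_lte(sum(component_bits(score_view(vs, strict))),
               sum(component_bits(score_view(vs))))
  }
})

test_that("the total is invariant under view order and equals the per-view sum", {
  bits <- list("4CH" = c(1, 1, 0, 1), "2CH" = c(1, 0, 0, 1),
               "3CH" = c(1, 1, 0, 1))
  p <- make_patient("perm", bits_by_view = bits, seed = 31)
  r <- compute_rspi(p)
  expect_equal(r$total, 8L)

  p_rev <- p
  p_rev$views <- p$views[c("3CH", "2CH", "4CH")]
  expect_equal(compute_rspi(p_rev)$total, r$total)

  indep <- sum(vapply(p$views, function(vs) sum(component_bits(score_view(vs))),
                      numeric(1)))
  expect_equal(r$total, as.integer(indep))
})

test_that("missing walls and missing views degrade to zero points with flags", {
  tm <- default_timing()
  t <- seq(0, 500, by = 5)
  late <- strain_trace(t, -10 * t / 500, "4CH", "lateral", "basal")
  vs <- view_strain_set("4CH", list(), list(late), tm)
  cv <- score_view(vs)
  expect_false(cv$assessable)
  expect_equal(sum(component_bits(cv)), 0)

  p <- make_patient("one_view", bits_by_view = list("4CH" = c(1, 1, 1, 1)),
                    seed = 41)
  r <- compute_rspi(p)
  expect_equal(r$total, 4L)
  expect_setequal(r$missing_views, c("2CH", "3CH"))
  expect_error(patient_record("none", views = list(), timing = tm), "non-empty")
})

test_that("the 70% ejection fraction constant is fixed", {
  expect_error(scoring_config(early_fraction = 0.6), "fixed constant")
  expect_silent(scoring_config(early_fraction = 0.70))
})

test_that("data-driven wall assignment recovers swapped roles", {
  # Build a 4CH view whose 'late' (lateral) wall actually carries the early
  # peak and whose 'early' wall shows the post-AVC peak: anatomic roles score
  # it differently from the data-driven mode, which swaps the walls back.
  tm <- default_timing()
  E <- ejection_length(tm)
  t <- seq(0, 495, by = 5)
  early_shape <- -15 * exp(-((t - 0.45 * E) / 25)^2 / 2) - 0.4 * t / 495
  late_shape <- -15 * exp(-((t - tm$avc - 60) / 35)^2 / 2) -
    3 * plogis((t - 0.08 * E) / (E / 30))
  vs <- view_strain_set(
    "4CH",
    early_wall = list(strain_trace(t, late_shape, "4CH", "septal", "mid")),
    late_wall = list(strain_trace(t, early_shape, "4CH", "lateral", "basal")),
    timing = tm
  )
  anat <- score_view(vs)
  swapped <- score_view(vs, scoring_config(wall_assignment = "data_driven"))
  expect_equal(unname(component_bits(anat)), c(0, 0, 0, 0))
  expect_equal(unname(component_bits(swapped)), c(1, 0, 1, 1))
  expect_true(swapped$detail$walls_swapped)
})
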