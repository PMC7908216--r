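#' Diastolic filling fraction LVDFT/RR
#'
#' Atrioventricular dyssynchrony measure: LV diastolic filling time as a
#' percentage of the RR interval. Values below 40% are the conventional
#' abnormal range.
#'
#' @param timing A [cardiac_timing()], or a filling time in ms when `rr` is
#'   given.
#' @param rr Optional RR interval (ms) when `timing` is a plain filling time.
#' @return Percentage (0-100 scale).
#' @export
lvdft_rr <- function(timing, rr = NULL) {
  if (inherits(timing, "cardiac_timing")) {
    ft <- timing$lv_filling_time
    rr <- timing$rr
  } else {
    ft <- as.numeric(timing)
    if (is.null(rr)) stop("rr required when timing is a plain filling time",
                          call. = FALSE)
  }
  if (is.na(rr) || rr <= 0) stop("RR interval must be positive", call. = FALSE)
  if (is.na(ft) || ft < 0) stop("filling time must be non-negative", call. = FALSE)
  100 * ft / rr
}

#' Interventricular mechanical delay (IVMD)
#'
#' Signed difference between aortic and pulmonary pre-ejection times; values
#' >= 40 ms are the conventional abnormal range.
#'
#' @param timing A [cardiac_timing()], or the aortic pre-ejection time (ms)
#'   when `pulmonary` is given.
#' @param pulmonary Optional pulmonary pre-ejection time (ms).
#' @return Delay in ms (signed).
#' @export
ivmd <- function(timing, pulmonary = NULL) {
  if (inherits(timing, "cardiac_timing")) {
    a <- timing$aortic_preejection
    p <- timing$pulmonary_preejection
  } else {
    a <- as.numeric(timing)
    p <- pulmonary
    if (is.null(p)) stop("pulmonary pre-ejection time required", call. = FALSE)
  }
  if (anyNA(c(a, p))) stop("both pre-ejection times are required", call. = FALSE)
  a - p
}

#' Septal-to-posterior wall motion delay (SPWMD)
#'
#' Delay between the peak inward motion of the septum and of the posterior
#' wall on M-mode displacement traces (positive values = posterior wall
#' peaks later; post-CRT reversal gives negative values). Traces encode
#' inward displacement as positive values; the peak inward time is the global
#' maximum, ties to the earliest sample.
#'
#' @param septal_motion,posterior_motion Lists with numeric `times` (ms) and
#'   `values` (inward displacement, arbitrary units), or `segment_trace`
#'   objects.
#' @param flat_tol Amplitude (max - min) at or below which a trace is deemed
#'   flat / akinetic and the delay not assessable. Default 1e-8.
#' @return Delay in ms, or `NA` with attribute `assessable = FALSE` when
#'   either trace is flat.
#' @export
spwmd <- function(septal_motion, posterior_motion, flat_tol = 1e-8) {
  peak_time <- function(tr) {
    times <- as.numeric(tr$times)
    v <- as.numeric(tr$values)
    if (length(times) != length(v) || any(diff(times) <= 0)) {
      stop("motion trace must have strictly increasing times", call. = FALSE)
    }
    if (diff(range(v)) <= flat_tol) return(NA_real_)
    times[which.max(v)]
  }
  ts <- peak_time(septal_motion)
  tp <- peak_time(posterior_motion)
  if (is.na(ts) || is.na(tp)) {
    return(structure(NA_real_, assessable = FALSE))
  }
  tp - ts
}

#' Time-to-peak velocity dyssynchrony panel
#'
#' Computes the classical intraventricular dyssynchrony statistics from the
#' 12 basal/mid tissue-velocity traces (two opposing walls x basal/mid in
#' each of the three apical views): the per-view maximal intraventricular
#' delay (range of the four time-to-peaks in that view), the maximum time
#' delay over all 12 segments, the maximal opposing-wall delay (largest
#' level-matched |basal-basal| or |mid-mid| difference between the two walls
#' of a view), and the Yu index (standard deviation of the 12 time-to-peaks).
#'
#' @param velocities List of exactly 12 [velocity_trace()] objects: for each
#'   apical view, two walls with one basal and one mid trace each.
#' @param timing A [cardiac_timing()] (ejection window for the peak search).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`
#'   (n) for the Yu index.
#' @return List with `time_to_peak` (named vector, ms), `view_max_delay`
#'   (named per view), `max_time_delay`, `opposing_wall_delay`, `yu_index`,
#'   and `pairing = "level-matched"`.
#' @export
timing_panel <- function(velocities, timing, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(timing, "cardiac_timing"))
  if (!is.list(velocities) || length(velocities) != 12L) {
    stop("timing_panel needs exactly 12 velocity traces", call. = FALSE)
  }
  for (tr in velocities) {
    if (!inherits(tr, "velocity_trace")) {
      stop("all entries must be velocity_trace objects", call. = FALSE)
    }
  }
  meta <- data.frame(
    view = vapply(velocities, `[[`, character(1), "view"),
    wall = vapply(velocities, `[[`, character(1), "wall"),
    level = vapply(velocities, `[[`, character(1), "level"),
    segment_id = vapply(velocities, `[[`, character(1), "segment_id"),
    stringsAsFactors = FALSE
  )
  for (v in APICAL_VIEWS) {
    sub <- meta[meta$view == v, ]
    if (nrow(sub) != 4L || length(unique(sub$wall)) != 2L ||
        !setequal(unique(sub$level), c("basal", "mid"))) {
      stop(sprintf(
        "view %s must contribute 4 traces: two walls x basal/mid", v),
        call. = FALSE)
    }
  }
  ttp <- vapply(velocities, time_to_peak_velocity, numeric(1), timing = timing)
  names(ttp) <- meta$segment_id

  view_max <- vapply(APICAL_VIEWS, function(v) {
    x <- ttp[meta$view == v]
    max(x) - min(x)
  }, numeric(1))

  opp <- 0
  for (v in APICAL_VIEWS) {
    sub <- which(meta$view == v)
    walls <- unique(meta$wall[sub])
    for (lev in c("basal", "mid")) {
      a <- ttp[sub][meta$wall[sub] == walls[1L] & meta$level[sub] == lev]
      b <- ttp[sub][meta$wall[sub] == walls[2L] & meta$level[sub] == lev]
      opp <- max(opp, abs(a - b))
    }
  }

  yu <- if (sd_type == "sample") {
    stats::sd(ttp)
  } else {
    sqrt(mean((ttp - mean(ttp))^2))
  }

  list(time_to_peak = ttp,
       view_max_delay = view_max,
       max_time_delay = max(ttp) - min(ttp),
       opposing_wall_delay = unname(opp),
       yu_index = yu,
       pairing = "level-matched")
}

#' Volumetric CRT responder classification
#'
#' A patient responds to CRT when the LV end-systolic volume falls by at
#' least 15% between baseline and follow-up (reverse remodelling). The
#' boundary is inclusive. Negative reductions (volume increase) occur and
#' classify as non-response.
#'
#' @param lvesv_base Baseline LVESV (mL), > 0. Vectorized.
#' @param lvesv_fu Follow-up LVESV (mL).
#' @param cutoff_pct Reduction cutoff in percent. Default 15.
#' @return List with `responder` (logical) and `delta_lvesv_pct` (percent
#'   reduction, positive = volume decreased).
#' @export
classify_responder <- function(lvesv_base, lvesv_fu, cutoff_pct = 15) {
  if (anyNA(lvesv_base) || any(lvesv_base <= 0)) {
    stop("baseline LVESV must be positive", call. = FALSE)
  }
  delta <- 100 * (lvesv_base - lvesv_fu) / lvesv_base
  list(responder = delta >= cutoff_pct, delta_lvesv_pct = delta)
}

#' Full dyssynchrony index panel for a patient
#'
#' Convenience wrapper assembling LVDFT/RR, IVMD, the time-to-peak velocity
#' panel (when velocity traces are present), the septal-flash pass-through
#' flag and the responder status into one row-like list.
#'
#' @param patient A [patient_record()].
#' @param sd_type Yu index denominator, see [timing_panel()].
#' @return Named list of index values (`NA` where the required inputs are
#'   absent).
#' @export
index_panel <- function(patient, sd_type = "sample") {
  stopifnot(inherits(patient, "patient_record"))
  tp <- if (!is.null(patient$velocity_traces)) {
    timing_panel(patient$velocity_traces, patient$timing, sd_type = sd_type)
  } else NULL
  resp <- if (!is.na(patient$lvesv_base) && !is.na(patient$lvesv_fu)) {
    classify_responder(patient$lvesv_base, patient$lvesv_fu)
  } else list(responder = NA, delta_lvesv_pct = NA_real_)
  list(
    id = patient$id,
    lvdft_rr = lvdft_rr(patient$timing),
    ivmd = ivmd(patient$timing),
    view_max_delay_4ch = if (is.null(tp)) NA_real_ else tp$view_max_delay[["4CH"]],
    view_max_delay_2ch = if (is.null(tp)) NA_real_ else tp$view_max_delay[["2CH"]],
    view_max_delay_3ch = if (is.null(tp)) NA_real_ else tp$view_max_delay[["3CH"]],
    max_time_delay = if (is.null(tp)) NA_real_ else tp$max_time_delay,
    opposing_wall_delay = if (is.null(tp)) NA_real_ else tp$opposing_wall_delay,
    yu_index = if (is.null(tp)) NA_real_ else tp$yu_index,
    septal_flash = patient$septal_flash,
    responder = resp$responder,
    delta_lvesv_pct = resp$delta_lvesv_pct
  )
}
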