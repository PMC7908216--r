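#' @keywords internal
"_PACKAGE"

APICAL_VIEWS <- c("4CH", "2CH", "3CH")
SEGMENT_LEVELS <- c("basal", "mid", "apical")

## Fixed anatomical wall roles per apical view: the early-activated wall is the
## (antero)septum where one exists; the 2-chamber view has no septum, so the
## anterior wall takes the early role there.
VIEW_WALLS <- list(
  "4CH" = c(early = "septal",       late = "lateral"),
  "2CH" = c(early = "anterior",     late = "inferior"),
  "3CH" = c(early = "anteroseptal", late = "posterior")
)

#' Segmental longitudinal strain trace
#'
#' One myocardial segment's longitudinal strain curve sampled over a single
#' beat. Time is in milliseconds from QRS onset (the zero reference for all
#' timing in this package); strain is in percent with negative values meaning
#' shortening, the standard speckle-tracking convention.
#'
#' @param times Numeric vector of sample times (ms from QRS onset), strictly
#'   increasing.
#' @param values Numeric vector of strain values (%), same length as `times`,
#'   all finite.
#' @param view Apical view label, one of `"4CH"`, `"2CH"`, `"3CH"`.
#' @param wall Anatomical wall name (e.g. `"septal"`, `"lateral"`).
#' @param level Segment level, one of `"basal"`, `"mid"`, `"apical"`. Scoring
#'   uses basal and mid segments only.
#' @param segment_id Optional segment label within the 18-segment model.
#' @return An object of class `strain_trace`.
#' @export
strain_trace <- function(times, values, view, wall, level,
                         segment_id = paste(wall, level, sep = "_")) {
  new_trace(times, values, view, wall, level, segment_id, class = "strain_trace")
}

#' Segmental myocardial velocity trace
#'
#' Tissue-velocity curve for one segment (tissue Doppler), used for the
#' time-to-peak systolic velocity dyssynchrony indexes. Units are any
#' consistent velocity unit; only peak timing is used.
#'
#' @inheritParams strain_trace
#' @param values Numeric vector of myocardial velocities.
#' @return An object of class `velocity_trace`.
#' @export
velocity_trace <- function(times, values, view, wall, level,
                           segment_id = paste(wall, level, sep = "_")) {
  new_trace(times, values, view, wall, level, segment_id, class = "velocity_trace")
}

new_trace <- function(times, values, view, wall, level, segment_id, class) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 2L) {
    stop("trace needs at least two samples", call. = FALSE)
  }
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (anyNA(times) || any(diff(times) <= 0)) {
    stop(sprintf("segment '%s': times must be strictly increasing", segment_id),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop(sprintf("segment '%s': values must be finite", segment_id), call. = FALSE)
  }
  view <- match.arg(view, APICAL_VIEWS)
  level <- match.arg(level, SEGMENT_LEVELS)
  structure(
    list(times = times, values = values, view = view, wall = as.character(wall),
         level = level, segment_id = as.character(segment_id)),
    class = c(class, "segment_trace")
  )
}

#' @export
print.segment_trace <- function(x, ...) {
  kind <- if (inherits(x, "strain_trace")) "strain" else "velocity"
  cat(sprintf("<%s trace> %s %s/%s (%s), %d samples over [%g, %g] ms\n",
              kind, x$view, x$wall, x$level, x$segment_id,
              length(x$times), x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

#' Cardiac timing annotations for one beat
#'
#' Timing intervals measured from QRS onset (time zero). The systolic ejection
#' phase is the interval from QRS onset to aortic valve closure (AVC); its
#' length `avc - qrs_onset` is the denominator of the 70%-of-ejection
#' criterion.
#'
#' @param avc Aortic valve closure time (ms from QRS onset), > 0.
#' @param aortic_preejection Aortic pre-ejection time (ms), > 0.
#' @param pulmonary_preejection Pulmonary pre-ejection time (ms), > 0.
#' @param lv_filling_time LV diastolic filling time (ms), > 0 and < `rr`.
#' @param rr RR interval (ms), > 0.
#' @param qrs_onset QRS onset (ms); fixed 0 by convention.
#' @return An object of class `cardiac_timing`.
#' @export
cardiac_timing <- function(avc, aortic_preejection, pulmonary_preejection,
                           lv_filling_time, rr, qrs_onset = 0) {
  vals <- c(avc = avc, aortic_preejection = aortic_preejection,
            pulmonary_preejection = pulmonary_preejection,
            lv_filling_time = lv_filling_time, rr = rr)
  if (anyNA(vals) || any(vals <= 0)) {
    bad <- names(vals)[is.na(vals) | vals <= 0]
    stop("cardiac_timing: intervals must be positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (qrs_onset != 0) {
    stop("qrs_onset is the time reference and must be 0", call. = FALSE)
  }
  if (lv_filling_time >= rr) {
    stop("lv_filling_time must be shorter than the RR interval", call. = FALSE)
  }
  structure(
    list(qrs_onset = 0, avc = as.numeric(avc),
         aortic_preejection = as.numeric(aortic_preejection),
         pulmonary_preejection = as.numeric(pulmonary_preejection),
         lv_filling_time = as.numeric(lv_filling_time), rr = as.numeric(rr)),
    class = "cardiac_timing"
  )
}

#' Ejection phase length (ms)
#'
#' @param timing A [cardiac_timing()] object.
#' @return The systolic ejection phase length in ms (QRS onset to AVC).
#' @export
ejection_length <- function(timing) {
  stopifnot(inherits(timing, "cardiac_timing"))
  timing$avc - timing$qrs_onset
}

#' Opposing-wall strain traces of one apical view
#'
#' Groups the basal/mid strain traces of the early-activated and the
#' late-activated wall of one apical view, with the beat's timing. The default
#' anatomical wall roles are septal/lateral (4CH), anteroseptal/posterior
#' (3CH) and anterior/inferior (2CH).
#'
#' @param view Apical view label.
#' @param early_wall List of [strain_trace()] objects for the early-activated
#'   wall (0-2 traces; an empty wall makes the view not assessable).
#' @param late_wall List of [strain_trace()] objects for the late-activated
#'   wall (0-2 traces).
#' @param timing A [cardiac_timing()] object.
#' @return An object of class `view_strain_set`.
#' @export
view_strain_set <- function(view, early_wall, late_wall, timing) {
  view <- match.arg(view, APICAL_VIEWS)
  stopifnot(inherits(timing, "cardiac_timing"))
  check_wall <- function(traces, role) {
    if (!is.list(traces)) stop(role, "_wall must be a list of strain traces", call. = FALSE)
    if (length(traces) > 2L) {
      stop(role, "_wall: at most two traces (basal, mid) per wall", call. = FALSE)
    }
    for (tr in traces) {
      if (!inherits(tr, "strain_trace")) {
        stop(role, "_wall entries must be strain_trace objects", call. = FALSE)
      }
      if (tr$view != view) {
        stop(sprintf("segment '%s' is tagged view %s, expected %s",
                     tr$segment_id, tr$view, view), call. = FALSE)
      }
      if (!tr$level %in% c("basal", "mid")) {
        stop(sprintf("segment '%s': scoring uses basal/mid segments only",
                     tr$segment_id), call. = FALSE)
      }
    }
    traces
  }
  structure(
    list(view = view, early_wall = check_wall(early_wall, "early"),
         late_wall = check_wall(late_wall, "late"), timing = timing),
    class = "view_strain_set"
  )
}

#' Patient record
#'
#' Bundles the three apical-view strain sets, optional tissue-velocity traces,
#' timing and the clinical fields used downstream (volumes, ejection fraction,
#' NYHA class, septal flash flag, QRS, rhythm descriptors).
#'
#' @param id Patient identifier.
#' @param views Named list of up to three [view_strain_set()] objects; names
#'   among `"4CH"`, `"2CH"`, `"3CH"`.
#' @param timing A [cardiac_timing()] object.
#' @param velocity_traces Optional list of 12 [velocity_trace()] objects (two
#'   walls x basal/mid x three views).
#' @param lvesv_base,lvesv_fu LV end-systolic volume at baseline / follow-up (mL).
#' @param lvedv_base,lvedv_fu LV end-diastolic volume at baseline / follow-up (mL).
#' @param lvef_base,lvef_fu LV ejection fraction (%), in (0, 100).
#' @param nyha_base,nyha_fu NYHA class, integer 1-4.
#' @param septal_flash Logical expert annotation (input flag, never computed).
#' @param qrs_ms QRS duration (ms).
#' @param lbbb Logical: left bundle branch block morphology.
#' @param upgrade Logical: upgrade from a prior device rather than de novo.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(id, views, timing, velocity_traces = NULL,
                           lvesv_base = NA_real_, lvesv_fu = NA_real_,
                           lvedv_base = NA_real_, lvedv_fu = NA_real_,
                           lvef_base = NA_real_, lvef_fu = NA_real_,
                           nyha_base = NA_integer_, nyha_fu = NA_integer_,
                           septal_flash = NA, qrs_ms = NA_real_,
                           lbbb = NA, upgrade = NA) {
  stopifnot(inherits(timing, "cardiac_timing"))
  if (!is.list(views) || length(views) < 1L) {
    stop("views must be a non-empty named list of view_strain_set objects",
         call. = FALSE)
  }
  if (is.null(names(views)) || !all(names(views) %in% APICAL_VIEWS)) {
    stop("views must be named with apical view labels (4CH, 2CH, 3CH)",
         call. = FALSE)
  }
  for (v in names(views)) {
    if (!inherits(views[[v]], "view_strain_set") || views[[v]]$view != v) {
      stop(sprintf("views[['%s']] must be a view_strain_set for view %s", v, v),
           call. = FALSE)
    }
  }
  check_pos <- function(x, nm) {
    if (!is.na(x) && x <= 0) stop(nm, " must be positive", call. = FALSE)
  }
  for (nm in c("lvesv_base", "lvesv_fu", "lvedv_base", "lvedv_fu")) {
    check_pos(get(nm), nm)
  }
  for (nm in c("lvef_base", "lvef_fu")) {
    x <- get(nm)
    if (!is.na(x) && (x <= 0 || x >= 100)) {
      stop(nm, " must lie in (0, 100)", call. = FALSE)
    }
  }
  for (nm in c("nyha_base", "nyha_fu")) {
    x <- get(nm)
    if (!is.na(x) && !x %in% 1:4) stop(nm, " must be in 1..4", call. = FALSE)
  }
  structure(
    list(id = as.character(id), views = views, timing = timing,
         velocity_traces = velocity_traces,
         lvesv_base = as.numeric(lvesv_base), lvesv_fu = as.numeric(lvesv_fu),
         lvedv_base = as.numeric(lvedv_base), lvedv_fu = as.numeric(lvedv_fu),
         lvef_base = as.numeric(lvef_base), lvef_fu = as.numeric(lvef_fu),
         nyha_base = as.integer(nyha_base), nyha_fu = as.integer(nyha_fu),
         septal_flash = as.logical(septal_flash), qrs_ms = as.numeric(qrs_ms),
         lbbb = as.logical(lbbb), upgrade = as.logical(upgrade)),
    class = "patient_record"
  )
}

## ---- curve primitives -----------------------------------------------------
## Traces are frame-rate limited, so all detectors work on the samples
## themselves (piecewise-linear view of the curve, no sub-sample
## interpolation of extremum position). Ties always break to the earliest
## sample so every result is deterministic.

window_idx <- function(trace, t0, t1) {
  times <- trace$times
  if (t1 < t0) stop("window end precedes window start", call. = FALSE)
  if (t0 < times[1L] || t1 > times[length(times)]) {
    stop(sprintf("window [%g, %g] outside trace support [%g, %g] (segment '%s')",
                 t0, t1, times[1L], times[length(times)], trace$segment_id),
         call. = FALSE)
  }
  idx <- which(times >= t0 & times <= t1)
  if (length(idx) == 0L) {
    stop("window contains no samples", call. = FALSE)
  }
  idx
}

## Interior local minima of a sampled curve, plateau-aware: a run of equal
## values counts as one candidate (its earliest sample) when both flanking
## runs are higher. Runs touching the window edge are not interior.
local_min_runs <- function(v) {
  r <- rle(v)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (j in 2:(k - 1L)) {
    if (r$values[j] < r$values[j - 1L] && r$values[j] < r$values[j + 1L]) {
      out <- c(out, starts[j])
    }
  }
  out
}

## Prominence of a minimum: on each side walk away from the minimum until the
## curve drops below it (or the window edge); the rise on that side is the
## highest value seen minus the minimum. Prominence is the smaller of the two
## rises, so an "evident" peak must rebound on both sides.
prominence_at <- function(v, i) {
  vi <- v[i]
  side_rise <- function(seq_idx) {
    best <- -Inf
    for (j in seq_idx) {
      if (v[j] < vi) break
      if (v[j] > best) best <- v[j]
    }
    if (is.finite(best)) best - vi else 0
  }
  left <- if (i > 1L) side_rise(seq(i - 1L, 1L)) else 0
  right <- if (i < length(v)) side_rise(seq(i + 1L, length(v))) else 0
  min(left, right)
}

#' Find an evident shortening peak in a strain trace
#'
#' Locates the most negative interior local minimum of strain within a time
#' window whose prominence (the rebound on both sides, measured to where the
#' curve next drops below the minimum or to the window edge) reaches
#' `min_prominence`. This operationalizes an "evident" negative peak strain
#' curve: a distinct early contraction with rebound, as opposed to ordinary
#' end-systolic shortening, which ends at the window edge and never qualifies.
#'
#' @param trace A [strain_trace()].
#' @param window Numeric length-2 vector `c(t0, t1)` in ms; must lie within
#'   the trace support.
#' @param min_prominence Minimum two-sided prominence in % strain (>= 0).
#' @param all Return every qualifying peak (ordered by time) instead of the
#'   single deepest one. Default `FALSE`.
#' @return `NULL` if no qualifying peak, else a list with `time`, `value` and
#'   `prominence` (the most negative qualifying minimum; ties in depth break
#'   to the earliest time). With `all = TRUE`, a list of such lists in time
#'   order (or `NULL`).
#' @export
find_shortening_peak <- function(trace, window, min_prominence, all = FALSE) {
  stopifnot(inherits(trace, "strain_trace"), length(window) == 2L,
            min_prominence >= 0)
  idx <- window_idx(trace, window[1L], window[2L])
  v <- trace$values[idx]
  cand <- local_min_runs(v)
  if (length(cand) == 0L) return(NULL)
  prom <- vapply(cand, function(i) prominence_at(v, i), numeric(1))
  keep <- prom >= min_prominence
  if (!any(keep)) return(NULL)
  cand <- cand[keep]
  prom <- prom[keep]
  if (all) {
    return(lapply(seq_along(cand), function(k) {
      list(time = trace$times[idx][cand[k]], value = v[cand[k]],
           prominence = prom[k])
    }))
  }
  ord <- order(v[cand], trace$times[idx][cand])[1L]
  list(time = trace$times[idx][cand[ord]], value = v[cand[ord]],
       prominence = prom[ord])
}

#' Maximum stretch (most positive strain) in a window
#'
#' Early-systolic positive strain of a late-activated wall (prestretch) is
#' detected as the most positive sample in the window; the caller applies a
#' threshold. On an all-negative trace this is simply the least negative value.
#'
#' @inheritParams find_shortening_peak
#' @return List with `time` and `value`; ties break to the earliest time.
#' @export
find_stretch_max <- function(trace, window) {
  stopifnot(inherits(trace, "strain_trace"), length(window) == 2L)
  idx <- window_idx(trace, window[1L], window[2L])
  v <- trace$values[idx]
  i <- which.max(v)   # which.max returns the first maximum
  list(time = trace$times[idx][i], value = v[i])
}

#' Time to peak systolic velocity
#'
#' Time of the maximum positive myocardial velocity within the ejection phase
#' (QRS onset to AVC), measured from QRS onset; the building block of the Yu
#' index and the maximal time-delay indexes.
#'
#' @param trace A [velocity_trace()] covering the ejection phase.
#' @param timing A [cardiac_timing()].
#' @return Time in ms; ties break to the earliest sample.
#' @export
time_to_peak_velocity <- function(trace, timing) {
  stopifnot(inherits(trace, "velocity_trace"), inherits(timing, "cardiac_timing"))
  idx <- window_idx(trace, timing$qrs_onset, timing$avc)
  v <- trace$values[idx]
  trace$times[idx][which.max(v)]
}

#' Time of global peak shortening
#'
#' Time of the global strain minimum over `[0, search_end]`. Searching past
#' AVC detects a late-activated wall whose peak contraction falls after
#' aortic valve closure; here an edge minimum does count (late shortening may
#' still be ongoing at the search end).
#'
#' @param trace A [strain_trace()].
#' @param search_end End of the search window (ms); must be within the trace.
#' @return Time in ms of the global minimum; ties break to the earliest sample.
#' @export
global_peak_shortening_time <- function(trace, search_end) {
  stopifnot(inherits(trace, "strain_trace"))
  idx <- window_idx(trace, 0, search_end)
  v <- trace$values[idx]
  trace$times[idx][which.min(v)]
}
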