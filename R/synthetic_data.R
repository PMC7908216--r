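#' Default cardiac timing for simulated beats
#'
#' A representative dyssynchronous heart-failure beat: heart rate about 70
#' bpm, ejection phase 330 ms, aortic pre-ejection delayed 40 ms beyond the
#' pulmonary pre-ejection, diastolic filling a little over 40% of the cycle.
#'
#' @return A [cardiac_timing()].
#' @export
default_timing <- function() {
  cardiac_timing(avc = 330, aortic_preejection = 140,
                 pulmonary_preejection = 100, lv_filling_time = 350, rr = 860)
}

## Evaluate an expression with a temporarily seeded RNG, restoring the
## caller's stream afterwards so simulation helpers never perturb it.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

## Waveforms are sums of logistic ramps and Gaussian bumps on a regular grid
## spanning 1.5 ejection lengths: smooth, physiologically plausible shapes
## that can realize every component-bit combination with wide margins against
## additive noise. Strain at the QRS-onset reference sample is exactly zero
## strain offset and carries no added noise (it is the reference frame).
strain_grid <- function(timing, dt) {
  E <- ejection_length(timing)
  seq(0, ceiling(1.5 * E / dt) * dt, by = dt)
}

early_wall_values <- function(t, E, c1, c3, peak_strain, early_peak_fraction) {
  avc <- E
  if (c1 == 1L) {
    tp <- early_peak_fraction * E
    ## steady shortening straight into the early peak (uniformly steep, so
    ## noise cannot carve spurious "evident" peaks out of a plateau before
    ## the true one), then a rebound and mild late drift
    ifelse(t <= tp,
           peak_strain * t / tp,
           peak_strain + 6 * (1 - exp(-((t - tp) / 35)^2 / 2)) -
             0.012 * (t - tp))
  } else {
    ## ordinary progressive shortening to a deep end-systolic minimum (the
    ## wall without a distinct early peak is the better-contracting one)
    1.35 * peak_strain * pmin(t, avc) / avc
  }
}

late_wall_values <- function(t, E, avc, c2, c4, peak_strain, prestretch_amp,
                             late_peak_delay) {
  t4 <- if (c4 == 1L) avc + late_peak_delay else 0.88 * avc
  v <- peak_strain * exp(-((t - t4) / 35)^2 / 2)
  ## background shortening drift: starts after the prestretch window when a
  ## prestretch bump is present, immediately otherwise
  if (c2 == 1L) {
    v <- v + prestretch_amp * exp(-((t - 0.15 * E) / 20)^2 / 2) -
      3 * stats::plogis((t - 0.45 * E) / (E / 25))
  } else {
    v <- v - 3 * stats::plogis((t - 0.08 * E) / (E / 30))
  }
  v
}

add_noise <- function(values, noise_sd) {
  if (noise_sd > 0) {
    eps <- stats::rnorm(length(values), 0, noise_sd)
    eps[1L] <- 0
    values <- values + eps
  }
  values
}

#' Synthesize one apical view with prescribed dyssynchrony components
#'
#' Builds a [view_strain_set()] whose early- and late-wall strain curves
#' realize a prescribed component-bit vector `(c1, c2, c3, c4)` exactly at
#' zero noise: an early shortening peak with rebound (c1) placed inside or
#' beyond the first 70% of the ejection phase (c3), an early-systolic
#' prestretch bump of the late wall (c2), and a late-wall global peak
#' shortening displaced past aortic valve closure (c4).
#'
#' @param view Apical view label (`"4CH"`, `"2CH"`, `"3CH"`).
#' @param bits Integer vector `c(c1, c2, c3, c4)` of target components;
#'   `c3 = 1` requires `c1 = 1`.
#' @param timing A [cardiac_timing()]. Default [default_timing()].
#' @param peak_strain Peak (most negative) strain in % (default -15).
#' @param prestretch_amp Prestretch bump amplitude in % (default +3).
#' @param early_peak_fraction Early-peak time as a fraction of the ejection
#'   phase; default 0.45 when `c3 = 1`, 0.75 when the peak must exceed 70%.
#' @param late_peak_delay Delay of the late-wall peak past AVC in ms
#'   (default 60).
#' @param noise_sd Additive white Gaussian noise SD in % strain (default 0).
#' @param dt Sampling interval in ms (default 5, about frame rate).
#' @param early_level,late_level Segment level carrying the feature on each
#'   wall; defaults follow the usual appearance (mid septum in 4CH, basal
#'   segments elsewhere).
#' @param seed Optional integer seed for the noise (RNG state restored).
#' @return A [view_strain_set()].
#' @export
make_view <- function(view, bits, timing = default_timing(),
                      peak_strain = -15, prestretch_amp = 3,
                      early_peak_fraction = NULL, late_peak_delay = 60,
                      noise_sd = 0, dt = 5,
                      early_level = if (view == "4CH") "mid" else "basal",
                      late_level = "basal", seed = NULL) {
  view <- match.arg(view, APICAL_VIEWS)
  bits <- as.integer(bits)
  stopifnot(length(bits) == 4L, all(bits %in% 0:1))
  if (bits[3L] == 1L && bits[1L] == 0L) {
    stop("contradictory component bits: c3 = 1 requires c1 = 1", call. = FALSE)
  }
  stopifnot(abs(peak_strain) <= 30, abs(prestretch_amp) <= 30)
  if (is.null(early_peak_fraction)) {
    early_peak_fraction <- if (bits[3L] == 1L) 0.45 else 0.75
  }
  stopifnot(early_peak_fraction > 0, early_peak_fraction < 1.5)

  E <- ejection_length(timing)
  t <- strain_grid(timing, dt)
  walls <- VIEW_WALLS[[view]]

  with_seed(seed, {
    early_v <- add_noise(
      early_wall_values(t, E, bits[1L], bits[3L], peak_strain,
                        early_peak_fraction),
      noise_sd)
    late_v <- add_noise(
      late_wall_values(t, E, timing$avc, bits[2L], bits[4L], peak_strain,
                       prestretch_amp, late_peak_delay),
      noise_sd)
    view_strain_set(
      view = view,
      early_wall = list(strain_trace(t, early_v, view, walls[["early"]],
                                     early_level)),
      late_wall = list(strain_trace(t, late_v, view, walls[["late"]],
                                    late_level)),
      timing = timing
    )
  })
}

## Deterministic mapping from a per-view point count (0..4) to a valid
## component-bit vector, and from a 0..12 total to three per-view counts.
view_score_bits <- function(k) {
  switch(as.character(k),
         "0" = c(0L, 0L, 0L, 0L),
         "1" = c(1L, 0L, 0L, 0L),
         "2" = c(1L, 1L, 0L, 0L),
         "3" = c(1L, 1L, 1L, 0L),
         "4" = c(1L, 1L, 1L, 1L),
         stop("view score must be 0..4", call. = FALSE))
}

split_total_score <- function(total) {
  stopifnot(total >= 0, total <= 12)
  base <- total %/% 3L
  rem <- total %% 3L
  counts <- rep(base, 3L) + c(rem >= 1L, rem >= 2L, 0L)
  stats::setNames(as.integer(counts), APICAL_VIEWS)
}

#' Synthesize a full patient with a prescribed RSPI
#'
#' Builds a [patient_record()] whose three views realize either an explicit
#' per-view component-bit list or a target RSPI total (distributed over the
#' views), together with consistent volumes for a prescribed responder label.
#'
#' @param id Patient identifier.
#' @param bits_by_view Named list (`"4CH"`, `"2CH"`, `"3CH"`) of 4-bit
#'   component vectors; overrides `target_score`.
#' @param target_score Target RSPI total 0-12 used when `bits_by_view` is
#'   `NULL`.
#' @param responder Logical: draw a follow-up LVESV giving at least a 15%
#'   reduction (responder) or less (non-responder).
#' @param timing,noise_sd,dt,seed Passed to [make_view()]; the seed also
#'   drives the clinical draws.
#' @param with_velocities Also attach 12 synthetic tissue-velocity traces.
#' @return A [patient_record()].
#' @export
make_patient <- function(id, bits_by_view = NULL, target_score = NULL,
                         responder = TRUE, timing = default_timing(),
                         noise_sd = 0, dt = 5, seed = NULL,
                         with_velocities = FALSE) {
  if (is.null(bits_by_view)) {
    if (is.null(target_score)) stop("give bits_by_view or target_score",
                                    call. = FALSE)
    bits_by_view <- lapply(split_total_score(target_score), view_score_bits)
  }
  stopifnot(all(names(bits_by_view) %in% APICAL_VIEWS))
  with_seed(seed, {
    views <- list()
    for (v in names(bits_by_view)) {
      views[[v]] <- make_view(v, bits_by_view[[v]], timing = timing,
                              noise_sd = noise_sd, dt = dt)
    }
    delta <- if (isTRUE(responder)) stats::runif(1, 15, 45) else
      stats::runif(1, -20, 14)
    lvesv_base <- stats::runif(1, 120, 260)
    lvef_base <- stats::runif(1, 18, 32)
    lvedv_base <- lvesv_base / (1 - lvef_base / 100)
    lvesv_fu <- lvesv_base * (1 - delta / 100)
    lvef_fu <- min(60, lvef_base + if (isTRUE(responder))
      stats::runif(1, 5, 15) else stats::runif(1, -3, 4))
    vel <- if (with_velocities) {
      offsets <- stats::setNames(round(stats::runif(12, -40, 40) / dt) * dt,
                                 velocity_segment_ids())
      make_velocity_set(150 + offsets, timing, dt = dt)
    } else NULL
    patient_record(
      id = id, views = views, timing = timing, velocity_traces = vel,
      lvesv_base = lvesv_base, lvesv_fu = lvesv_fu,
      lvedv_base = lvedv_base, lvedv_fu = lvedv_base * (1 - delta / 150),
      lvef_base = lvef_base, lvef_fu = lvef_fu,
      nyha_base = sample(2:3, 1), nyha_fu = sample(1:3, 1),
      septal_flash = stats::runif(1) < 0.4,
      qrs_ms = stats::runif(1, 140, 200),
      lbbb = stats::runif(1) < 0.7,
      upgrade = stats::runif(1) < 0.4
    )
  })
}

velocity_segment_ids <- function() {
  out <- character(0)
  for (v in APICAL_VIEWS) {
    for (w in VIEW_WALLS[[v]]) {
      for (lev in c("basal", "mid")) {
        out <- c(out, paste(v, w, lev, sep = "_"))
      }
    }
  }
  out
}

#' Synthesize the 12 tissue-velocity traces with given peak times
#'
#' One Gaussian systolic velocity bump per segment, centred at the requested
#' time-to-peak (snapped to the sampling grid), for the two walls x basal/mid
#' of each apical view.
#'
#' @param ttp Named numeric vector of 12 target time-to-peaks (ms), names as
#'   produced by [velocity_segment_ids()], all within the ejection phase.
#' @param timing A [cardiac_timing()].
#' @param dt Sampling interval (ms).
#' @param amplitude Bump amplitude (arbitrary units).
#' @return List of 12 [velocity_trace()] objects.
#' @export
make_velocity_set <- function(ttp, timing = default_timing(), dt = 5,
                              amplitude = 6) {
  ids <- velocity_segment_ids()
  if (is.null(names(ttp))) names(ttp) <- ids
  stopifnot(setequal(names(ttp), ids))
  E <- ejection_length(timing)
  t <- seq(0, ceiling(1.1 * E / dt) * dt, by = dt)
  lapply(ids, function(id) {
    parts <- strsplit(id, "_")[[1L]]
    centre <- min(max(round(ttp[[id]] / dt) * dt, 2 * dt), timing$avc - 2 * dt)
    v <- amplitude * exp(-((t - centre) / 30)^2 / 2)
    velocity_trace(t, v, view = parts[1L], wall = parts[2L], level = parts[3L],
                   segment_id = id)
  })
}

#' Synthesize a septal/posterior M-mode motion pair with a known delay
#'
#' @param offset Posterior-minus-septal peak delay in ms (may be negative).
#' @param septal_peak Septal peak inward time (ms). Default 150.
#' @param dt Sampling interval (ms).
#' @param duration Trace length (ms).
#' @return List with `septal` and `posterior` motion traces (times/values).
#' @export
make_motion_pair <- function(offset, septal_peak = 150, dt = 5, duration = 600) {
  t <- seq(0, duration, by = dt)
  bump <- function(centre) 8 * exp(-((t - centre) / 40)^2 / 2)
  list(septal = list(times = t, values = bump(septal_peak)),
       posterior = list(times = t, values = bump(septal_peak + offset)))
}

#' Synthesize a cohort with a prescribed responder x high-RSPI structure
#'
#' In exact-count mode the four cells of the responder-by-high-RSPI 2x2 are
#' reproduced without sampling: each patient receives waveforms realizing an
#' RSPI total drawn from the high (at or above the cutoff) or low score range
#' as its cell requires, and baseline/follow-up volumes consistent with its
#' responder label. In stochastic mode cell membership is drawn from
#' per-group high-RSPI probabilities.
#'
#' @param tp,fp,fn,tn Exact cell counts (test = high RSPI, condition =
#'   responder). Supply either these or `n_responders`/`n_nonresponders`.
#' @param n_responders,n_nonresponders Group sizes for stochastic mode.
#' @param p_high_responder,p_high_nonresponder High-RSPI probability per
#'   group in stochastic mode.
#' @param cutoff RSPI cutoff separating the high/low score ranges. Default 7.
#' @param high_scores,low_scores Candidate RSPI totals for the two ranges.
#' @param noise_sd Strain noise SD (%). Default 0 so assigned scores are
#'   recovered exactly.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param with_velocities Attach synthetic velocity traces to each patient.
#' @return List of [patient_record()] objects; attribute `assigned` is a
#'   data.frame with each patient's assigned score and labels.
#' @export
make_cohort <- function(tp = NULL, fp = NULL, fn = NULL, tn = NULL,
                        n_responders = NULL, n_nonresponders = NULL,
                        p_high_responder = 0.5, p_high_nonresponder = 0.1,
                        cutoff = 7L, high_scores = cutoff:12,
                        low_scores = 0:(cutoff - 1L), noise_sd = 0,
                        seed = NULL, with_velocities = FALSE) {
  exact <- !is.null(tp)
  if (exact) {
    if (anyNA(c(tp, fp, fn, tn)) || any(c(tp, fp, fn, tn) < 0)) {
      stop("exact-count mode needs all four non-negative cell counts",
           call. = FALSE)
    }
    cells <- data.frame(
      responder = rep(c(TRUE, TRUE, FALSE, FALSE), c(tp, fn, fp, tn)),
      high = rep(c(TRUE, FALSE, TRUE, FALSE), c(tp, fn, fp, tn))
    )
  } else {
    if (is.null(n_responders) || is.null(n_nonresponders)) {
      stop("give exact cell counts or group sizes", call. = FALSE)
    }
  }
  with_seed(seed, {
    if (!exact) {
      cells <- data.frame(
        responder = rep(c(TRUE, FALSE), c(n_responders, n_nonresponders)),
        high = c(stats::runif(n_responders) < p_high_responder,
                 stats::runif(n_nonresponders) < p_high_nonresponder)
      )
    }
    n <- nrow(cells)
    if (n == 0L) stop("empty cohort specification", call. = FALSE)
    score <- ifelse(cells$high,
                    high_scores[1L + (seq_len(n) - 1L) %% length(high_scores)],
                    low_scores[1L + (seq_len(n) - 1L) %% length(low_scores)])
    patients <- vector("list", n)
    for (i in seq_len(n)) {
      patients[[i]] <- make_patient(
        id = sprintf("P%03d", i), target_score = score[i],
        responder = cells$responder[i], noise_sd = noise_sd,
        with_velocities = with_velocities
      )
    }
    attr(patients, "assigned") <- data.frame(
      id = vapply(patients, `[[`, character(1), "id"),
      score = as.integer(score), high = cells$high,
      responder = cells$responder
    )
    patients
  })
}
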