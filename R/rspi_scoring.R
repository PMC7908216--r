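#' Scoring configuration for the RSPI components
#'
#' Thresholds and windows that turn the visual criteria for the four
#' dyssynchrony components into a deterministic decision rule. The 70%
#' fraction of the ejection phase for component 3 is a fixed constant of the
#' index; the remaining fields operationalize "evident" peaks and are
#' configurable.
#'
#' @param contraction_prominence Minimum two-sided prominence (% strain) for
#'   an early-wall shortening peak to count as an evident early contraction
#'   (component 1). Default 2.
#' @param prestretch_threshold Minimum positive strain (%) for late-wall
#'   prestretch (component 2). Default +1.
#' @param prestretch_window_fraction Fraction of the ejection phase within
#'   which prestretch must occur. Default 0.5 (early systole).
#' @param early_fraction Fraction of the ejection phase for component 3.
#'   Fixed at 0.70; changing it is an error.
#' @param require_rebound If `TRUE` (default) component 1 requires a two-sided
#'   rebound (interior local minimum); if `FALSE` a contraction movement whose
#'   drop from the preceding maximum reaches `contraction_prominence` also
#'   qualifies even without rebound.
#' @param late_peak_search_frac How far past AVC (as a fraction of the
#'   ejection length) to search for the late-wall peak contraction
#'   (component 4). Default 0.4.
#' @param cutoff RSPI classification cutoff (points, boundary inclusive).
#'   Default 7.
#' @param wall_assignment `"anatomic"` (default) fixes the early/late wall
#'   roles per view; `"data_driven"` swaps the roles when the nominal late
#'   wall has the earlier qualifying shortening peak.
#' @param pattern_in_2ch Whether the classical-pattern criteria may be
#'   satisfied in the 2-chamber view, which has no septal wall. Default `TRUE`
#'   (the anterior wall takes the early role there).
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(contraction_prominence = 2.0,
                           prestretch_threshold = 1.0,
                           prestretch_window_fraction = 0.5,
                           early_fraction = 0.70,
                           require_rebound = TRUE,
                           late_peak_search_frac = 0.4,
                           cutoff = 7L,
                           wall_assignment = c("anatomic", "data_driven"),
                           pattern_in_2ch = TRUE) {
  if (early_fraction != 0.70) {
    stop("early_fraction is a fixed constant of the index (0.70)", call. = FALSE)
  }
  stopifnot(contraction_prominence >= 0, prestretch_threshold >= 0,
            prestretch_window_fraction > 0, prestretch_window_fraction <= 1.5,
            late_peak_search_frac > 0, cutoff >= 0, cutoff <= 12)
  structure(
    list(contraction_prominence = contraction_prominence,
         prestretch_threshold = prestretch_threshold,
         prestretch_window_fraction = prestretch_window_fraction,
         early_fraction = 0.70,
         require_rebound = isTRUE(require_rebound),
         late_peak_search_frac = late_peak_search_frac,
         cutoff = as.integer(cutoff),
         wall_assignment = match.arg(wall_assignment),
         pattern_in_2ch = isTRUE(pattern_in_2ch)),
    class = "scoring_config"
  )
}

## Earliest qualifying early-contraction peak among a wall's traces, or NULL.
## With require_rebound = FALSE a one-sided "contraction movement" peak (drop
## from the preceding running maximum >= prominence at the window-global
## minimum) also qualifies.
earliest_wall_peak <- function(traces, avc, config) {
  best <- NULL
  for (tr in traces) {
    pks <- find_shortening_peak(tr, c(0, avc), config$contraction_prominence,
                                all = TRUE)
    pk <- if (is.null(pks)) NULL else pks[[1L]]   # earliest qualifying peak
    if (is.null(pk) && !config$require_rebound) {
      idx <- window_idx(tr, 0, avc)
      v <- tr$values[idx]
      i <- which.min(v)
      drop <- max(v[seq_len(i)]) - v[i]
      if (drop >= config$contraction_prominence) {
        pk <- list(time = tr$times[idx][i], value = v[i], prominence = drop)
      }
    }
    if (!is.null(pk)) {
      pk$segment_id <- tr$segment_id
      if (is.null(best) || pk$time < best$time) best <- pk
    }
  }
  best
}

#' Score the four RSPI components in one apical view
#'
#' Assesses, on the basal/mid strain traces of one view, the four
#' dyssynchrony components: (1) evident contraction of the early-activated
#' wall; (2) prestretching of the late-activated wall; (3) the early-wall
#' peak contraction falling within the first 70% of the systolic ejection
#' phase (scored only when component 1 is present); (4) peak contraction of
#' the late-activated wall after aortic valve closure. Components are
#' assessed independently except for the 3-requires-1 constraint, and wall
#' aggregation is existential: any one qualifying basal or mid segment sets a
#' component.
#'
#' @param view_set A [view_strain_set()].
#' @param config A [scoring_config()].
#' @return An object of class `component_vector`: fields `c1`, `c2`, `c3`,
#'   `c4` (0/1), `view`, `assessable`, and a `detail` list recording each
#'   decision's triggering segment and time.
#' @export
score_view <- function(view_set, config = scoring_config()) {
  stopifnot(inherits(view_set, "view_strain_set"),
            inherits(config, "scoring_config"))
  timing <- view_set$timing
  E <- ejection_length(timing)
  avc <- timing$avc

  early <- view_set$early_wall
  late <- view_set$late_wall
  if (length(early) == 0L || length(late) == 0L) {
    return(component_vector(0L, 0L, 0L, 0L, view_set$view, assessable = FALSE,
                            detail = list(reason = "missing wall traces")))
  }

  swapped <- FALSE
  if (config$wall_assignment == "data_driven") {
    pk_e <- earliest_wall_peak(early, avc, config)
    pk_l <- earliest_wall_peak(late, avc, config)
    if (!is.null(pk_l) && (is.null(pk_e) || pk_l$time < pk_e$time)) {
      tmp <- early; early <- late; late <- tmp
      swapped <- TRUE
    }
  }

  pk <- earliest_wall_peak(early, avc, config)
  c1 <- as.integer(!is.null(pk))
  c3 <- as.integer(c1 == 1L && pk$time <= config$early_fraction * E)

  stretch_end <- config$prestretch_window_fraction * E
  best_stretch <- NULL
  for (tr in late) {
    s <- find_stretch_max(tr, c(0, stretch_end))
    if (is.null(best_stretch) || s$value > best_stretch$value) {
      best_stretch <- s
      best_stretch$segment_id <- tr$segment_id
    }
  }
  c2 <- as.integer(best_stretch$value >= config$prestretch_threshold)

  search_end <- avc + config$late_peak_search_frac * E
  late_peak <- NULL
  for (tr in late) {
    tmin <- global_peak_shortening_time(tr, search_end)
    if (tmin > avc && (is.null(late_peak) || tmin < late_peak$time)) {
      late_peak <- list(time = tmin, segment_id = tr$segment_id)
    }
  }
  c4 <- as.integer(!is.null(late_peak))

  component_vector(
    c1, c2, c3, c4, view_set$view, assessable = TRUE,
    detail = list(
      early_peak = pk, stretch = best_stretch, late_peak = late_peak,
      ejection_ms = E, early_limit_ms = config$early_fraction * E,
      walls_swapped = swapped
    )
  )
}

component_vector <- function(c1, c2, c3, c4, view, assessable = TRUE,
                             detail = list()) {
  stopifnot(c3 <= c1)
  structure(
    list(c1_early_contraction = as.integer(c1),
         c2_prestretch = as.integer(c2),
         c3_within_70pct = as.integer(c3),
         c4_late_peak_after_avc = as.integer(c4),
         view = view, assessable = isTRUE(assessable), detail = detail),
    class = "component_vector"
  )
}

#' Component bits of a scored view
#'
#' @param x A `component_vector` from [score_view()].
#' @return Integer vector `c(c1, c2, c3, c4)`.
#' @export
component_bits <- function(x) {
  stopifnot(inherits(x, "component_vector"))
  c(c1 = x$c1_early_contraction, c2 = x$c2_prestretch,
    c3 = x$c3_within_70pct, c4 = x$c4_late_peak_after_avc)
}

#' @export
print.component_vector <- function(x, ...) {
  b <- component_bits(x)
  cat(sprintf("<%s components> (c1,c2,c3,c4) = (%d,%d,%d,%d), %d point(s)%s\n",
              x$view, b[1], b[2], b[3], b[4], sum(b),
              if (x$assessable) "" else " [not assessable]"))
  invisible(x)
}

#' Compute the Regional Strain Pattern Index for a patient
#'
#' Scores the four components in each of the three apical views and sums the
#' twelve bits into the 0-12 RSPI. A patient is classified as high-RSPI when
#' the total reaches the cutoff (default >= 7 points). A missing or
#' non-assessable view contributes 0 points and is flagged.
#'
#' @param patient A [patient_record()].
#' @param config A [scoring_config()].
#' @return An object of class `rspi_result`: `per_view` (list of
#'   `component_vector`s), `total` (0-12), `high` (logical), `cutoff`,
#'   `missing_views`.
#' @export
compute_rspi <- function(patient, config = scoring_config()) {
  stopifnot(inherits(patient, "patient_record"))
  present <- intersect(APICAL_VIEWS, names(patient$views))
  if (length(present) == 0L) stop("no assessable views", call. = FALSE)
  per_view <- list()
  for (v in APICAL_VIEWS) {
    if (v %in% present) {
      per_view[[v]] <- score_view(patient$views[[v]], config)
    } else {
      per_view[[v]] <- component_vector(0L, 0L, 0L, 0L, v, assessable = FALSE,
                                        detail = list(reason = "view missing"))
    }
  }
  total <- sum(vapply(per_view, function(cv) sum(component_bits(cv)), numeric(1)))
  structure(
    list(per_view = per_view, total = as.integer(total),
         high = classify_high_rspi(total, config$cutoff),
         cutoff = config$cutoff,
         missing_views = setdiff(APICAL_VIEWS, present)),
    class = "rspi_result"
  )
}

#' @export
print.rspi_result <- function(x, ...) {
  cat(sprintf("RSPI total: %d / 12 (%s, cutoff >= %d)\n", x$total,
              if (x$high) "high" else "low", x$cutoff))
  for (cv in x$per_view) print(cv)
  if (length(x$missing_views)) {
    cat("missing views:", paste(x$missing_views, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify an RSPI total as high or low
#'
#' @param total Integer RSPI total, 0-12.
#' @param cutoff Classification cutoff (points); the boundary is inclusive,
#'   so a total equal to the cutoff is high. Default 7.
#' @return Logical.
#' @export
classify_high_rspi <- function(total, cutoff = 7L) {
  if (any(is.na(total)) || any(total < 0) || any(total > 12)) {
    stop("RSPI total must lie in 0..12", call. = FALSE)
  }
  total >= cutoff
}
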