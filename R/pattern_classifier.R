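#' Classify the strain pattern as classical (LBBB-related) or heterogeneous
#'
#' Applies the three-criterion rule for the LBBB-related "classical" strain
#' pattern per apical view: (1) early contraction of at least one basal or
#' mid segment of the early-activated ((antero)septal) wall together with
#' early stretching of the opposing wall; (2) the early peak contraction not
#' exceeding 70% of the ejection phase; (3) a peak contraction of the
#' stretched wall after aortic valve closure. In terms of the RSPI component
#' bits these are c1&c2, c3 and c4, so a view fulfils the criteria exactly
#' when all four components are present. If at least one view fulfils all
#' three criteria the patient's pattern is classical, otherwise heterogeneous.
#'
#' The criteria are defined on septal/anteroseptal walls, which exist in the
#' 4- and 3-chamber views only; whether the 2-chamber view (early wall:
#' anterior) may also satisfy them is controlled by `config$pattern_in_2ch`
#' (default yes) and recorded in the result.
#'
#' @param patient A [patient_record()].
#' @param config A [scoring_config()].
#' @return An object of class `pattern_result`: `per_view` (named logical:
#'   criteria fulfilled in that view), `criteria` (per-view 3-bit detail),
#'   `label` (`"classical"` or `"heterogeneous"`), `views_considered`.
#' @export
classify_pattern <- function(patient, config = scoring_config()) {
  stopifnot(inherits(patient, "patient_record"))
  rspi <- compute_rspi(patient, config)
  considered <- if (config$pattern_in_2ch) APICAL_VIEWS else c("4CH", "3CH")
  per_view <- logical(0)
  criteria <- list()
  for (v in APICAL_VIEWS) {
    b <- component_bits(rspi$per_view[[v]])
    crit <- c(early_contraction_and_stretch = b[["c1"]] == 1L && b[["c2"]] == 1L,
              within_70pct = b[["c3"]] == 1L,
              late_peak_after_avc = b[["c4"]] == 1L)
    criteria[[v]] <- crit
    per_view[v] <- (v %in% considered) && all(crit)
  }
  structure(
    list(per_view = per_view, criteria = criteria,
         label = if (any(per_view)) "classical" else "heterogeneous",
         views_considered = considered),
    class = "pattern_result"
  )
}

#' @export
print.pattern_result <- function(x, ...) {
  cat(sprintf("strain pattern: %s (criteria fulfilled in: %s)\n", x$label,
              if (any(x$per_view)) {
                paste(names(x$per_view)[x$per_view], collapse = ", ")
              } else "no view"))
  invisible(x)
}
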