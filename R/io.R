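SCHEMA_VERSION <- "1.0"

trace_to_list <- function(tr, role = NULL) {
  out <- list(view = tr$view, wall = tr$wall, level = tr$level,
              segment_id = tr$segment_id, time_ms = tr$times, value = tr$values)
  if (!is.null(role)) out$role <- role
  out
}

patient_to_list <- function(p) {
  traces <- list()
  for (v in names(p$views)) {
    vs <- p$views[[v]]
    for (tr in vs$early_wall) traces[[length(traces) + 1L]] <- trace_to_list(tr, "early")
    for (tr in vs$late_wall) traces[[length(traces) + 1L]] <- trace_to_list(tr, "late")
  }
  vel <- if (!is.null(p$velocity_traces)) {
    lapply(p$velocity_traces, trace_to_list)
  } else NULL
  list(
    id = p$id,
    timing = p$timing[c("qrs_onset", "avc", "aortic_preejection",
                        "pulmonary_preejection", "lv_filling_time", "rr")],
    clinical = list(
      lvesv_base = p$lvesv_base, lvesv_fu = p$lvesv_fu,
      lvedv_base = p$lvedv_base, lvedv_fu = p$lvedv_fu,
      lvef_base = p$lvef_base, lvef_fu = p$lvef_fu,
      nyha_base = p$nyha_base, nyha_fu = p$nyha_fu,
      septal_flash = p$septal_flash, qrs_ms = p$qrs_ms,
      lbbb = p$lbbb, upgrade = p$upgrade
    ),
    traces = traces,
    velocity_traces = vel
  )
}

#' Write a patient list to the JSON trace-file schema
#'
#' The on-disk schema is versioned JSON: a `patients` array, each entry with
#' `id`, a `timing` block (`qrs_onset`, `avc`, `aortic_preejection`,
#' `pulmonary_preejection`, `lv_filling_time`, `rr`, all ms), a `clinical`
#' block, and `traces` entries carrying `view`, `wall`, `level`,
#' `segment_id`, `role` (early/late wall) and the `time_ms`/`value` sample
#' arrays (strain in %, negative = shortening).
#'
#' @param patients List of [patient_record()] objects.
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  stopifnot(is.list(patients))
  doc <- list(
    schema_version = SCHEMA_VERSION,
    units = list(time = "ms from QRS onset",
                 strain = "percent, negative = shortening"),
    patients = lapply(patients, patient_to_list)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

stop_field <- function(id, field, why) {
  stop(sprintf("patient '%s': field '%s' %s", id, field, why), call. = FALSE)
}

num_or <- function(x, default = NA_real_) {
  if (is.null(x) || length(x) == 0L) default else as.numeric(x)
}

lgl_or <- function(x) if (is.null(x) || length(x) == 0L) NA else as.logical(x)

list_to_patient <- function(pl) {
  id <- if (is.null(pl$id)) "<unnamed>" else as.character(pl$id)
  tm <- pl$timing
  for (f in c("avc", "aortic_preejection", "pulmonary_preejection",
              "lv_filling_time", "rr")) {
    if (is.null(tm[[f]])) stop_field(id, paste0("timing.", f), "is missing")
  }
  timing <- tryCatch(
    cardiac_timing(tm$avc, tm$aortic_preejection, tm$pulmonary_preejection,
                   tm$lv_filling_time, tm$rr,
                   qrs_onset = num_or(tm$qrs_onset, 0)),
    error = function(e) stop_field(id, "timing", conditionMessage(e))
  )
  cl <- if (is.null(pl$clinical)) list() else pl$clinical

  by_view <- list()
  for (tl in pl$traces) {
    for (f in c("view", "wall", "level", "time_ms", "value")) {
      if (is.null(tl[[f]])) {
        stop_field(id, sprintf("traces[segment '%s'].%s",
                               if (is.null(tl$segment_id)) "?" else tl$segment_id,
                               f), "is missing")
      }
    }
    role <- if (!is.null(tl$role)) tl$role else {
      walls <- VIEW_WALLS[[tl$view]]
      if (is.null(walls) || !tl$wall %in% walls) {
        stop_field(id, sprintf("traces[segment '%s'].role",
                               if (is.null(tl$segment_id)) tl$wall else tl$segment_id),
                   "is missing and the wall name has no default role")
      }
      names(walls)[walls == tl$wall]
    }
    tr <- tryCatch(
      strain_trace(unlist(tl$time_ms), unlist(tl$value), tl$view, tl$wall,
                   tl$level,
                   segment_id = if (is.null(tl$segment_id))
                     paste(tl$wall, tl$level, sep = "_") else tl$segment_id),
      error = function(e) stop_field(id, "traces", conditionMessage(e))
    )
    key <- tl$view
    if (is.null(by_view[[key]])) by_view[[key]] <- list(early = list(), late = list())
    by_view[[key]][[role]] <- c(by_view[[key]][[role]], list(tr))
  }
  views <- list()
  for (v in names(by_view)) {
    views[[v]] <- tryCatch(
      view_strain_set(v, by_view[[v]]$early, by_view[[v]]$late, timing),
      error = function(e) stop_field(id, sprintf("views[%s]", v),
                                     conditionMessage(e))
    )
  }
  vel <- NULL
  if (!is.null(pl$velocity_traces) && length(pl$velocity_traces) > 0L) {
    vel <- lapply(pl$velocity_traces, function(tl) {
      tryCatch(
        velocity_trace(unlist(tl$time_ms), unlist(tl$value), tl$view, tl$wall,
                       tl$level,
                       segment_id = if (is.null(tl$segment_id))
                         paste(tl$wall, tl$level, sep = "_") else tl$segment_id),
        error = function(e) stop_field(id, "velocity_traces",
                                       conditionMessage(e))
      )
    })
  }
  tryCatch(
    patient_record(
      id = id, views = views, timing = timing, velocity_traces = vel,
      lvesv_base = num_or(cl$lvesv_base), lvesv_fu = num_or(cl$lvesv_fu),
      lvedv_base = num_or(cl$lvedv_base), lvedv_fu = num_or(cl$lvedv_fu),
      lvef_base = num_or(cl$lvef_base), lvef_fu = num_or(cl$lvef_fu),
      nyha_base = num_or(cl$nyha_base, NA_integer_),
      nyha_fu = num_or(cl$nyha_fu, NA_integer_),
      septal_flash = lgl_or(cl$septal_flash), qrs_ms = num_or(cl$qrs_ms),
      lbbb = lgl_or(cl$lbbb), upgrade = lgl_or(cl$upgrade)
    ),
    error = function(e) stop_field(id, "clinical", conditionMessage(e))
  )
}

#' Load patients from the JSON trace-file schema
#'
#' Fully validates every record on load (schema version, timing fields,
#' strictly increasing sample times, wall/view consistency) and fails with a
#' message naming the offending patient and field.
#'
#' @param path Path to a `.json` file written by [write_patients()] (or
#'   conforming to the documented schema).
#' @return List of [patient_record()] objects.
#' @export
load_patients <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version)) {
    stop("not a trace file: missing schema_version", call. = FALSE)
  }
  if (!identical(as.character(doc$schema_version), SCHEMA_VERSION)) {
    stop("unsupported schema_version: ", doc$schema_version, call. = FALSE)
  }
  lapply(doc$patients, list_to_patient)
}

#' Write / read the CSV long-format alternative
#'
#' Two plain CSV files carry the same information as the JSON schema: a trace
#' table in long format (`patient_id`, `trace_type`, `view`, `wall`, `level`,
#' `segment_id`, `role`, `time_ms`, `value`) and a patient table with the
#' timing and clinical columns, one row per patient.
#'
#' @param patients List of [patient_record()] objects.
#' @param traces_path,patients_path Paths of the two CSV files.
#' @return For the writer, the two paths invisibly; for the reader, a list of
#'   [patient_record()] objects.
#' @export
write_patients_csv <- function(patients, traces_path, patients_path) {
  trows <- list()
  prows <- list()
  for (p in patients) {
    pl <- patient_to_list(p)
    for (tl in pl$traces) {
      trows[[length(trows) + 1L]] <- data.frame(
        patient_id = p$id, trace_type = "strain", view = tl$view,
        wall = tl$wall, level = tl$level, segment_id = tl$segment_id,
        role = tl$role, time_ms = tl$time_ms, value = tl$value,
        stringsAsFactors = FALSE)
    }
    if (!is.null(pl$velocity_traces)) {
      for (tl in pl$velocity_traces) {
        trows[[length(trows) + 1L]] <- data.frame(
          patient_id = p$id, trace_type = "velocity", view = tl$view,
          wall = tl$wall, level = tl$level, segment_id = tl$segment_id,
          role = NA_character_, time_ms = tl$time_ms, value = tl$value,
          stringsAsFactors = FALSE)
      }
    }
    prows[[length(prows) + 1L]] <- data.frame(
      id = p$id, qrs_onset = p$timing$qrs_onset, avc = p$timing$avc,
      aortic_preejection = p$timing$aortic_preejection,
      pulmonary_preejection = p$timing$pulmonary_preejection,
      lv_filling_time = p$timing$lv_filling_time, rr = p$timing$rr,
      lvesv_base = p$lvesv_base, lvesv_fu = p$lvesv_fu,
      lvedv_base = p$lvedv_base, lvedv_fu = p$lvedv_fu,
      lvef_base = p$lvef_base, lvef_fu = p$lvef_fu,
      nyha_base = p$nyha_base, nyha_fu = p$nyha_fu,
      septal_flash = p$septal_flash, qrs_ms = p$qrs_ms, lbbb = p$lbbb,
      upgrade = p$upgrade, stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, trows), traces_path, row.names = FALSE)
  utils::write.csv(do.call(rbind, prows), patients_path, row.names = FALSE)
  invisible(c(traces = traces_path, patients = patients_path))
}

#' @rdname write_patients_csv
#' @export
load_patients_csv <- function(traces_path, patients_path) {
  for (f in c(traces_path, patients_path)) {
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  tdf <- utils::read.csv(traces_path, stringsAsFactors = FALSE)
  pdf <- utils::read.csv(patients_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "trace_type", "view", "wall", "level", "segment_id",
            "role", "time_ms", "value")
  miss <- setdiff(need, names(tdf))
  if (length(miss)) {
    stop("trace table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(pdf)), function(i) {
    pr <- pdf[i, ]
    sub <- tdf[tdf$patient_id == pr$id, ]
    split_traces <- function(type) {
      ss <- sub[sub$trace_type == type, ]
      lapply(split(ss, ss$segment_id)[unique(ss$segment_id)], function(seg) {
        seg <- seg[order(seg$time_ms), ]
        list(view = seg$view[1L], wall = seg$wall[1L], level = seg$level[1L],
             segment_id = seg$segment_id[1L],
             role = if (is.na(seg$role[1L])) NULL else seg$role[1L],
             time_ms = seg$time_ms, value = seg$value)
      })
    }
    clin_names <- c("lvesv_base", "lvesv_fu", "lvedv_base", "lvedv_fu",
                    "lvef_base", "lvef_fu", "nyha_base", "nyha_fu",
                    "septal_flash", "qrs_ms", "lbbb", "upgrade")
    vel <- split_traces("velocity")
    list_to_patient(list(
      id = pr$id,
      timing = as.list(pr[c("qrs_onset", "avc", "aortic_preejection",
                            "pulmonary_preejection", "lv_filling_time", "rr")]),
      clinical = lapply(as.list(pr[clin_names]), function(x)
        if (is.na(x)) NULL else x),
      traces = unname(split_traces("strain")),
      velocity_traces = if (length(vel)) unname(vel) else NULL
    ))
  })
}

#' Run the full scoring and evaluation pipeline over a cohort
#'
#' For each patient: RSPI components per view and total, high/low class,
#' classical/heterogeneous pattern, dyssynchrony index panel and responder
#' status. At cohort level: the responder-by-high-RSPI 2x2 with its
#' diagnostic summary, the ROC of the RSPI total with the Youden-optimal
#' cutoff, and the univariate logistic regression of response on the
#' high-RSPI indicator. Deterministic given the inputs.
#'
#' @param patients List of [patient_record()] objects.
#' @param config A [scoring_config()].
#' @return List of class `rspi_pipeline`: `per_patient` (data.frame),
#'   `table` ([two_by_two()]), `diagnostics`, `roc`, `logistic`, `config`.
#'   Cohort elements are `NULL` when outcomes are absent or one-class.
#' @export
run_pipeline <- function(patients, config = scoring_config()) {
  if (!is.list(patients) || length(patients) == 0L) {
    stop("no patients", call. = FALSE)
  }
  rows <- lapply(patients, function(p) {
    r <- compute_rspi(p, config)
    pat <- classify_pattern(p, config)
    idx <- index_panel(p)
    bits <- lapply(r$per_view, component_bits)
    data.frame(
      id = p$id,
      c1_4ch = bits[["4CH"]][["c1"]], c2_4ch = bits[["4CH"]][["c2"]],
      c3_4ch = bits[["4CH"]][["c3"]], c4_4ch = bits[["4CH"]][["c4"]],
      c1_2ch = bits[["2CH"]][["c1"]], c2_2ch = bits[["2CH"]][["c2"]],
      c3_2ch = bits[["2CH"]][["c3"]], c4_2ch = bits[["2CH"]][["c4"]],
      c1_3ch = bits[["3CH"]][["c1"]], c2_3ch = bits[["3CH"]][["c2"]],
      c3_3ch = bits[["3CH"]][["c3"]], c4_3ch = bits[["3CH"]][["c4"]],
      rspi_total = r$total, rspi_high = r$high, pattern = pat$label,
      lvdft_rr = idx$lvdft_rr, ivmd = idx$ivmd, yu_index = idx$yu_index,
      max_time_delay = idx$max_time_delay,
      opposing_wall_delay = idx$opposing_wall_delay,
      septal_flash = idx$septal_flash,
      responder = idx$responder, delta_lvesv_pct = idx$delta_lvesv_pct,
      stringsAsFactors = FALSE
    )
  })
  per_patient <- do.call(rbind, rows)

  tab <- diag <- roc <- logi <- NULL
  have_outcome <- !all(is.na(per_patient$responder))
  if (have_outcome) {
    tab <- two_by_two_from_labels(per_patient$rspi_high, per_patient$responder)
    diag <- diagnostics(tab)
    both <- length(unique(stats::na.omit(per_patient$responder))) == 2L
    if (both) {
      roc <- roc_curve(per_patient$rspi_total, per_patient$responder)
      logi <- logistic_univariate(as.numeric(per_patient$rspi_high),
                                  per_patient$responder)
    }
  }
  structure(list(per_patient = per_patient, table = tab, diagnostics = diag,
                 roc = roc, logistic = logi, config = config),
            class = "rspi_pipeline")
}

#' @export
print.rspi_pipeline <- function(x, ...) {
  cat(sprintf("rspi pipeline: %d patients, %d high-RSPI, %d classical pattern\n",
              nrow(x$per_patient), sum(x$per_patient$rspi_high),
              sum(x$per_patient$pattern == "classical")))
  if (!is.null(x$diagnostics)) print(x$diagnostics)
  if (!is.null(x$roc)) print(x$roc)
  invisible(x)
}
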