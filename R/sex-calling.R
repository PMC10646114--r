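#' Thresholds for peptide-based sex calling
#'
#' The decision logic works on apex intensities of marker XIC peaks. A
#' sample with any AMELY-specific detection is male. Without AMELY, the
#' maximum AMELX apex decides between a confident female call (at or above
#' `female_min_amelx`; published female cohorts sit at ~1e6-1e7 counts), a
#' cautious "probable female" (between `weak_floor` and `female_min_amelx`;
#' attenuated AMELX at ~1e5 counts can reflect taphonomic peptide loss or,
#' rarely, AMELY deletion in a male) and undetermined (below `weak_floor`).
#' The 1e6 boundary interpolates between the published female band and the
#' single published ambiguous case; it is configuration, not a constant.
#'
#' @param female_min_amelx minimum AMELX apex intensity (counts) for a
#'   confident female call (default 1e6).
#' @param weak_floor minimum AMELX apex intensity for a probable-female call
#'   (default 1e4); must be below `female_min_amelx`.
#' @param tol_ppm XIC extraction half-width in ppm (default 5).
#' @param min_abs_intensity,min_snr,noise_floor peak-detection settings
#'   passed to [detectPeak()].
#' @return a named list of thresholds (class `"callThresholds"`).
#' @export
callThresholds <- function(female_min_amelx = 1e6, weak_floor = 1e4,
                           tol_ppm = 5, min_abs_intensity = 1e4,
                           min_snr = 3, noise_floor = 1) {
  if (weak_floor >= female_min_amelx)
    stop("weak_floor must be below female_min_amelx", call. = FALSE)
  structure(list(female_min_amelx = female_min_amelx,
                 weak_floor = weak_floor, tol_ppm = tol_ppm,
                 min_abs_intensity = min_abs_intensity, min_snr = min_snr,
                 noise_floor = noise_floor),
            class = "callThresholds")
}

#' Evaluate all panel markers on one run
#'
#' Extracts one XIC per panel marker, runs peak detection, and aggregates
#' the evidence the sex call is based on: whether any AMELY-specific marker
#' was detected, the maximum apex intensity over detected AMELX-specific
#' markers (0 if none), and the number of detected non-sex-diagnostic
#' (shared / enamelin) markers as a preservation indicator.
#'
#' @param run an [MSRun-class].
#' @param panel a [MarkerPanel-class].
#' @param thresholds a [callThresholds()] list.
#' @return list with elements `sample_id`, `peaks` (one row per marker, as
#'   from [detectPeak()]), `amely_detected`, `amelx_max_intensity`,
#'   `preservation_markers_detected`.
#' @export
evaluateMarkers <- function(run, panel = defaultPanel(),
                            thresholds = callThresholds()) {
  stopifnot(is(run, "MSRun"), is(panel, "MarkerPanel"))
  m <- markerTable(panel)
  traces <- .xicTraces(run, panel, tol_ppm = thresholds$tol_ppm)
  peaks <- do.call(rbind, lapply(traces, detectPeak,
                                 min_abs_intensity = thresholds$min_abs_intensity,
                                 min_snr = thresholds$min_snr,
                                 noise_floor = thresholds$noise_floor))
  amely <- m$specificity == "AMELY" & m$role == "sex_diagnostic"
  amelx <- m$specificity == "AMELX" & m$role == "sex_diagnostic"
  other <- m$role %in% c("shared_corroboration", "preservation_qc")
  x_hit <- peaks$detected & amelx
  list(sample_id = sampleId(run),
       peaks = peaks,
       amely_detected = any(peaks$detected & amely),
       amelx_max_intensity = if (any(x_hit)) max(peaks$apex_intensity[x_hit]) else 0,
       preservation_markers_detected = sum(peaks$detected & other))
}

#' Categorical sex call from marker evidence
#'
#' Male if any AMELY-specific peptide was detected; otherwise female when
#' the strongest AMELX apex reaches `female_min_amelx`; otherwise probable
#' female when it reaches `weak_floor` (low AMELX can reflect degradation
#' or AMELY deletion, so the call stays cautious); otherwise undetermined.
#'
#' @param evidence result of [evaluateMarkers()].
#' @param thresholds a [callThresholds()] list.
#' @return one-row data.frame: `sample_id`, `call` (one of `"male"`,
#'   `"female"`, `"probable_female"`, `"undetermined"`), `amely_detected`,
#'   `amelx_max_intensity`, `preservation_markers_detected`, `rationale`.
#' @export
callSex <- function(evidence, thresholds = callThresholds()) {
  stopifnot(is.list(evidence), !is.null(evidence$amelx_max_intensity))
  amelx <- evidence$amelx_max_intensity
  if (isTRUE(evidence$amely_detected)) {
    call <- "male"
    why <- "AMELY-specific peptide detected"
  } else if (amelx >= thresholds$female_min_amelx) {
    call <- "female"
    why <- sprintf("no AMELY; AMELX apex %.3g >= %.3g", amelx,
                   thresholds$female_min_amelx)
  } else if (amelx >= thresholds$weak_floor) {
    call <- "probable_female"
    why <- sprintf(
      "no AMELY; weak AMELX apex %.3g (degradation or AMELY deletion possible)",
      amelx)
  } else {
    call <- "undetermined"
    why <- "no AMELY and no usable AMELX signal"
  }
  data.frame(sample_id = evidence$sample_id, call = call,
             amely_detected = isTRUE(evidence$amely_detected),
             amelx_max_intensity = amelx,
             preservation_markers_detected =
               evidence$preservation_markers_detected,
             rationale = why, stringsAsFactors = FALSE)
}

#' Extraction-blank quality control
#'
#' A clean extraction blank must show no detectable peak for any panel
#' marker. Failure lists the detected markers; batch results are flagged,
#' not discarded, on failure.
#'
#' @param blank_run the blank's [MSRun-class].
#' @inheritParams evaluateMarkers
#' @return list with `pass` (logical) and `detected_markers` (character).
#' @export
qcBlank <- function(blank_run, panel = defaultPanel(),
                    thresholds = callThresholds()) {
  ev <- evaluateMarkers(blank_run, panel, thresholds)
  hits <- ev$peaks$marker_label[ev$peaks$detected]
  list(pass = length(hits) == 0L, detected_markers = hits)
}

#' Sex-call a batch of runs with blank QC
#'
#' Calls every run against the panel, attaches per-marker apex intensities,
#' summarises call counts, and evaluates the extraction blank when given.
#'
#' @param runs list of [MSRun-class] objects with unique sample ids.
#' @param blank optional blank [MSRun-class] for QC.
#' @inheritParams evaluateMarkers
#' @return list with `calls` (data.frame, one row per run: call columns
#'   plus one `apex_<label>` column per marker), `summary` (named counts of
#'   the four call categories) and `qc` (from [qcBlank()], or `NULL`).
#' @export
callBatch <- function(runs, blank = NULL, panel = defaultPanel(),
                      thresholds = callThresholds()) {
  ids <- vapply(runs, sampleId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  m <- markerTable(panel)
  rows <- lapply(runs, function(run) {
    ev <- evaluateMarkers(run, panel, thresholds)
    row <- callSex(ev, thresholds)
    apex <- ev$peaks$apex_intensity
    apex[!ev$peaks$detected] <- NA_real_
    apx <- as.data.frame(as.list(apex))
    names(apx) <- paste0("apex_", m$label)
    cbind(row, apx)
  })
  calls <- do.call(rbind, rows)
  if (!is.null(calls)) rownames(calls) <- NULL
  cats <- c("male", "female", "probable_female", "undetermined")
  summary <- if (is.null(calls)) stats::setNames(integer(4), cats) else
    vapply(cats, function(k) sum(calls$call == k), integer(1))
  qc <- if (!is.null(blank)) qcBlank(blank, panel, thresholds) else NULL
  if (!is.null(calls))
    calls$qc_flag <- if (is.null(qc) || isTRUE(qc$pass)) "pass" else "fail"
  list(calls = calls, summary = summary, qc = qc)
}
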